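test_that("fold-change filter keeps domains at or above threshold", {
    isl <- simplePeaks("chr1", c(1000L, 3000L, 5000L), c(2000L, 4000L, 6000L),
                       foldChange = c(3.0, 1.9, 2.0))
    kept <- foldChangeFilter(isl, 2.0)
    expect_equal(mcols(kept)$foldChange, c(3.0, 2.0))
    # idempotent subset
    expect_equal(length(foldChangeFilter(kept, 2.0)), length(kept))
})

test_that("fold-change fallback uses library-scaled counts and pseudocount", {
    isl <- simplePeaks("chr1", c(1000L, 3000L), c(2000L, 4000L))
    mcols(isl)$ipCount <- c(30, 10)
    mcols(isl)$ctrlCount <- c(0, 40)
    # equal library sizes; ctrl=0 -> pseudocount 1 -> FC 30
    kept <- foldChangeFilter(isl, 2.0, ipTotal = 1e6, ctrlTotal = 1e6)
    expect_equal(mcols(kept)$ipCount, 30)
    expect_error(foldChangeFilter(simplePeaks("chr1", 1L, 10L), 2.0),
                 "neither")
})

test_that("top-peak selection takes ceil(f*n) by descending score", {
    set.seed(2)
    pk <- simplePeaks("chr1", seq(1000L, by = 1000L, length.out = 20L),
                      seq(1200L, by = 1000L, length.out = 20L),
                      negLog10P = sample(seq(1, 20)))
    top <- selectTopPeaks(pk, "fraction", 0.1)
    expect_equal(length(top), 2L)
    expect_equal(sort(mcols(top)$negLog10P, decreasing = TRUE),
                 c(20, 19))
    # score cutoff keeps exactly p <= 1e-5
    cut <- selectTopPeaks(pk, "score_cutoff", 5)
    expect_equal(length(cut), sum(mcols(pk)$negLog10P >= 5))
    # all-tied scores fall back to coordinate order
    tied <- simplePeaks("chr1", c(4000L, 1000L, 3000L, 2000L),
                        c(4100L, 1100L, 3100L, 2100L), negLog10P = 7)
    half <- selectTopPeaks(tied, "fraction", 0.5)
    expect_equal(start(half), c(1000L, 2000L))
})

test_that("peak-set overlap counts shared-base contacts both ways", {
    a <- simplePeaks("chr1", c(1L, 201L), c(100L, 300L))
    b <- simplePeaks("chr1", 51L, 80L)
    rep <- comparePeakSets(a, b)
    expect_equal(rep@overlappedA, 1L)
    expect_equal(rep@nA - rep@overlappedA, 1L)  # unique_a
    expect_equal(rep@pctA, 50.0)
    expect_equal(rep@pctB, 100.0)
    # identical sets overlap fully both ways
    idr <- comparePeakSets(a, a)
    expect_equal(c(idr@pctA, idr@pctB), c(100, 100))
    # bookends (0 shared bases) do not count
    c1 <- simplePeaks("chr1", 1L, 100L)
    c2 <- simplePeaks("chr1", 101L, 200L)
    expect_equal(comparePeakSets(c1, c2)@overlappedA, 0L)
})

test_that("peak-set overlap matches the brute-force pairwise oracle", {
    set.seed(13)
    for (rep in 1:3) {
        nA <- 120L; nB <- 100L
        mk <- function(n) {
            st <- sample.int(50000L, n)
            simplePeaks(sample(c("chr1", "chr2"), n, TRUE), st,
                        st + sample.int(300L, n, TRUE))
        }
        a <- mk(nA); b <- mk(nB)
        got <- comparePeakSets(a, b)
        overA <- 0L
        for (i in seq_len(nA)) {
            hit <- FALSE
            for (j in seq_len(nB))
                if (as.character(seqnames(a))[i] ==
                    as.character(seqnames(b))[j] &&
                    start(a)[i] <= end(b)[j] && start(b)[j] <= end(a)[i])
                    hit <- TRUE
            overA <- overA + hit
        }
        expect_equal(got@overlappedA, overA)
    }
})

test_that("peaks are assigned to genes within 10 kb of TSS or TES", {
    g <- c(chr1 = 1000000L)
    genes <- simpleGenes("chr1", c(50001L, 120001L), c(60000L, 130000L),
                         strand = c("+", "+"), id = c("gA", "gB"),
                         genome = g)
    # peak center 9 kb upstream of gA's TSS (0-based TSS 50000)
    pk <- simplePeaks("chr1", 40951L, 41050L, genome = g)  # center0 41000
    asn <- assignPeaksToGenes(pk, genes, 10000L)
    expect_equal(asn$gene, "gA")
    expect_equal(asn$anchor, "TSS")
    expect_equal(asn$distance, -9000L)
    expect_true(asn$is_closest)
    # 15 kb away from both anchors of any gene: no assignment
    far <- simplePeaks("chr1", 75001L, 75100L, genome = g)  # center0 75050
    expect_equal(nrow(assignPeaksToGenes(far, genes, 10000L)), 0L)
})

test_that("nearest gene is flagged and ties flag all", {
    g <- c(chr1 = 1000000L)
    # TSSs 2 kb and 5 kb from the peak center (0-based center 100000)
    genes <- simpleGenes("chr1", c(102001L, 105001L), c(103000L, 106000L),
                         strand = c("+", "+"), id = c("near", "farr"),
                         genome = g)
    pk <- simplePeaks("chr1", 99951L, 100050L, genome = g)
    asn <- assignPeaksToGenes(pk, genes, 10000L)
    expect_equal(nrow(asn), 2L)
    expect_equal(asn$gene[asn$is_closest], "near")
    # equidistant genes are both flagged, in id order
    eq <- simpleGenes("chr1", c(102001L, 95001L), c(103000L, 98001L),
                      strand = c("+", "-"), id = c("zz", "aa"), genome = g)
    asn2 <- assignPeaksToGenes(pk, eq, 10000L)
    expect_equal(asn2$gene[asn2$is_closest], c("aa", "zz"))
    # stored distances recompute exactly from stored coordinates
    center0 <- (asn2$peak_start + asn2$peak_end) %/% 2L
    expect_equal(abs(asn2$distance), abs(center0 - 102000L) * c(1L, 1L))
})

test_that("empty gene list warns and returns no assignments", {
    pk <- simplePeaks("chr1", 100L, 200L)
    expect_warning(asn <- assignPeaksToGenes(pk, GRanges(id = character(0))),
                   "empty gene list")
    expect_equal(nrow(asn), 0L)
})

test_that("center windows are centered, fixed-width and clipped", {
    g <- c(chr1 = 100000L)
    # peak 0-based [100, 300) -> window [150, 250)
    pk <- simplePeaks("chr1", 101L, 300L, genome = g)
    w <- centerWindows(pk, 100L)
    expect_equal(c(start(w) - 1L, end(w)), c(150L, 250L))
    expect_equal(width(w), 100L)
    # peak at the chromosome start clips to [0, 55)
    edge <- simplePeaks("chr1", 1L, 10L, genome = g)
    we <- centerWindows(edge, 100L)
    expect_equal(c(start(we) - 1L, end(we)), c(0L, 55L))
    expect_error(centerWindows(pk, 99L), "even")
})
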