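test_that("regulatory domains mirror strand and keep proximal inside", {
    g <- c(chr1 = 1000000L)
    # + gene, 0-based TSS 10000, U=5000 D=1000 -> [5000, 11000)
    plus <- simpleGenes("chr1", 10001L, 12000L, "+", "gP", genome = g)
    d <- buildDomains(plus, U = 5000L, D = 1000L)
    expect_equal(c(start(d) - 1L, end(d)), c(5000L, 11000L))
    # - gene, 0-based TSS 10000 -> [9000, 15000)
    minus <- simpleGenes("chr1", 8001L, 10001L, "-", "gM", genome = g)
    dm <- buildDomains(minus, U = 5000L, D = 1000L)
    expect_equal(c(start(dm) - 1L, end(dm)), c(9000L, 15000L))
    # extension is truncated at a neighbour's proximal domain and never
    # shrinks the gene's own proximal domain
    two <- simpleGenes("chr1", c(10001L, 14001L), c(12000L, 16000L),
                       c("+", "+"), c("g1", "g2"), genome = g)
    dt <- buildDomains(two, U = 5000L, D = 1000L, UE = 10000L, DE = 10000L)
    # g2's proximal starts at 9000, inside g1's proximal [5000,11000): g1
    # gains no downstream extension; upstream is unobstructed and extends
    # the full 10 kb (clipped at the chromosome start)
    expect_equal(c(start(dt)[1] - 1L, end(dt)[1]), c(0L, 11000L))
    # g1's proximal blocks g2's upstream extension symmetrically
    expect_equal(start(dt)[2] - 1L, 9000L)
    # upstream of g1 there is no neighbour: full 10 kb extension
    expect_equal(start(buildDomains(two[1], U = 5000L, D = 1000L,
                                    UE = 10000L, DE = 0L)) - 1L, 0L)
    # proximal recorded inside extended
    expect_true(all(mcols(dt)$proximal_start >= start(dt) &
                    mcols(dt)$proximal_end <= end(dt)))
})

test_that("domain union length matches per-base membership on a toy genome", {
    set.seed(21)
    g <- c(chr1 = 100000L)
    st <- sort(sample(seq(5000L, 90000L, by = 3000L), 12L))
    genes <- simpleGenes("chr1", st, st + 1500L,
                         sample(c("+", "-"), 12L, TRUE),
                         genome = g)
    dom <- buildDomains(genes, U = 5000L, D = 1000L, UE = 2000L,
                        DE = 2000L)
    base <- logical(100000L)
    for (i in seq_along(dom))
        base[start(dom)[i]:end(dom)[i]] <- TRUE
    expect_equal(sum(GenomicRanges::width(
        GenomicRanges::reduce(dom, ignore.strand = TRUE))), sum(base))
})

test_that("binomial tail reproduces the hand-summed example", {
    g <- c(chr1 = 1000L)
    # one gene whose extended domain covers exactly 100 bp of a 1 kb genome
    gene <- simpleGenes("chr1", 501L, 540L, "+", "g1", genome = g)
    dom <- buildDomains(gene, U = 50L, D = 50L)   # 0-based [450, 550)
    expect_equal(sum(GenomicRanges::width(dom)), 100L)
    ann <- data.frame(gene = "g1", term = "T1")
    # 5 peaks, 3 centers inside the domain
    pk <- simplePeaks("chr1", c(461L, 481L, 501L, 701L, 901L),
                      c(480L, 500L, 520L, 720L, 920L), genome = g)
    res <- binomialEnrichment(pk, dom, ann, denominator = "genome")
    expect_equal(res$k, 3L)
    expect_equal(res$p_term, 0.1)
    # P[Bin(5, 0.1) >= 3] = 0.0081 + 0.00045 + 0.00001 = 0.00856
    expect_equal(res$p_value, 0.00856, tolerance = 1e-10)
})

test_that("binomial tail equals exhaustive outcome enumeration (n <= 12)", {
    for (case in list(c(n = 5, p = 0.1, k = 3), c(n = 12, p = 0.3, k = 7),
                      c(n = 8, p = 0.5, k = 0), c(n = 10, p = 0.02, k = 2))) {
        n <- case[["n"]]; p <- case[["p"]]; k <- case[["k"]]
        # oracle: walk all 2^n success/failure outcomes
        tail <- 0
        for (mask in 0:(2^n - 1)) {
            s <- sum(bitwAnd(mask, 2^(0:(n - 1))) > 0)
            if (s >= k) tail <- tail + p^s * (1 - p)^(n - s)
        }
        got <- if (k == 0) 1 else pbinom(k - 1, n, p, lower.tail = FALSE)
        expect_equal(got, tail, tolerance = 1e-12)
    }
})

test_that("degenerate enrichment inputs hit the certain cases", {
    g <- c(chr1 = 10000L)
    gene <- simpleGenes("chr1", 5001L, 6000L, "+", "g1", genome = g)
    dom <- buildDomains(gene, U = 100L, D = 100L)
    ann <- data.frame(gene = "g1", term = "T1")
    # no peak center in the domain -> p = 1
    far <- simplePeaks("chr1", c(101L, 201L), c(120L, 220L), genome = g)
    expect_equal(binomialEnrichment(far, dom, ann,
                                    denominator = "genome")$p_value, 1)
    # p_term = 1 (annotatable denominator, single term covers it all)
    inpk <- simplePeaks("chr1", 4951L, 5050L, genome = g)
    res <- binomialEnrichment(inpk, dom, ann, denominator = "annotatable")
    expect_equal(res$p_term, 1)
    expect_equal(res$p_value, 1)
})

test_that("BH adjustment follows the step-up rule", {
    expect_equal(bhFdr(c(0.01, 0.02, 0.03)), c(0.03, 0.03, 0.03))
    expect_equal(bhFdr(0.2), 0.2)
    expect_equal(bhFdr(rep(0.05, 4)), rep(0.05, 4))
    expect_error(bhFdr(c(0.5, 1.2)), "\\[0, 1\\]")
})

test_that("a strongly enriched term ranks first on synthetic data", {
    hits <- 0L
    for (seed in 1:5) {
        cfg <- simulationConfig(seed = seed, nPeaks = 250L, nGenes = 60L,
                                nTerms = 6L, termEnrichment = 10)
        ann <- simulateAnnotation(cfg)
        pk <- simulateTermPeaks(ann, cfg)
        genes <- ann$genes[mcols(ann$genes)$id %in% ann$annotations$gene]
        doms <- buildDomains(genes)
        res <- binomialEnrichment(pk, doms, ann$annotations,
                                  denominator = "genome")
        hits <- hits + (res$term[1L] == ann$enrichedTerm)
    }
    expect_gte(hits, 4L)
})
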