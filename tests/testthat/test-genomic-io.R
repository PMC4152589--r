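test_that("SAM ingestion converts coordinates and decodes flags", {
    sam <- tinySAM(c(
        samLine("r1", 0L, "chr1", 1L, 60L),
        samLine("r2", 99L, "chr1", 101L, 37L, rnext = "=", pnext = 265L,
                tlen = 200L),
        samLine("r3", 16L, "chr1", 51L, 0L),
        "r4\t4\t*\t0\t0\t*\t*\t0\t0\t*\t*"))
    rs <- readSAM(sam)
    gr <- mappedReads(rs)
    expect_s4_class(rs, "ReadSet")
    expect_equal(length(gr), 3L)
    expect_equal(unmappedCount(rs), 1L)
    # POS=1 CIGAR=36M -> 0-based [0, 36) i.e. 1-based [1, 36]
    expect_equal(start(gr)[1], 1L)
    expect_equal(end(gr)[1], 36L)
    # FLAG 99: paired, proper, first-in-pair, plus strand
    m <- mcols(gr)
    expect_true(m$isPaired[2] && m$isProper[2] && m$isFirst[2])
    expect_equal(as.character(strand(gr))[2], "+")
    expect_equal(m$tlen[2], 200L)
    # FLAG 16: minus strand; MAPQ 0 retained as the multi-map placeholder
    expect_equal(as.character(strand(gr))[3], "-")
    expect_equal(m$mapq[3], 0L)
    # genome table from @SQ
    expect_equal(unname(GenomeInfoDb::seqlengths(genomeTable(rs))["chr1"]),
                 1000L)
})

test_that("SAM round-trip through writeSAM preserves alignments", {
    reads <- makeReads("chr1", c(10L, 500L, 999L), width = 36L,
                       strand = c("+", "-", "+"), mapq = c(60L, 0L, 20L),
                       genome = c(chr1 = 2000L))
    path <- tempfile(fileext = ".sam")
    writeSAM(reads, path)
    back <- mappedReads(readSAM(path))
    expect_equal(start(back), start(reads))
    expect_equal(end(back), end(reads))
    expect_equal(as.character(strand(back)), as.character(strand(reads)))
    expect_equal(mcols(back)$mapq, mcols(reads)$mapq)
    expect_equal(mcols(back)$qname, mcols(reads)$qname)
})

test_that("missing @SQ header is an explicit error", {
    path <- tempfile(fileext = ".sam")
    writeLines(c("@HD\tVN:1.6", samLine("r1", 0L, "chr1", 1L, 60L)), path)
    expect_error(readSAM(path), "@SQ|parse")
})

test_that("peak dialects map their columns", {
    # encodePeak: 10 columns, col8 is -log10 p
    ep <- tempfile()
    writeLines(c("chr1\t100\t300\tpeakA\t500\t.\t8.5\t5.30103\t3.2\t100",
                 "chr1\t400\t500\t0.005\t200\t.\t4.0\t9.1\t6.0\t50"), ep)
    pk <- readPeaks(ep, "encodePeak")
    expect_equal(start(pk), c(101L, 401L))
    expect_equal(mcols(pk)$negLog10P[1], 5.30103)
    # dual-use column 4: verbatim name plus numeric parse
    expect_equal(mcols(pk)$name, c("peakA", "0.005"))
    expect_equal(mcols(pk)$idr[2], 0.005)
    expect_true(is.na(mcols(pk)$idr[1]))

    # SICER island summary: 8 columns with fold change and raw FDR
    sc <- tempfile()
    writeLines("chr1\t0\t2000\t120\t40\t1e-10\t1.5\t1e-8", sc)
    isl <- readPeaks(sc, "sicer_summary")
    expect_equal(mcols(isl)$foldChange, 1.5)
    expect_equal(mcols(isl)$negLog10Fdr, 8)
    expect_equal(mcols(isl)$ipCount, 120)

    # bare BED3: absent scores, unstranded
    b3 <- tempfile()
    writeLines("chr1\t10\t20", b3)
    bp <- readPeaks(b3, "bed")
    expect_true(is.na(mcols(bp)$score))
    expect_equal(as.character(strand(bp)), "*")

    # dialect / parse errors
    expect_error(readPeaks(sc, "encodePeak"), "10 columns")
    bad <- tempfile()
    writeLines("chr1\t10\t20\tx\tNOTNUM\t.\t1\t2\t3\t-1", bad)
    expect_error(readPeaks(bad, "encodePeak"), "non-numeric")
})

test_that("peak writer emits 0-based encodePeak that round-trips", {
    pk <- simplePeaks("chr1", c(101L, 401L), c(300L, 500L),
                      negLog10P = c(5.5, 2.25))
    mcols(pk)$idr <- c(0.005, NA)
    out <- tempfile()
    writePeaks(pk, out, "encodePeak")
    fields <- strsplit(readLines(out), "\t")
    expect_equal(fields[[1]][2], "100")       # back to 0-based
    expect_equal(fields[[1]][4], "0.005")     # IDR in the name column
    expect_equal(fields[[2]][4], "pk2")
    back <- readPeaks(out, "encodePeak")
    expect_equal(start(back), start(pk))
    expect_equal(mcols(back)$negLog10P, mcols(pk)$negLog10P)
    expect_equal(mcols(back)$idr[1], 0.005)
})

test_that("bedGraph output omits zero runs and round-trips exactly", {
    si <- GenomeInfoDb::Seqinfo("chr1", 1000L)
    frags <- GRanges("chr1", IRanges(1L, 100L), seqinfo = si)
    track <- coverageFromFragments(frags)
    path <- tempfile(fileext = ".bedgraph")
    writeTrack(track, path, "bedgraph")
    body <- grep("^track", readLines(path), invert = TRUE, value = TRUE)
    expect_equal(body, "chr1\t0\t100\t1")

    # multiset round-trip on a layered track
    frags2 <- GRanges("chr1", IRanges(c(1L, 51L, 400L), c(100L, 150L, 420L)),
                      seqinfo = si)
    t2 <- coverageFromFragments(frags2)
    p2 <- tempfile()
    writeTrack(t2, p2, "bedgraph")
    back <- readBedGraph(p2, si = si)
    t3 <- new("CoverageTrack",
              coverage = GenomicRanges::coverage(back, weight = "score",
                                                 width = as.list(c(chr1 = 1000L))),
              seqinfo = si, normalized = FALSE, librarySize = NA_real_)
    expect_equal(as.numeric(t3@coverage$chr1), as.numeric(t2@coverage$chr1))
})

test_that("Wig output is fixedStep with span = step", {
    si <- GenomeInfoDb::Seqinfo("chr1", 100L)
    track <- coverageFromFragments(
        GRanges("chr1", IRanges(1L, 100L), seqinfo = si))
    t4 <- new("CoverageTrack", coverage = track@coverage * 4L,
              seqinfo = si, normalized = FALSE, librarySize = NA_real_)
    path <- tempfile(fileext = ".wig")
    writeTrack(t4, path, "wig", step = 20L)
    lines <- readLines(path)
    expect_match(lines[2], "fixedStep chrom=chr1 start=1 step=20 span=20")
    expect_equal(as.numeric(lines[3:7]), rep(4, 5))
    expect_equal(length(lines), 7L)
})

test_that("an empty track writes a valid header-only file", {
    si <- GenomeInfoDb::Seqinfo("chr1", 1000L)
    empty <- coverageFromFragments(GRanges(seqinfo = si))
    p <- tempfile()
    writeTrack(empty, p, "bedgraph")
    expect_equal(length(readLines(p)), 1L)
    writeTrack(empty, p, "wig")
    expect_equal(length(readLines(p)), 1L)
})

test_that("sequence windows are fetched verbatim and bounds-checked", {
    fa <- tempfile(fileext = ".fa")
    writeLines(c(">chrT something", "acgtACGT"), fa)
    # 0-based [2, 6) is 1-based [3, 6]
    expect_equal(fetchSequence(fa, "chrT", 3L, 6L), "GTAC")
    expect_equal(fetchSequence(fa, "chrT", 5L, 4L), "")
    expect_error(fetchSequence(fa, "chrT", 5L, 12L), "outside")
    expect_error(fetchSequence(fa, "chrX", 1L, 2L), "not found")
})

test_that("chrom.sizes tables become a Seqinfo", {
    p <- tempfile()
    writeLines(c("chr1\t1000", "chr2\t500"), p)
    si <- readChromSizes(p)
    expect_equal(unname(GenomeInfoDb::seqlengths(si)), c(1000L, 500L))
    bad <- tempfile()
    writeLines("chr1\t0", bad)
    expect_error(readChromSizes(bad), "> 0")
})
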