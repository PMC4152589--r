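test_that("pair classification follows the MAPQ-0 multi-map convention", {
    pairs <- makePairs("chr1", c(100L, 200L, 300L), "chr1",
                       c(260L, 360L, 460L),
                       mapq1 = c(60L, 30L, 0L), mapq2 = c(37L, 0L, 0L))
    expect_equal(as.character(classifyPairs(pairs)),
                 c("both_unique", "one_unique", "both_multi"))
})

test_that("single-end MAPQ filter keeps the boundary value", {
    reads <- makeReads("chr1", c(100L, 200L, 300L), mapq = c(19L, 20L, 0L))
    kept <- filterMapqSingle(reads, 20L)
    expect_equal(mcols(kept)$mapq, 20L)
    expect_equal(length(filterMapqSingle(reads, 0L)), 3L)
    # the random-match option exempts MAPQ-0 placements
    expect_equal(mcols(filterMapqSingle(reads, 20L, exemptMapq0 = TRUE))$mapq,
                 c(20L, 0L))
})

test_that("pair MAPQ filter drops whole pairs, with the both-zero exemption", {
    pairs <- makePairs("chr1", c(100L, 200L, 300L), "chr1",
                       c(260L, 360L, 460L),
                       mapq1 = c(5L, 60L, 0L), mapq2 = c(60L, 45L, 0L))
    expect_equal(length(filterMapqPairs(pairs, 20L)), 1L)
    kept <- filterMapqPairs(pairs, 20L, keepMultiBothZero = TRUE)
    expect_equal(length(kept), 2L)
    expect_equal(mcols(firstMate(kept))$mapq, c(60L, 0L))
})

test_that("pair filters never break pairing", {
    set.seed(11)
    n <- 60L
    pairs <- makePairs("chr1", sample.int(5000L, n), "chr1",
                       sample.int(5000L, n),
                       mapq1 = sample(c(0L, 5L, 30L, 60L), n, TRUE),
                       mapq2 = sample(c(0L, 5L, 30L, 60L), n, TRUE),
                       strand1 = sample(c("+", "-"), n, TRUE),
                       strand2 = sample(c("+", "-"), n, TRUE))
    for (out in list(filterMapqPairs(pairs, 20L),
                     filterProperPairs(pairs),
                     applyMultimapPolicy(pairs, "one_end_unique"))) {
        qn <- c(mcols(firstMate(out))$qname, mcols(secondMate(out))$qname)
        expect_true(all(table(qn) == 2L))
    }
})

test_that("proper-pair filter enforces chromosome, orientation, insert", {
    # FR insert 200 within [1,1000]
    ok <- makePairs("chr1", 100L, "chr1", 264L)
    expect_equal(length(filterProperPairs(ok)), 1L)
    # RR orientation rejected
    rr <- makePairs("chr1", 100L, "chr1", 264L, strand1 = "-",
                    strand2 = "-")
    expect_equal(length(filterProperPairs(rr)), 0L)
    # cross-chromosome rejected
    cross <- makePairs("chr1", 100L, "chr2", 264L, tlen = 0L)
    expect_equal(length(filterProperPairs(cross)), 0L)
    # insert bounds inclusive
    expect_equal(length(filterProperPairs(ok, minInsert = 200L,
                                          maxInsert = 200L)), 1L)
    expect_equal(length(filterProperPairs(ok, minInsert = 201L,
                                          maxInsert = 1000L)), 0L)
})

test_that("multi-mapper policies keep the documented class unions", {
    mapq1 <- c(rep(60L, 10L), rep(30L, 5L), rep(0L, 3L))
    mapq2 <- c(rep(50L, 10L), rep(0L, 5L), rep(0L, 3L))
    n <- length(mapq1)
    pairs <- makePairs("chr1", seq(100L, by = 500L, length.out = n),
                       "chr1", seq(300L, by = 500L, length.out = n),
                       mapq1 = mapq1, mapq2 = mapq2)
    expect_equal(length(applyMultimapPolicy(pairs, "unique_only")), 10L)
    expect_equal(length(applyMultimapPolicy(pairs, "one_end_unique")), 15L)
    expect_equal(length(applyMultimapPolicy(pairs,
                                            "one_end_unique_plus_random")),
                 18L)
})

test_that("duplicate marking keys on chrom, 5' position and strand", {
    # three reads with the same + strand 5' end: one representative
    reads <- makeReads("chr1", c(100L, 100L, 100L), mapq = c(10L, 60L, 30L))
    marked <- markDuplicates(reads)
    expect_equal(sum(!mcols(marked)$isDuplicate), 1L)
    expect_equal(which(!mcols(marked)$isDuplicate), 2L)  # highest MAPQ wins

    # same span, opposite strands: different 5' keys, both kept
    rev <- makeReads("chr1", c(100L, 100L), strand = c("+", "-"))
    expect_equal(sum(mcols(markDuplicates(rev))$isDuplicate), 0L)

    # ties by input order
    tie <- makeReads("chr1", c(100L, 100L), mapq = c(30L, 30L))
    expect_equal(which(!mcols(markDuplicates(tie))$isDuplicate), 1L)

    # PE: identical outer coordinates collapse to one pair
    pairs <- makePairs("chr1", c(100L, 100L, 400L), "chr1",
                       c(264L, 264L, 564L))
    mk <- markDuplicates(pairs)
    expect_equal(sum(!mcols(firstMate(mk))$isDuplicate), 2L)
})

test_that("duplicate marking is idempotent and matches brute force", {
    set.seed(42)
    for (rep in 1:3) {
        n <- 200L
        reads <- makeReads(sample(c("chr1", "chr2"), n, TRUE),
                           sample.int(40L, n, TRUE),
                           strand = sample(c("+", "-"), n, TRUE),
                           mapq = sample.int(60L, n, TRUE),
                           genome = c(chr1 = 1000L, chr2 = 1000L))
        marked <- markDuplicates(reads)
        # brute-force oracle: all-pairs key comparison, representative is
        # highest MAPQ then earliest input index
        fp <- ifelse(as.character(strand(reads)) == "+",
                     start(reads), end(reads))
        key <- paste(as.character(seqnames(reads)), fp,
                     as.character(strand(reads)))
        expectDup <- logical(n)
        for (i in seq_len(n)) {
            grp <- which(key == key[i])
            best <- grp[which.max(mcols(reads)$mapq[grp])]
            expectDup[i] <- i != best
        }
        expect_equal(mcols(marked)$isDuplicate, expectDup)
        expect_equal(mcols(markDuplicates(marked))$isDuplicate, expectDup)
        expect_equal(length(dedup(marked)), length(unique(key)))
    }
})

test_that("raising the MAPQ cutoff never adds survivors", {
    set.seed(5)
    reads <- makeReads("chr1", sample.int(5000L, 150L),
                       mapq = sample(0:60, 150L, TRUE))
    prev <- mcols(filterMapqSingle(reads, 0L))$qname
    for (ct in c(1L, 10L, 20L, 30L, 61L)) {
        cur <- mcols(filterMapqSingle(reads, ct))$qname
        expect_true(all(cur %in% prev))
        prev <- cur
    }
})

test_that("library complexity reproduces the worked ratio", {
    # 22.27 M uniquely mapped, 16.9 M after duplicate filtering
    cx <- libraryComplexity(22.27e6, 16.9e6)
    expect_equal(cx@complexity, 16.9 / 22.27, tolerance = 1e-12)
    expect_equal(round(cx@complexity, 3), 0.759)
    expect_equal(round(cx@duplicatePct, 1), 24.1)
    expect_false(cx@guidelineFlag)

    expect_equal(libraryComplexity(100, 100)@complexity, 1.0)
    expect_equal(libraryComplexity(50, 1)@complexity, 1 / 50)
    expect_true(libraryComplexity(10e6, 8e6)@guidelineFlag)
    expect_error(libraryComplexity(0, 0), "positive")
    expect_error(libraryComplexity(10, 11), "exceed")
})
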