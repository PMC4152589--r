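#' Classify mapped pairs by mapping uniqueness
#'
#' Aligners following the BWA convention assign MAPQ 0 to reads placed at
#' one of several equally good locations, so MAPQ > 0 marks a uniquely
#' mapped end. Every mapped pair falls in exactly one of three classes:
#' `both_unique` (a), `one_unique` (b), `both_multi` (c).
#'
#' @param pairs a [ReadPairs] with both mates mapped.
#' @return factor with levels `both_unique`, `one_unique`, `both_multi`.
#' @export
classifyPairs <- function(pairs) {
    u1 <- mcols(pairs@first)$mapq > 0L
    u2 <- mcols(pairs@second)$mapq > 0L
    factor(ifelse(u1 & u2, "both_unique",
           ifelse(u1 | u2, "one_unique", "both_multi")),
           levels = c("both_unique", "one_unique", "both_multi"))
}

#' MAPQ filter for single-end reads
#'
#' Keeps reads with `mapq >= cutoff` (reads *below* the threshold are
#' removed, so the boundary value survives).
#'
#' @param reads `GRanges` of mapped single-end reads (or a [ReadSet]).
#' @param cutoff minimum mapping quality (default 20).
#' @param exemptMapq0 keep MAPQ-0 reads regardless of the cutoff; used with
#'   the single-end random-match multi-mapper option, where MAPQ 0 denotes
#'   the aligner's single randomly reported placement.
#' @return surviving reads, same container as the input.
#' @export
filterMapqSingle <- function(reads, cutoff = 20L, exemptMapq0 = FALSE) {
    if (is(reads, "ReadSet")) {
        out <- reads
        out@reads <- filterMapqSingle(reads@reads, cutoff, exemptMapq0)
        return(out)
    }
    mq <- mcols(reads)$mapq
    reads[mq >= cutoff | (exemptMapq0 & mq == 0L)]
}

#' MAPQ filter for read pairs
#'
#' A pair is removed when either end's MAPQ is below the cutoff, except
#' that pairs whose two ends both map to multiple locations (both MAPQ 0)
#' can be retained with `keepMultiBothZero = TRUE`, preserving the option
#' of analysing repetitive regions. Pairing is never broken: mates survive
#' or fall together.
#'
#' @param pairs a [ReadPairs].
#' @param cutoff minimum MAPQ per end (default 20).
#' @param keepMultiBothZero retain `both_multi` pairs (default `FALSE`).
#' @return surviving [ReadPairs].
#' @export
filterMapqPairs <- function(pairs, cutoff = 20L, keepMultiBothZero = FALSE) {
    q1 <- mcols(pairs@first)$mapq
    q2 <- mcols(pairs@second)$mapq
    keep <- q1 >= cutoff & q2 >= cutoff
    if (keepMultiBothZero) keep <- keep | (q1 == 0L & q2 == 0L)
    new("ReadPairs", first = pairs@first[keep], second = pairs@second[keep])
}

#' Proper-pair filter: chromosome, orientation, insert size
#'
#' Keeps pairs whose mates lie on the same chromosome, point toward each
#' other (`FR`) when `requireFR`, and whose insert (`|TLEN|`) falls within
#' the configured bounds. This is the geometry filter that removes
#' improperly mapped pairs with small inserts or wrong orientation.
#'
#' @param pairs a [ReadPairs].
#' @param minInsert,maxInsert inclusive insert-size bounds in bp
#'   (defaults 1 and 1000).
#' @param requireFR require FR orientation (default `TRUE`).
#' @return surviving [ReadPairs].
#' @export
filterProperPairs <- function(pairs, minInsert = 1L, maxInsert = 1000L,
                              requireFR = TRUE) {
    stopifnot2(minInsert <= maxInsert, "minInsert must be <= maxInsert")
    ins <- insertSize(pairs)
    ori <- pairOrientation(pairs)
    keep <- ori != "cross" & ins >= minInsert & ins <= maxInsert
    if (requireFR) keep <- keep & ori == "FR"
    new("ReadPairs", first = pairs@first[keep], second = pairs@second[keep])
}

#' Multi-mapper retention policy for pairs
#'
#' Three policies over the classes of [classifyPairs()]: `unique_only`
#' keeps class a; `one_end_unique` keeps a and b; and
#' `one_end_unique_plus_random` additionally keeps class c, whose pairs
#' contribute the single placement the aligner reported (a random match
#' chosen upstream when both ends align to multiple locations).
#'
#' @param pairs a [ReadPairs], already proper.
#' @param policy policy name (see above).
#' @return surviving [ReadPairs].
#' @export
applyMultimapPolicy <- function(pairs,
        policy = c("unique_only", "one_end_unique",
                   "one_end_unique_plus_random")) {
    policy <- match.arg(policy)
    cls <- classifyPairs(pairs)
    keep <- switch(policy,
        unique_only = cls == "both_unique",
        one_end_unique = cls != "both_multi",
        one_end_unique_plus_random = rep(TRUE, length(pairs)))
    new("ReadPairs", first = pairs@first[keep], second = pairs@second[keep])
}

# shared key machinery -------------------------------------------------------

dupKeySE <- function(gr) {
    fp <- fivePrimeEnds(gr)
    paste(as.character(seqnames(fp)), start(fp), as.character(strand(fp)),
          sep = ":")
}

dupKeyPE <- function(pairs) {
    k1 <- dupKeySE(pairs@first)
    k2 <- dupKeySE(pairs@second)
    ori <- pairOrientation(pairs)
    # order the two 5' anchors so mate labelling cannot split a key
    paste(pmin(k1, k2), pmax(k1, k2), ori, sep = "|")
}

#' Mark PCR duplicates
#'
#' Duplicates are reads (or pairs) sharing a genomic key: for single-end
#' reads `(chromosome, 5' position, strand)`; for pairs the 5' positions of
#' both mates plus the pair orientation. Exactly one representative per key
#' is left unflagged — the record with the highest MAPQ (pairs: highest
#' summed MAPQ), ties resolved by input order. The operation is idempotent
#' and does not reorder records.
#'
#' The 5' position is the alignment start on the plus strand and the
#' alignment end on the minus strand, without soft-clip adjustment.
#'
#' @param x a [ReadSet], `GRanges` of single-end reads, or [ReadPairs].
#' @return same container with the `isDuplicate` metadata column set.
#' @export
markDuplicates <- function(x) {
    if (is(x, "ReadSet")) {
        out <- x
        out@reads <- markDuplicates(x@reads)
        return(out)
    }
    if (is(x, "ReadPairs")) {
        key <- dupKeyPE(x)
        score <- mcols(x@first)$mapq + mcols(x@second)$mapq
        dup <- duplicatedByKey(key, score)
        mcols(x@first)$isDuplicate <- dup
        mcols(x@second)$isDuplicate <- dup
        return(x)
    }
    key <- dupKeySE(x)
    mcols(x)$isDuplicate <- duplicatedByKey(key, mcols(x)$mapq)
    x
}

# TRUE for every record that is not its key's representative
duplicatedByKey <- function(key, score) {
    n <- length(key)
    if (!n) return(logical(0))
    # representative: max score, ties -> earliest input index
    ord <- order(key, -score, seq_len(n))
    first <- !duplicated(key[ord])
    dup <- rep(TRUE, n)
    dup[ord[first]] <- FALSE
    dup
}

#' Drop flagged duplicates
#'
#' @param x a [ReadSet], `GRanges`, or [ReadPairs] whose `isDuplicate`
#'   column has been set by [markDuplicates()].
#' @return same container restricted to non-duplicate records.
#' @export
dedup <- function(x) {
    if (is(x, "ReadSet")) {
        out <- x
        out@reads <- x@reads[!mcols(x@reads)$isDuplicate]
        return(out)
    }
    if (is(x, "ReadPairs")) {
        keep <- !mcols(x@first)$isDuplicate
        return(new("ReadPairs", first = x@first[keep],
                   second = x@second[keep]))
    }
    x[!mcols(x)$isDuplicate]
}

#' Library complexity from read counts
#'
#' Complexity is the ratio of duplicate-filtered reads to total uniquely
#' mapped reads; `duplicatePct = 100 * (1 - complexity)`. The guideline
#' flag compares against the ~0.8 reference value expected of a good
#' ChIP library at around 10 M mapped reads.
#'
#' @param totalUniqueMapped uniquely mapped read count before duplicate
#'   removal.
#' @param afterDedup read count after duplicate removal.
#' @return a [ComplexityReport].
#' @examples
#' libraryComplexity(22.27e6, 16.9e6)  # ~0.759, 24.1% duplicates
#' @export
libraryComplexity <- function(totalUniqueMapped, afterDedup) {
    stopifnot2(totalUniqueMapped > 0 && afterDedup > 0,
               "read counts must be positive (complexity undefined at 0)")
    stopifnot2(afterDedup <= totalUniqueMapped,
               "afterDedup cannot exceed totalUniqueMapped")
    cx <- afterDedup / totalUniqueMapped
    new("ComplexityReport",
        totalUniqueMapped = totalUniqueMapped, afterDedup = afterDedup,
        complexity = cx, duplicatePct = 100 * (1 - cx),
        guidelineFlag = cx >= 0.8)
}
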