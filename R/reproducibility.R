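#' Merge replicate read sets
#'
#' Concatenates the mapped reads of several [ReadSet]s (e.g. IP replicates
#' before pseudoreplicate construction). All inputs must share the same
#' genome table.
#'
#' @param ... two or more [ReadSet]s (or a single one, returned as is).
#' @return a merged [ReadSet].
#' @export
mergeReplicates <- function(...) {
    sets <- list(...)
    stopifnot2(length(sets) >= 1L, "at least one ReadSet required")
    si <- genomeTable(sets[[1L]])
    for (s in sets[-1L])
        if (!identical(seqlengths(genomeTable(s)), seqlengths(si)))
            stop("replicates disagree on the genome table", call. = FALSE)
    reads <- do.call(c, lapply(sets, mappedReads))
    new("ReadSet", reads = reads,
        nUnmapped = sum(vapply(sets, unmappedCount, integer(1))),
        source = "")
}

#' Split reads into two equal pseudoreplicates
#'
#' Randomly permutes the reads under the given seed and assigns the first
#' `ceiling(n/2)` to pseudoreplicate 1 and the rest to pseudoreplicate 2.
#' The two halves partition the input exactly and their sizes differ by at
#' most one; the split is deterministic given the seed, and the caller's
#' RNG stream is left untouched.
#'
#' @param x a [ReadSet] (or `GRanges`) with at least two reads.
#' @param seed integer seed (default 42).
#' @return list of two objects of the same class as `x`, named
#'   `pseudo1`/`pseudo2`.
#' @export
splitPseudoreplicates <- function(x, seed = 42L) {
    gr <- if (is(x, "ReadSet")) x@reads else x
    n <- length(gr)
    stopifnot2(n >= 2L, "need at least 2 reads to split")
    perm <- withSeed(seed, sample.int(n))
    n1 <- ceiling(n / 2)
    i1 <- sort(perm[seq_len(n1)])
    i2 <- sort(perm[(n1 + 1L):n])
    wrap <- function(idx) {
        if (is(x, "ReadSet"))
            new("ReadSet", reads = gr[idx], nUnmapped = 0L, source = "")
        else gr[idx]
    }
    list(pseudo1 = wrap(i1), pseudo2 = wrap(i2))
}

#' Match peaks across two replicate sets
#'
#' Greedy best-overlap pairing: candidate pairs are all >= 1 bp overlaps,
#' ranked by overlap width (ties by coordinate), and each peak enters at
#' most one pair. Used to decide which peaks are "shared" before IDR
#' annotation.
#'
#' @param a,b `GRanges` peak sets.
#' @return integer matrix with columns `a`, `b` of paired indices.
#' @export
matchPeaks <- function(a, b) {
    hits <- findOverlaps(a, b, ignore.strand = TRUE)
    if (!length(hits))
        return(matrix(integer(0), ncol = 2L,
                      dimnames = list(NULL, c("a", "b"))))
    ov <- width(IRanges::pintersect(granges(a)[queryHits(hits)],
                                    granges(b)[subjectHits(hits)]))
    ord <- order(-ov, queryHits(hits), subjectHits(hits))
    qa <- queryHits(hits)[ord]; qb <- subjectHits(hits)[ord]
    usedA <- logical(length(a)); usedB <- logical(length(b))
    keep <- logical(length(qa))
    for (i in seq_along(qa)) {
        if (!usedA[qa[i]] && !usedB[qb[i]]) {
            keep[i] <- TRUE
            usedA[qa[i]] <- TRUE; usedB[qb[i]] <- TRUE
        }
    }
    cbind(a = qa[keep], b = qb[keep])
}

#' Annotate peaks with IDR values in the dual-use name column
#'
#' Shared peaks receive their estimated IDR (< 1) in the encodePeak name
#' column (and the `idr` metadata column); peaks with no counterpart in
#' the other replicate receive the arbitrary value 1, so consistent peaks
#' can later be extracted at any cutoff.
#'
#' @param peaks `GRanges` of peaks.
#' @param idr numeric vector parallel to `peaks`: the IDR of each shared
#'   peak, `NA` for replicate-specific peaks.
#' @return `peaks` with `idr` set (specific peaks at 1) and `name`
#'   mirroring it.
#' @export
annotateIdr <- function(peaks, idr) {
    stopifnot2(length(idr) == length(peaks),
               "idr must be parallel to peaks")
    shared <- !is.na(idr)
    if (any(idr[shared] >= 1 | idr[shared] < 0))
        stop("IDR of a shared peak must lie in [0, 1)", call. = FALSE)
    v <- ifelse(shared, idr, 1)
    mcols(peaks)$idr <- v
    mcols(peaks)$name <- as.character(v)
    peaks
}

#' Count consistent peaks at an IDR cutoff
#'
#' @param peaks annotated peaks (`idr` metadata column), or a numeric
#'   vector of IDR values.
#' @param cutoff IDR cutoff (default 0.01); counting is monotone
#'   non-decreasing in the cutoff.
#' @return integer count of peaks with `idr <= cutoff`.
#' @export
countConsistent <- function(peaks, cutoff = 0.01) {
    v <- if (is.numeric(peaks)) peaks else mcols(peaks)$idr
    stopifnot2(!is.null(v), "peaks carry no idr values; annotate first")
    sum(v <= cutoff, na.rm = TRUE)
}

#' Factor-of-two reproducibility assessment
#'
#' Computes the rescue ratio (consistent peaks between true replicates vs
#' between pseudoreplicates of the merged IP, max/min) and the
#' self-consistency ratio (between the within-replicate pseudoreplicate
#' counts, max/min). An experiment with good reproducibility has both
#' ratios at or below 2; a larger ratio suggests generating a third
#' replicate. The conservative list is the true-replicate count; the
#' optimal list the larger of the true and merged-pseudoreplicate counts.
#'
#' @param nTrue consistent peaks between biological replicates.
#' @param nMergedPseudo consistent peaks between pseudoreplicates of the
#'   merged IP.
#' @param nSelf1,nSelf2 consistent peaks between pseudoreplicates within
#'   each biological replicate.
#' @return a [ReproducibilityReport]; ratios are stored unrounded and
#'   printed to one decimal.
#' @examples
#' assessReproducibility(21224, 26971, 22382, 14286)  # 1.3 / 1.6, pass
#' @export
assessReproducibility <- function(nTrue, nMergedPseudo, nSelf1, nSelf2) {
    counts <- c(nTrue, nMergedPseudo, nSelf1, nSelf2)
    if (any(counts <= 0))
        stop("all consistent-peak counts must be positive; a zero count ",
             "indicates a failed replicate (consider a third replicate)",
             call. = FALSE)
    rescue <- max(nTrue, nMergedPseudo) / min(nTrue, nMergedPseudo)
    self <- max(nSelf1, nSelf2) / min(nSelf1, nSelf2)
    new("ReproducibilityReport",
        nTrue = nTrue, nMergedPseudo = nMergedPseudo,
        nSelf1 = nSelf1, nSelf2 = nSelf2,
        rescueRatio = rescue, selfRatio = self,
        pass = rescue <= 2 && self <= 2,
        conservativeN = nTrue, optimalN = max(nTrue, nMergedPseudo))
}

#' Ratios of a reproducibility report, rounded for presentation
#'
#' @param report a [ReproducibilityReport].
#' @param digits decimals (default 1, matching the usual presentation).
#' @return named numeric vector `rescue`, `self`.
#' @export
reproducibilityRatios <- function(report, digits = 1L) {
    c(rescue = round(report@rescueRatio, digits),
      self = round(report@selfRatio, digits))
}

#' @rdname reproducibilityRatios
#' @export
reproducibilityPass <- function(report) report@pass

#' Consistent-peak counts over a grid of IDR cutoffs
#'
#' The summary behind the count-versus-cutoff table and plot of an IDR
#' run: one row per cutoff, one column per annotated peak set.
#'
#' @param annotated named list of annotated peak sets (or IDR vectors).
#' @param cutoffs IDR cutoffs (default the conventional grid 0.001-0.1).
#' @return `data.frame` with column `idr_cutoff` plus one count column per
#'   input.
#' @export
consistencyTable <- function(annotated,
        cutoffs = c(0.001, 0.005, 0.01, 0.02, 0.05, 0.1)) {
    out <- data.frame(idr_cutoff = cutoffs)
    for (nm in names(annotated))
        out[[nm]] <- vapply(cutoffs,
            function(ct) countConsistent(annotated[[nm]], ct), numeric(1))
    out
}
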