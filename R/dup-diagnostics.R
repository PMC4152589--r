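#' Non-peak background regions
#'
#' The complement, within chromosome bounds, of the union of all peaks
#' extended by `pad` bp on both sides (default 100). Reads falling in the
#' padding belong to neither the peak class nor the non-peak class — the
#' pad is a buffer zone around peak edges.
#'
#' @param peaks `GRanges` of peaks with a `Seqinfo` carrying chromosome
#'   lengths (or supply `si`).
#' @param si optional `Seqinfo`.
#' @param pad bp added to each peak side before complementing.
#' @return `GRanges` of non-peak regions.
#' @export
nonpeakComplement <- function(peaks, si = NULL, pad = 100L) {
    if (is.null(si)) si <- seqinfo(peaks)
    whole <- genomeRanges(si)
    if (!length(peaks)) return(whole)
    padded <- trim(suppressWarnings(
        granges(peaks) + pad))
    GenomicRanges::setdiff(whole, reduce(padded, ignore.strand = TRUE),
                           ignore.strand = TRUE)
}

#' Table-shaped duplicate summary from bare counts
#'
#' The arithmetic behind a duplicate-distribution table row:
#' `dup_pct = 100 * duplicates / (non_duplicates + duplicates)` and
#' `portion_pct = 100 * duplicates / total_duplicates`.
#'
#' @param class region class labels.
#' @param spanBp union length of each class in bp.
#' @param nonDuplicates,duplicates read counts per class.
#' @param totalDuplicates duplicate count of the whole library.
#' @return `data.frame` with columns `class`, `span_bp`,
#'   `non_duplicates`, `duplicates`, `sum`, `dup_pct`, `portion_pct`.
#' @export
dupStatsTable <- function(class, spanBp, nonDuplicates, duplicates,
                          totalDuplicates) {
    s <- nonDuplicates + duplicates
    data.frame(class = class, span_bp = spanBp,
               non_duplicates = nonDuplicates, duplicates = duplicates,
               sum = s,
               dup_pct = ifelse(s > 0, 100 * duplicates / s, 0),
               portion_pct = if (totalDuplicates > 0)
                   100 * duplicates / totalDuplicates else 0)
}

#' Duplicate statistics per region class
#'
#' Assigns each read to a region class by its 5' position (a point rule,
#' so disjoint classes partition the reads exactly) and tabulates
#' duplicate counts, duplicate percentage and each class's share of the
#' library's duplicates. Typical classes: all peaks, top peaks, the
#' non-peak complement, and the library total.
#'
#' @param reads `GRanges` (or [ReadSet]) with `isDuplicate` set by
#'   [markDuplicates()].
#' @param regions named list of `GRanges`, one per region class.
#' @param total also append a `total` row for the whole library
#'   (default `TRUE`).
#' @return `data.frame` as in [dupStatsTable()]; a class with no reads
#'   reports `dup_pct` 0.
#' @export
regionDupStats <- function(reads, regions, total = TRUE) {
    if (is(reads, "ReadSet")) reads <- mappedReads(reads)
    stopifnot2("isDuplicate" %in% colnames(mcols(reads)),
               "reads carry no duplicate flags; run markDuplicates() first")
    fp <- fivePrimeEnds(reads)
    isdup <- mcols(reads)$isDuplicate
    totalDup <- sum(isdup)
    rows <- lapply(names(regions), function(nm) {
        inr <- countOverlaps(fp, regions[[nm]], ignore.strand = TRUE) > 0L
        dupStatsTable(nm, unionWidth(regions[[nm]]),
                      sum(inr & !isdup), sum(inr & isdup), totalDup)
    })
    out <- do.call(rbind, rows)
    if (total)
        out <- rbind(out, dupStatsTable("total",
            sum(as.numeric(seqlengths(seqinfo(reads))), na.rm = TRUE),
            sum(!isdup), totalDup, totalDup))
    `rownames<-`(out, NULL)
}

#' Duplicate level stratified by peak-confidence decile
#'
#' Ranks peaks by score descending (default `-log10 p`, ties broken by
#' coordinate), splits them into `nGroups` contiguous groups of equal
#' size (a remainder goes to the earlier, higher-confidence groups), and
#' reports the duplicate percentage of the reads whose 5' position falls
#' in each group's peaks. A strong monotone decrease over the deciles is
#' the signature of duplicates concentrating in confident punctate peaks;
#' a flat profile near the background level is typical of broad marks.
#'
#' @param peaks scored `GRanges` of peaks.
#' @param reads `GRanges` (or [ReadSet]) with duplicate flags.
#' @param rankBy score column (default `"negLog10P"`; use
#'   `"negLog10Fdr"` for SICER-style islands).
#' @param nGroups number of groups (default 10); `length(peaks)` must be
#'   at least `nGroups`.
#' @return `data.frame` with columns `group`, `n_peaks`, `duplicates`,
#'   `total_reads`, `dup_pct`, group 1 being the most confident.
#' @export
decileProfile <- function(peaks, reads,
                          rankBy = c("negLog10P", "negLog10Fdr", "score"),
                          nGroups = 10L) {
    rankBy <- match.arg(rankBy)
    if (is(reads, "ReadSet")) reads <- mappedReads(reads)
    n <- length(peaks)
    if (n < nGroups)
        stop("only ", n, " peaks for ", nGroups,
             " groups; reduce nGroups", call. = FALSE)
    s <- peakScores(peaks, rankBy)
    ord <- scoreOrder(peaks, s)
    base <- n %/% nGroups
    extra <- n %% nGroups
    sizes <- rep(base, nGroups) + c(rep(1L, extra), rep(0L, nGroups - extra))
    grp <- rep(seq_len(nGroups), sizes)
    fp <- fivePrimeEnds(reads)
    isdup <- mcols(reads)$isDuplicate
    res <- lapply(seq_len(nGroups), function(g) {
        pk <- peaks[ord][grp == g]
        inr <- countOverlaps(fp, pk, ignore.strand = TRUE) > 0L
        tot <- sum(inr)
        dup <- sum(inr & isdup)
        data.frame(group = g, n_peaks = sum(grp == g), duplicates = dup,
                   total_reads = tot,
                   dup_pct = if (tot > 0) 100 * dup / tot else 0)
    })
    `rownames<-`(do.call(rbind, res), NULL)
}
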