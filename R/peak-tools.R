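#' Fold-change filter for broad enrichment domains
#'
#' SICER reports islands filtered on FDR but not on enrichment over the
#' control; this filter removes candidate domains whose fold change is
#' below the threshold (default 2). When the `foldChange` column is absent
#' it is derived from raw counts as
#' `(ip/ipTotal) / (ctrl/ctrlTotal)` with a pseudocount of 1 on a zero
#' control count.
#'
#' @param peaks `GRanges` from [readPeaks()] (SICER dialect), carrying
#'   `foldChange` or `ipCount`/`ctrlCount`.
#' @param threshold minimum fold change kept (default 2).
#' @param ipTotal,ctrlTotal library sizes for the count fallback.
#' @return surviving peaks (subset of the input; idempotent).
#' @export
foldChangeFilter <- function(peaks, threshold = 2.0,
                             ipTotal = NULL, ctrlTotal = NULL) {
    m <- mcols(peaks)
    fc <- if ("foldChange" %in% colnames(m)) m$foldChange
          else rep(NA_real_, length(peaks))
    if (anyNA(fc)) {
        if (!all(c("ipCount", "ctrlCount") %in% colnames(m)) ||
            is.null(ipTotal) || is.null(ctrlTotal))
            stop("peaks carry neither foldChange nor IP/control counts ",
                 "with library totals", call. = FALSE)
        ctrl <- ifelse(m$ctrlCount == 0, 1, m$ctrlCount)
        fcc <- (m$ipCount / ipTotal) / (ctrl / ctrlTotal)
        fc[is.na(fc)] <- fcc[is.na(fc)]
    }
    peaks[fc >= threshold]
}

# descending score, ties broken by (chrom, start) for determinism
scoreOrder <- function(peaks, score) {
    order(-score, as.character(seqnames(peaks)), start(peaks))
}

peakScores <- function(peaks, scoreField = c("auto", "negLog10P",
                                             "negLog10Fdr", "score")) {
    scoreField <- match.arg(scoreField)
    m <- mcols(peaks)
    pick <- function(f) if (f %in% colnames(m) && !all(is.na(m[[f]])))
        m[[f]] else NULL
    s <- if (scoreField == "auto")
        pick("negLog10P") %||% pick("negLog10Fdr") %||% pick("score")
    else pick(scoreField)
    if (is.null(s))
        stop("no usable score field on peaks", call. = FALSE)
    s
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Select the strongest peaks
#'
#' Sorts peaks by score descending (by default `-log10 p`, falling back to
#' `-log10 FDR` then `score`; ties broken by chromosome and start) and
#' keeps the top fraction (`k = ceiling(f * n)`), a fixed count, or all
#' peaks at or above a score cutoff. The default fraction 0.1 reproduces
#' the "top 10% of peaks with the largest -log10(p)" selection used for
#' motif discovery and profile annotation.
#'
#' @param peaks `GRanges` with score metadata.
#' @param mode `"fraction"`, `"count"`, or `"score_cutoff"`.
#' @param value the fraction, count, or cutoff (default 0.1).
#' @param scoreField which score column to rank on (default `"auto"`).
#' @return the selected peaks, in score order.
#' @export
selectTopPeaks <- function(peaks,
                           mode = c("fraction", "count", "score_cutoff"),
                           value = 0.1, scoreField = "auto") {
    mode <- match.arg(mode)
    s <- peakScores(peaks, scoreField)
    ord <- scoreOrder(peaks, s)
    k <- switch(mode,
        fraction = ceiling(value * length(peaks)),
        count = min(as.integer(value), length(peaks)),
        score_cutoff = sum(s >= value))
    if (mode == "score_cutoff") peaks[ord][which(s[ord] >= value)]
    else peaks[ord][seq_len(k)]
}

#' Compare two peak sets by 1-bp overlap
#'
#' A peak of one set counts as overlapped when it shares at least one base
#' with any peak of the other set (half-open arithmetic: `a.start < b.end`
#' and `b.start < a.end`).
#'
#' @param a,b `GRanges` peak sets.
#' @return an [OverlapReport].
#' @export
comparePeakSets <- function(a, b) {
    oa <- sum(countOverlaps(a, b, ignore.strand = TRUE) > 0L)
    ob <- sum(countOverlaps(b, a, ignore.strand = TRUE) > 0L)
    new("OverlapReport",
        nA = length(a), nB = length(b),
        overlappedA = oa, overlappedB = ob,
        pctA = if (length(a)) 100 * oa / length(a) else NA_real_,
        pctB = if (length(b)) 100 * ob / length(b) else NA_real_)
}

#' Percentage of overlapped peaks
#'
#' The overlap arithmetic of an [OverlapReport] on bare counts:
#' `100 * overlapped / total`.
#'
#' @param overlapped,total peak counts.
#' @return numeric percentage.
#' @export
overlapPercent <- function(overlapped, total) 100 * overlapped / total

# TSS/TES anchors in 0-based coordinates; tss is the 5' anchor
geneAnchors0 <- function(genes) {
    plus <- as.character(strand(genes)) != "-"
    list(tss = ifelse(plus, start(genes) - 1L, end(genes) - 1L),
         tes = ifelse(plus, end(genes) - 1L, start(genes) - 1L))
}

#' Assign peaks to putative cis-regulated genes
#'
#' For every peak, the signed distance from the peak center to each gene's
#' transcription start site (TSS) and end site (TES) is measured; all
#' genes whose nearer anchor lies within `maxDistance` (default 10 kb) are
#' reported, and the nearest is flagged `is_closest` (distance ties flag
#' all tied genes, emitted in lexicographic gene-id order).
#'
#' Distances are in bp on the genomic axis (`center - anchor`), so the
#' sign is genomic left/right, not gene-relative up/downstream.
#'
#' @param peaks `GRanges` of peaks.
#' @param genes `GRanges` of gene models with an `id` metadata column;
#'   `start`/`end` span the gene, strand gives the 5' anchor.
#' @param maxDistance maximum center-to-anchor distance in bp.
#' @return `data.frame` with columns `peak`, `chrom`, `peak_start`,
#'   `peak_end` (0-based half-open, mirroring the peak_vs_gene table),
#'   `gene`, `anchor`, `distance`, `is_closest`.
#' @export
assignPeaksToGenes <- function(peaks, genes, maxDistance = 10000L) {
    empty <- data.frame(peak = character(0), chrom = character(0),
                        peak_start = integer(0), peak_end = integer(0),
                        gene = character(0), anchor = character(0),
                        distance = integer(0), is_closest = logical(0))
    if (!length(genes)) {
        warning("empty gene list; no assignments made")
        return(empty)
    }
    if (!length(peaks)) return(empty)
    anch <- geneAnchors0(genes)
    centers0 <- (start(peaks) - 1L + end(peaks)) %/% 2L
    pk_chr <- as.character(seqnames(peaks))
    g_chr <- as.character(seqnames(genes))
    ids <- as.character(mcols(genes)$id)
    pname <- if ("name" %in% colnames(mcols(peaks)))
        as.character(mcols(peaks)$name) else paste0("peak_", seq_along(peaks))
    out <- vector("list", length(peaks))
    for (i in seq_along(peaks)) {
        onchr <- which(g_chr == pk_chr[i])
        if (!length(onchr)) next
        dTSS <- centers0[i] - anch$tss[onchr]
        dTES <- centers0[i] - anch$tes[onchr]
        useTSS <- abs(dTSS) <= abs(dTES)
        d <- ifelse(useTSS, dTSS, dTES)
        sel <- which(abs(d) <= maxDistance)
        if (!length(sel)) next
        df <- data.frame(
            peak = pname[i], chrom = pk_chr[i],
            peak_start = start(peaks)[i] - 1L, peak_end = end(peaks)[i],
            gene = ids[onchr][sel],
            anchor = ifelse(useTSS[sel], "TSS", "TES"),
            distance = d[sel],
            is_closest = abs(d[sel]) == min(abs(d[sel])))
        out[[i]] <- df[order(-df$is_closest, df$gene), ]
    }
    res <- do.call(rbind, out[!vapply(out, is.null, logical(1))])
    if (is.null(res)) empty else `rownames<-`(res, NULL)
}

#' Fixed-width windows centered on peaks
#'
#' The window around each peak center (`floor((start0 + end0) / 2)`),
#' clipped to the chromosome; used e.g. to cut 100-bp sequences around
#' peaks for motif discovery.
#'
#' @param peaks `GRanges` of peaks (with `Seqinfo` for clipping).
#' @param width window width in bp, even, >= 2 (default 100).
#' @return `GRanges` of windows.
#' @export
centerWindows <- function(peaks, width = 100L) {
    stopifnot2(width >= 2L && width %% 2L == 0L,
               "width must be an even number >= 2")
    c0 <- (start(peaks) - 1L + end(peaks)) %/% 2L
    s0 <- pmax(c0 - width %/% 2L, 0L)
    gr <- suppressWarnings(
        GRanges(seqnames(peaks), IRanges(s0 + 1L, c0 + width %/% 2L),
                seqinfo = seqinfo(peaks)))
    trim(gr)
}
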