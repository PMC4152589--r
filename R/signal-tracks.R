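#' Extend single-end reads to fragment length
#'
#' Each mapped read is extended from its 5' end to the library's average
#' fragment length (default 200 bp) in its strand direction, then clipped
#' to the chromosome, emulating the sequenced fragment that produced it.
#'
#' @param reads `GRanges` of mapped single-end reads (strand set).
#' @param fragmentLength target fragment length in bp (default 200).
#' @return `GRanges` of fragment intervals, clipped to chromosome bounds.
#' @export
extendSingleEnd <- function(reads, fragmentLength = 200L) {
    trim(suppressWarnings(
        resize(granges(reads), width = fragmentLength, fix = "start")))
}

#' Fragment intervals from proper pairs
#'
#' One fragment per pair, anchored at the leftmost mate's 5' end and
#' extended by the insert estimated from the observed mapping positions
#' (`|TLEN|`), rather than by a per-library average — the actual
#' coordinates of the mates give better resolution across a genome of
#' variable fragment lengths.
#'
#' @param pairs a [ReadPairs] of proper FR pairs.
#' @return `GRanges` of fragment intervals, one per pair.
#' @export
fragmentFromPair <- function(pairs) {
    ins <- insertSize(pairs)
    if (any(ins == 0L))
        stop("pair(s) with TLEN 0 encountered; run filterProperPairs() first",
             call. = FALSE)
    left <- pmin(start(pairs@first), start(pairs@second))
    gr <- GRanges(seqnames(pairs@first), IRanges(left, width = ins),
                  seqinfo = seqinfo(pairs@first))
    trim(gr)
}

#' Raw coverage track from fragments
#'
#' Per-base coverage (number of fragments covering each base), run-length
#' encoded per chromosome.
#'
#' @param fragments `GRanges` of fragment intervals with a `Seqinfo`
#'   carrying chromosome lengths (or supply `si`).
#' @param si optional `Seqinfo` overriding the fragments' own.
#' @return a raw [CoverageTrack].
#' @export
coverageFromFragments <- function(fragments, si = NULL) {
    if (is.null(si)) si <- seqinfo(fragments)
    sl <- seqlengths(si)
    stopifnot2(!anyNA(sl), "chromosome lengths required to build coverage")
    cov <- GenomicRanges::coverage(granges(fragments), width = as.list(sl))
    new("CoverageTrack", coverage = cov, seqinfo = si,
        normalized = FALSE, librarySize = NA_real_)
}

#' Per-million library-size normalization
#'
#' Scales every value by `1e6 / librarySize`, expressing coverage as if
#' the library held one million mapped fragments. Applying it twice is an
#' error.
#'
#' @param track a raw [CoverageTrack].
#' @param librarySize mapped fragment count used to build the track.
#' @return normalized [CoverageTrack].
#' @export
normalizePerMillion <- function(track, librarySize) {
    stopifnot2(!track@normalized,
               "track is already normalized; refusing to scale twice")
    stopifnot2(librarySize > 0, "librarySize must be > 0")
    new("CoverageTrack", coverage = track@coverage * (1e6 / librarySize),
        seqinfo = track@seqinfo, normalized = TRUE,
        librarySize = librarySize)
}

#' Fixed-step window values of a track
#'
#' Splits each chromosome into consecutive windows of `step` bp and
#' returns the mean per-base coverage of each window; a trailing partial
#' window is averaged over its true width. These are the values rendered
#' into fixedStep Wig by [writeTrack()].
#'
#' @param track a [CoverageTrack].
#' @param step window size in bp (default 20).
#' @return named list of numeric vectors, one per chromosome.
#' @export
wigSteps <- function(track, step = 20L) {
    stopifnot2(step >= 1L, "step must be >= 1")
    lapply(track@coverage, function(rle) {
        len <- length(rle)
        if (len == 0L) return(numeric(0))
        nwin <- ceiling(len / step)
        w <- rep(as.integer(step), nwin)
        w[nwin] <- len - (nwin - 1L) * step
        vw <- Views(rle, successiveIRanges(w))
        as.numeric(viewMeans(vw))
    })
}
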