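#' Write a coverage track as bedGraph or fixedStep Wig
#'
#' bedGraph output encodes the track's maximal constant runs, one line per
#' run (`chrom start end value`, 0-based half-open), omitting zero-valued
#' runs. Wig output is `fixedStep` with `span` equal to `step`; each value
#' is the mean per-base coverage of its window (see [wigSteps()]). A
#' chromosome with no signal is omitted from the body, so an empty track
#' yields a header-only file.
#'
#' @param track a [CoverageTrack].
#' @param path output path.
#' @param format `"bedgraph"` or `"wig"`.
#' @param step window size in bp for Wig rendering (default 20).
#' @param name track name for the header line.
#' @return `path`, invisibly.
#' @export
writeTrack <- function(track, path, format = c("bedgraph", "wig"),
                       step = 20L, name = "coverage") {
    format <- match.arg(format)
    stopifnot2(is(track, "CoverageTrack"), "track must be a CoverageTrack")
    sl <- seqlengths(track@seqinfo)
    over <- lengths(track@coverage) > sl[names(track@coverage)]
    if (any(over))
        stop("track exceeds chromosome length on ",
             paste(names(track@coverage)[over], collapse = ","),
             call. = FALSE)
    con <- file(path, "w")
    on.exit(close(con))
    if (format == "bedgraph") {
        writeLines(sprintf("track type=bedGraph name=\"%s\"", name), con)
        for (chrom in names(track@coverage)) {
            rle <- track@coverage[[chrom]]
            rl <- S4Vectors::runLength(rle)
            rv <- S4Vectors::runValue(rle)
            ends <- cumsum(as.numeric(rl))
            starts <- ends - rl
            keep <- rv != 0
            if (!any(keep)) next
            writeLines(sprintf("%s\t%s\t%s\t%s", chrom,
                               format(starts[keep], scientific = FALSE,
                                      trim = TRUE),
                               format(ends[keep], scientific = FALSE,
                                      trim = TRUE),
                               format(rv[keep], trim = TRUE)), con)
        }
    } else {
        writeLines(sprintf("track type=wiggle_0 name=\"%s\"", name), con)
        for (chrom in names(track@coverage)) {
            v <- wigSteps(track, step)[[chrom]]
            last <- if (length(v)) max(c(0L, which(v != 0))) else 0L
            if (last == 0L) next
            writeLines(sprintf("fixedStep chrom=%s start=1 step=%d span=%d",
                               chrom, step, step), con)
            writeLines(format(v[seq_len(last)], trim = TRUE), con)
        }
    }
    invisible(path)
}

#' Read a bedGraph file back into interval runs
#'
#' Counterpart of [writeTrack()]'s bedGraph output, used to round-trip
#' tracks. Track-definition header lines are skipped.
#'
#' @param path bedGraph file.
#' @param si optional `Seqinfo`.
#' @return `GRanges` (1-based, closed) with a `score` metadata column.
#' @export
readBedGraph <- function(path, si = NULL) {
    lines <- readLines(path)
    lines <- lines[!grepl("^(track|#|browser)", lines) & nzchar(lines)]
    if (!length(lines))
        return(GRanges(score = numeric(0)))
    tab <- data.table::fread(text = lines, header = FALSE, sep = "\t")
    gr <- GRanges(tab[[1]], IRanges(tab[[2]] + 1L, tab[[3]]))
    mcols(gr)$score <- as.numeric(tab[[4]])
    if (!is.null(si)) {
        GenomeInfoDb::seqlevels(gr) <- seqlevels(si)
        seqinfo(gr) <- si
    }
    gr
}

#' Fetch a nucleotide window from a FASTA file
#'
#' Returns the uppercased sequence of the requested window. No
#' reverse-complementing is performed; strand handling belongs to the
#' caller.
#'
#' @param fasta path to a FASTA file, or a [Biostrings::DNAStringSet].
#' @param chrom sequence name.
#' @param start,end 1-based closed coordinates of the window; `end <
#'   start` denotes an empty window.
#' @return a character scalar of length `end - start + 1` (or `""`).
#' @export
fetchSequence <- function(fasta, chrom, start, end) {
    seqs <- if (is(fasta, "DNAStringSet")) fasta
            else Biostrings::readDNAStringSet(fasta)
    names(seqs) <- sub("\\s.*$", "", names(seqs))
    if (!chrom %in% names(seqs))
        stop("sequence '", chrom, "' not found", call. = FALSE)
    if (end < start) return("")
    if (start < 1L || end > length(seqs[[chrom]]))
        stop("window [", start, ",", end, "] outside '", chrom, "' (length ",
             length(seqs[[chrom]]), ")", call. = FALSE)
    toupper(as.character(Biostrings::subseq(seqs[[chrom]], start, end)))
}
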