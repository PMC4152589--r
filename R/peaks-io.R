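#' Read peak calls in the dialects the pipeline consumes
#'
#' Three tab-separated dialects are understood, all with BED-style 0-based
#' half-open coordinates (converted to the package's 1-based `GRanges`
#' convention on the way in):
#'
#' * `encodePeak` — the 10-column narrowPeak/encodePeak layout emitted by
#'   MACS2 (`chrom start end name score strand signal -log10(p) -log10(q)
#'   summit`). Column 4 is dual-use: a peak name, or the peak's IDR value
#'   when the file has been through [annotateIdr()]. It is exposed verbatim
#'   as `name` and, when numeric, parsed into the `idr` metadata column.
#' * `sicer_summary` — the 8-column SICER island-summary layout
#'   (`chrom start end ip_count control_count p fold_change FDR`); raw
#'   p/FDR are converted to `negLog10P` / `negLog10Fdr`.
#' * `bed` — plain BED with 3 to 6 columns.
#'
#' @param path file path.
#' @param dialect one of `"encodePeak"`, `"sicer_summary"`, `"bed"`.
#' @param si optional `Seqinfo` to attach.
#' @return `GRanges` with metadata columns `name`, `score`, `foldChange`,
#'   `negLog10P`, `negLog10Fdr`, `idr` (and `ipCount`/`ctrlCount` for
#'   SICER), `NA` where the dialect does not carry the field.
#' @export
readPeaks <- function(path, dialect = c("encodePeak", "sicer_summary", "bed"),
                      si = NULL) {
    dialect <- match.arg(dialect)
    tab <- data.table::fread(path, header = FALSE, sep = "\t",
                             colClasses = list(character = 1))
    nc <- ncol(tab)
    num <- function(v, what) {
        x <- suppressWarnings(as.numeric(v))
        if (anyNA(x) && !all(is.na(v)))
            stop("non-numeric ", what, " field in '", path, "'",
                 call. = FALSE)
        x
    }
    if (dialect == "encodePeak") {
        if (nc != 10L)
            stop("encodePeak requires 10 columns, found ", nc, call. = FALSE)
        gr <- GRanges(tab[[1]], IRanges(num(tab[[2]], "start") + 1L,
                                        num(tab[[3]], "end")),
                      strand = ifelse(tab[[6]] %in% c("+", "-"),
                                      tab[[6]], "*"))
        idr <- suppressWarnings(as.numeric(tab[[4]]))
        mcols(gr) <- DataFrame(
            name = as.character(tab[[4]]), score = num(tab[[5]], "score"),
            foldChange = num(tab[[7]], "signal"),
            negLog10P = num(tab[[8]], "-log10 p"),
            negLog10Fdr = num(tab[[9]], "-log10 q"),
            idr = idr)
    } else if (dialect == "sicer_summary") {
        if (nc != 8L)
            stop("sicer_summary requires 8 columns, found ", nc,
                 call. = FALSE)
        gr <- GRanges(tab[[1]], IRanges(num(tab[[2]], "start") + 1L,
                                        num(tab[[3]], "end")))
        p <- num(tab[[6]], "p-value"); fdr <- num(tab[[8]], "FDR")
        mcols(gr) <- DataFrame(
            name = paste0("island_", seq_len(nrow(tab))),
            score = NA_real_,
            foldChange = num(tab[[7]], "fold-change"),
            negLog10P = -log10(pmax(p, .Machine$double.xmin)),
            negLog10Fdr = -log10(pmax(fdr, .Machine$double.xmin)),
            idr = NA_real_,
            ipCount = num(tab[[4]], "IP count"),
            ctrlCount = num(tab[[5]], "control count"))
    } else {
        if (nc < 3L || nc > 6L)
            stop("bed requires 3-6 columns, found ", nc, call. = FALSE)
        gr <- GRanges(tab[[1]], IRanges(num(tab[[2]], "start") + 1L,
                                        num(tab[[3]], "end")),
                      strand = if (nc >= 6L)
                          ifelse(tab[[6]] %in% c("+", "-"), tab[[6]], "*")
                      else "*")
        mcols(gr) <- DataFrame(
            name = if (nc >= 4L) as.character(tab[[4]])
                   else paste0("peak_", seq_len(nrow(tab))),
            score = if (nc >= 5L) num(tab[[5]], "score") else NA_real_,
            foldChange = NA_real_, negLog10P = NA_real_,
            negLog10Fdr = NA_real_, idr = NA_real_)
    }
    if (!is.null(si)) {
        GenomeInfoDb::seqlevels(gr) <- seqlevels(si)
        seqinfo(gr) <- si
    }
    gr
}

#' Write peaks in encodePeak or BED layout
#'
#' Coordinates are emitted 0-based half-open. In `encodePeak` layout,
#' column 4 carries the `idr` metadata value when present (the annotated
#' convention) and the peak `name` otherwise; absent numeric fields are
#' written as `-1`, the narrowPeak missing-value convention.
#'
#' @param peaks `GRanges` as returned by [readPeaks()] (extra metadata
#'   columns are ignored).
#' @param path output path.
#' @param dialect `"encodePeak"` or `"bed"` (BED6).
#' @return `path`, invisibly.
#' @export
writePeaks <- function(peaks, path, dialect = c("encodePeak", "bed")) {
    dialect <- match.arg(dialect)
    m <- mcols(peaks)
    g <- function(col, default) {
        v <- if (col %in% colnames(m)) m[[col]] else rep(NA, length(peaks))
        ifelse(is.na(v), default, v)
    }
    chrom <- as.character(seqnames(peaks))
    s0 <- format(start(peaks) - 1L, scientific = FALSE, trim = TRUE)
    e0 <- format(end(peaks), scientific = FALSE, trim = TRUE)
    strnd <- as.character(strand(peaks)); strnd[strnd == "*"] <- "."
    name <- g("name", "peak")
    idr <- if ("idr" %in% colnames(m)) m$idr else rep(NA_real_, length(peaks))
    col4 <- ifelse(is.na(idr), name, as.character(idr))
    lines <- if (dialect == "encodePeak") {
        if (length(peaks)) sprintf("%s\t%s\t%s\t%s\t%s\t%s\t%s\t%s\t%s\t-1",
            chrom, s0, e0, col4,
            format(g("score", 0), trim = TRUE),
            strnd,
            format(g("foldChange", 0), trim = TRUE),
            format(g("negLog10P", -1), trim = TRUE),
            format(g("negLog10Fdr", -1), trim = TRUE)) else character(0)
    } else {
        if (length(peaks)) sprintf("%s\t%s\t%s\t%s\t%s\t%s",
            chrom, s0, e0, name, format(g("score", 0), trim = TRUE),
            strnd) else character(0)
    }
    writeLines(lines, path)
    invisible(path)
}
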