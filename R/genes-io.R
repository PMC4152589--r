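#' Read BED-like gene models
#'
#' Tab-separated, BED6-style: `chrom start end id score strand` (score
#' column optional when exactly five columns are supplied as
#' `chrom start end id strand` is *not* accepted — the layout is
#' positional BED). Coordinates are 0-based half-open on disk. The
#' interval spans the gene; its strand determines which end is the TSS
#' (5' anchor) and which the TES.
#'
#' @param path file path.
#' @param si optional `Seqinfo`.
#' @return `GRanges` with an `id` metadata column.
#' @export
readGenes <- function(path, si = NULL) {
    tab <- data.table::fread(path, header = FALSE, sep = "\t",
                             colClasses = list(character = 1))
    stopifnot2(ncol(tab) >= 6L, "gene table needs 6 BED-like columns")
    stopifnot2(all(tab[[6]] %in% c("+", "-")),
               "gene strand must be + or -")
    gr <- GRanges(tab[[1]], IRanges(as.integer(tab[[2]]) + 1L,
                                    as.integer(tab[[3]])),
                  strand = tab[[6]])
    mcols(gr)$id <- as.character(tab[[4]])
    if (!is.null(si)) {
        GenomeInfoDb::seqlevels(gr) <- seqlevels(si)
        seqinfo(gr) <- si
    }
    gr
}

#' TSS and TES anchors of gene models
#'
#' The TSS is the 5' end of the gene (start on `+`, end on `-`); the TES
#' the opposite end. Returned as width-1 `GRanges`.
#'
#' @param genes `GRanges` gene models.
#' @return list with `tss` and `tes` `GRanges`.
#' @export
geneAnchors <- function(genes) {
    plus <- as.character(strand(genes)) != "-"
    tss <- ifelse(plus, start(genes), end(genes))
    tes <- ifelse(plus, end(genes), start(genes))
    list(tss = GRanges(seqnames(genes), IRanges(tss, width = 1L),
                       strand = strand(genes), seqinfo = seqinfo(genes)),
         tes = GRanges(seqnames(genes), IRanges(tes, width = 1L),
                       strand = strand(genes), seqinfo = seqinfo(genes)))
}
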