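#' Read a SAM file into a ReadSet
#'
#' Ingests a (headered) SAM file via [Rsamtools::asBam()] and
#' [Rsamtools::scanBam()]. SAM's 1-based `POS` and CIGAR reference width
#' define each record's range; flag bits are decoded into the boolean
#' metadata columns documented in [ReadSet]. Unmapped records (flag 0x4) are
#' counted, never silently dropped. Input record order is preserved.
#'
#' @param path path to a SAM (or BAM) file with `@SQ` header lines.
#' @return a [ReadSet].
#' @examples
#' sam <- tempfile(fileext = ".sam")
#' writeLines(c("@HD\tVN:1.6", "@SQ\tSN:chr1\tLN:1000",
#'   "r1\t0\tchr1\t1\t60\t36M\t*\t0\t0\t*\t*"), sam)
#' rs <- readSAM(sam)
#' start(mappedReads(rs))  # SAM POS 1 -> 1-based start 1 (0-based 0)
#' @export
readSAM <- function(path) {
    stopifnot2(file.exists(path), paste("no such file:", path))
    bam <- if (grepl("\\.bam$", path, ignore.case = TRUE)) path else
        tryCatch(
            Rsamtools::asBam(path, tempfile(), overwrite = TRUE,
                             indexDestination = FALSE),
            error = function(e) stop("SAM parse error in '", path, "': ",
                                     conditionMessage(e), call. = FALSE))
    hdr <- Rsamtools::scanBamHeader(bam)[[1L]]$targets
    if (!length(hdr))
        stop("SAM header of '", path, "' has no @SQ lines; a genome table ",
             "is required", call. = FALSE)
    si <- Seqinfo(names(hdr), unname(hdr))
    p <- Rsamtools::ScanBamParam(what = c("qname", "flag", "rname", "pos",
                                          "mapq", "cigar", "isize",
                                          "mrnm", "mpos"))
    b <- Rsamtools::scanBam(bam, param = p)[[1L]]
    unmapped <- bitwAnd(b$flag, 4L) != 0L
    n_un <- sum(unmapped)
    keep <- !unmapped
    rw <- GenomicAlignments::cigarWidthAlongReferenceSpace(b$cigar[keep])
    gr <- GRanges(as.character(b$rname[keep]),
                  IRanges(b$pos[keep], width = rw),
                  strand = ifelse(bitwAnd(b$flag[keep], 16L) != 0L, "-", "+"),
                  seqinfo = si)
    mapq <- b$mapq[keep]
    mapq[is.na(mapq)] <- 0L
    mcols(gr) <- DataFrame(
        qname = b$qname[keep],
        flag = b$flag[keep],
        mapq = mapq,
        tlen = ifelse(is.na(b$isize[keep]), 0L, b$isize[keep]),
        isPaired = bitwAnd(b$flag[keep], 1L) != 0L,
        isFirst = bitwAnd(b$flag[keep], 64L) != 0L,
        isProper = bitwAnd(b$flag[keep], 2L) != 0L,
        isDuplicate = bitwAnd(b$flag[keep], 1024L) != 0L,
        mrnm = as.character(b$mrnm[keep]),
        mpos = b$mpos[keep])
    new("ReadSet", reads = gr, nUnmapped = as.integer(n_un),
        source = path)
}

#' Write alignments back out as SAM
#'
#' Emits a minimal, valid SAM file (`@HD`/`@SQ` header plus the mandatory
#' eleven columns) for a [ReadSet] or [ReadPairs]. Sequences and qualities
#' are written as `*`; CIGAR is `<width>M`. Pairs are written with mates on
#' adjacent lines. The duplicate flag bit (0x400) is synchronised with the
#' `isDuplicate` column.
#'
#' @param x a [ReadSet], [ReadPairs], or `GRanges` with read metadata.
#' @param path output path.
#' @param si `Seqinfo` for the header; taken from `x` when omitted.
#' @return `path`, invisibly.
#' @export
writeSAM <- function(x, path, si = NULL) {
    if (is(x, "ReadPairs")) {
        n <- length(x)
        gr <- c(x@first, x@second)[rep(seq_len(n), each = 2L) +
                                   rep(c(0L, n), n)]
    } else if (is(x, "ReadSet")) gr <- x@reads
    else gr <- x
    if (is.null(si)) si <- seqinfo(gr)
    sl <- seqlengths(si)
    hdr <- c("@HD\tVN:1.6\tSO:unsorted",
             sprintf("@SQ\tSN:%s\tLN:%d", names(sl), sl))
    m <- mcols(gr)
    flag <- m$flag
    flag <- bitwOr(bitwAnd(flag, bitwNot(1024L)),
                   ifelse(m$isDuplicate, 1024L, 0L))
    mrnm <- if ("mrnm" %in% colnames(m)) m$mrnm else NA_character_
    mpos <- if ("mpos" %in% colnames(m)) m$mpos else NA_integer_
    body <- if (length(gr)) sprintf(
        "%s\t%d\t%s\t%d\t%d\t%dM\t%s\t%d\t%d\t*\t*",
        m$qname, flag, as.character(seqnames(gr)), start(gr), m$mapq,
        width(gr),
        ifelse(is.na(mrnm), "*",
               ifelse(mrnm == as.character(seqnames(gr)), "=", mrnm)),
        ifelse(is.na(mpos), 0L, mpos),
        m$tlen) else character(0)
    writeLines(c(hdr, body), path)
    invisible(path)
}

#' Read a UCSC chrom.sizes table
#'
#' Two tab-separated columns, chromosome name and length in bp.
#'
#' @param path path to the table.
#' @return a [GenomeInfoDb::Seqinfo].
#' @export
readChromSizes <- function(path) {
    tab <- data.table::fread(path, header = FALSE, sep = "\t",
                             col.names = c("chrom", "len"))
    stopifnot2(all(tab$len > 0), "chromosome lengths must be > 0")
    Seqinfo(as.character(tab$chrom), tab$len)
}

#' Pair up the mates of a paired-end ReadSet
#'
#' Matches first-in-pair records with their mates by query name among the
#' mapped reads of `x`. Records whose mate is unmapped or missing are
#' dropped (they belong to the proper-pair filter's reject class, not to any
#' pair-level filter). Pair order follows the first mate's position in the
#' input file.
#'
#' @param x a [ReadSet] holding paired-end alignments.
#' @return a [ReadPairs].
#' @export
pairReads <- function(x) {
    gr <- x@reads
    gr <- gr[mcols(gr)$isPaired]
    f <- gr[mcols(gr)$isFirst]
    s <- gr[!mcols(gr)$isFirst]
    idx <- match(mcols(f)$qname, mcols(s)$qname)
    keep <- !is.na(idx)
    new("ReadPairs", first = f[keep], second = s[idx[keep]])
}

#' Pair geometry: insert size and mate orientation
#'
#' `insertSize()` is `|TLEN|` in bp. `pairOrientation()` classifies each
#' pair as `FR` (mates pointing toward each other, the proper ChIP
#' geometry), `RF`, `FF`, `RR`, or `cross` for mates on different
#' chromosomes.
#'
#' @param pairs a [ReadPairs].
#' @return integer vector / character vector, parallel to `pairs`.
#' @export
insertSize <- function(pairs) abs(mcols(pairs@first)$tlen)

#' @rdname insertSize
#' @export
pairOrientation <- function(pairs) {
    f <- pairs@first; s <- pairs@second
    out <- rep("cross", length(f))
    same <- as.character(seqnames(f)) == as.character(seqnames(s))
    if (!any(same)) return(out)
    fs <- as.character(strand(f))[same]
    ss <- as.character(strand(s))[same]
    # orient by genomic order: the leftmost mate's strand comes first
    leftFirst <- start(f)[same] <= start(s)[same]
    left <- ifelse(leftFirst, fs, ss)
    right <- ifelse(leftFirst, ss, fs)
    cls <- ifelse(left == "+" & right == "-", "FR",
           ifelse(left == "-" & right == "+", "RF",
           ifelse(left == "+" & right == "+", "FF", "RR")))
    out[same] <- cls
    out
}
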