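# In-code fixtures shared across the suite.

library(GenomicRanges)
library(S4Vectors)

# Write a SAM file with the given body lines under a one- or two-chromosome
# header; returns the path.
tinySAM <- function(lines, genome = c(chr1 = 1000L)) {
    path <- tempfile(fileext = ".sam")
    hdr <- c("@HD\tVN:1.6",
             sprintf("@SQ\tSN:%s\tLN:%d", names(genome), genome))
    writeLines(c(hdr, lines), path)
    path
}

samLine <- function(qname, flag, chrom, pos, mapq, cigar = "36M",
                    rnext = "*", pnext = 0, tlen = 0) {
    sprintf("%s\t%d\t%s\t%d\t%d\t%s\t%s\t%d\t%d\t*\t*",
            qname, flag, chrom, pos, mapq, cigar, rnext, pnext, tlen)
}

# Bare GRanges of reads with the metadata layout the filters expect.
makeReads <- function(chrom, start, width = 36L, strand = "+", mapq = 60L,
                      qname = NULL, genome = c(chr1 = 100000L),
                      flag = NULL) {
    n <- length(start)
    strand <- rep_len(strand, n); mapq <- rep_len(as.integer(mapq), n)
    if (is.null(qname)) qname <- sprintf("r%04d", seq_len(n))
    if (is.null(flag)) flag <- ifelse(strand == "-", 16L, 0L)
    gr <- GRanges(rep_len(chrom, n), IRanges(start, width = width),
                  strand = strand,
                  seqinfo = GenomeInfoDb::Seqinfo(names(genome),
                                                  unname(genome)))
    mcols(gr) <- DataFrame(qname = qname, flag = flag, mapq = mapq,
                           tlen = 0L, isPaired = FALSE, isFirst = FALSE,
                           isProper = FALSE, isDuplicate = FALSE,
                           mrnm = NA_character_, mpos = NA_integer_)
    gr
}

# A ReadPairs object from parallel mate descriptions.
makePairs <- function(chrom1, start1, chrom2, start2, mapq1 = 60L,
                      mapq2 = 60L, strand1 = "+", strand2 = "-",
                      width = 36L, tlen = NULL,
                      genome = c(chr1 = 100000L, chr2 = 100000L)) {
    n <- length(start1)
    if (is.null(tlen)) {
        # FR same-chromosome default: outer span
        tlen <- ifelse(rep_len(chrom1, n) == rep_len(chrom2, n),
                       pmax(start1, start2) + width - pmin(start1, start2),
                       0L)
    }
    qn <- sprintf("p%04d", seq_len(n))
    f <- makeReads(chrom1, start1, width, strand1, mapq1, qn, genome,
                   flag = 64L + ifelse(rep_len(strand1, n) == "-", 16L, 0L))
    s <- makeReads(chrom2, start2, width, strand2, mapq2, qn, genome,
                   flag = 128L + ifelse(rep_len(strand2, n) == "-", 16L, 0L))
    mcols(f)$tlen <- as.integer(tlen)
    mcols(s)$tlen <- -as.integer(tlen)
    mcols(f)$isPaired <- mcols(s)$isPaired <- TRUE
    mcols(f)$isFirst <- TRUE
    new("ReadPairs", first = f, second = s)
}

simplePeaks <- function(chrom, start, end, negLog10P = NA_real_,
                        negLog10Fdr = NA_real_, foldChange = NA_real_,
                        genome = c(chr1 = 100000L, chr2 = 100000L)) {
    n <- length(start)
    gr <- GRanges(rep_len(chrom, n), IRanges(start, end),
                  seqinfo = GenomeInfoDb::Seqinfo(names(genome),
                                                  unname(genome)))
    mcols(gr) <- DataFrame(name = paste0("pk", seq_len(n)),
                           score = rep(0, n),
                           foldChange = rep_len(foldChange, n),
                           negLog10P = rep_len(negLog10P, n),
                           negLog10Fdr = rep_len(negLog10Fdr, n),
                           idr = rep(NA_real_, n))
    gr
}

simpleGenes <- function(chrom, start, end, strand, id = NULL,
                        genome = c(chr1 = 100000L, chr2 = 100000L)) {
    n <- length(start)
    if (is.null(id)) id <- paste0("g", seq_len(n))
    gr <- GRanges(rep_len(chrom, n), IRanges(start, end), strand = strand,
                  seqinfo = GenomeInfoDb::Seqinfo(names(genome),
                                                  unname(genome)))
    mcols(gr)$id <- id
    gr
}
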