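#' @import methods
#' @importFrom S4Vectors DataFrame mcols mcols<- queryHits subjectHits
#' @importFrom IRanges IRanges Views successiveIRanges viewMeans RleList
#' @importFrom GenomicRanges GRanges seqnames strand strand<- start end width
#'   resize trim reduce findOverlaps countOverlaps granges
#' @importFrom GenomeInfoDb Seqinfo seqlengths seqinfo seqinfo<- seqlevels
#' @importFrom stats pbinom p.adjust rnorm rpois runif rbinom rexp cor
#' @importFrom utils head tail
NULL

#' ReadSet: mapped alignments plus bookkeeping from one SAM file
#'
#' A light container for the alignments of one sequencing library. Mapped
#' records are held as a [GenomicRanges::GRanges] (1-based, closed; converted
#' from 1-based SAM POS and CIGAR reference width) with metadata columns
#' `qname`, `flag`, `mapq`, `tlen`, and the decoded flag bits `isPaired`,
#' `isFirst`, `isProper`, `isDuplicate`. Unmapped records are retained as a
#' count so library totals stay honest. The genome (chromosome names and
#' lengths from the `@SQ` header) travels with the object as a
#' [GenomeInfoDb::Seqinfo].
#'
#' Input order of the SAM file is preserved; several downstream rules
#' (duplicate-representative tie-breaking, pseudoreplicate splitting) are
#' defined relative to that order.
#'
#' @slot reads `GRanges` of mapped records, in file order.
#' @slot nUnmapped integer count of unmapped records.
#' @slot source character scalar, path the object was read from (or `""`).
#' @export
setClass("ReadSet",
    representation(reads = "GRanges", nUnmapped = "integer",
                   source = "character"))

setValidity("ReadSet", function(object) {
    need <- c("qname", "flag", "mapq", "tlen",
              "isPaired", "isFirst", "isProper", "isDuplicate")
    missing <- setdiff(need, colnames(mcols(object@reads)))
    if (length(missing))
        return(paste("missing read columns:", paste(missing, collapse = ", ")))
    if (length(object@reads) && any(width(object@reads) < 1L))
        return("mapped reads must have positive width")
    if (object@nUnmapped < 0L) return("nUnmapped must be >= 0")
    TRUE
})

#' ReadPairs: mate-paired alignments kept in lockstep
#'
#' Both mates of each properly parsed pair, as two parallel `GRanges`
#' (`first` = first-in-pair, `second` = its mate). All pair-level filters
#' operate on this class so that pairing is never broken: a filter keeps or
#' drops both mates together.
#'
#' @slot first,second `GRanges` with the same metadata columns as the reads
#'   in a [ReadSet]; element `i` of each slot are mates.
#' @export
setClass("ReadPairs", representation(first = "GRanges", second = "GRanges"))

setValidity("ReadPairs", function(object) {
    if (length(object@first) != length(object@second))
        return("first and second must be parallel")
    if (length(object@first) &&
        !all(mcols(object@first)$qname == mcols(object@second)$qname))
        return("mates must share query names")
    TRUE
})

#' CoverageTrack: stepwise per-base fragment coverage
#'
#' Genome-wide coverage held as an [IRanges::RleList] (one run-length encoded
#' vector per chromosome, each exactly as long as its chromosome), plus the
#' normalization state. Raw tracks count fragments per base; normalized
#' tracks carry raw values scaled by 1e6 / `librarySize` ("per million
#' mapped reads").
#'
#' @slot coverage `RleList`, one numeric/integer Rle per chromosome.
#' @slot seqinfo `Seqinfo` describing the genome.
#' @slot normalized logical scalar.
#' @slot librarySize numeric; mapped-fragment count used for scaling
#'   (`NA` until normalized).
#' @export
setClass("CoverageTrack",
    representation(coverage = "RleList", seqinfo = "Seqinfo",
                   normalized = "logical", librarySize = "numeric"))

setValidity("CoverageTrack", function(object) {
    sl <- seqlengths(object@seqinfo)
    if (!all(names(object@coverage) %in% names(sl)))
        return("coverage chromosomes absent from seqinfo")
    got <- lengths(object@coverage)
    want <- sl[names(object@coverage)]
    if (any(got != want))
        return(paste0("coverage length mismatch on ",
                      paste(names(got)[got != want], collapse = ",")))
    if (any(vapply(object@coverage, function(x) any(S4Vectors::runValue(x) < 0),
                   logical(1))))
        return("coverage values must be >= 0")
    TRUE
})

#' ComplexityReport: library complexity after duplicate filtering
#'
#' Library complexity is the fraction of uniquely mapped reads that survive
#' duplicate removal; ~0.8 at 10 M reads is the usual quality guideline for
#' ChIP libraries.
#'
#' @slot totalUniqueMapped,afterDedup numeric read counts.
#' @slot complexity numeric in (0, 1], `afterDedup / totalUniqueMapped`.
#' @slot duplicatePct numeric, `100 * (1 - complexity)`.
#' @slot guidelineFlag logical, `TRUE` when complexity >= 0.8.
#' @export
setClass("ComplexityReport",
    representation(totalUniqueMapped = "numeric", afterDedup = "numeric",
                   complexity = "numeric", duplicatePct = "numeric",
                   guidelineFlag = "logical"))

setValidity("ComplexityReport", function(object) {
    if (object@afterDedup > object@totalUniqueMapped)
        return("afterDedup cannot exceed totalUniqueMapped")
    if (object@complexity <= 0 || object@complexity > 1)
        return("complexity must lie in (0, 1]")
    TRUE
})

#' OverlapReport: reciprocal overlap between two peak sets
#'
#' A peak counts as overlapped when it shares at least one base with any
#' peak of the other set.
#'
#' @slot nA,nB set sizes.
#' @slot overlappedA,overlappedB peaks of each set touched by the other.
#' @slot pctA,pctB `100 * overlapped / n` per set.
#' @export
setClass("OverlapReport",
    representation(nA = "integer", nB = "integer",
                   overlappedA = "integer", overlappedB = "integer",
                   pctA = "numeric", pctB = "numeric"))

#' ReproducibilityReport: factor-of-two IDR consistency bookkeeping
#'
#' Consistent-peak counts between true biological replicates, between
#' pseudoreplicates of the merged IP, and between pseudoreplicates within
#' each replicate, with the two derived ratios. An experiment passes when
#' neither the rescue ratio nor the self-consistency ratio exceeds 2.
#'
#' @slot nTrue consistent peaks between biological replicates
#'   (= size of the conservative list).
#' @slot nMergedPseudo consistent peaks between pseudoreplicates of the
#'   merged IP.
#' @slot nSelf1,nSelf2 consistent peaks between pseudoreplicates within
#'   replicate 1 / replicate 2.
#' @slot rescueRatio max/min of (`nTrue`, `nMergedPseudo`), unrounded.
#' @slot selfRatio max/min of (`nSelf1`, `nSelf2`), unrounded.
#' @slot pass logical, both ratios <= 2.
#' @slot conservativeN,optimalN conservative / optimal reproducible-peak
#'   list sizes (`nTrue`, `max(nTrue, nMergedPseudo)`).
#' @export
setClass("ReproducibilityReport",
    representation(nTrue = "numeric", nMergedPseudo = "numeric",
                   nSelf1 = "numeric", nSelf2 = "numeric",
                   rescueRatio = "numeric", selfRatio = "numeric",
                   pass = "logical", conservativeN = "numeric",
                   optimalN = "numeric"))

setValidity("ReproducibilityReport", function(object) {
    if (object@rescueRatio < 1 || object@selfRatio < 1)
        return("ratios are max/min and must be >= 1")
    TRUE
})

setMethod("show", "ReadSet", function(object) {
    cat("ReadSet:", length(object@reads), "mapped,",
        object@nUnmapped, "unmapped record(s)\n")
    cat("  genome:", paste0(seqlevels(object@reads), collapse = ","), "\n")
})

setMethod("show", "ReadPairs", function(object) {
    cat("ReadPairs:", length(object@first), "pair(s)\n")
})

setMethod("show", "CoverageTrack", function(object) {
    cat("CoverageTrack over", length(object@coverage), "chromosome(s);",
        if (object@normalized)
            sprintf("normalized (library %g)", object@librarySize)
        else "raw", "\n")
})

setMethod("show", "ComplexityReport", function(object) {
    cat(sprintf(paste0("Library complexity: %.3f (%.0f / %.0f unique",
                       " mapped reads; %.1f%% duplicates)%s\n"),
                object@complexity, object@afterDedup,
                object@totalUniqueMapped, object@duplicatePct,
                if (object@guidelineFlag) "" else "  [below 0.8 guideline]"))
})

setMethod("show", "OverlapReport", function(object) {
    cat(sprintf("Peak-set overlap: A %d/%d (%.1f%%), B %d/%d (%.1f%%)\n",
                object@overlappedA, object@nA, object@pctA,
                object@overlappedB, object@nB, object@pctB))
})

setMethod("show", "ReproducibilityReport", function(object) {
    cat(sprintf("Rescue ratio %.1f, self-consistency ratio %.1f -> %s\n",
                round(object@rescueRatio, 1), round(object@selfRatio, 1),
                if (object@pass) "PASS (both <= 2)" else "FAIL (ratio > 2)"))
    cat(sprintf("Conservative list: %.0f peaks; optimal list: %.0f peaks\n",
                object@conservativeN, object@optimalN))
})

#' @describeIn ReadSet number of mapped records
#' @param x,object a `ReadSet`
#' @export
setMethod("length", "ReadSet", function(x) length(x@reads))

#' Accessors for ReadSet and ReadPairs
#'
#' `mappedReads()` returns the mapped records as a `GRanges`;
#' `unmappedCount()` the number of unmapped records; `genomeTable()` the
#' `Seqinfo` carried by the object; `firstMate()`/`secondMate()` the two
#' sides of a [ReadPairs].
#'
#' @param x a `ReadSet` or `ReadPairs`
#' @return see individual descriptions.
#' @export
mappedReads <- function(x) x@reads

#' @rdname mappedReads
#' @export
unmappedCount <- function(x) x@nUnmapped

#' @rdname mappedReads
#' @export
genomeTable <- function(x) {
    if (is(x, "ReadSet")) seqinfo(x@reads)
    else if (is(x, "CoverageTrack")) x@seqinfo
    else seqinfo(x)
}

#' @rdname mappedReads
#' @export
firstMate <- function(x) x@first

#' @rdname mappedReads
#' @export
secondMate <- function(x) x@second

#' @describeIn ReadPairs number of pairs
#' @param x a `ReadPairs`
#' @export
setMethod("length", "ReadPairs", function(x) length(x@first))

#' Coverage values of a track
#'
#' @param x a [CoverageTrack]
#' @return the underlying `RleList`.
#' @export
trackCoverage <- function(x) x@coverage

#' @rdname trackCoverage
#' @export
isNormalized <- function(x) x@normalized

#' Fields of a complexity report as a one-row data.frame
#'
#' Columns mirror the complexity TSV emitted by the pipeline:
#' `total_unique_mapped`, `after_dedup`, `complexity`, `duplicate_pct`,
#' `meets_guideline`.
#'
#' @param x a [ComplexityReport]
#' @export
as.data.frame.ComplexityReport <- function(x, ...) {
    data.frame(total_unique_mapped = x@totalUniqueMapped,
               after_dedup = x@afterDedup,
               complexity = x@complexity,
               duplicate_pct = x@duplicatePct,
               meets_guideline = x@guidelineFlag)
}
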