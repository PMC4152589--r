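#' Gene regulatory domains (basal plus extension)
#'
#' Each annotated gene gets a proximal (basal) regulatory domain from `U`
#' bp upstream of its TSS to `D` bp downstream (defaults 5000 and 1000),
#' strand-aware, plus an optional extension of up to `UE` bp further
#' upstream and `DE` bp further downstream. Following the GREAT
#' basal-plus-extension rule, an extension is truncated where it would
#' enter a neighbouring gene's proximal domain, but a gene's own proximal
#' domain is never shrunk (proximal is always contained in extended).
#' Domains are clipped to chromosome bounds.
#'
#' @param genes `GRanges` of gene models with `id` metadata; only genes
#'   annotated with at least one ontology term should be passed (filter
#'   with the annotation table first).
#' @param U,D proximal upstream/downstream distances in bp.
#' @param UE,DE maximum upstream/downstream extensions in bp (default 0).
#' @return `GRanges` of extended domains with metadata `id`,
#'   `proximal_start`, `proximal_end` (1-based, closed).
#' @export
buildDomains <- function(genes, U = 5000L, D = 1000L, UE = 0L, DE = 0L) {
    stopifnot2(all(c(U, D, UE, DE) >= 0), "U, D, UE, DE must be >= 0")
    plus <- as.character(strand(genes)) != "-"
    tss0 <- ifelse(plus, start(genes) - 1L, end(genes) - 1L)
    # proximal domain in 0-based half-open coordinates:
    # + strand [tss-U, tss+D), - strand [tss-D, tss+U)
    ps <- ifelse(plus, tss0 - U, tss0 - D)
    pe <- ifelse(plus, tss0 + D, tss0 + U)
    extL <- ifelse(plus, UE, DE)   # extension on the genomic-left side
    extR <- ifelse(plus, DE, UE)
    es <- pmax(ps - extL, 0)
    ee <- pe + extR
    chr <- as.character(seqnames(genes))
    for (i in seq_along(genes)) {
        others <- which(chr == chr[i])
        others <- others[others != i]
        if (!length(others)) next
        # a neighbour's proximal domain blocks extension where it would be
        # entered; the gene's own proximal domain is never reduced
        leftEnds <- pe[others][ps[others] < ps[i]]
        if (length(leftEnds))
            es[i] <- min(ps[i], max(es[i], max(leftEnds)))
        rightStarts <- ps[others][pe[others] > pe[i]]
        if (length(rightStarts))
            ee[i] <- max(pe[i], min(ee[i], min(rightStarts)))
    }
    si <- seqinfo(genes)
    # domains may poke past the chromosome before the final trim
    gr <- suppressWarnings(
        GRanges(chr, IRanges(pmax(es, 0) + 1L, ee), strand = strand(genes),
                seqinfo = si))
    mcols(gr) <- DataFrame(id = mcols(genes)$id,
                           proximal_start = pmax(ps, 0) + 1L,
                           proximal_end = pe)
    trim(gr)
}

#' Read a two-column gene-to-term annotation table
#'
#' Tab-separated `gene_id<TAB>term_id`, the layout of pre-propagated
#' ontology downloads.
#'
#' @param path file path.
#' @return `data.frame` with columns `gene`, `term`.
#' @export
readTermAnnotations <- function(path) {
    tab <- data.table::fread(path, header = FALSE, sep = "\t",
                             col.names = c("gene", "term"),
                             colClasses = "character")
    as.data.frame(tab)
}

#' Binomial enrichment of ontology terms over peak points
#'
#' GREAT-style test: each peak is reduced to its center point; for a term
#' annotating genes with regulatory-domain union of length `L` within an
#' annotatable genome of length `G` (the union of all genes' extended
#' domains), the number of peak centers falling in the term's union is
#' compared against `Binomial(n, p = L/G)`, upper tail
#' (`P[X >= k]`). Benjamini-Hochberg FDR is reported alongside the raw
#' p-values.
#'
#' @param peaks `GRanges` of peaks (centers are the test points).
#' @param domains regulatory domains from [buildDomains()].
#' @param annotations `data.frame` with columns `gene`, `term`.
#' @param denominator `"annotatable"` (union of all extended domains, the
#'   default) or `"genome"` (sum of chromosome lengths from the domains'
#'   `Seqinfo`).
#' @return `data.frame`, one row per term, with columns `term`, `n`, `k`,
#'   `p_term`, `p_value`, `fdr`, `genes` (comma-separated annotated genes
#'   whose domains caught a peak), ordered by `p_value`.
#' @export
binomialEnrichment <- function(peaks, domains, annotations,
                               denominator = c("annotatable", "genome")) {
    denominator <- match.arg(denominator)
    annotations <- annotations[annotations$gene %in% mcols(domains)$id, ,
                               drop = FALSE]
    G <- if (denominator == "annotatable") unionWidth(domains)
         else sum(as.numeric(seqlengths(seqinfo(domains))))
    stopifnot2(is.finite(G) && G > 0, "annotatable genome length must be > 0")
    pts <- centerPoints(peaks)
    n <- length(pts)
    terms <- unique(annotations$term)
    rows <- lapply(terms, function(tm) {
        gs <- annotations$gene[annotations$term == tm]
        dom <- domains[mcols(domains)$id %in% gs]
        if (!length(dom)) return(NULL)       # term with no modelled genes
        L <- unionWidth(dom)
        p <- min(L / G, 1)
        hit <- countOverlaps(pts, dom, ignore.strand = TRUE) > 0L
        k <- sum(hit)
        pv <- if (k == 0L) 1 else pbinom(k - 1L, n, p, lower.tail = FALSE)
        hitGenes <- mcols(dom)$id[countOverlaps(dom, pts,
                                                ignore.strand = TRUE) > 0L]
        data.frame(term = tm, n = n, k = k, p_term = p, p_value = pv,
                   genes = paste(sort(unique(hitGenes)), collapse = ","))
    })
    res <- do.call(rbind, rows[!vapply(rows, is.null, logical(1))])
    if (is.null(res))
        return(data.frame(term = character(0), n = integer(0),
                          k = integer(0), p_term = numeric(0),
                          p_value = numeric(0), fdr = numeric(0),
                          genes = character(0)))
    res$fdr <- bhFdr(res$p_value)
    res <- res[order(res$p_value, res$term),
               c("term", "n", "k", "p_term", "p_value", "fdr", "genes")]
    `rownames<-`(res, NULL)
}

#' Benjamini-Hochberg adjusted p-values
#'
#' Step-up false discovery rate control, delegated to
#' [stats::p.adjust()].
#'
#' @param p numeric vector of p-values in \[0, 1\].
#' @return adjusted p-values, same length and order.
#' @export
bhFdr <- function(p) {
    stopifnot2(all(p >= 0 & p <= 1, na.rm = TRUE),
               "p-values must lie in [0, 1]")
    p.adjust(p, method = "BH")
}
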