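#' Configuration for the synthetic ChIP-Seq generator
#'
#' Bundles every knob of the fixture generator with validation. Defaults
#' describe a small but realistic punctate (TF-like) experiment: a 2 Mb
#' two-chromosome genome, 50 peaks of ~300 bp, 10-fold read enrichment in
#' peaks over a background of 0.005 reads/bp, duplicate rates graded from
#' ~55% in the strongest peaks down to ~10% in the weakest against a 5%
#' background — the structure in which PCR duplicates concentrate in
#' confident punctate peaks. `peakDupRates` may be a scalar or one rate
#' per peak in descending-confidence order.
#'
#' @param seed integer RNG seed.
#' @param genome named integer vector of chromosome lengths.
#' @param nPeaks number of planted peaks.
#' @param peakWidthMean,peakWidthSd peak width distribution (bp).
#' @param backgroundRate background read density, reads per bp.
#' @param enrichment read-density fold enrichment inside peaks.
#' @param backgroundDupRate duplicate fraction among background reads.
#' @param peakDupRates duplicate fraction among peak reads; scalar or
#'   vector recycled over peaks ranked by confidence.
#' @param paired emit proper FR pairs instead of single-end reads.
#' @param fragmentMean,fragmentSd insert-size distribution for pairs
#'   (truncated at `readLength`).
#' @param readLength read length in bp.
#' @param multimapFraction fraction of reads (pairs: per end) emitted
#'   with MAPQ 0, the multi-mapping placeholder.
#' @param nGenes,geneWidth gene-model fixture shape.
#' @param nTerms number of ontology terms (genes are partitioned).
#' @param termEnrichment peak-density fold enrichment inside the
#'   designated term's regulatory domains.
#' @return a validated list of class `simulationConfig`.
#' @export
simulationConfig <- function(seed = 1L,
                             genome = c(chrA = 1200000L, chrB = 800000L),
                             nPeaks = 50L,
                             peakWidthMean = 300, peakWidthSd = 50,
                             backgroundRate = 0.005,
                             enrichment = 10,
                             backgroundDupRate = 0.05,
                             peakDupRates = seq(0.55, 0.10, length.out = 50),
                             paired = FALSE,
                             fragmentMean = 200, fragmentSd = 20,
                             readLength = 36L,
                             multimapFraction = 0.05,
                             nGenes = 60L, geneWidth = 2000L,
                             nTerms = 6L,
                             termEnrichment = 1) {
    cfg <- as.list(environment())
    rates <- c(cfg$backgroundDupRate, cfg$peakDupRates, cfg$multimapFraction)
    stopifnot2(all(rates >= 0 & rates < 1), "rates must lie in [0, 1)")
    stopifnot2(all(cfg$genome > 0), "chromosome lengths must be > 0")
    if (cfg$paired)
        stopifnot2(cfg$fragmentMean > cfg$readLength,
                   "fragment mean must exceed the read length for pairs")
    expected <- sum(cfg$genome) * cfg$backgroundRate * max(1, cfg$enrichment)
    stopifnot2(expected < sum(cfg$genome),
               "expected reads exceed genome capacity; lower the rates")
    class(cfg) <- "simulationConfig"
    cfg
}

#' Preset fixture profiles
#'
#' `tf_like` is the punctate profile: strong enrichment, duplicates graded
#' with peak confidence (monotone decile trend). `broad_like` is the
#' diffuse-mark profile: wide domains, modest enrichment, and a uniform
#' duplicate rate equal to the background, so the decile profile is flat.
#'
#' @param profile `"tf_like"` or `"broad_like"`.
#' @param seed RNG seed.
#' @param ... overrides passed to [simulationConfig()].
#' @return a `simulationConfig`.
#' @export
simulationProfile <- function(profile = c("tf_like", "broad_like"),
                              seed = 1L, ...) {
    profile <- match.arg(profile)
    if (profile == "tf_like")
        simulationConfig(seed = seed, ...)
    else
        simulationConfig(seed = seed, nPeaks = 30L,
                         peakWidthMean = 2000, peakWidthSd = 400,
                         enrichment = 4,
                         backgroundDupRate = 0.05,
                         peakDupRates = 0.05, ...)
}

# non-overlapping intervals with >= gap bp between them, uniform starts
placeIntervals <- function(genome, n, widths, gap = 300L) {
    chroms <- names(genome)
    out <- vector("list", n)
    placed <- GRanges(seqinfo = Seqinfo(chroms, unname(genome)))
    for (i in seq_len(n)) {
        w <- widths[i]
        for (try in 1:200) {
            chr <- sample(chroms, 1L, prob = genome / sum(genome))
            s <- sample.int(genome[[chr]] - w - gap, 1L) + gap %/% 2L
            cand <- GRanges(chr, IRanges(s, width = w),
                            seqinfo = seqinfo(placed))
            padded <- suppressWarnings(trim(placed + gap))
            if (!length(findOverlaps(cand, padded))) break
            cand <- NULL
        }
        if (is.null(cand))
            stop("genome too small to place ", n, " intervals", call. = FALSE)
        out[[i]] <- cand
        placed <- c(placed, cand)
    }
    unlist(GenomicRanges::GRangesList(out))
}

# sample read 5' positions uniformly within `region`, n of them
sample5prime <- function(region, n) {
    if (n == 0L)
        return(data.frame(chrom = character(0), pos5 = integer(0),
                          strand = character(0)))
    w <- width(region)
    idx <- sample.int(length(region), n, replace = TRUE,
                      prob = w / sum(w))
    off <- floor(runif(n) * w[idx])
    data.frame(chrom = as.character(seqnames(region))[idx],
               pos5 = start(region)[idx] + as.integer(off),
               strand = sample(c("+", "-"), n, replace = TRUE))
}

# duplicate a class of reads by re-emission so the duplicate fraction of
# the final class equals `rate` by construction
reemit <- function(df, rate) {
    n <- nrow(df)
    if (n == 0L || rate <= 0) return(df[0, , drop = FALSE])
    m <- round(rate * n / (1 - rate))
    if (m == 0L) return(df[0, , drop = FALSE])
    df[sample.int(n, m, replace = TRUE), , drop = FALSE]
}

#' Simulate a ChIP-Seq library as SAM plus ground truth
#'
#' Plants `nPeaks` non-overlapping peaks, draws background reads uniformly
#' over the non-peak complement (peaks padded by 100 bp) at
#' `backgroundRate` reads/bp and peak reads at `backgroundRate *
#' enrichment` within each peak, then creates duplicates by re-emitting
#' existing reads at the class's configured rate — so planted duplicate
#' fractions are exact by construction, up to rare positional collisions
#' between independent reads. Peak read counts also set the planted peak
#' scores (`-log10 p` proxy), so stronger peaks carry higher confidence
#' and, under the default graded `peakDupRates`, more duplicates.
#' `multimapFraction` of reads get MAPQ 0. Paired mode emits proper FR
#' pairs with insert ~ Normal(`fragmentMean`, `fragmentSd`) truncated at
#' the read length.
#'
#' Identical config and seed give byte-identical output files.
#'
#' @param config a [simulationConfig()].
#' @param dir output directory (created if needed).
#' @return list with `sam` (path), `truth` (`data.frame`: one row per
#'   emitted read/pair with origin and planted duplicate status), `peaks`
#'   (`GRanges` of planted peaks with `name`, `negLog10P`, `dupRate`),
#'   and `si` (`Seqinfo`).
#' @export
simulateReads <- function(config, dir = tempfile("simreads")) {
    stopifnot2(inherits(config, "simulationConfig"),
               "config must come from simulationConfig()")
    dir.create(dir, showWarnings = FALSE, recursive = TRUE)
    withSeed(config$seed, {
        si <- Seqinfo(names(config$genome), unname(config$genome))
        widths <- pmax(50L, as.integer(round(
            rnorm(config$nPeaks, config$peakWidthMean, config$peakWidthSd))))
        peaks <- placeIntervals(config$genome, config$nPeaks, widths,
                                gap = 2L * 100L + 50L)
        seqinfo(peaks) <- si
        bg <- nonpeakComplement(peaks, si = si, pad = 100L)

        # originals
        nBg <- rpois(1L, sum(width(bg)) * config$backgroundRate)
        bgReads <- sample5prime(bg, nBg)
        bgReads$origin <- rep("background", nrow(bgReads))
        peakRate <- config$backgroundRate * config$enrichment
        nPk <- rpois(config$nPeaks, width(peaks) * peakRate)
        # planted significance: Poisson upper tail of the read count
        # against the background expectation (a -log10 p proxy)
        scores <- -log10(pmax(1e-12,
            stats::ppois(nPk - 1L, width(peaks) * config$backgroundRate,
                         lower.tail = FALSE)))
        rank <- order(-scores, as.character(seqnames(peaks)), start(peaks))
        conf <- integer(config$nPeaks); conf[rank] <- seq_len(config$nPeaks)
        dupRates <- rep_len(config$peakDupRates, config$nPeaks)[conf]
        pkReads <- lapply(seq_len(config$nPeaks), function(i) {
            df <- sample5prime(peaks[i], nPk[i])
            df$origin <- rep(paste0("peak_", i), nrow(df))
            df
        })
        reads <- rbind(bgReads, do.call(rbind, pkReads))
        reads$planted_dup <- FALSE

        # duplicates by re-emission, per class
        dups <- list(reemit(bgReads, config$backgroundDupRate))
        for (i in seq_len(config$nPeaks))
            dups[[i + 1L]] <- reemit(pkReads[[i]], dupRates[i])
        dups <- do.call(rbind, dups)
        if (!is.null(dups) && nrow(dups)) {
            dups$planted_dup <- TRUE
            reads <- rbind(reads, dups)
        }
        n <- nrow(reads)
        reads$mapq <- sample(20:60, n, replace = TRUE)
        reads$mapq[runif(n) < config$multimapFraction] <- 0L
        reads$qname <- sprintf("read_%06d", seq_len(n))

        rl <- config$readLength
        chromLen <- config$genome[reads$chrom]
        if (!config$paired) {
            # alignment span from the 5' position, kept inside the chromosome
            pos5 <- pmin(pmax(reads$pos5, rl), chromLen)
            startAln <- ifelse(reads$strand == "+", pos5,
                               pos5 - rl + 1L)
            startAln <- pmax(1L, pmin(startAln, chromLen - rl + 1L))
            gr <- GRanges(reads$chrom, IRanges(startAln, width = rl),
                          strand = reads$strand, seqinfo = si)
            mcols(gr) <- DataFrame(
                qname = reads$qname,
                flag = ifelse(reads$strand == "-", 16L, 0L),
                mapq = reads$mapq, tlen = 0L,
                isPaired = FALSE, isFirst = FALSE, isProper = FALSE,
                isDuplicate = FALSE,
                mrnm = NA_character_, mpos = NA_integer_)
            sam <- file.path(dir, "reads.sam")
            writeSAM(gr, sam, si = si)
            truth <- data.frame(qname = reads$qname, chrom = reads$chrom,
                                pos5 = pos5, strand = reads$strand,
                                origin = reads$origin,
                                planted_dup = reads$planted_dup,
                                mapq = reads$mapq)
        } else {
            ins <- pmax(rl, as.integer(round(
                rnorm(n, config$fragmentMean, config$fragmentSd))))
            left <- pmax(1L, pmin(reads$pos5,
                                  chromLen - ins))
            right <- left + ins - 1L
            mapq2 <- sample(20:60, n, replace = TRUE)
            mapq2[runif(n) < config$multimapFraction] <- 0L
            mk <- function(st, en, strand, flag, mapq, tlen, mpos)
                GRanges(reads$chrom, IRanges(st, en), strand = strand,
                        seqinfo = si,
                        qname = reads$qname, flag = flag, mapq = mapq,
                        tlen = tlen,
                        isPaired = TRUE, isFirst = bitwAnd(flag, 64L) > 0L,
                        isProper = TRUE, isDuplicate = FALSE,
                        mrnm = reads$chrom, mpos = mpos)
            first <- mk(left, left + rl - 1L, "+", 99L, reads$mapq, ins,
                        right - rl + 1L)
            second <- mk(right - rl + 1L, right, "-", 147L, mapq2, -ins,
                         left)
            pairs <- new("ReadPairs", first = first, second = second)
            sam <- file.path(dir, "reads.sam")
            writeSAM(pairs, sam, si = si)
            truth <- data.frame(qname = reads$qname, chrom = reads$chrom,
                                pos5 = left, insert = ins,
                                strand = "+",
                                origin = reads$origin,
                                planted_dup = reads$planted_dup,
                                mapq = reads$mapq, mapq2 = mapq2)
        }
        mcols(peaks) <- DataFrame(name = paste0("peak_", seq_along(peaks)),
                                  score = pmin(1000, round(scores)),
                                  foldChange = nPk /
                                      pmax(1e-9, width(peaks) *
                                               config$backgroundRate),
                                  negLog10P = scores,
                                  negLog10Fdr = NA_real_,
                                  idr = NA_real_,
                                  dupRate = dupRates)
        utils::write.table(truth, file.path(dir, "truth.tsv"), sep = "\t",
                           quote = FALSE, row.names = FALSE)
        list(sam = sam, truth = truth, peaks = peaks, si = si)
    })
}

#' Simulate replicate peak sets with IDR values
#'
#' Builds `nShared` peaks present in both replicates — jittered by a few
#' bp and carrying correlated scores and a low IDR (uniform on
#' `[0, sharedIdrMax)`) — plus replicate-specific peaks that receive no
#' counterpart (IDR 1 after [annotateIdr()]).
#'
#' @param config a [simulationConfig()] (genome and seed are used).
#' @param nShared,nSpecific1,nSpecific2 peak counts.
#' @param sharedIdrMax upper bound of shared-peak IDR draws
#'   (default 0.009, i.e. below the conventional 0.01 cutoff).
#' @return list with annotated `rep1`, `rep2` (`GRanges` with `idr`), and
#'   `truth` (the planted counts).
#' @export
simulatePeakScores <- function(config, nShared = 100L, nSpecific1 = 20L,
                               nSpecific2 = 15L, sharedIdrMax = 0.009) {
    withSeed(config$seed, {
        si <- Seqinfo(names(config$genome), unname(config$genome))
        tot <- nShared + nSpecific1 + nSpecific2
        base <- placeIntervals(config$genome, tot,
                               rep(250L, tot), gap = 400L)
        seqinfo(base) <- si
        shared <- base[seq_len(nShared)]
        sp1 <- base[nShared + seq_len(nSpecific1)]
        sp2 <- base[nShared + nSpecific1 + seq_len(nSpecific2)]
        jitter <- function(gr) suppressWarnings(trim(GenomicRanges::shift(
            gr, sample(-10:10, length(gr), replace = TRUE))))
        idrShared <- runif(nShared, 0, sharedIdrMax)
        score <- rexp(nShared, 1 / 20) + 5
        deco <- function(gr, sc) {
            mcols(gr) <- DataFrame(name = paste0("p", seq_along(gr)),
                                   score = round(sc), foldChange = NA_real_,
                                   negLog10P = sc, negLog10Fdr = NA_real_,
                                   idr = NA_real_)
            gr
        }
        rep1 <- deco(c(granges(shared), granges(sp1)),
                     c(score, rexp(nSpecific1, 1 / 5) + 3))
        rep2 <- deco(c(granges(jitter(shared)), granges(sp2)),
                     c(score + rnorm(nShared, 0, 2),
                       rexp(nSpecific2, 1 / 5) + 3))
        idr1 <- c(idrShared, rep(NA_real_, nSpecific1))
        idr2 <- c(idrShared, rep(NA_real_, nSpecific2))
        list(rep1 = annotateIdr(rep1, idr1),
             rep2 = annotateIdr(rep2, idr2),
             truth = list(nShared = nShared, nSpecific1 = nSpecific1,
                          nSpecific2 = nSpecific2))
    })
}

#' Simulate gene models and ontology annotations
#'
#' Places `nGenes` non-overlapping stranded genes and partitions them over
#' `nTerms` ontology terms; `term_1` is the designated (potentially
#' enriched) term. Optionally writes BED-like gene and two-column
#' annotation files.
#'
#' @param config a [simulationConfig()].
#' @param dir optional output directory for `genes.tsv` and `terms.tsv`.
#' @return list with `genes` (`GRanges`, `id` metadata), `annotations`
#'   (`data.frame` gene/term), `enrichedTerm`, `si`, and file paths when
#'   `dir` was given.
#' @export
simulateAnnotation <- function(config, dir = NULL) {
    withSeed(config$seed + 1L, {
        si <- Seqinfo(names(config$genome), unname(config$genome))
        genes <- placeIntervals(config$genome, config$nGenes,
                                rep(config$geneWidth, config$nGenes),
                                gap = 500L)
        seqinfo(genes) <- si
        strand(genes) <- sample(c("+", "-"), config$nGenes, replace = TRUE)
        mcols(genes)$id <- sprintf("gene_%03d", seq_len(config$nGenes))
        term <- paste0("term_", rep_len(seq_len(config$nTerms),
                                        config$nGenes))
        ann <- data.frame(gene = mcols(genes)$id,
                          term = term[sample.int(config$nGenes)])
        out <- list(genes = genes, annotations = ann,
                    enrichedTerm = "term_1", si = si)
        if (!is.null(dir)) {
            dir.create(dir, showWarnings = FALSE, recursive = TRUE)
            gf <- file.path(dir, "genes.tsv")
            writeLines(sprintf("%s\t%d\t%d\t%s\t0\t%s",
                               as.character(seqnames(genes)),
                               start(genes) - 1L, end(genes),
                               mcols(genes)$id,
                               as.character(strand(genes))), gf)
            tf <- file.path(dir, "terms.tsv")
            utils::write.table(ann, tf, sep = "\t", quote = FALSE,
                               row.names = FALSE, col.names = FALSE)
            out$genesFile <- gf
            out$termsFile <- tf
        }
        out
    })
}

#' Simulate peaks enriched in one term's regulatory domains
#'
#' Places `nPeaks` peak centers so that read density inside the designated
#' term's regulatory-domain union is `termEnrichment`-fold the density
#' elsewhere (factor 1 gives uniform placement).
#'
#' @param annotation output of [simulateAnnotation()].
#' @param config a [simulationConfig()] (`termEnrichment`, `nPeaks`,
#'   `seed`).
#' @param U,D,UE,DE regulatory-domain parameters (see [buildDomains()]).
#' @return `GRanges` of peaks.
#' @export
simulateTermPeaks <- function(annotation, config,
                              U = 5000L, D = 1000L, UE = 0L, DE = 0L) {
    withSeed(config$seed + 2L, {
        si <- annotation$si
        domains <- buildDomains(annotation$genes, U, D, UE, DE)
        enr <- domains[mcols(domains)$id %in%
            annotation$annotations$gene[annotation$annotations$term ==
                                        annotation$enrichedTerm]]
        enrU <- reduce(granges(enr), ignore.strand = TRUE)
        G <- sum(as.numeric(seqlengths(si)))
        L1 <- sum(width(enrU))
        f <- config$termEnrichment
        wProb <- f * L1 / (G - L1 + f * L1)
        n <- config$nPeaks
        inEnr <- runif(n) < wProb
        rest <- GenomicRanges::setdiff(genomeRanges(si), enrU,
                                       ignore.strand = TRUE)
        c1 <- sample5prime(enrU, sum(inEnr))
        c2 <- sample5prime(rest, sum(!inEnr))
        cts <- rbind(c1, c2)
        w <- 200L
        gr <- trim(suppressWarnings(
            GRanges(cts$chrom,
                    IRanges(pmax(1L, cts$pos5 - w %/% 2L), width = w),
                    seqinfo = si)))
        mcols(gr) <- DataFrame(name = paste0("gp_", seq_along(gr)),
                               score = 100, foldChange = NA_real_,
                               negLog10P = rexp(length(gr), 1 / 10) + 2,
                               negLog10Fdr = NA_real_, idr = NA_real_)
        gr
    })
}
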