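#' Run the post-processing pipeline end to end
#'
#' Orchestrates the stages over a sample table: read filtering (MAPQ,
#' pair geometry, multi-mapper policy), duplicate marking and library
#' complexity, normalized coverage tracks, then either fold-change
#' filtering of broad domains (broad profile) or IDR consistency
#' bookkeeping (punctate profile with replicates), peak-to-gene
#' assignment, binomial GO enrichment, and duplicate diagnostics. Every
#' number in the summary TSVs is produced by the corresponding exported
#' function on the stage outputs. A machine-readable `manifest.json`
#' records outputs and headline quantities.
#'
#' @param config a YAML file path or an equivalent nested list. Keys:
#'   `mode` (`se`/`pe`), `profile` (`punctate`/`broad`), `seed`,
#'   `output_dir`, `samples` (list of `id`, `role` (`IP`/`control`),
#'   `replicate`, `sam`), optional `filter`, `tracks`, `peaks` (punctate:
#'   IDR-annotated encodePeak paths `rep1`, `rep2`, `self1`, `self2`,
#'   `merged_pseudo`, plus `idr_cutoff`), `domains` (broad: SICER
#'   `islands` path and `min_fold_change`), `annotation` (`genes`,
#'   `terms`, `max_distance`, `go` with `U`/`D`/`UE`/`DE`).
#' @return invisibly, the manifest list.
#' @export
runPipeline <- function(config) {
    if (is.character(config)) config <- yaml::read_yaml(config)
    cfg <- config
    stopifnot2(!is.null(cfg$output_dir), "config needs output_dir")
    stopifnot2(length(cfg$samples) >= 1L, "config needs a samples table")
    roles <- vapply(cfg$samples, `[[`, "", "role")
    stopifnot2(any(roles == "IP"), "at least one IP sample required")
    mode <- cfg$mode %||% "se"
    profile <- cfg$profile %||% "punctate"
    if (profile == "broad" && !is.null(cfg$peaks))
        stop("broad profile does not support the IDR stage", call. = FALSE)
    seed <- cfg$seed %||% 42L
    fcfg <- cfg$filter %||% list()
    mapq <- fcfg$mapq %||% 20L
    removeDup <- fcfg$remove_duplicates %||% TRUE
    tcfg <- cfg$tracks %||% list()
    outdir <- cfg$output_dir
    dir.create(outdir, showWarnings = FALSE, recursive = TRUE)
    manifest <- list(mode = mode, profile = profile, seed = seed,
                     outputs = list(), numbers = list())
    stage <- function(name, expr) {
        message("[peakforge] stage: ", name)
        tryCatch(expr, error = function(e)
            stop("stage '", name, "' failed: ", conditionMessage(e),
                 call. = FALSE))
    }

    # ---- filter + dedup + complexity ---------------------------------
    filtered <- list()
    complexity <- NULL
    firstIPMarked <- NULL
    for (s in cfg$samples) {
        rs <- stage(paste0("read:", s$id), readSAM(s$sam))
        stage(paste0("filter:", s$id), {
            if (mode == "pe") {
                pairs <- pairReads(rs)
                pairs <- filterMapqPairs(pairs, mapq,
                    keepMultiBothZero = fcfg$keep_multi_both_zero %||% FALSE)
                pairs <- filterProperPairs(pairs,
                    minInsert = fcfg$min_insert %||% 1L,
                    maxInsert = fcfg$max_insert %||% 1000L)
                pairs <- applyMultimapPolicy(pairs,
                    policy = fcfg$policy %||% "unique_only")
                marked <- markDuplicates(pairs)
                nTot <- length(marked)
                kept <- if (removeDup) dedup(marked) else marked
                filtered[[s$id]] <- kept
                cx <- libraryComplexity(nTot,
                    sum(!mcols(firstMate(marked))$isDuplicate))
            } else {
                reads <- filterMapqSingle(mappedReads(rs), mapq,
                    exemptMapq0 = fcfg$se_random_match %||% FALSE)
                marked <- markDuplicates(reads)
                nTot <- length(marked)
                kept <- if (removeDup) dedup(marked) else marked
                filtered[[s$id]] <- kept
                cx <- libraryComplexity(nTot,
                                        sum(!mcols(marked)$isDuplicate))
            }
            if (s$role == "IP" && is.null(firstIPMarked))
                firstIPMarked <- marked
            complexity <- rbind(complexity,
                cbind(library = s$id, as.data.frame(cx)))
        })
    }
    cxPath <- file.path(outdir, "complexity.tsv")
    utils::write.table(complexity, cxPath, sep = "\t", quote = FALSE,
                       row.names = FALSE)
    manifest$outputs$complexity <- cxPath

    # ---- coverage tracks ---------------------------------------------
    stage("tracks", {
        for (id in names(filtered)) {
            x <- filtered[[id]]
            frags <- if (is(x, "ReadPairs")) fragmentFromPair(x)
                     else extendSingleEnd(x,
                         tcfg$fragment_length %||% 200L)
            track <- coverageFromFragments(frags)
            if (tcfg$normalize %||% TRUE)
                track <- normalizePerMillion(track, length(frags))
            bg <- file.path(outdir, paste0(id, ".bedgraph"))
            wg <- file.path(outdir, paste0(id, ".wig"))
            writeTrack(track, bg, "bedgraph", name = id)
            writeTrack(track, wg, "wig", step = tcfg$step %||% 20L,
                       name = id)
            manifest$outputs$tracks <-
                c(manifest$outputs$tracks, bg, wg)
        }
    })

    # ---- peak stage ---------------------------------------------------
    mainPeaks <- NULL
    if (profile == "broad" && !is.null(cfg$domains)) {
        stage("fold-change-filter", {
            islands <- readPeaks(cfg$domains$islands, "sicer_summary")
            kept <- foldChangeFilter(islands,
                threshold = cfg$domains$min_fold_change %||% 2.0)
            bed <- file.path(outdir, "domains_filtered.bed")
            writePeaks(kept, bed, "bed")
            manifest$outputs$domains <- bed
            manifest$numbers$domains_input <- length(islands)
            manifest$numbers$domains_kept <- length(kept)
            mainPeaks <- kept
        })
    } else if (!is.null(cfg$peaks)) {
        stage("idr-report", {
            pk <- cfg$peaks
            cutoff <- pk$idr_cutoff %||% 0.01
            sets <- list(
                true_replicates = readPeaks(pk$rep1, "encodePeak"),
                self_rep1 = readPeaks(pk$self1, "encodePeak"),
                self_rep2 = readPeaks(pk$self2, "encodePeak"),
                merged_pseudo = readPeaks(pk$merged_pseudo, "encodePeak"))
            counts <- vapply(sets, countConsistent, numeric(1),
                             cutoff = cutoff)
            rep <- assessReproducibility(counts[["true_replicates"]],
                                         counts[["merged_pseudo"]],
                                         counts[["self_rep1"]],
                                         counts[["self_rep2"]])
            tab <- consistencyTable(sets)
            rp <- file.path(outdir, "repro.tsv")
            ratios <- reproducibilityRatios(rep)
            summary <- data.frame(
                n_true = rep@nTrue, n_merged_pseudo = rep@nMergedPseudo,
                n_self_1 = rep@nSelf1, n_self_2 = rep@nSelf2,
                rescue_ratio = ratios[["rescue"]],
                self_ratio = ratios[["self"]],
                pass = rep@pass,
                conservative_n = rep@conservativeN,
                optimal_n = rep@optimalN)
            utils::write.table(summary, rp, sep = "\t", quote = FALSE,
                               row.names = FALSE)
            utils::write.table(tab,
                file.path(outdir, "repro_cutoffs.tsv"), sep = "\t",
                quote = FALSE, row.names = FALSE)
            manifest$outputs$repro <- rp
            manifest$numbers$rescue_ratio <- ratios[["rescue"]]
            manifest$numbers$self_ratio <- ratios[["self"]]
            manifest$numbers$pass <- rep@pass
            manifest$numbers$conservative_n <- rep@conservativeN
            manifest$numbers$optimal_n <- rep@optimalN
            cons <- sets$true_replicates
            mainPeaks <- cons[mcols(cons)$idr <= cutoff]
        })
    }

    # ---- annotation stages -------------------------------------------
    if (!is.null(cfg$annotation) && !is.null(mainPeaks) &&
        length(mainPeaks)) {
        acfg <- cfg$annotation
        genes <- stage("read-genes", readGenes(acfg$genes))
        stage("assign-genes", {
            asn <- assignPeaksToGenes(mainPeaks, genes,
                maxDistance = acfg$max_distance %||% 10000L)
            ap <- file.path(outdir, "peak_vs_gene.tsv")
            utils::write.table(asn, ap, sep = "\t", quote = FALSE,
                               row.names = FALSE)
            manifest$outputs$peak_vs_gene <- ap
            manifest$numbers$assigned_peaks <- length(unique(asn$peak))
        })
        if (!is.null(acfg$terms)) stage("go-enrichment", {
            ann <- readTermAnnotations(acfg$terms)
            gcfg <- acfg$go %||% list()
            annotated <- genes[mcols(genes)$id %in% ann$gene]
            doms <- buildDomains(annotated,
                U = gcfg$U %||% 5000L, D = gcfg$D %||% 1000L,
                UE = gcfg$UE %||% 0L, DE = gcfg$DE %||% 0L)
            go <- binomialEnrichment(mainPeaks, doms, ann)
            gp <- file.path(outdir, "go_enrichment.tsv")
            utils::write.table(go, gp, sep = "\t", quote = FALSE,
                               row.names = FALSE)
            manifest$outputs$go <- gp
            if (nrow(go)) manifest$numbers$top_go_term <- go$term[1L]
        })
    }

    # ---- duplicate diagnostics ---------------------------------------
    if (!is.null(mainPeaks) && length(mainPeaks) >= 10L &&
        !is.null(firstIPMarked)) stage("dup-diagnostics", {
        reads <- if (is(firstIPMarked, "ReadPairs"))
            firstMate(firstIPMarked) else firstIPMarked
        si <- seqinfo(reads)
        top <- selectTopPeaks(mainPeaks, "fraction", 0.1)
        regions <- list(all_peaks = granges(mainPeaks),
                        top_peaks = granges(top),
                        non_peak = nonpeakComplement(mainPeaks, si = si))
        ds <- regionDupStats(reads, regions)
        dp <- file.path(outdir, "dup_regions.tsv")
        utils::write.table(ds, dp, sep = "\t", quote = FALSE,
                           row.names = FALSE)
        prof <- decileProfile(mainPeaks, reads,
            rankBy = if (profile == "broad") "negLog10Fdr" else "negLog10P")
        pp <- file.path(outdir, "dup_profile.tsv")
        utils::write.table(prof, pp, sep = "\t", quote = FALSE,
                           row.names = FALSE)
        manifest$outputs$dup_regions <- dp
        manifest$outputs$dup_profile <- pp
        manifest$numbers$all_peaks_dup_pct <-
            ds$dup_pct[ds$class == "all_peaks"]
        manifest$numbers$non_peak_dup_pct <-
            ds$dup_pct[ds$class == "non_peak"]
    })

    mp <- file.path(outdir, "manifest.json")
    jsonlite::write_json(manifest, mp, auto_unbox = TRUE, digits = NA,
                         pretty = TRUE)
    message("[peakforge] done; manifest at ", mp)
    invisible(manifest)
}
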