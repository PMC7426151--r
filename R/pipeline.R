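#' Default pipeline configuration
#'
#' All thresholds default to the analysis conventions used throughout the
#' package: TD threshold tau = 1.25, DE fold-change threshold 1.25, BY FDR
#' < 0.005, ORA BH-adjusted p < 0.01. Growth defaults mirror the
#' fermentative/nonfermentative contrast the simulator emulates (a lower
#' maximum growth rate and carrying-capacity plateau on ethanol than on
#' glucose).
#'
#' @param sim a [simConfig()] (or argument list for one).
#' @param timepoints time points to simulate and analyze.
#' @param tau TD threshold.
#' @param fcThreshold,fdrThreshold,deMethod DE-calling parameters.
#' @param oraCutoff ORA adjusted-p cutoff.
#' @param nIter resampling/permutation iterations.
#' @param tauGrid TD-threshold sweep grid.
#' @param growth named list of per-medium logistic parameters.
#' @param seed master seed; stage streams are derived from it.
#' @return list of class `"PipelineConfig"`.
#' @export
pipelineConfig <- function(sim = simConfig(),
                           timepoints = c("t0", "t100", "t110"),
                           tau = 1.25, fcThreshold = 1.25,
                           fdrThreshold = 0.005, deMethod = "BY",
                           oraCutoff = 0.01, nIter = 1000,
                           tauGrid = seq(1, 4, by = 0.5),
                           growth = list(
                               YPD = list(K = 1.3, r = 0.21, N0 = 0.06),
                               YPE = list(K = 1.1, r = 0.13, N0 = 0.06)),
                           seed = 1L) {
    if (!inherits(sim, "SimConfig")) sim <- do.call(simConfig, sim)
    if (tau < 1 || fcThreshold <= 0 || fdrThreshold <= 0 || oraCutoff <= 0)
        stop("invalid PipelineConfig: thresholds must be positive ",
             "(tau >= 1)")
    cfg <- list(sim = sim, timepoints = timepoints, tau = tau,
                fcThreshold = fcThreshold, fdrThreshold = fdrThreshold,
                deMethod = deMethod, oraCutoff = oraCutoff,
                nIter = as.integer(nIter), tauGrid = tauGrid,
                growth = growth, seed = as.integer(seed))
    class(cfg) <- "PipelineConfig"
    cfg
}

#' Run the full synthetic-data analysis pipeline
#'
#' Simulates a genome (catalog, counts, growth curves, annotation map),
#' then runs every analysis stage: differential expression per time point,
#' DE-set overlaps across time points, duplicate-vs-singleton and WGD-vs-SSD
#' Fisher enrichment, TD computation per time point with binomial TD
#' enrichment and the resampling null of the mean responder fold change,
#' five-way pair categories with their permutation null, the TD-threshold
#' sweep, logistic growth fits with a YPE/YPD comparison, and ORA of the
#' upregulated set against the simulated annotation. All stage outputs are
#' written as TSV under `outDir` together with a plain-text summary; the
#' run is fully determined by the seeds in the config.
#'
#' @param config a [pipelineConfig()].
#' @param outDir output directory (created if missing).
#' @return invisibly, a list with every stage result and the output paths.
#' @export
runPipeline <- function(config = pipelineConfig(), outDir = tempfile("tdrun")) {
    if (!inherits(config, "PipelineConfig"))
        stop("config must be a pipelineConfig()")
    dir.create(outDir, showWarnings = FALSE, recursive = TRUE)
    pth <- function(...) file.path(outDir, ...)
    wtab <- function(df, name) {
        utils::write.table(as.data.frame(df), pth(name), sep = "\t",
                           quote = FALSE, row.names = FALSE)
        name
    }
    logline <- function(...) message("[dupliTD] ", ...)
    simc <- config$sim
    simc$seed <- config$seed

    logline("simulating catalog and counts")
    sim <- simulateCatalog(simc)
    design <- makeDesign(timepoints = config$timepoints,
                         nReplicates = simc$nReplicates)
    dcs <- simulateCounts(sim$catalog, sim$truth, simc, design)
    writeCountMatrix(dcs, pth("counts.tsv"), pth("design.tsv"))
    writeCatalog(sim$catalog, pth("catalog.tsv"))
    wtab(sim$truth$genes, "truth_genes.tsv")
    wtab(sim$truth$pairs, "truth_pairs.tsv")

    logline("differential expression per time point")
    de <- lapply(config$timepoints, function(tp)
        runDGE(dcs, tp, config$fcThreshold, config$fdrThreshold,
               config$deMethod))
    names(de) <- config$timepoints
    for (tp in config$timepoints)
        wtab(deTable(de[[tp]]), paste0("de_", tp, ".tsv"))

    logline("DE-set overlaps")
    upSets <- lapply(de, function(d) names(deCalls(d))[deCalls(d) == "up"])
    downSets <- lapply(de, function(d)
        names(deCalls(d))[deCalls(d) == "down"])
    overlaps <- list(up = overlapSummary(upSets),
                     down = overlapSummary(downSets))
    wtab(overlaps$up$pairwise, "overlap_up.tsv")
    wtab(overlaps$down$pairwise, "overlap_down.tsv")

    cls <- geneClasses(sim$catalog)
    enrRows <- list()
    tdRes <- list()
    catNull <- list()
    resampRes <- list()
    sweeps <- list()
    sf <- computeSizeFactors(dcs)
    for (tp in config$timepoints) {
        logline("TD analysis at ", tp)
        calls <- deCalls(de[[tp]])
        lfcs <- stats::setNames(deTable(de[[tp]])$lfc,
                                deTable(de[[tp]])$gene)
        tdTab <- computeTD(dcs, sim$catalog, tp, "YPD", config$tau,
                           sizeFactors = sf)
        tdRes[[tp]] <- tdTab
        wtab(tdTab, paste0("td_", tp, ".tsv"))

        # duplicate vs singleton enrichment among called genes
        for (dir in c("up", "down")) {
            isDup <- cls != "singleton"
            called <- calls == dir
            tab <- matrix(c(sum(isDup & called), sum(isDup & !called),
                            sum(!isDup & called), sum(!isDup & !called)),
                          2, byrow = TRUE)
            fe <- fisherEnrichment(tab)
            enrRows[[length(enrRows) + 1L]] <- data.frame(
                timepoint = tp, contrast = "duplicate_vs_singleton",
                direction = dir, oddsRatio = fe$oddsRatio, p = fe$p,
                stringsAsFactors = FALSE)
            wgdCalled <- sum(cls == "WGD" & called)
            ssdCalled <- sum(cls == "SSD" & called)
            tab2 <- matrix(c(wgdCalled, sum(cls == "WGD") - wgdCalled,
                             ssdCalled, sum(cls == "SSD") - ssdCalled),
                           2, byrow = TRUE)
            fe2 <- fisherEnrichment(tab2)
            enrRows[[length(enrRows) + 1L]] <- data.frame(
                timepoint = tp, contrast = "WGD_vs_SSD", direction = dir,
                oddsRatio = fe2$oddsRatio, p = fe2$p,
                stringsAsFactors = FALSE)
        }

        # binomial TD enrichment + resampling null of mean responder |lfc|
        ok <- tdTab[!tdTab$excluded & !is.na(tdTab$td), , drop = FALSE]
        poolGenes <- c(ok$gene_a, ok$gene_b)
        tdGenes <- c(ok$gene_a[ok$td], ok$gene_b[ok$td])
        p0 <- length(tdGenes) / length(poolGenes)
        for (dir in c("up", "down")) {
            resp <- poolGenes[calls[poolGenes] == dir]
            k <- sum(resp %in% tdGenes)
            n <- length(resp)
            pEnr <- if (n > 0 && p0 > 0 && p0 < 1)
                binomialTdEnrichment(k, n, p0)$p else NA_real_
            enrRows[[length(enrRows) + 1L]] <- data.frame(
                timepoint = tp, contrast = "TD_binomial", direction = dir,
                oddsRatio = NA_real_, p = pEnr, stringsAsFactors = FALSE)
            respTd <- resp[resp %in% tdGenes]
            poolLfc <- abs(lfcs[tdGenes])
            if (length(respTd) >= 3 && length(respTd) <= length(poolLfc)) {
                rs <- resamplingNullMean(
                    poolLfc, length(respTd), mean(abs(lfcs[respTd])),
                    nIter = config$nIter,
                    seed = config$seed + 100L + match(tp, config$timepoints))
                resampRes[[paste(tp, dir)]] <- rs
            }
        }

        dupCalls <- calls[unique(c(ok$gene_a, ok$gene_b))]
        catNull[[tp]] <- categoryCountNull(
            ok, dupCalls, nIter = config$nIter,
            seed = config$seed + 200L + match(tp, config$timepoints))
        wtab(catNull[[tp]], paste0("category_null_", tp, ".tsv"))

        sweeps[[tp]] <- tdThresholdSweep(tdTab, calls, config$tauGrid)
        wtab(sweeps[[tp]], paste0("td_sweep_", tp, ".tsv"))
    }
    enrichment <- do.call(rbind, enrRows)
    wtab(enrichment, "enrichment.tsv")

    logline("growth curves")
    growthTabs <- lapply(names(config$growth), function(med) {
        g <- config$growth[[med]]
        od <- simulateGrowthCurves(g$K, g$r, g$N0,
                                   times = seq(0, 78, by = 0.25),
                                   noiseSd = 0.01, nWells = 7,
                                   seed = config$seed + 300L +
                                       match(med, names(config$growth)))
        od$well <- paste0(med, "_", od$well)
        od$medium <- med
        od
    })
    odAll <- do.call(rbind, growthTabs)
    wtab(odAll, "od600.tsv")
    fits <- fitGrowthTable(odAll)
    fits$medium <- sub("_.*", "", fits$well)
    wtab(fits, "growth_fits.tsv")
    media <- unique(fits$medium)
    growthCmp <- if (length(media) >= 2L)
        compareGrowth(fits[fits$medium == media[1], ],
                      fits[fits$medium == media[2], ]) else NULL
    if (!is.null(growthCmp)) wtab(growthCmp, "growth_comparison.tsv")

    logline("over-representation analysis")
    trueUp <- sim$truth$genes$gene[sim$truth$genes$isDe &
                                   sim$truth$genes$lfc > 0]
    annot <- simulateAnnotationMap(sim$catalog, nTerms = 50,
                                   genesPerTerm = 40,
                                   plantedGenes = utils::head(trueUp, 40),
                                   seed = config$seed + 400L)
    wtab(annot, "annotation.tsv")
    oraRes <- hypergeometricOra(upSets[[1]], annot, geneIds(sim$catalog),
                                config$oraCutoff)
    wtab(oraRes, "ora_up_t0.tsv")

    logline("summary")
    sm <- c(
        sprintf("genes: %d (%d singletons, %d WGD pairs, %d SSD pairs)",
                length(cls), sum(cls == "singleton"),
                sum(cls == "WGD") / 2, sum(cls == "SSD") / 2),
        sprintf("samples: %d", ncol(dcs)),
        vapply(config$timepoints, function(tp) {
            calls <- deCalls(de[[tp]])
            sprintf("%s: %d up, %d down; TD pairs (tau=%.2f): %d/%d",
                    tp, sum(calls == "up"), sum(calls == "down"),
                    config$tau, sum(tdRes[[tp]]$td, na.rm = TRUE),
                    nrow(tdRes[[tp]]))
        }, character(1)),
        sprintf("core up genes: %d; core down genes: %d",
                overlaps$up$coreSize, overlaps$down$coreSize))
    writeLines(sm, pth("summary.txt"))
    invisible(list(outDir = outDir, catalog = sim$catalog,
                   truth = sim$truth, counts = dcs, de = de,
                   overlaps = overlaps, enrichment = enrichment,
                   td = tdRes, categoryNull = catNull,
                   resampling = resampRes, sweeps = sweeps,
                   growthFits = fits, growthComparison = growthCmp,
                   ora = oraRes))
}
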