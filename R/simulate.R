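#' Simulation configuration
#'
#' Bundles and validates all parameters of the synthetic-data generator. The
#' defaults emulate a yeast-like genome: 555 whole-genome-duplicate (WGD)
#' pairs and 560 small-scale-duplicate (SSD) pairs among roughly 6,000 genes,
#' with about 80% of duplicate pairs transcriptionally diverged, three
#' biological replicates per condition, and negative-binomial count noise.
#'
#' @param nSingletons number of singleton genes.
#' @param nWgdPairs,nSsdPairs numbers of WGD and SSD pairs.
#' @param fracTdPairs proportion of duplicate pairs with a planted copy-wise
#'   expression divergence.
#' @param tdLogRatioSd spread (sd, natural-log scale) of the planted copy
#'   log-ratio; the magnitude is `|N(0, tdLogRatioSd)|`, applied
#'   multiplicatively to a randomly chosen copy.
#' @param fracDe baseline proportion of genes with a condition (YPE vs YPD)
#'   effect.
#' @param deLfcMean,deLfcSd mean and sd of the planted log2 condition effect.
#' @param dispersion negative-binomial dispersion phi (variance =
#'   mu + phi * mu^2).
#' @param libSizeMean expected library size (total counts per sample).
#' @param libSizeSdlog sd (log scale) of the lognormal library-size factors;
#'   0 gives identical library sizes.
#' @param nReplicates replicates per (medium, timepoint) condition.
#' @param deTdCoupling log-odds increment that a gene belonging to a
#'   transcriptionally diverged pair carries a condition effect; 0 decouples
#'   divergence from the condition response.
#' @param seed integer seed; every simulator call derives its stream from it.
#' @return a validated list of class `"SimConfig"`.
#' @export
simConfig <- function(nSingletons = 3770, nWgdPairs = 555, nSsdPairs = 560,
                      fracTdPairs = 0.8, tdLogRatioSd = 0.5,
                      fracDe = 0.2, deLfcMean = 0, deLfcSd = 1.5,
                      dispersion = 0.1, libSizeMean = 5e5,
                      libSizeSdlog = 0.15, nReplicates = 3,
                      deTdCoupling = 0, seed = 1L) {
    cfg <- list(nSingletons = as.integer(nSingletons),
                nWgdPairs = as.integer(nWgdPairs),
                nSsdPairs = as.integer(nSsdPairs),
                fracTdPairs = fracTdPairs, tdLogRatioSd = tdLogRatioSd,
                fracDe = fracDe, deLfcMean = deLfcMean, deLfcSd = deLfcSd,
                dispersion = dispersion, libSizeMean = libSizeMean,
                libSizeSdlog = libSizeSdlog,
                nReplicates = as.integer(nReplicates),
                deTdCoupling = deTdCoupling, seed = as.integer(seed))
    bad <- function(m) stop("invalid SimConfig: ", m, call. = FALSE)
    if (cfg$nSingletons < 0 || cfg$nWgdPairs < 0 || cfg$nSsdPairs < 0)
        bad("gene and pair counts must be >= 0")
    for (p in c("fracTdPairs", "fracDe"))
        if (cfg[[p]] < 0 || cfg[[p]] > 1)
            bad(paste(p, "must lie in [0, 1]"))
    if (cfg$tdLogRatioSd < 0) bad("tdLogRatioSd must be >= 0")
    if (cfg$dispersion < 0) bad("dispersion must be >= 0")
    if (cfg$libSizeMean <= 0) bad("libSizeMean must be > 0")
    if (cfg$libSizeSdlog < 0) bad("libSizeSdlog must be >= 0")
    if (cfg$nReplicates < 1) bad("nReplicates must be >= 1")
    class(cfg) <- "SimConfig"
    cfg
}

#' Simulate a gene catalog with planted copy-wise divergence
#'
#' Generates singleton, WGD and SSD gene identifiers, pairs the duplicates,
#' and plants a transcriptional divergence in a fraction `fracTdPairs` of
#' pairs: the log-ratio magnitude is drawn as `|N(0, tdLogRatioSd)|` and
#' applied to a randomly chosen copy; the remaining pairs have copy ratio
#' exactly 1. Condition (DE) effects are assigned per gene with probability
#' `plogis(qlogis(fracDe) + deTdCoupling * inTdPair)` and effect sizes
#' `N(deLfcMean, deLfcSd)` on the log2 scale.
#'
#' @param cfg a [simConfig()] object.
#' @return a list with `catalog` (a [GeneCatalog-class]) and `truth`, itself a
#'   list of `genes` (DataFrame: gene, baseline, lfc, isDe) and `pairs`
#'   (DataFrame: pair_id, class, gene_a, gene_b, copy_ratio, divergent_copy,
#'   log_ratio). `baseline` is the expected YPD count at unit library factor.
#' @export
simulateCatalog <- function(cfg) {
    if (!inherits(cfg, "SimConfig")) cfg <- do.call(simConfig, cfg)
    set.seed(cfg$seed)
    sgl <- sprintf("SGL%05d", seq_len(cfg$nSingletons))
    wgdA <- sprintf("WGD%04dA", seq_len(cfg$nWgdPairs))
    wgdB <- sprintf("WGD%04dB", seq_len(cfg$nWgdPairs))
    ssdA <- sprintf("SSD%04dA", seq_len(cfg$nSsdPairs))
    ssdB <- sprintf("SSD%04dB", seq_len(cfg$nSsdPairs))
    nPairs <- cfg$nWgdPairs + cfg$nSsdPairs
    pairId <- c(sprintf("WGDP%04d", seq_len(cfg$nWgdPairs)),
                sprintf("SSDP%04d", seq_len(cfg$nSsdPairs)))
    pairClass <- rep(c("WGD", "SSD"), c(cfg$nWgdPairs, cfg$nSsdPairs))
    geneA <- c(wgdA, ssdA); geneB <- c(wgdB, ssdB)

    info <- DataFrame(
        gene = c(sgl, geneA, geneB),
        class = c(rep("singleton", cfg$nSingletons), pairClass, pairClass),
        pair_id = c(rep(NA_character_, cfg$nSingletons), pairId, pairId),
        partner = c(rep(NA_character_, cfg$nSingletons), geneB, geneA))
    catalog <- new("GeneCatalog", info = info)

    isTd <- if (nPairs) stats::runif(nPairs) < cfg$fracTdPairs else logical(0)
    mag <- ifelse(isTd, abs(stats::rnorm(nPairs, 0, cfg$tdLogRatioSd)), 0)
    divergent <- ifelse(stats::runif(nPairs) < 0.5, "a", "b")
    divergent[!isTd] <- NA_character_
    logRatio <- ifelse(is.na(divergent), 0,
                       ifelse(divergent == "a", mag, -mag))

    genes <- as.character(info$gene)
    nGenes <- length(genes)
    rel <- stats::rlnorm(nGenes, meanlog = 0, sdlog = 1)
    names(rel) <- genes
    # planted copy divergence: chosen copy multiplied by exp(magnitude);
    # both copies share the pair's baseline draw
    if (nPairs) {
        rel[geneB] <- rel[geneA]
        tdIdx <- which(isTd)
        upGene <- ifelse(divergent[tdIdx] == "a", geneA[tdIdx], geneB[tdIdx])
        rel[upGene] <- rel[upGene] * exp(mag[tdIdx])
    }
    baseline <- rel / sum(rel) * cfg$libSizeMean

    inTd <- genes %in% c(geneA[isTd], geneB[isTd])
    pDe <- stats::plogis(stats::qlogis(cfg$fracDe) + cfg$deTdCoupling * inTd)
    isDe <- stats::runif(nGenes) < pDe
    lfc <- ifelse(isDe, stats::rnorm(nGenes, cfg$deLfcMean, cfg$deLfcSd), 0)

    truth <- list(
        genes = DataFrame(gene = genes, baseline = unname(baseline),
                          lfc = lfc, isDe = isDe),
        pairs = DataFrame(pair_id = pairId, class = pairClass,
                          gene_a = geneA, gene_b = geneB,
                          copy_ratio = exp(mag), divergent_copy = divergent,
                          log_ratio = logRatio))
    list(catalog = catalog, truth = truth)
}

#' Build a sample design table
#'
#' @param timepoints character vector of time points.
#' @param media character vector of growth media.
#' @param nReplicates replicates per (timepoint, medium) cell.
#' @param line evolution-line label.
#' @return data.frame with sample, line, timepoint, medium, replicate.
#' @export
makeDesign <- function(timepoints = "t0", media = c("YPD", "YPE"),
                       nReplicates = 3, line = "a1") {
    grid <- expand.grid(replicate = seq_len(nReplicates), medium = media,
                        timepoint = timepoints, stringsAsFactors = FALSE)
    data.frame(sample = sprintf("%s_%s_%s_r%d", line, grid$timepoint,
                                grid$medium, grid$replicate),
               line = line, timepoint = grid$timepoint,
               medium = grid$medium, replicate = grid$replicate,
               stringsAsFactors = FALSE)
}

#' Simulate RNA-seq counts from a catalog and its planted truth
#'
#' Counts are drawn from a negative binomial with mean
#' `baseline * 2^(lfc * [medium == "YPE"]) * libraryFactor` and variance
#' `mu + dispersion * mu^2` (Poisson when `dispersion == 0`). Library factors
#' are lognormal around 1 with sd `libSizeSdlog` and are recorded in the
#' colData. The per-gene baseline already carries the planted copy-wise
#' divergence (see [simulateCatalog()]).
#'
#' @param catalog a [GeneCatalog-class].
#' @param truth the `truth` list from [simulateCatalog()].
#' @param cfg a [simConfig()].
#' @param design a design data.frame, see [makeDesign()].
#' @return a [DupCountSet-class] with library factors in `colData`.
#' @export
simulateCounts <- function(catalog, truth, cfg,
                           design = makeDesign(nReplicates = cfg$nReplicates)) {
    if (!inherits(cfg, "SimConfig")) cfg <- do.call(simConfig, cfg)
    if (nrow(design) == 0L) stop("design must be non-empty")
    genes <- geneIds(catalog)
    tg <- truth$genes
    if (!setequal(genes, tg$gene))
        stop("truth does not cover the catalog gene universe")
    idx <- match(genes, tg$gene)
    baseline <- tg$baseline[idx]
    lfc <- tg$lfc[idx]
    set.seed(cfg$seed + 1L)
    nS <- nrow(design)
    libFactor <- stats::rlnorm(nS, meanlog = -cfg$libSizeSdlog^2 / 2,
                               sdlog = cfg$libSizeSdlog)
    isYpe <- design$medium == "YPE"
    mu <- outer(baseline, libFactor) *
        2^(outer(lfc, as.numeric(isYpe)))
    cnt <- if (cfg$dispersion == 0) {
        matrix(stats::rpois(length(mu), lambda = mu), nrow = nrow(mu))
    } else {
        matrix(stats::rnbinom(length(mu), mu = mu, size = 1 / cfg$dispersion),
               nrow = nrow(mu))
    }
    dimnames(cnt) <- list(genes, design$sample)
    design$libFactor <- libFactor
    DupCountSet(cnt, design)
}

#' Simulate codon-aligned duplicate CDS pairs at a target synonymous divergence
#'
#' Each pair descends from a random stop-free ancestor of `nCodons` codons;
#' one copy accumulates synonymous single-nucleotide substitutions at
#' distinct codons until the expected NG86 proportion of synonymous
#' differences matches `targetDs` after Jukes-Cantor correction. Amino-acid
#' sequences are preserved by construction and no stop codons are introduced.
#'
#' @param nPairs number of pairs.
#' @param targetDs target dS (synonymous substitutions per synonymous site).
#' @param nCodons codons per sequence (>= 30).
#' @param seed integer seed.
#' @return list with `cds` (a [Biostrings::DNAStringSet], names
#'   `pair####_a/_b`) and `truth` (DataFrame: pair_id, target_ds,
#'   realized_ds).
#' @export
simulateCdsPairs <- function(nPairs, targetDs, nCodons = 300, seed = 1L) {
    if (nCodons < 30) stop("nCodons must be >= 30")
    if (targetDs < 0) stop("targetDs must be >= 0")
    pTarget <- 0.75 * (1 - exp(-4 / 3 * targetDs))
    tabs <- ng86Tables()
    sense <- tabs$sense
    set.seed(seed)
    seqs <- character(2L * nPairs)
    nm <- character(2L * nPairs)
    realized <- numeric(nPairs)
    for (i in seq_len(nPairs)) {
        anc <- sample(sense, nCodons, replace = TRUE)
        s1 <- paste(anc, collapse = "")
        mutable <- which(lengths(tabs$synNeighbors[anc]) > 0L)
        S <- sum(tabs$synSites[anc])
        m <- round(pTarget * S)
        if (m > length(mutable))
            stop("saturation: targetDs unreachable at this sequence length")
        der <- anc
        if (m > 0) {
            at <- sample(mutable, m)
            for (j in at) {
                nb <- tabs$synNeighbors[[anc[j]]]
                der[j] <- nb[sample.int(length(nb), 1L)]
            }
        }
        s2 <- paste(der, collapse = "")
        seqs[2L * i - 1L] <- s1
        seqs[2L * i] <- s2
        nm[2L * i - 1L] <- sprintf("pair%04d_a", i)
        nm[2L * i] <- sprintf("pair%04d_b", i)
        realized[i] <- ng86Ds(s1, s2)$dS
    }
    cds <- Biostrings::DNAStringSet(stats::setNames(seqs, nm))
    truth <- DataFrame(pair_id = sprintf("pair%04d", seq_len(nPairs)),
                       target_ds = targetDs, realized_ds = realized)
    list(cds = cds, truth = truth)
}

#' Simulate logistic OD600 growth curves
#'
#' @param K carrying capacity (OD600), must exceed `N0`.
#' @param r intrinsic growth rate (h^-1).
#' @param N0 initial OD600.
#' @param times measurement grid in hours (default every 15 min over 78 h,
#'   the plate-reader schedule the generator emulates).
#' @param noiseSd sd of additive Gaussian observation noise; values are
#'   floored at 0.
#' @param nWells number of replicate wells.
#' @param seed integer seed.
#' @return data.frame with well, time_h, od600.
#' @export
simulateGrowthCurves <- function(K, r, N0, times = seq(0, 78, by = 0.25),
                                 noiseSd = 0, nWells = 1, seed = 1L) {
    if (!(K > N0 && N0 > 0)) stop("require K > N0 > 0")
    if (r <= 0) stop("require r > 0")
    set.seed(seed)
    mu <- K / (1 + ((K - N0) / N0) * exp(-r * times))
    out <- do.call(rbind, lapply(seq_len(nWells), function(w) {
        od <- mu + stats::rnorm(length(times), 0, noiseSd)
        data.frame(well = sprintf("W%03d", w), time_h = times,
                   od600 = pmax(od, 0), stringsAsFactors = FALSE)
    }))
    rownames(out) <- NULL
    out
}

#' Simulate a term-to-gene annotation map
#'
#' Random terms of size `genesPerTerm` drawn from the gene universe, with an
#' optional planted term enriched in a supplied gene set.
#'
#' @param genes character gene universe (or a [GeneCatalog-class]).
#' @param nTerms number of random terms.
#' @param genesPerTerm genes per random term.
#' @param plantedGenes optional character vector; when given, a term named
#'   `plantedTerm` containing these genes (topped up with random genes to
#'   `genesPerTerm` if shorter) is added.
#' @param plantedTerm name of the planted term.
#' @param seed integer seed.
#' @return data.frame with columns term, gene.
#' @export
simulateAnnotationMap <- function(genes, nTerms, genesPerTerm,
                                  plantedGenes = NULL,
                                  plantedTerm = "PLANTED", seed = 1L) {
    if (is(genes, "GeneCatalog")) genes <- geneIds(genes)
    if (genesPerTerm > length(genes))
        stop("genesPerTerm exceeds the gene universe")
    set.seed(seed)
    rows <- lapply(seq_len(nTerms), function(i)
        data.frame(term = sprintf("T%04d", i),
                   gene = sample(genes, genesPerTerm),
                   stringsAsFactors = FALSE))
    if (!is.null(plantedGenes)) {
        planted <- unique(plantedGenes)
        if (!all(planted %in% genes))
            stop("plantedGenes must lie in the gene universe")
        pad <- setdiff(genes, planted)
        extra <- max(0L, genesPerTerm - length(planted))
        members <- c(planted, if (extra) sample(pad, extra))
        rows <- c(rows, list(data.frame(term = plantedTerm, gene = members,
                                        stringsAsFactors = FALSE)))
    }
    if (length(rows) == 0L)
        return(data.frame(term = character(), gene = character(),
                          stringsAsFactors = FALSE))
    out <- do.call(rbind, rows)
    rownames(out) <- NULL
    out
}
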