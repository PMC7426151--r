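# Small shared fixtures, built in code.

smallSim <- function(seed = 1, ...) {
    args <- utils::modifyList(list(nSingletons = 100, nWgdPairs = 20,
                                   nSsdPairs = 20, seed = seed),
                              list(...))
    cfg <- do.call(simConfig, args)
    sim <- simulateCatalog(cfg)
    list(cfg = cfg, catalog = sim$catalog, truth = sim$truth,
         counts = simulateCounts(sim$catalog, sim$truth, cfg))
}

# a DupCountSet with fully specified means: genes x (3 YPD + 3 YPE)
countsFromMeans <- function(muYpd, muYpe, dispersion = 0.1, nRep = 3,
                            seed = 1) {
    set.seed(seed)
    genes <- sprintf("g%04d", seq_along(muYpd))
    design <- makeDesign(nReplicates = nRep)
    # makeDesign orders YPD replicates then YPE replicates
    mu <- cbind(matrix(muYpd, length(muYpd), nRep),
                matrix(muYpe, length(muYpe), nRep))
    cnt <- if (dispersion == 0) {
        matrix(rpois(length(mu), mu), nrow = nrow(mu))
    } else {
        matrix(rnbinom(length(mu), mu = mu, size = 1 / dispersion),
               nrow = nrow(mu))
    }
    dimnames(cnt) <- list(genes, design$sample)
    DupCountSet(cnt, design)
}
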