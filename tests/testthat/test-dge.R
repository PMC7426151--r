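test_that("size factors are median-of-ratios with geometric mean 1", {
    cnt <- matrix(rpois(300, 100), 100, 3,
                  dimnames = list(sprintf("g%d", 1:100), c("a", "b", "c")))
    same <- cnt[, c(1, 1, 1)]
    colnames(same) <- c("a", "b", "c")
    expect_equal(unname(computeSizeFactors(same)), c(1, 1, 1))

    two <- cbind(a = cnt[, 1], b = 2 * cnt[, 1])
    sf <- computeSizeFactors(two)
    nc <- normalizedCounts(two, sf)
    expect_equal(rowMeans(nc[, 1, drop = FALSE]),
                 rowMeans(nc[, 2, drop = FALSE]))

    set.seed(1)
    nb <- matrix(rnbinom(5000, mu = 200, size = 5), 500, 10)
    dimnames(nb) <- list(sprintf("g%d", 1:500), sprintf("s%d", 1:10))
    expect_equal(exp(mean(log(computeSizeFactors(nb)))), 1,
                 tolerance = 1e-12)
    zero <- nb; zero[, 1] <- 0
    expect_error(computeSizeFactors(zero), "zero total")
})

test_that("dispersion estimates track the simulated truth", {
    # Poisson data: raw dispersion should collapse toward 0
    cfg <- simConfig(nSingletons = 2000, nWgdPairs = 0, nSsdPairs = 0,
                     dispersion = 0, libSizeSdlog = 0, fracDe = 0,
                     nReplicates = 6, seed = 4)
    sim <- simulateCatalog(cfg)
    dcs <- simulateCounts(sim$catalog, sim$truth, cfg)
    phi <- estimateDispersions(dcs)
    expect_lte(median(phi), 0.01)

    cfg2 <- simConfig(nSingletons = 2000, nWgdPairs = 0, nSsdPairs = 0,
                      dispersion = 0.2, fracDe = 0, nReplicates = 6,
                      seed = 5)
    sim2 <- simulateCatalog(cfg2)
    dcs2 <- simulateCounts(sim2$catalog, sim2$truth, cfg2)
    phi2 <- estimateDispersions(dcs2)
    expect_gte(median(phi2), 0.1)
    expect_lte(median(phi2), 0.3)
})

test_that("constant counts give a zero raw moment estimate", {
    des <- makeDesign()
    cnt <- matrix(50L, 3, 6,
                  dimnames = list(c("g1", "g2", "g3"), des$sample))
    dcs <- DupCountSet(cnt, des)
    phi <- estimateDispersions(dcs)
    expect_equal(unname(attr(phi, "raw")), c(0, 0, 0))
})

test_that("single-replicate designs are refused with guidance", {
    des <- makeDesign(nReplicates = 1)
    cnt <- matrix(rpois(20, 50), 10, 2,
                  dimnames = list(sprintf("g%d", 1:10), des$sample))
    dcs <- DupCountSet(cnt, des)
    expect_error(estimateDispersions(dcs), "common")
})

test_that("identical groups give lfc 0 and p 1", {
    des <- makeDesign()
    cnt <- matrix(rep(c(10L, 200L, 3000L), 6), 3, 6,
                  dimnames = list(c("g1", "g2", "g3"), des$sample))
    dcs <- DupCountSet(cnt, des)
    res <- nbTest(dcs, "t0")
    expect_equal(res$lfc, c(0, 0, 0))
    expect_equal(res$p, c(1, 1, 1))
})

test_that("raw p-values are calibrated under the null", {
    fp <- vapply(1:6, function(s) {
        cfg <- simConfig(nSingletons = 2000, nWgdPairs = 0, nSsdPairs = 0,
                         fracDe = 0, dispersion = 0.1, seed = s)
        sim <- simulateCatalog(cfg)
        dcs <- simulateCounts(sim$catalog, sim$truth, cfg)
        mean(nbTest(dcs, "t0")$p < 0.05)
    }, numeric(1))
    expect_gt(mean(fp), 0.03)
    expect_lt(mean(fp), 0.07)
})

test_that("BH and BY step-up adjustments match hand computation", {
    p <- c(0.01, 0.02, 0.03)
    expect_equal(adjustPvalues(p, "BH"), c(0.03, 0.03, 0.03))
    expect_equal(adjustPvalues(p, "BY"), c(0.03, 0.03, 0.03) * (11 / 6))
    expect_equal(adjustPvalues(0.2, "BH"), 0.2)
    expect_error(adjustPvalues(c(0.5, 1.2)), "0, 1")
    # ordering invariants
    set.seed(2)
    q <- runif(50)
    expect_true(all(adjustPvalues(q, "BY") >= adjustPvalues(q, "BH")))
    expect_true(all(adjustPvalues(q, "BH") >= q))
})

test_that("trinary calls respect strict thresholds", {
    expect_equal(callDE(log2(1.25), 1e-6), "unchanged")
    expect_equal(callDE(log2(1.30), 0.004), "up")
    expect_equal(callDE(log2(0.70), 0.004), "down")
    expect_equal(callDE(log2(1.30), 0.005), "unchanged")
    expect_error(callDE(1, 0.5, fcThreshold = 0), "> 0")
})

test_that("calls are invariant to a global library rescaling", {
    sim <- smallSim(seed = 8, fracDe = 0.3, deLfcSd = 2)
    de1 <- deCalls(runDGE(sim$counts, "t0"))
    cnt2 <- counts(sim$counts) * 3L
    dcs2 <- DupCountSet(cnt2,
                        as.data.frame(SummarizedExperiment::colData(sim$counts)))
    de2 <- deCalls(runDGE(dcs2, "t0"))
    expect_identical(de1, de2)
})

test_that("planted symmetric lfc = 2 genes are recovered with high power", {
    pw <- vapply(1:5, function(s) {
        cfg <- simConfig(nSingletons = 2000, nWgdPairs = 0, nSsdPairs = 0,
                         fracDe = 0, dispersion = 0.1, seed = s)
        sim <- simulateCatalog(cfg)
        tr <- sim$truth
        tr$genes$baseline <- rep(500, nrow(tr$genes))
        set.seed(s + 1000)
        planted <- sample(seq_len(2000), 400)
        up <- planted[1:200]
        tr$genes$lfc <- 0
        tr$genes$lfc[up] <- 2
        tr$genes$lfc[planted[201:400]] <- -2
        dcs <- simulateCounts(sim$catalog, tr, cfg)
        calls <- deCalls(runDGE(dcs, "t0"))
        mean(calls[tr$genes$gene[up]] == "up")
    }, numeric(1))
    expect_gte(mean(pw), 0.8)
})

test_that("false calls under the null stay within the FDR budget", {
    nCalls <- vapply(1:10, function(s) {
        cfg <- simConfig(nSingletons = 1000, nWgdPairs = 0, nSsdPairs = 0,
                         fracDe = 0, dispersion = 0.1, seed = s + 50)
        sim <- simulateCatalog(cfg)
        dcs <- simulateCounts(sim$catalog, sim$truth, cfg)
        sum(deCalls(runDGE(dcs, "t0")) != "unchanged")
    }, numeric(1))
    expect_lte(mean(nCalls), 0.005 * 1000 * 2)
})
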