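makeTdFixture <- function(muA, muB, tau = 1.25, dispersion = 0,
                          seed = 1) {
    # two-copy pairs with exact YPD means (dispersion 0, huge counts make
    # the ratio essentially exact); YPE means equal to YPD
    nPair <- length(muA)
    genes <- c(sprintf("p%02dA", seq_len(nPair)),
               sprintf("p%02dB", seq_len(nPair)))
    catalog <- assembleCatalog(
        genes,
        wgdPairs = data.frame(gene_a = sprintf("p%02dA", seq_len(nPair)),
                              gene_b = sprintf("p%02dB", seq_len(nPair))))
    design <- makeDesign()
    mu <- rbind(matrix(muA, nPair, 6), matrix(muB, nPair, 6))
    cnt <- matrix(as.numeric(mu), nrow(mu), 6)
    dimnames(cnt) <- list(genes, design$sample)
    dcs <- DupCountSet(round(cnt), design)
    computeTD(dcs, catalog, "t0", "YPD", tau = tau,
              sizeFactors = stats::setNames(rep(1, 6), design$sample))
}

test_that("TD ratio thresholds are strict and label-symmetric", {
    # exact means 100 vs 80 (ratio on pseudocounted means)
    td <- makeTdFixture(c(100, 100, 100), c(80, 50, 100))
    r <- (100 + 0.5) / (80 + 0.5)
    expect_equal(td$td_ratio[1], r)
    expect_false(td$td[1])          # 1.2484 < 1.25: not TD
    expect_equal(td$td_ratio[2], 100.5 / 50.5)
    expect_true(td$td[2])
    expect_equal(td$td_ratio[3], 1)
    expect_true(is.na(td$high_copy[3]))
    # swapping copy labels leaves ratio and flag unchanged
    swapped <- makeTdFixture(c(80, 50, 100), c(100, 100, 100))
    expect_equal(swapped$td_ratio, td$td_ratio)
    expect_equal(swapped$td, td$td)
})

test_that("pairs with both copies at zero are flagged and excluded", {
    td <- makeTdFixture(c(100, 0), c(50, 0))
    expect_false(td$excluded[1])
    expect_true(td$excluded[2])
    expect_true(is.na(td$td_ratio[2]))
})

test_that("TDC labels follow the higher/lower expressed copy", {
    td <- makeTdFixture(c(100, 100), c(50, 50))
    calls <- c(p01A = "up", p01B = "unchanged",
               p02A = "unchanged", p02B = "down")
    lab <- as.data.frame(classifyTDC(td, calls))
    expect_equal(lab$tdc[lab$gene == "p01A"], "high")
    expect_equal(lab$call[lab$gene == "p01A"], "up")
    expect_equal(lab$tdc[lab$gene == "p02B"], "low")
    expect_equal(lab$call[lab$gene == "p02B"], "down")
    # no responding copy -> no rows
    none <- classifyTDC(td, c(p01A = "unchanged", p01B = "unchanged",
                              p02A = "unchanged", p02B = "unchanged"))
    expect_equal(nrow(none), 0L)
    # refuse non-TD pairs
    nonTd <- makeTdFixture(100, 95)
    expect_error(classifyTDC(nonTd, calls), "refused")
})

test_that("pair categories cover all call combinations symmetrically", {
    expect_equal(classifyPairCategory("up", "up"), "BothUp")
    expect_equal(classifyPairCategory("down", "down"), "BothDown")
    expect_equal(classifyPairCategory("up", "down"), "Discordant")
    expect_equal(classifyPairCategory("down", "up"), "Discordant")
    expect_equal(classifyPairCategory("down", "unchanged"),
                 "OneDownOneUnchanged")
    expect_equal(classifyPairCategory("unchanged", "up"),
                 "OneUpOneUnchanged")
    expect_equal(classifyPairCategory("unchanged", "unchanged"),
                 "BothUnchanged")
    calls <- c("up", "down", "unchanged")
    grid <- expand.grid(a = calls, b = calls, stringsAsFactors = FALSE)
    expect_identical(classifyPairCategory(grid$a, grid$b),
                     classifyPairCategory(grid$b, grid$a))
    expect_error(classifyPairCategory("up", "sideways"), "calls")
})

test_that("Fisher two-sided p matches exhaustive enumeration", {
    r <- fisherEnrichment(matrix(c(10, 10, 10, 10), 2))
    expect_equal(r$oddsRatio, 1)
    expect_equal(r$p, 1)
    r2 <- fisherEnrichment(matrix(c(5, 0, 0, 5), 2))
    expect_equal(r2$p, 2 / choose(10, 5), tolerance = 1e-12)
    set.seed(3)
    for (i in 1:30) {
        tab <- matrix(rpois(4, 6), 2)
        expect_equal(fisherEnrichment(tab)$p, bruteFisher(tab),
                     tolerance = 1e-12)
        expect_equal(fisherEnrichment(tab)$p,
                     stats::fisher.test(tab)$p.value, tolerance = 1e-7)
    }
    expect_error(fisherEnrichment(matrix(c(-1, 1, 1, 1), 2)),
                 "non-negative")
})

test_that("binomial enrichment matches closed forms", {
    expect_equal(binomialTdEnrichment(3, 3, 0.5)$p, 0.125)
    expect_equal(binomialTdEnrichment(0, 10, 0.3)$p, 1)
    expect_equal(binomialTdEnrichment(2, 10, 0.3, "less")$p,
                 pbinom(2, 10, 0.3))
    expect_error(binomialTdEnrichment(5, 3, 0.5), "k <= n")
    expect_error(binomialTdEnrichment(1, 3, 0), "p0")
})

test_that("resampling null matches exhaustive enumeration on tiny pools", {
    pool <- c(1, 2, 3)
    r <- resamplingNullMean(pool, 2, observed = 2.5, nIter = 6000,
                            seed = 1, direction = "greater")
    exact <- bruteSubsetMeanP(pool, 2, 2.5, "greater")   # 1/3
    expect_equal(exact, 1 / 3)
    se <- sqrt(exact * (1 - exact) / 6000)
    expect_lt(abs(r$p - exact), 3 * se + 2 / 6001)

    set.seed(10)
    pool2 <- rnorm(8)
    obs <- mean(pool2[1:3])
    r2 <- resamplingNullMean(pool2, 3, obs, nIter = 4000, seed = 2)
    exact2 <- bruteSubsetMeanP(pool2, 3, obs,
                               if (obs >= mean(pool2)) "greater" else "less")
    se2 <- sqrt(max(exact2, 1 / 56) * (1 - min(exact2, 1 - 1 / 56)) / 4000)
    expect_lt(abs(r2$p - exact2), 3 * se2 + 2 / 4001)
})

test_that("degenerate and repeated resampling runs behave", {
    pool <- c(4, 8, 15, 16)
    r <- resamplingNullMean(pool, 4, observed = mean(pool), nIter = 50,
                            seed = 3)
    expect_true(all(r$null == mean(pool)))
    expect_equal(r$p, 1)
    a <- resamplingNullMean(pool, 2, observed = 10, nIter = 200, seed = 7)
    b <- resamplingNullMean(pool, 2, observed = 10, nIter = 200, seed = 7)
    expect_identical(a$null, b$null)
    expect_error(resamplingNullMean(pool, 9, 1), "exceeds")
})

test_that("category permutation null conserves totals and flags planting", {
    sim <- smallSim(seed = 21)
    pairs <- as.data.frame(pairTable(sim$catalog))
    genes <- c(pairs$gene_a, pairs$gene_b)
    allUnchanged <- stats::setNames(rep("unchanged", length(genes)), genes)
    res <- categoryCountNull(pairs, allUnchanged, nIter = 99, seed = 1)
    expect_equal(res$observed[res$category == "BothUnchanged"],
                 nrow(pairs))
    expect_equal(res$p[res$category == "BothUnchanged"], 1)
    expect_equal(sum(res$observed), nrow(pairs))

    # planted coupling: both copies of 20 pairs forced down
    calls <- allUnchanged
    forced <- pairs[1:20, ]
    calls[c(forced$gene_a, forced$gene_b)] <- "down"
    res2 <- categoryCountNull(pairs, calls, nIter = 999, seed = 2)
    expect_lte(res2$p[res2$category == "BothDown"], 10 / 1000)
})

test_that("plasticity-TD correlation behaves on planted and degenerate input", {
    set.seed(5)
    lt <- abs(rnorm(100, 0, 1)) + 0.1
    plast <- exp(log(lt) + rnorm(100, 0, 0.1))
    r <- plasticityTdCorrelation(exp(lt), plast)
    expect_gte(r$r, 0.9)
    x <- exp(abs(rnorm(50)))
    self <- plasticityTdCorrelation(x, x)
    expect_equal(self$r, 1)
    expect_error(plasticityTdCorrelation(rep(2, 10), x[1:10]),
                 "zero variance")
    expect_error(plasticityTdCorrelation(c(1, 2), c(1, 2)), "at least 3")
})

test_that("TD-threshold sweep is monotone and saturates correctly", {
    sim <- smallSim(seed = 31, fracDe = 0.4, deLfcSd = 2.5)
    calls <- deCalls(runDGE(sim$counts, "t0"))
    td <- computeTD(sim$counts, sim$catalog, "t0")
    sw <- tdThresholdSweep(td, calls, tauGrid = c(1, 1.5, 2, 50))
    all_up <- sw[sw$group == "all" & sw$direction == "up", ]
    expect_true(all(diff(all_up$nTd) <= 0))
    # tau = 1: every unequal pair is TD, p0 near 1, enrichment saturated
    expect_gte(all_up$p0[1], 0.99)
    expect_equal(all_up$p[1], 1)
    # tau above any observed ratio: empty TD pool, p0 = 0
    expect_equal(all_up$nTd[4], 0L)
    expect_error(tdThresholdSweep(td, calls, tauGrid = c(0.5)), ">= 1")
})

test_that("rank-sum comparison matches exact enumeration and handles ties", {
    r <- compareGroupsRanksum(c(1, 2, 3), c(4, 5, 6))
    expect_equal(r$p, 0.1)     # 2/20 orderings as extreme
    expect_equal(r$medianA, 2)
    same <- compareGroupsRanksum(c(1, 1, 2, 2), c(1, 1, 2, 2))
    expect_equal(same$p, 1)
    set.seed(6)
    shift <- compareGroupsRanksum(rnorm(200), rnorm(200, 1))
    expect_lt(shift$p, 1e-6)
    expect_error(compareGroupsRanksum(numeric(0), 1), "non-empty")
})

test_that("overlap percentages follow the reported-set convention", {
    A <- sprintf("g%04d", 1:833)
    B <- c(A[1:557], sprintf("x%04d", 1:100))
    ov <- overlapSummary(list(t0 = A, t100 = B))
    row <- ov$pairwise[ov$pairwise$from == "t0", ]
    expect_equal(row$intersection, 557)
    expect_equal(row$pct, 66.9)
    disjoint <- overlapSummary(list(a = c("p", "q"), b = c("r", "s")))
    expect_true(all(disjoint$pairwise$pct == 0))
    expect_equal(disjoint$coreSize, 0L)
    three <- overlapSummary(list(a = c("1", "2", "3"), b = c("2", "3"),
                                 c = c("3", "4")))
    expect_equal(three$core, "3")
})
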