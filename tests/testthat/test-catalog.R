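test_that("WGD pair lists are read as deduplicated unordered pairs", {
    f <- withr::local_tempfile(fileext = ".tsv")
    writeLines(c("A\tB", "B\tA", "C\tD"), f)
    p <- readWgdPairs(f)
    expect_equal(nrow(p), 2L)
    expect_equal(p$gene_a, c("A", "C"))

    writeLines(c("A\tA"), f)
    expect_error(readWgdPairs(f), "self-pair")
    writeLines(c("A\tB", "onlyonefield"), f)
    expect_error(readWgdPairs(f), "line 2")
    writeLines(c("A\tB", "A\tC"), f)
    expect_error(readWgdPairs(f), "conflicting")
})

test_that("a 555-row pair file yields 555 pairs", {
    f <- withr::local_tempfile(fileext = ".tsv")
    writeLines(sprintf("YL%03dW\tYR%03dW", 1:555, 1:555), f)
    expect_equal(nrow(readWgdPairs(f)), 555L)
})

test_that("reciprocal best hits respect thresholds and reciprocity", {
    hits <- data.frame(
        qseqid = c("A", "B", "C", "B", "D", "E"),
        sseqid = c("B", "A", "B", "C", "E", "D"),
        evalue = c(1e-20, 1e-18, 1e-30, 1e-40, 1e-9, 1e-9),
        bitscore = c(200, 190, 300, 310, 49.9, 60),
        stringsAsFactors = FALSE)
    rbh <- reciprocalBestHits(hits)
    # A<->B mutual best; C's best is B but B's best is C?? B's best is C
    # (310 > 190), so (B, C) is the reciprocal pair, excluding A
    expect_equal(nrow(rbh), 1L)
    expect_equal(c(rbh$gene_a, rbh$gene_b), c("B", "C"))
    # D->E fails the 50-bit cutoff in one direction: no pair
    expect_false(any(rbh$gene_a == "D" | rbh$gene_b == "D"))

    # simple mutual best
    h2 <- data.frame(qseqid = c("A", "B"), sseqid = c("B", "A"),
                     evalue = c(1e-20, 1e-18), bitscore = c(200, 190))
    expect_equal(nrow(reciprocalBestHits(h2)), 1L)
    # reciprocity broken: A->B best but B->C best, C->B best
    h3 <- data.frame(qseqid = c("A", "B", "C"),
                     sseqid = c("B", "C", "B"),
                     evalue = 1e-20, bitscore = c(100, 200, 150))
    r3 <- reciprocalBestHits(h3)
    expect_false(any(r3$gene_a == "A" | r3$gene_b == "A"))
    expect_equal(nrow(r3), 1L)
    # E-value cutoff
    h4 <- data.frame(qseqid = c("A", "B"), sseqid = c("B", "A"),
                     evalue = c(1e-3, 1e-20), bitscore = c(200, 190))
    expect_equal(nrow(reciprocalBestHits(h4)), 0L)
    # output is a matching
    expect_false(anyDuplicated(unlist(rbh[, 1:2])) > 0)
})

test_that("NG86 counts match the hand example", {
    r <- ng86Ds("GGTGGGGGA", "GGCGGGGGA")
    expect_equal(r$S, 3)
    expect_equal(r$Sd, 1)
    expect_equal(r$pS, 1 / 3)
    expect_equal(r$dS, -0.75 * log(5 / 9), tolerance = 1e-12)
    ident <- ng86Ds("GGTGGG", "GGTGGG")
    expect_equal(ident$Sd, 0)
    expect_equal(ident$dS, 0)
})

test_that("NG86 equals the brute-force oracle on random pairs", {
    set.seed(99)
    for (i in 1:25) {
        s1 <- randomCds(40)
        s2 <- mutateCds(s1, sample(1:25, 1))
        a <- ng86Ds(s1, s2)
        b <- bruteNg86(s1, s2)
        expect_equal(a$S, b$S, tolerance = 1e-9)
        expect_equal(a$Sd, b$Sd, tolerance = 1e-9)
        if (!is.na(a$dS) && !is.na(b$dS))
            expect_equal(a$dS, b$dS, tolerance = 1e-9)
    }
})

test_that("NG86 is symmetric and validates its input", {
    set.seed(7)
    s1 <- randomCds(30); s2 <- mutateCds(s1, 10)
    a <- ng86Ds(s1, s2); b <- ng86Ds(s2, s1)
    expect_equal(a$Sd, b$Sd)
    expect_equal(a$dS, b$dS)
    expect_error(ng86Ds("GGTG", "GGTA"), "multiple of 3")
    expect_error(ng86Ds("GGT", "GGTAAA"), "equal length")
    expect_error(ng86Ds("TAAGGG", "TAAGGG"), "stop")
    # ambiguous codons are skipped pairwise
    r <- ng86Ds("GGTNNNGGA", "GGCAAAGGA")
    expect_equal(r$nCodons, 2L)
})

test_that("dS is monotone in pS below saturation", {
    ps <- seq(0.01, 0.7, by = 0.05)
    ds <- -0.75 * log(1 - 4 / 3 * ps)
    expect_true(all(diff(ds) > 0))
})

test_that("dS filter removes planted outliers and keeps WGD-like pairs", {
    wgd <- simulateCdsPairs(80, targetDs = 0.5, nCodons = 200, seed = 1)
    like <- simulateCdsPairs(60, targetDs = 0.5, nCodons = 200, seed = 2)
    far <- simulateCdsPairs(15, targetDs = 2.5, nCodons = 200, seed = 3)
    cand <- c(stats::setNames(like$truth$realized_ds,
                              paste0("like", seq_len(60))),
              stats::setNames(far$truth$realized_ds,
                              paste0("far", seq_len(15))))
    res <- filterSsdByDs(cand, wgd$truth$realized_ds)
    expect_gte(mean(res$keep[startsWith(names(cand), "like")]), 0.95)
    expect_equal(sum(res$keep[startsWith(names(cand), "far")]), 0L)
    expect_true(is.finite(res$ks))
    # boundary behaviors
    expect_true(filterSsdByDs(c(x = median(wgd$truth$realized_ds)),
                              wgd$truth$realized_ds)$keep[["x"]])
    expect_false(filterSsdByDs(c(y = 10 * max(wgd$truth$realized_ds)),
                               wgd$truth$realized_ds)$keep[["y"]])
    expect_error(filterSsdByDs(c(a = 1), numeric(0)), "empty reference")
})

test_that("assembleCatalog partitions the gene universe", {
    genes <- sprintf("g%02d", 1:10)
    wgd <- data.frame(gene_a = c("g01", "g03"), gene_b = c("g02", "g04"))
    ssd <- data.frame(gene_a = "g05", gene_b = "g06")
    cat1 <- assembleCatalog(genes, wgd, ssd)
    cls <- geneClasses(cat1)
    expect_equal(sum(cls == "singleton"), 4L)
    expect_equal(sum(cls != "singleton"), 6L)
    expect_equal(sum(cls == "singleton") + nrow(as.data.frame(pairTable(cat1))) * 2L,
                 10L)

    # WGD precedence over a conflicting SSD pair
    ssd2 <- data.frame(gene_a = c("g01", "g05"), gene_b = c("g07", "g06"))
    expect_warning(cat2 <- assembleCatalog(genes, wgd, ssd2), "precedence")
    expect_equal(unname(geneClasses(cat2)[c("g01", "g07")]),
                 c("WGD", "singleton"))

    expect_equal(unname(table(geneClasses(assembleCatalog(genes)))[["singleton"]]),
                 10L)
    expect_error(assembleCatalog(genes[1:3], wgd), "absent")
})

test_that("catalogs survive a TSV round trip", {
    sim <- smallSim(seed = 2)
    f <- withr::local_tempfile(fileext = ".tsv")
    writeCatalog(sim$catalog, f)
    back <- readCatalog(f)
    expect_identical(geneClasses(back), geneClasses(sim$catalog))
    expect_identical(as.data.frame(pairTable(back)),
                     as.data.frame(pairTable(sim$catalog)))
})
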