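#' Transcriptional divergence of duplicate pairs in a reference background
#'
#' For every duplicate pair, the mean normalized expression of each copy is
#' computed across the replicates of one (timepoint, medium) background
#' (default YPD, the paradigm being that divergence is judged in the
#' non-stress background and can differ between backgrounds), with a 0.5
#' pseudocount. The TD ratio is the higher mean divided by the lower; a
#' pair is transcriptionally diverged (TD) when the ratio strictly exceeds
#' `tau`. Pairs whose two copies have zero raw counts throughout the
#' background are flagged `excluded` and get an `NA` ratio.
#'
#' @param x a [DupCountSet-class].
#' @param catalog a [GeneCatalog-class].
#' @param timepoint background time point.
#' @param medium background medium (default `"YPD"`).
#' @param tau TD threshold on the max/min ratio (default 1.25, a 25%
#'   difference; strict).
#' @param sizeFactors optional precomputed size factors for `x`.
#' @return DataFrame, one row per pair: pair_id, class, gene_a, gene_b,
#'   expr_a, expr_b (pseudocounted means), td_ratio, td, high_copy,
#'   low_copy, excluded. The background and tau are kept in `metadata()`.
#' @export
computeTD <- function(x, catalog, timepoint, medium = "YPD", tau = 1.25,
                      sizeFactors = NULL) {
    if (tau < 1) stop("tau must be >= 1")
    cd <- as.data.frame(colData(x))
    keep <- cd$timepoint == timepoint & cd$medium == medium
    if (!any(keep))
        stop("no samples in background (", timepoint, ", ", medium, ")")
    if (is.null(sizeFactors)) sizeFactors <- computeSizeFactors(x)
    nc <- normalizedCounts(x, sizeFactors)[, keep, drop = FALSE]
    raw <- counts(x)[, keep, drop = FALSE]
    pt <- pairTable(catalog)
    pt <- pt[pt$gene_a %in% rownames(nc) & pt$gene_b %in% rownames(nc), ,
             drop = FALSE]
    ma <- rowMeans(nc[pt$gene_a, , drop = FALSE])
    mb <- rowMeans(nc[pt$gene_b, , drop = FALSE])
    rawZero <- rowSums(raw[pt$gene_a, , drop = FALSE]) == 0 &
        rowSums(raw[pt$gene_b, , drop = FALSE]) == 0
    ea <- ma + 0.5
    eb <- mb + 0.5
    ratio <- pmax(ea, eb) / pmin(ea, eb)
    ratio[rawZero] <- NA_real_
    td <- ratio > tau
    high <- ifelse(ea > eb, pt$gene_a, ifelse(eb > ea, pt$gene_b,
                                              NA_character_))
    low <- ifelse(ea > eb, pt$gene_b, ifelse(eb > ea, pt$gene_a,
                                             NA_character_))
    high[rawZero] <- low[rawZero] <- NA_character_
    out <- DataFrame(pair_id = pt$pair_id, class = pt$class,
                     gene_a = pt$gene_a, gene_b = pt$gene_b,
                     expr_a = unname(ea), expr_b = unname(eb),
                     td_ratio = unname(ratio), td = unname(td),
                     high_copy = high, low_copy = low,
                     excluded = unname(rawZero))
    metadata(out) <- list(timepoint = timepoint, medium = medium, tau = tau)
    out
}

#' TD ratio of two expression values
#'
#' @param a,b positive expression values (vectors recycle).
#' @return `pmax(a, b) / pmin(a, b)`.
#' @export
tdRatio <- function(a, b) pmax(a, b) / pmin(a, b)

#' Label responding copies of TD pairs as high- or low-TDC
#'
#' Within a transcriptionally diverged pair, a copy that responds to the
#' condition (an `up` or `down` DE call) is the high-TDC copy when it is
#' the higher-expressed member and the low-TDC copy otherwise.
#'
#' @param tdTab a [computeTD()] table restricted to TD pairs (rows with
#'   `td` not TRUE are refused).
#' @param calls named character vector of DE calls per gene.
#' @return DataFrame with gene, pair_id, call, tdc (`"high"`/`"low"`); one
#'   row per responding copy (no rows when neither copy responds).
#' @export
classifyTDC <- function(tdTab, calls) {
    if (any(!tdTab$td | is.na(tdTab$td)))
        stop("classification refused: non-TD pair in input")
    rows <- list()
    for (i in seq_len(nrow(tdTab))) {
        for (g in c(tdTab$gene_a[i], tdTab$gene_b[i])) {
            cl <- calls[[g]]
            if (is.null(cl) || is.na(cl) || cl == "unchanged") next
            tdc <- if (!is.na(tdTab$high_copy[i]) &&
                       g == tdTab$high_copy[i]) "high" else "low"
            rows[[length(rows) + 1L]] <-
                data.frame(gene = g, pair_id = tdTab$pair_id[i],
                           call = cl, tdc = tdc, stringsAsFactors = FALSE)
        }
    }
    if (length(rows) == 0L)
        return(DataFrame(gene = character(), pair_id = character(),
                         call = character(), tdc = character()))
    DataFrame(do.call(rbind, rows))
}

#' Five-way category of a duplicate pair from its copies' DE calls
#'
#' Maps the nine combinations of copy calls onto `BothUp`, `BothDown`,
#' `Discordant` (one up, one down), `OneUpOneUnchanged`,
#' `OneDownOneUnchanged` and `BothUnchanged`; symmetric in the copies.
#'
#' @param callA,callB character vectors of calls
#'   (`up`/`down`/`unchanged`), recycled to a common length.
#' @return character vector of categories.
#' @export
classifyPairCategory <- function(callA, callB) {
    ok <- c("up", "down", "unchanged")
    if (!all(callA %in% ok) || !all(callB %in% ok))
        stop("calls must be up, down or unchanged")
    n <- max(length(callA), length(callB))
    callA <- rep_len(callA, n); callB <- rep_len(callB, n)
    out <- character(n)
    both <- paste(pmin(callA, callB), pmax(callA, callB))
    out[both == "up up"] <- "BothUp"
    out[both == "down down"] <- "BothDown"
    out[both == "down up"] <- "Discordant"
    out[both == "unchanged up"] <- "OneUpOneUnchanged"
    out[both == "down unchanged"] <- "OneDownOneUnchanged"
    out[both == "unchanged unchanged"] <- "BothUnchanged"
    out
}

#' Fisher's exact test on a 2x2 table
#'
#' Two-sided p-value by summing, over all tables with the observed margins,
#' the hypergeometric probabilities not exceeding that of the observed
#' table (with the customary `1 + 1e-7` relative tolerance). The reported
#' odds ratio is the sample cross-product `(ad)/(bc)`, with a Haldane 0.5
#' added to every cell when any cell is zero.
#'
#' @param tab 2x2 matrix of non-negative integers.
#' @return list with `table`, `oddsRatio`, `p`.
#' @export
fisherEnrichment <- function(tab) {
    tab <- as.matrix(tab)
    if (!all(dim(tab) == c(2L, 2L)))
        stop("tab must be 2x2")
    if (any(tab < 0) || any(abs(tab - round(tab)) > 1e-8))
        stop("cells must be non-negative integers")
    tab <- round(tab)
    a <- tab[1, 1]
    r1 <- sum(tab[1, ]); c1 <- sum(tab[, 1]); n <- sum(tab)
    lo <- max(0L, r1 + c1 - n); hi <- min(r1, c1)
    support <- lo:hi
    probs <- stats::dhyper(support, c1, n - c1, r1)
    pObs <- stats::dhyper(a, c1, n - c1, r1)
    p <- min(1, sum(probs[probs <= pObs * (1 + 1e-7)]))
    t2 <- tab
    if (any(t2 == 0)) t2 <- t2 + 0.5
    orr <- (t2[1, 1] * t2[2, 2]) / (t2[1, 2] * t2[2, 1])
    list(table = tab, oddsRatio = unname(orr), p = unname(p))
}

#' Exact binomial test for TD enrichment among responding duplicates
#'
#' Tests whether `k` transcriptionally diverged genes among `n` responders
#' exceed (or fall short of) the pool TD fraction `p0`:
#' upper tail \eqn{P = \sum_{i=k}^{n} \binom{n}{i} p_0^i (1-p_0)^{n-i}}.
#'
#' @param k number of TD responders.
#' @param n number of responders.
#' @param p0 TD fraction of the corresponding gene pool, in (0, 1).
#' @param alternative `"greater"` (default, the upper tail), `"less"`, or
#'   `"two.sided"` (both tails by the minimum-likelihood rule, as in
#'   [stats::binom.test()]).
#' @return list with k, n, p0, alternative, p.
#' @export
binomialTdEnrichment <- function(k, n, p0,
                                 alternative = c("greater", "less",
                                                 "two.sided")) {
    alternative <- match.arg(alternative)
    if (k < 0 || k > n) stop("require 0 <= k <= n")
    if (p0 <= 0 || p0 >= 1) stop("p0 must lie in (0, 1)")
    p <- switch(alternative,
                greater = stats::pbinom(k - 1, n, p0, lower.tail = FALSE),
                less = stats::pbinom(k, n, p0),
                two.sided = stats::binom.test(k, n, p0,
                                              alternative = "two.sided")$p.value)
    list(k = k, n = n, p0 = p0, alternative = alternative, p = unname(p))
}

#' Resampling null distribution of a subset mean
#'
#' Draws `nIter` subsets of size `subsetSize` without replacement from
#' `pool`, records the subset statistic (mean by default), and returns the
#' one-sided empirical p-value with the +1 correction:
#' `p = (1 + #{null >= observed}) / (nIter + 1)` for direction
#' `"greater"` (mirrored for `"less"`). The null mean and sd are reported
#' for a normal overlay; the empirical p is the decision statistic.
#'
#' @param pool numeric vector to resample from.
#' @param subsetSize subset size (<= `length(pool)`).
#' @param observed observed statistic of the real subset.
#' @param nIter number of resamples (default 10000).
#' @param seed optional integer seed.
#' @param direction `"auto"` (sign of observed minus null mean),
#'   `"greater"` or `"less"`.
#' @param statistic summary function (default `mean`).
#' @return list with observed, subsetSize, null, nullMean, nullSd,
#'   direction, p.
#' @export
resamplingNullMean <- function(pool, subsetSize, observed, nIter = 10000,
                               seed = NULL,
                               direction = c("auto", "greater", "less"),
                               statistic = mean) {
    direction <- match.arg(direction)
    if (subsetSize > length(pool))
        stop("subsetSize exceeds the pool")
    if (!is.null(seed)) set.seed(seed)
    null <- vapply(seq_len(nIter),
                   function(i) statistic(pool[sample.int(length(pool),
                                                         subsetSize)]),
                   numeric(1))
    if (direction == "auto")
        direction <- if (observed >= mean(null)) "greater" else "less"
    p <- if (direction == "greater")
        (1 + sum(null >= observed)) / (nIter + 1)
    else (1 + sum(null <= observed)) / (nIter + 1)
    list(observed = observed, subsetSize = subsetSize, null = null,
         nullMean = mean(null), nullSd = stats::sd(null),
         direction = direction, p = p)
}

#' Permutation null for duplicate-pair category counts
#'
#' The observed count of pairs in each five-way category (plus
#' `BothUnchanged`) is compared to a null obtained by permuting the DE
#' calls across all duplicate genes — preserving the genome-wide numbers
#' of up/down/unchanged calls — and recounting categories. One-sided
#' empirical p-values with the +1 correction; the direction per category
#' follows the sign of (observed - null mean).
#'
#' @param pairs DataFrame/data.frame with gene_a, gene_b (e.g.
#'   [pairTable()] or a [computeTD()] result).
#' @param calls named character vector of DE calls per gene (must cover
#'   all pair members).
#' @param nIter number of permutations (default 999).
#' @param seed optional integer seed.
#' @return data.frame with category, observed, nullMean, nullSd,
#'   direction, p.
#' @export
categoryCountNull <- function(pairs, calls, nIter = 999, seed = NULL) {
    if (nrow(pairs) < 1L) stop("need at least one pair")
    genes <- unique(c(pairs$gene_a, pairs$gene_b))
    if (!all(genes %in% names(calls)))
        stop("calls must cover every duplicate gene")
    cats <- c("BothUp", "BothDown", "Discordant", "OneUpOneUnchanged",
              "OneDownOneUnchanged", "BothUnchanged")
    countCats <- function(cl) {
        x <- classifyPairCategory(cl[pairs$gene_a], cl[pairs$gene_b])
        tabulate(factor(x, levels = cats), nbins = length(cats))
    }
    v <- calls[genes]
    observed <- countCats(v)
    if (!is.null(seed)) set.seed(seed)
    nullCounts <- matrix(0L, nIter, length(cats))
    for (i in seq_len(nIter)) {
        perm <- stats::setNames(sample(v), genes)
        nullCounts[i, ] <- countCats(perm)
    }
    nullMean <- colMeans(nullCounts)
    direction <- ifelse(observed >= nullMean, "greater", "less")
    p <- vapply(seq_along(cats), function(j) {
        if (direction[j] == "greater")
            (1 + sum(nullCounts[, j] >= observed[j])) / (nIter + 1)
        else (1 + sum(nullCounts[, j] <= observed[j])) / (nIter + 1)
    }, numeric(1))
    data.frame(category = cats, observed = observed, nullMean = nullMean,
               nullSd = apply(nullCounts, 2L, stats::sd),
               direction = direction, p = p, stringsAsFactors = FALSE)
}

#' Correlation between copy-wise divergence and expression plasticity
#'
#' Pearson correlation, on the log scale, between the TD ratio of a
#' duplicate and its expression plasticity (the YPE/YPD fold change), with
#' the two-sided p-value from the t transform.
#'
#' @param tdRatio positive TD ratios (one per gene or pair).
#' @param plasticity positive linear fold changes, same length.
#' @return list with r, p, n.
#' @export
plasticityTdCorrelation <- function(tdRatio, plasticity) {
    ok <- is.finite(tdRatio) & is.finite(plasticity) & tdRatio > 0 &
        plasticity > 0
    x <- log(tdRatio[ok]); y <- log(plasticity[ok])
    if (length(x) < 3L) stop("need at least 3 pairs with defined values")
    if (stats::sd(x) == 0 || stats::sd(y) == 0)
        stop("zero variance: correlation undefined")
    ct <- stats::cor.test(x, y, method = "pearson")
    list(r = unname(ct$estimate), p = ct$p.value, n = length(x))
}

#' TD-threshold sensitivity sweep
#'
#' Re-runs the TD enrichment analysis over a grid of TD thresholds `tau`
#' (from equal expression to a 4-fold difference by default), for up- and
#' downregulated genes and for all duplicates / WGDs / SSDs separately.
#' For each cell: the TD gene pool size, the pool TD fraction `p0`, the
#' responder count `n`, the TD responder count `k`, and the upper-tail
#' binomial p. Degenerate cells (`p0` of 0 or 1, or no responders) get the
#' saturated p of 1 (or `NA` when the pool is empty, flagged `undefined`).
#'
#' @param tdTab a [computeTD()] table computed at any `tau` (ratios are
#'   reused; the sweep re-thresholds them).
#' @param calls named character vector of DE calls per gene.
#' @param tauGrid thresholds >= 1 (default `seq(1, 4, by = 0.25)`).
#' @return data.frame with tau, group, direction, poolSize, nTd, p0, n, k,
#'   p, undefined.
#' @export
tdThresholdSweep <- function(tdTab, calls, tauGrid = seq(1, 4, by = 0.25)) {
    if (any(tauGrid < 1)) stop("tau values must be >= 1")
    groups <- list(all = c("WGD", "SSD"), WGD = "WGD", SSD = "SSD")
    rows <- list()
    for (tau in tauGrid) {
        for (gn in names(groups)) {
            sub <- tdTab[tdTab$class %in% groups[[gn]] & !tdTab$excluded, ,
                         drop = FALSE]
            poolGenes <- c(sub$gene_a, sub$gene_b)
            tdPairs <- !is.na(sub$td_ratio) & sub$td_ratio > tau
            tdGenes <- c(sub$gene_a[tdPairs], sub$gene_b[tdPairs])
            poolSize <- length(poolGenes)
            p0 <- if (poolSize) length(tdGenes) / poolSize else NA_real_
            for (dir in c("up", "down")) {
                cl <- calls[poolGenes]
                resp <- poolGenes[!is.na(cl) & cl == dir]
                n <- length(resp)
                k <- sum(resp %in% tdGenes)
                undef <- poolSize == 0L
                p <- if (undef || n == 0L) NA_real_
                else if (p0 >= 1) 1
                else if (p0 <= 0) { if (k == 0L) 1 else 0 }
                else binomialTdEnrichment(k, n, p0)$p
                rows[[length(rows) + 1L]] <- data.frame(
                    tau = tau, group = gn, direction = dir,
                    poolSize = poolSize, nTd = length(tdGenes), p0 = p0,
                    n = n, k = k, p = p, undefined = undef,
                    stringsAsFactors = FALSE)
            }
        }
    }
    out <- do.call(rbind, rows)
    rownames(out) <- NULL
    out
}

#' Wilcoxon-Mann-Whitney comparison of two groups
#'
#' Exact enumeration when the two groups together hold at most 12 tie-free
#' values; the normal approximation with tie correction (no continuity
#' correction) otherwise. Group medians are reported alongside.
#'
#' @param a,b numeric vectors (non-empty).
#' @return list with p, medianA, medianB, statistic.
#' @export
compareGroupsRanksum <- function(a, b) {
    if (length(a) == 0L || length(b) == 0L)
        stop("both groups must be non-empty")
    ties <- anyDuplicated(c(a, b)) > 0L
    exact <- (length(a) + length(b) <= 12L) && !ties
    wt <- suppressWarnings(stats::wilcox.test(a, b, exact = exact,
                                              correct = FALSE))
    list(p = min(1, wt$p.value), medianA = stats::median(a),
         medianB = stats::median(b), statistic = unname(wt$statistic))
}

#' Overlaps of DE call sets across time points
#'
#' Pairwise and overall intersections of gene sets (e.g. genes upregulated
#' at each time point), with percentages relative to the first-named set
#' rounded to one decimal, and the core set shared by all.
#'
#' @param sets named list of character vectors over a common gene universe.
#' @return list with `sizes`, `pairwise` (data.frame: from, to,
#'   intersection, pct — percentage of `from` also in `to`), `core`
#'   (character vector shared by all sets) and `coreSize`.
#' @export
overlapSummary <- function(sets) {
    stopifnot(is.list(sets), length(sets) >= 1L)
    if (is.null(names(sets)) || any(!nzchar(names(sets))))
        names(sets) <- paste0("set", seq_along(sets))
    sets <- lapply(sets, unique)
    nm <- names(sets)
    rows <- list()
    for (i in seq_along(sets)) for (j in seq_along(sets)) {
        if (i == j) next
        int <- length(intersect(sets[[i]], sets[[j]]))
        pct <- if (length(sets[[i]])) round(100 * int / length(sets[[i]]), 1)
               else NA_real_
        rows[[length(rows) + 1L]] <- data.frame(
            from = nm[i], to = nm[j], intersection = int, pct = pct,
            stringsAsFactors = FALSE)
    }
    core <- Reduce(intersect, sets)
    list(sizes = lengths(sets),
         pairwise = do.call(rbind, rows),
         core = core, coreSize = length(core))
}
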