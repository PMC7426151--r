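#' Median-of-ratios size factors
#'
#' DESeq-style normalization: per sample, the median ratio of its counts to
#' the per-gene geometric mean across samples, rescaled so the factors have
#' geometric mean 1. Genes with a zero count in any sample are excluded from
#' the reference; when no gene is positive everywhere, total-count ratios
#' are used instead (with a warning).
#'
#' @param x a [DupCountSet-class] or a count matrix.
#' @return named numeric vector of positive per-sample factors.
#' @export
computeSizeFactors <- function(x) {
    cnt <- if (is(x, "DupCountSet")) counts(x) else as.matrix(x)
    if (any(colSums(cnt) <= 0))
        stop("normalization error: sample with zero total counts")
    allPos <- rowSums(cnt <= 0) == 0L
    if (any(allPos)) {
        lc <- log(cnt[allPos, , drop = FALSE])
        ref <- rowMeans(lc)
        sf <- exp(apply(lc - ref, 2L, stats::median))
    } else {
        warning("no gene with all-positive counts; using total-count ratios")
        tot <- colSums(cnt)
        sf <- tot / exp(mean(log(tot)))
    }
    sf <- sf / exp(mean(log(sf)))
    stats::setNames(sf, colnames(cnt))
}

#' Normalized counts
#'
#' @param x a [DupCountSet-class] or count matrix.
#' @param sizeFactors optional precomputed factors ([computeSizeFactors()]).
#' @return matrix of counts divided by their sample's size factor.
#' @export
normalizedCounts <- function(x, sizeFactors = computeSizeFactors(x)) {
    cnt <- if (is(x, "DupCountSet")) counts(x) else as.matrix(x)
    sweep(cnt, 2L, sizeFactors, "/")
}

.groupStats <- function(nc, groups) {
    lev <- unique(groups)
    m <- s2 <- matrix(NA_real_, nrow(nc), length(lev))
    n <- integer(length(lev))
    for (i in seq_along(lev)) {
        sub <- nc[, groups == lev[i], drop = FALSE]
        n[i] <- ncol(sub)
        m[, i] <- rowMeans(sub)
        s2[, i] <- if (n[i] >= 2L) apply(sub, 1L, stats::var) else NA_real_
    }
    list(mean = m, var = s2, n = n)
}

#' Per-gene NB dispersion by moments, shrunk toward the common value
#'
#' Within each (medium, timepoint) condition the sample mean and variance of
#' normalized counts give the raw moment estimate
#' `phi = max(0, (s2 - m) / m^2)` after pooling across conditions (variances
#' pooled by their degrees of freedom, means weighted by replicate number).
#' Raw estimates are shrunk toward the genome-wide common dispersion (the
#' mean of the raw estimates over expressed genes, which is close to
#' unbiased where the per-gene median is not) with weight
#' `w = nPrior / (nPrior + df)`, where `df` is the pooled within-condition
#' degrees of freedom — heavy shrinkage at typical replicate numbers, which
#' stabilizes the Wald test.
#'
#' @param object a [DupCountSet-class].
#' @param timepoint optional: restrict to one time point.
#' @param nPrior prior weight (default 10 "prior degrees of freedom").
#' @param sizeFactors optional precomputed size factors.
#' @return numeric vector of per-gene dispersions, with the common
#'   (median) dispersion in attribute `"common"`.
#' @aliases estimateDispersions
#' @importFrom BiocGenerics estimateDispersions
#' @exportMethod estimateDispersions
setMethod("estimateDispersions", "DupCountSet",
          function(object, timepoint = NULL, nPrior = 10,
                   sizeFactors = NULL) {
    x <- object
    cd <- as.data.frame(colData(x))
    keep <- if (is.null(timepoint)) rep(TRUE, ncol(x)) else
        cd$timepoint == timepoint
    sub <- x[, keep]
    cd <- cd[keep, , drop = FALSE]
    if (is.null(sizeFactors)) sizeFactors <- computeSizeFactors(sub)
    nc <- normalizedCounts(sub, sizeFactors)
    groups <- paste(cd$medium, cd$timepoint)
    gs <- .groupStats(nc, groups)
    df <- gs$n - 1L
    if (all(df == 0L))
        stop("every condition has a single replicate; per-gene dispersion ",
             "cannot be estimated - supply a common dispersion instead")
    w <- df[df > 0]
    pooledVar <- as.vector(gs$var[, df > 0, drop = FALSE] %*% w / sum(w))
    pooledMean <- as.vector(gs$mean %*% gs$n / sum(gs$n))
    raw <- pmax(0, (pooledVar - pooledMean) / pooledMean^2)
    raw[!is.finite(raw)] <- NA_real_
    common <- mean(raw[pooledMean > 0], na.rm = TRUE)
    if (!is.finite(common)) common <- 0
    dfg <- sum(df)
    wShrink <- nPrior / (nPrior + dfg)
    phi <- wShrink * common + (1 - wShrink) * raw
    phi[is.na(phi)] <- common
    attr(phi, "common") <- common
    attr(phi, "raw") <- raw
    stats::setNames(phi, rownames(x))
})

#' Wald negative-binomial test for the YPE vs YPD contrast
#'
#' The log2 fold change is `log2((meanYPE + 0.5) / (meanYPD + 0.5))` on
#' normalized counts averaged within group (the 0.5 pseudocount keeps zero
#' counts finite). Its delta-method standard error uses the NB variance
#' `mu + phi mu^2` of each group mean; the Wald statistic is referred to
#' the standard normal, two-sided. The shrunken dispersion (see
#' [estimateDispersions()]) keeps the statistic close to nominally
#' calibrated at typical replicate numbers.
#'
#' @param x a [DupCountSet-class].
#' @param timepoint the time point at which YPE is contrasted to YPD.
#' @param phi per-gene dispersions (see [estimateDispersions()]); by default
#'   estimated from the samples at `timepoint`.
#' @param sizeFactors optional precomputed size factors (computed on the
#'   subset otherwise).
#' @param nPrior shrinkage weight passed to [estimateDispersions()].
#' @return DataFrame with gene, baseMean, lfc, se, p.
#' @export
nbTest <- function(x, timepoint, phi = NULL, sizeFactors = NULL,
                   nPrior = 10) {
    cd <- as.data.frame(colData(x))
    keep <- cd$timepoint == timepoint
    if (!any(keep)) stop("design error: no samples at timepoint ", timepoint)
    sub <- x[, keep]
    cd <- cd[keep, , drop = FALSE]
    if (!all(c("YPD", "YPE") %in% cd$medium))
        stop("design error: need both YPD and YPE samples at ", timepoint)
    if (is.null(sizeFactors)) sizeFactors <- computeSizeFactors(sub)
    if (is.null(phi))
        phi <- estimateDispersions(sub, nPrior = nPrior,
                                   sizeFactors = sizeFactors)
    nc <- normalizedCounts(sub, sizeFactors)
    e <- cd$medium == "YPE"
    n1 <- sum(e); n0 <- sum(!e)
    m1 <- rowMeans(nc[, e, drop = FALSE])
    m0 <- rowMeans(nc[, !e, drop = FALSE])
    lfc <- log2((m1 + 0.5) / (m0 + 0.5))
    v1 <- m1 + phi * m1^2
    v0 <- m0 + phi * m0^2
    se <- sqrt(v1 / (n1 * (m1 + 0.5)^2) + v0 / (n0 * (m0 + 0.5)^2)) / log(2)
    z <- ifelse(se > 0, lfc / se, 0)
    p <- 2 * stats::pnorm(-abs(z))
    p[se == 0] <- 1
    DataFrame(gene = rownames(sub), baseMean = (m1 * n1 + m0 * n0) / (n1 + n0),
              lfc = unname(lfc), se = unname(se), p = unname(p))
}

#' Multiple-testing adjustment (BH / BY step-up)
#'
#' @param p numeric vector of p-values in \[0, 1\].
#' @param method `"BH"` (Benjamini-Hochberg) or `"BY"`
#'   (Benjamini-Yekutieli, BH inflated by `sum(1/i)`).
#' @return adjusted p-values, monotone and capped at 1.
#' @export
adjustPvalues <- function(p, method = c("BY", "BH")) {
    method <- match.arg(method)
    if (any(is.na(p)) || any(p < 0 | p > 1))
        stop("p-values must lie in [0, 1]")
    stats::p.adjust(p, method = method)
}

#' Trinary differential-expression call
#'
#' `up` requires linear fold change strictly above `fcThreshold` and FDR
#' strictly below `fdrThreshold`; `down` is symmetric with `1/fcThreshold`;
#' everything else is `unchanged`.
#'
#' @param lfc log2 fold changes.
#' @param fdr adjusted p-values.
#' @param fcThreshold linear fold-change threshold (default 1.25, i.e. a
#'   25% change).
#' @param fdrThreshold FDR threshold (default 0.005).
#' @return character vector of calls.
#' @export
callDE <- function(lfc, fdr, fcThreshold = 1.25, fdrThreshold = 0.005) {
    if (fcThreshold <= 0 || fdrThreshold <= 0)
        stop("thresholds must be > 0")
    fc <- 2^lfc
    ifelse(fc > fcThreshold & fdr < fdrThreshold, "up",
           ifelse(fc < 1 / fcThreshold & fdr < fdrThreshold, "down",
                  "unchanged"))
}

#' Differential expression at one time point (YPE vs YPD)
#'
#' Normalization, dispersion estimation, Wald NB test, FDR adjustment and
#' trinary calling in one step.
#'
#' @inheritParams nbTest
#' @param fcThreshold,fdrThreshold call thresholds (defaults 1.25, 0.005).
#' @param method p-value adjustment, `"BY"` (default) or `"BH"`.
#' @return a [DEResult-class].
#' @export
runDGE <- function(x, timepoint, fcThreshold = 1.25, fdrThreshold = 0.005,
                   method = c("BY", "BH"), nPrior = 10) {
    method <- match.arg(method)
    res <- nbTest(x, timepoint, nPrior = nPrior)
    fdr <- adjustPvalues(res$p, method)
    call <- callDE(res$lfc, fdr, fcThreshold, fdrThreshold)
    tb <- DataFrame(gene = res$gene, baseMean = res$baseMean, lfc = res$lfc,
                    p = res$p, fdr = fdr, call = call)
    new("DEResult", table = tb, timepoint = timepoint,
        fcThreshold = fcThreshold, fdrThreshold = fdrThreshold,
        method = method)
}
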