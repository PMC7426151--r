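#' Fit a logistic growth curve to an OD600 series
#'
#' Least-squares fit of \eqn{N(t) = K / (1 + ((K - N_0)/N_0) e^{-rt})} via
#' Levenberg-Marquardt ([minpack.lm::nlsLM]). Initial values: `K` from the
#' maximum OD, `N0` from the first positive OD, `r` from the log-linear
#' slope over the earliest quarter of the time range. `r` is reported as
#' the maximum growth rate \eqn{\mu_{max}} (the convention of logistic
#' growth-curve fitters). A blank (uninoculated control) level can be
#' subtracted first; ODs are floored at `1e-4` before any log operation.
#' Series with too little dynamic range (max/min below `minFoldRange`), a
#' failed optimizer, or non-positive fitted parameters yield a flagged,
#' non-converged fit with parameters withheld.
#'
#' @param times numeric, hours.
#' @param od numeric OD600 readings, same length (>= 5).
#' @param blank optional numeric: blank readings (their mean is
#'   subtracted) or a single baseline value.
#' @param minFoldRange minimum max/min OD ratio to attempt a fit
#'   (default 1.2).
#' @return a [GrowthFit-class].
#' @export
fitLogistic <- function(times, od, blank = NULL, minFoldRange = 1.2) {
    if (length(times) != length(od)) stop("times and od lengths differ")
    if (length(od) < 5L) stop("need at least 5 time points")
    if (!is.null(blank)) od <- od - mean(blank)
    od <- pmax(od, 1e-4)
    failed <- function() new("GrowthFit", K = NA_real_, r = NA_real_,
                             N0 = NA_real_, sigma = NA_real_,
                             converged = FALSE, nObs = length(od))
    if (max(od) / min(od) < minFoldRange) return(failed())
    K0 <- max(od)
    N00 <- od[which(od > 1e-4)[1]]
    if (is.na(N00)) N00 <- 1e-4
    early <- times <= min(times) + 0.25 * diff(range(times))
    r0 <- tryCatch(unname(stats::coef(stats::lm(log(od[early]) ~
                                                    times[early]))[2]),
                   error = function(e) NA_real_)
    if (!is.finite(r0) || r0 <= 0) r0 <- 0.1
    dat <- data.frame(t = times, y = od)
    fit <- tryCatch(
        minpack.lm::nlsLM(y ~ K / (1 + ((K - N0) / N0) * exp(-r * t)),
                          data = dat,
                          start = list(K = K0, N0 = max(N00, 1e-4), r = r0),
                          lower = c(K = 1e-6, N0 = 1e-6, r = 1e-6),
                          control = minpack.lm::nls.lm.control(
                              maxiter = 200, ftol = 1e-12, ptol = 1e-12)),
        error = function(e) NULL)
    if (is.null(fit)) return(failed())
    cf <- stats::coef(fit)
    if (!(cf[["K"]] > cf[["N0"]] && cf[["N0"]] > 0 && cf[["r"]] > 1e-5))
        return(failed())
    new("GrowthFit", K = unname(cf[["K"]]), r = unname(cf[["r"]]),
        N0 = unname(cf[["N0"]]),
        sigma = sqrt(mean(stats::residuals(fit)^2)),
        converged = TRUE, nObs = length(od))
}

#' Fit logistic curves to a long OD table, one fit per well
#'
#' @param od data.frame with columns well, time_h, od600 (see
#'   [simulateGrowthCurves()]); wells whose name matches `blankGroup` are
#'   pooled into the blank and not fitted.
#' @param blankGroup optional regular expression marking blank wells.
#' @return data.frame with well, K, r, N0, sigma, converged.
#' @export
fitGrowthTable <- function(od, blankGroup = NULL) {
    blank <- NULL
    if (!is.null(blankGroup)) {
        isBlank <- grepl(blankGroup, od$well)
        if (any(isBlank)) blank <- od$od600[isBlank]
        od <- od[!isBlank, , drop = FALSE]
    }
    wells <- unique(od$well)
    out <- lapply(wells, function(w) {
        sub <- od[od$well == w, , drop = FALSE]
        f <- fitLogistic(sub$time_h, sub$od600, blank = blank)
        data.frame(well = w, K = f@K, r = f@r, N0 = f@N0, sigma = f@sigma,
                   converged = f@converged, stringsAsFactors = FALSE)
    })
    do.call(rbind, out)
}

#' Compare growth parameters between two groups of fits
#'
#' Wilcoxon rank-sum comparison of the carrying capacity `K` and the
#' maximum growth rate `r` between two groups of [GrowthFit-class] objects
#' (or rows of [fitGrowthTable()] output). Non-converged fits are
#' excluded, with a message recording the exclusion.
#'
#' @param fitsA,fitsB lists of GrowthFit, or data.frames with columns K,
#'   r, converged.
#' @return data.frame with param, medianA, medianB, p.
#' @export
compareGrowth <- function(fitsA, fitsB) {
    extract <- function(f) {
        if (is.data.frame(f))
            return(data.frame(K = f$K, r = f$r, converged = f$converged))
        do.call(rbind, lapply(f, function(g)
            data.frame(K = g@K, r = g@r, converged = g@converged)))
    }
    a <- extract(fitsA); b <- extract(fitsB)
    if (is.null(a) || is.null(b) || nrow(a) < 2L || nrow(b) < 2L)
        stop("need at least 2 fits per group")
    nDrop <- sum(!a$converged) + sum(!b$converged)
    if (nDrop > 0)
        message(nDrop, " non-converged fit(s) excluded from the comparison")
    a <- a[a$converged, , drop = FALSE]
    b <- b[b$converged, , drop = FALSE]
    if (nrow(a) == 0L || nrow(b) == 0L)
        stop("a group has no converged fits")
    do.call(rbind, lapply(c("K", "r"), function(par) {
        cmp <- compareGroupsRanksum(a[[par]], b[[par]])
        data.frame(param = par, medianA = cmp$medianA,
                   medianB = cmp$medianB, p = cmp$p,
                   stringsAsFactors = FALSE)
    }))
}

#' Generations implied by serial-transfer bottlenecks
#'
#' Each passage at a bottleneck fraction `f` requires `log2(1/f)` doublings
#' to regrow, so `generations = nPassages * log2(1/f)`. The rounded value
#' uses the nearest integer, switching to two significant figures from 100
#' generations up (the convention for reporting large generation counts).
#'
#' @param nPassages number of passages (>= 0).
#' @param fraction bottleneck fraction in (0, 1), e.g. 0.01 for a 1%
#'   transfer.
#' @return list with `generations` (raw) and `rounded`.
#' @export
generationsFromBottleneck <- function(nPassages, fraction) {
    if (fraction <= 0 || fraction >= 1)
        stop("fraction must lie in (0, 1)")
    if (nPassages < 0) stop("nPassages must be >= 0")
    raw <- nPassages * log2(1 / fraction)
    rounded <- if (raw >= 100) signif(raw, 2) else round(raw)
    list(generations = raw, rounded = rounded)
}
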