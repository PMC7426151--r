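#' @import methods
#' @importFrom S4Vectors DataFrame metadata metadata<-
#' @importFrom SummarizedExperiment SummarizedExperiment assay assayNames colData rowData
NULL

#' DupCountSet: a count matrix with its experimental design
#'
#' A thin extension of [SummarizedExperiment::SummarizedExperiment] holding a
#' single `"counts"` assay of non-negative integer RNA-seq counts together
#' with per-sample design metadata: the evolution line, the time point
#' (`t0`, `t100`, `t110`), the growth medium (`YPD` glucose or `YPE`
#' ethanol), and the replicate.
#'
#' @slot .Data inherited SummarizedExperiment representation.
#' @export
setClass("DupCountSet", contains = "SummarizedExperiment")

setValidity("DupCountSet", function(object) {
    msg <- NULL
    if (!"counts" %in% assayNames(object))
        msg <- c(msg, "assay 'counts' is required")
    else {
        cnt <- assay(object, "counts")
        if (!is.numeric(cnt))
            msg <- c(msg, "counts must be numeric")
        else {
            if (any(cnt < 0, na.rm = TRUE))
                msg <- c(msg, "counts must be non-negative")
            if (any(abs(cnt - round(cnt)) > 1e-8, na.rm = TRUE))
                msg <- c(msg, "counts must be whole numbers")
        }
    }
    need <- c("medium", "timepoint", "replicate")
    miss <- setdiff(need, colnames(colData(object)))
    if (length(miss))
        msg <- c(msg, paste0("design columns missing from colData: ",
                             paste(miss, collapse = ", ")))
    if (is.null(msg)) TRUE else msg
})

#' Construct a DupCountSet
#'
#' @param counts integer matrix, genes in rows (rownames required), samples in
#'   columns (colnames required).
#' @param design data.frame with one row per sample (matched to columns of
#'   `counts` by the `sample` column or by rownames) containing at least
#'   `medium`, `timepoint` and `replicate`.
#' @return A [DupCountSet-class] object.
#' @examples
#' cnt <- matrix(rpois(12, 50), nrow = 3,
#'               dimnames = list(paste0("g", 1:3), paste0("s", 1:4)))
#' des <- data.frame(sample = paste0("s", 1:4),
#'                   medium = rep(c("YPD", "YPE"), each = 2),
#'                   timepoint = "t0", replicate = rep(1:2, 2))
#' DupCountSet(cnt, des)
#' @export
DupCountSet <- function(counts, design) {
    counts <- as.matrix(counts)
    if (is.null(rownames(counts)) || is.null(colnames(counts)))
        stop("'counts' must have row and column names")
    design <- as.data.frame(design)
    if ("sample" %in% colnames(design)) {
        rownames(design) <- as.character(design$sample)
    }
    if (!setequal(rownames(design), colnames(counts)))
        stop("design must cover every sample of 'counts' exactly once")
    design <- design[colnames(counts), , drop = FALSE]
    se <- SummarizedExperiment(assays = list(counts = counts),
                               colData = DataFrame(design))
    new("DupCountSet", se)
}

#' GeneCatalog: singleton/WGD/SSD classification of a gene universe
#'
#' Records, for every gene, its duplication class (`singleton`, `WGD` for
#' whole-genome duplicates, `SSD` for small-scale duplicates) and, for
#' duplicates, the pair it belongs to and its partner copy. The partner
#' relation is symmetric and involutive and no gene belongs to two pairs.
#'
#' @slot info a [S4Vectors::DataFrame] with columns `gene`, `class`,
#'   `pair_id`, `partner` (the latter two `NA` for singletons).
#' @export
setClass("GeneCatalog", representation(info = "DataFrame"))

setValidity("GeneCatalog", function(object) {
    info <- object@info
    msg <- NULL
    need <- c("gene", "class", "pair_id", "partner")
    if (!all(need %in% colnames(info)))
        return(paste0("info needs columns: ", paste(need, collapse = ", ")))
    if (anyDuplicated(info$gene))
        msg <- c(msg, "duplicated gene ids")
    if (!all(info$class %in% c("singleton", "WGD", "SSD")))
        msg <- c(msg, "class must be singleton, WGD or SSD")
    sing <- info$class == "singleton"
    if (any(!is.na(info$partner[sing])) || any(!is.na(info$pair_id[sing])))
        msg <- c(msg, "singletons must have NA pair_id and partner")
    dup <- !sing
    if (any(is.na(info$partner[dup])) || any(is.na(info$pair_id[dup])))
        msg <- c(msg, "duplicates must have a pair_id and a partner")
    if (any(dup)) {
        partner <- stats::setNames(as.character(info$partner), info$gene)
        g <- info$gene[dup]
        back <- partner[partner[g]]
        if (any(is.na(back)) || !all(back == g))
            msg <- c(msg, "partner relation must be symmetric and involutive")
        if (any(partner[g] == g))
            msg <- c(msg, "a gene cannot be its own partner")
        tab <- table(info$pair_id[dup])
        if (any(tab != 2L))
            msg <- c(msg, "every pair_id must contain exactly two genes")
    }
    if (is.null(msg)) TRUE else msg
})

#' DEResult: per-gene differential-expression results
#'
#' Holds the YPE vs YPD contrast at one time point: log2 fold change, raw
#' p-value, FDR-adjusted p-value and the trinary call (`up`, `down`,
#' `unchanged`) at the fold-change and FDR thresholds used.
#'
#' @slot table [S4Vectors::DataFrame] with columns `gene`, `baseMean`,
#'   `lfc`, `p`, `fdr`, `call`.
#' @slot timepoint character, the contrasted time point.
#' @slot fcThreshold numeric, linear fold-change threshold (strict).
#' @slot fdrThreshold numeric, FDR threshold (strict).
#' @slot method character, p-value adjustment method (`"BY"` or `"BH"`).
#' @export
setClass("DEResult",
         representation(table = "DataFrame", timepoint = "character",
                        fcThreshold = "numeric", fdrThreshold = "numeric",
                        method = "character"))

setValidity("DEResult", function(object) {
    tb <- object@table
    need <- c("gene", "baseMean", "lfc", "p", "fdr", "call")
    msg <- NULL
    if (!all(need %in% colnames(tb)))
        return(paste0("table needs columns: ", paste(need, collapse = ", ")))
    if (!all(tb$call %in% c("up", "down", "unchanged")))
        msg <- c(msg, "call must be up, down or unchanged")
    ok <- !is.na(tb$p) & !is.na(tb$fdr)
    if (any(tb$fdr[ok] + 1e-12 < tb$p[ok]))
        msg <- c(msg, "fdr must be >= raw p elementwise")
    if (is.null(msg)) TRUE else msg
})

#' GrowthFit: a fitted logistic growth curve
#'
#' Least-squares fit of \eqn{N(t) = K / (1 + ((K - N0)/N0) e^{-rt})} to an
#' OD600 time series. `r` is reported as the maximum growth rate
#' \eqn{\mu_{max}} (per hour); `K` is the carrying capacity (OD600).
#'
#' @slot K numeric carrying capacity (NA when not converged).
#' @slot r numeric intrinsic growth rate, h^-1 (NA when not converged).
#' @slot N0 numeric initial population size (NA when not converged).
#' @slot sigma numeric residual standard deviation.
#' @slot converged logical convergence flag.
#' @slot nObs integer number of fitted observations.
#' @export
setClass("GrowthFit",
         representation(K = "numeric", r = "numeric", N0 = "numeric",
                        sigma = "numeric", converged = "logical",
                        nObs = "integer"))

setValidity("GrowthFit", function(object) {
    if (isTRUE(object@converged)) {
        if (!(object@K > object@N0 && object@N0 > 0 && object@r > 0))
            return("converged fit requires K > N0 > 0 and r > 0")
    }
    TRUE
})
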