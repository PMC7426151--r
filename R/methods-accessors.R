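#' @describeIn DupCountSet counts assay accessor
#' @param object a DupCountSet
#' @export
setMethod("counts", "DupCountSet", function(object) assay(object, "counts"))

#' @describeIn DupCountSet gene ids (rownames)
#' @param x a DupCountSet
#' @export
setMethod("geneIds", "DupCountSet", function(x) rownames(x))

#' @describeIn GeneCatalog gene ids
#' @param x a GeneCatalog
#' @export
setMethod("geneIds", "GeneCatalog", function(x) as.character(x@info$gene))

#' @describeIn GeneCatalog per-gene classes, named by gene
#' @export
setMethod("geneClasses", "GeneCatalog", function(x)
    stats::setNames(as.character(x@info$class), x@info$gene))

#' @describeIn GeneCatalog one row per duplicate pair
#' @export
setMethod("pairTable", "GeneCatalog", function(x) {
    info <- x@info
    dup <- info[!is.na(info$pair_id), , drop = FALSE]
    if (nrow(dup) == 0L)
        return(DataFrame(pair_id = character(), gene_a = character(),
                         gene_b = character(), class = character()))
    sp <- split(seq_len(nrow(dup)), as.character(dup$pair_id))
    ids <- names(sp)
    ga <- gb <- cl <- character(length(sp))
    for (i in seq_along(sp)) {
        rows <- sp[[i]]
        g <- sort(as.character(dup$gene[rows]))
        ga[i] <- g[1L]; gb[i] <- g[2L]
        cl[i] <- as.character(dup$class[rows[1L]])
    }
    o <- order(ids)
    DataFrame(pair_id = ids[o], gene_a = ga[o], gene_b = gb[o],
              class = cl[o])
})

#' @describeIn DEResult full result table
#' @param x a DEResult
#' @export
setMethod("deTable", "DEResult", function(x) x@table)

#' @describeIn DEResult calls as a named vector
#' @export
setMethod("deCalls", "DEResult", function(x)
    stats::setNames(as.character(x@table$call), x@table$gene))

#' @describeIn GrowthFit fitted parameters (K, r, N0)
#' @param object a GrowthFit
#' @param ... unused
#' @export
setMethod("coef", "GrowthFit", function(object, ...)
    c(K = object@K, r = object@r, N0 = object@N0))

setMethod("show", "DupCountSet", function(object) {
    cat("DupCountSet:", nrow(object), "genes x", ncol(object), "samples\n")
    cd <- colData(object)
    cat("  media:", paste(sort(unique(as.character(cd$medium))),
                          collapse = ", "), "\n")
    cat("  timepoints:", paste(sort(unique(as.character(cd$timepoint))),
                               collapse = ", "), "\n")
    invisible(object)
})

setMethod("show", "GeneCatalog", function(object) {
    cl <- geneClasses(object)
    tab <- table(factor(cl, levels = c("singleton", "WGD", "SSD")))
    cat("GeneCatalog:", length(cl), "genes |",
        tab[["singleton"]], "singletons,",
        tab[["WGD"]] / 2L, "WGD pairs,",
        tab[["SSD"]] / 2L, "SSD pairs\n")
    invisible(object)
})

setMethod("show", "DEResult", function(object) {
    tb <- object@table
    cat("DEResult (YPE vs YPD, ", object@timepoint, "): ",
        nrow(tb), " genes; FC > ", object@fcThreshold,
        ", ", object@method, " FDR < ", object@fdrThreshold, "\n", sep = "")
    cat("  up:", sum(tb$call == "up"),
        " down:", sum(tb$call == "down"),
        " unchanged:", sum(tb$call == "unchanged"), "\n")
    invisible(object)
})

setMethod("show", "GrowthFit", function(object) {
    if (object@converged) {
        cat(sprintf(
            "GrowthFit: K = %.4g OD600, mu_max = %.4g h^-1, N0 = %.4g (n = %d, sigma = %.3g)\n",
            object@K, object@r, object@N0, object@nObs, object@sigma))
    } else {
        cat("GrowthFit: not converged (", object@nObs, "points )\n")
    }
    invisible(object)
})
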