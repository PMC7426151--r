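#' Hypergeometric over-representation analysis
#'
#' For each term of a term-to-gene map, tests whether the gene set hits the
#' term more often than expected from the universe: upper-tail
#' hypergeometric p with `k` hits out of a term of size `K`, a set of size
#' `n` and a universe of size `N`, BH-adjusted across the tested terms.
#' Terms are intersected with the universe first; by convention the
#' universe is the set of genes that entered the expression analysis, not
#' all annotated genes.
#'
#' @param geneSet character vector of genes of interest (intersected with
#'   the universe; genes outside it are dropped with a warning).
#' @param termMap data.frame with columns term, gene.
#' @param universe character vector of background genes (non-empty).
#' @param pCutoff enrichment flag threshold on the adjusted p
#'   (default 0.01).
#' @return data.frame ordered by p: term, k, K, n, N, p, padj, enriched.
#' @export
hypergeometricOra <- function(geneSet, termMap, universe, pCutoff = 0.01) {
    universe <- unique(as.character(universe))
    if (length(universe) == 0L) stop("empty universe")
    geneSet <- unique(as.character(geneSet))
    out <- setdiff(geneSet, universe)
    if (length(out)) {
        warning(length(out), " gene(s) of the set outside the universe ",
                "were dropped")
        geneSet <- intersect(geneSet, universe)
    }
    termMap <- termMap[termMap$gene %in% universe, , drop = FALSE]
    terms <- split(unique(paste(termMap$term, termMap$gene, sep = "\r")),
                   sub("\r.*", "", unique(paste(termMap$term, termMap$gene,
                                                sep = "\r"))))
    n <- length(geneSet)
    N <- length(universe)
    rows <- lapply(names(terms), function(tm) {
        members <- sub(".*\r", "", terms[[tm]])
        K <- length(members)
        k <- length(intersect(members, geneSet))
        p <- stats::phyper(k - 1, K, N - K, n, lower.tail = FALSE)
        data.frame(term = tm, k = k, K = K, n = n, N = N, p = p,
                   stringsAsFactors = FALSE)
    })
    if (length(rows) == 0L)
        return(data.frame(term = character(), k = integer(), K = integer(),
                          n = integer(), N = integer(), p = numeric(),
                          padj = numeric(), enriched = logical(),
                          stringsAsFactors = FALSE))
    res <- do.call(rbind, rows)
    res$padj <- stats::p.adjust(res$p, method = "BH")
    res$enriched <- res$padj < pCutoff
    res <- res[order(res$p, res$term), , drop = FALSE]
    rownames(res) <- NULL
    res
}
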