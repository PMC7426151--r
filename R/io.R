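#' Write a count matrix and its design as TSV
#'
#' @param x a [DupCountSet-class].
#' @param countsPath,designPath output paths; the count file has the gene
#'   id as first column, the design file one row per sample.
#' @return invisibly, the two paths.
#' @export
writeCountMatrix <- function(x, countsPath, designPath) {
    cnt <- counts(x)
    df <- data.frame(gene = rownames(cnt), cnt, check.names = FALSE,
                     stringsAsFactors = FALSE)
    utils::write.table(df, countsPath, sep = "\t", quote = FALSE,
                       row.names = FALSE)
    des <- as.data.frame(colData(x))
    des <- cbind(sample = rownames(des), des)
    utils::write.table(des, designPath, sep = "\t", quote = FALSE,
                       row.names = FALSE)
    invisible(c(countsPath, designPath))
}

#' Read a count matrix and design written by [writeCountMatrix()]
#'
#' @param countsPath,designPath TSV paths.
#' @return a [DupCountSet-class].
#' @export
readCountMatrix <- function(countsPath, designPath) {
    df <- utils::read.delim(countsPath, check.names = FALSE,
                            stringsAsFactors = FALSE)
    cnt <- as.matrix(df[, -1, drop = FALSE])
    rownames(cnt) <- df[[1]]
    des <- utils::read.delim(designPath, stringsAsFactors = FALSE)
    DupCountSet(cnt, des)
}

#' Write a duplicate pair list as two-column TSV
#'
#' @param pairs data.frame with gene_a, gene_b.
#' @param path output path.
#' @return invisibly, the path.
#' @export
writePairList <- function(pairs, path) {
    utils::write.table(pairs[, c("gene_a", "gene_b")], path, sep = "\t",
                       quote = FALSE, row.names = FALSE, col.names = FALSE)
    invisible(path)
}

#' Write a GeneCatalog as TSV
#'
#' @param catalog a [GeneCatalog-class].
#' @param path output path.
#' @return invisibly, the path.
#' @export
writeCatalog <- function(catalog, path) {
    utils::write.table(as.data.frame(catalog@info), path, sep = "\t",
                       quote = FALSE, row.names = FALSE)
    invisible(path)
}

#' Read a GeneCatalog written by [writeCatalog()]
#'
#' @param path TSV path.
#' @return a [GeneCatalog-class].
#' @export
readCatalog <- function(path) {
    df <- utils::read.delim(path, stringsAsFactors = FALSE,
                            na.strings = c("NA", ""))
    new("GeneCatalog", info = DataFrame(df))
}
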