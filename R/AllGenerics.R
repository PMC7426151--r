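#' @importFrom BiocGenerics counts
NULL

#' Extract gene identifiers
#' @param x a GeneCatalog or DupCountSet
#' @return character vector of gene ids
#' @export
setGeneric("geneIds", function(x) standardGeneric("geneIds"))

#' Extract per-gene duplication classes
#' @param x a GeneCatalog
#' @return named character vector (singleton/WGD/SSD)
#' @export
setGeneric("geneClasses", function(x) standardGeneric("geneClasses"))

#' Extract the duplicate pair table
#' @param x a GeneCatalog
#' @return DataFrame with one row per pair: pair_id, gene_a, gene_b, class
#' @export
setGeneric("pairTable", function(x) standardGeneric("pairTable"))

#' Extract the DE result table
#' @param x a DEResult
#' @return DataFrame with gene, baseMean, lfc, p, fdr, call
#' @export
setGeneric("deTable", function(x) standardGeneric("deTable"))

#' Extract DE calls as a named vector
#' @param x a DEResult
#' @return named character vector of up/down/unchanged calls
#' @export
setGeneric("deCalls", function(x) standardGeneric("deCalls"))
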