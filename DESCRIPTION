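Package: dupliTD
Title: Transcriptional Divergence Analysis of Duplicate Gene Pairs
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Tools to quantify and test transcriptional divergence (TD)
    between the two copies of duplicated genes in RNA-seq count data.
    Provides negative-binomial differential-expression calling with
    Benjamini-Yekutieli FDR control, classification of duplicate pairs by
    origin (whole-genome vs small-scale duplication) via reciprocal best
    BLAST hits and Nei-Gojobori synonymous-divergence filtering, TD and
    diverged-copy (TDC) statistics with binomial and Fisher enrichment
    tests, resampling null distributions, a TD-threshold sensitivity
    sweep, logistic growth-curve fitting, hypergeometric
    over-representation analysis, and a synthetic-data generator that
    reproduces the statistical structure the analysis assumes.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.3)
Imports:
    methods,
    stats,
    utils,
    BiocGenerics,
    S4Vectors,
    SummarizedExperiment,
    Biostrings,
    minpack.lm
Suggests:
    testthat (>= 3.0.0),
    withr,
    jsonlite
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
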