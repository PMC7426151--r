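#' @importFrom Biostrings GENETIC_CODE DNAStringSet readDNAStringSet writeXStringSet
NULL

# Cached NG86 lookup tables: per-codon synonymous site fractions, per
# codon-pair (Sd, Nd) averaged over all orderings of single-nucleotide
# steps, and synonymous single-step neighbors (used by the CDS simulator).
.ng86Cache <- new.env(parent = emptyenv())

ng86Tables <- function() {
    if (!is.null(.ng86Cache$tabs)) return(.ng86Cache$tabs)
    gc <- Biostrings::GENETIC_CODE
    codons <- names(gc)
    nts <- c("A", "C", "G", "T")
    sense <- codons[gc != "*"]

    aaOf <- function(cod) unname(gc[cod])
    splitCod <- strsplit(codons, "")
    names(splitCod) <- codons

    # synonymous site fraction per codon: at each position, the fraction of
    # the three alternative nucleotides that preserve the amino acid
    # (changes to stop codons count as nonsynonymous)
    synSites <- stats::setNames(numeric(length(sense)), sense)
    synNeighbors <- stats::setNames(vector("list", length(sense)), sense)
    for (cod in sense) {
        s <- 0
        nbs <- character(0)
        for (pos in 1:3) {
            for (nt in setdiff(nts, splitCod[[cod]][pos])) {
                alt <- splitCod[[cod]]
                alt[pos] <- nt
                alt <- paste(alt, collapse = "")
                if (gc[alt] != "*" && gc[alt] == gc[cod]) {
                    s <- s + 1 / 3
                    nbs <- c(nbs, alt)
                }
            }
        }
        synSites[cod] <- s
        synNeighbors[[cod]] <- nbs
    }

    # per codon pair: average synonymous / nonsynonymous difference counts
    # over all orderings of the single-nucleotide steps, equally weighted;
    # steps through stop intermediates count as nonsynonymous changes
    stepSyn <- function(c1, c2) {
        a1 <- gc[c1]; a2 <- gc[c2]
        (a1 != "*") && (a2 != "*") && (a1 == a2)
    }
    pathCounts <- function(c1, c2) {
        pos <- which(splitCod[[c1]] != splitCod[[c2]])
        d <- length(pos)
        if (d == 0L) return(c(0, 0))
        perms <- if (d == 1L) list(pos) else {
            if (d == 2L) list(pos, rev(pos)) else {
                out <- list()
                for (i in 1:3) for (j in 1:3) if (i != j)
                    out[[length(out) + 1L]] <- c(pos[i], pos[j],
                                                 pos[setdiff(1:3, c(i, j))])
                out
            }
        }
        tot <- c(0, 0)
        for (ord in perms) {
            cur <- splitCod[[c1]]
            sd <- 0; nd <- 0
            for (p in ord) {
                nxt <- cur
                nxt[p] <- splitCod[[c2]][p]
                if (stepSyn(paste(cur, collapse = ""),
                            paste(nxt, collapse = ""))) sd <- sd + 1
                else nd <- nd + 1
                cur <- nxt
            }
            tot <- tot + c(sd, nd)
        }
        tot / length(perms)
    }
    n <- length(sense)
    SD <- matrix(0, n, n, dimnames = list(sense, sense))
    ND <- matrix(0, n, n, dimnames = list(sense, sense))
    for (i in seq_len(n)) for (j in seq_len(n)) {
        if (i < j) {
            cnt <- pathCounts(sense[i], sense[j])
            SD[i, j] <- SD[j, i] <- cnt[1]
            ND[i, j] <- ND[j, i] <- cnt[2]
        }
    }
    .ng86Cache$tabs <- list(sense = sense, synSites = synSites,
                            synNeighbors = synNeighbors, SD = SD, ND = ND)
    .ng86Cache$tabs
}

.toCodons <- function(x) {
    if (is(x, "DNAString") || is(x, "DNAStringSet")) x <- as.character(x)
    x <- toupper(as.character(x)[1L])
    if (nchar(x) %% 3 != 0)
        stop("sequence length must be a multiple of 3")
    substring(x, seq(1, nchar(x), by = 3), seq(3, nchar(x), by = 3))
}

#' Nei-Gojobori (NG86) synonymous divergence between two aligned CDS
#'
#' Counts synonymous sites per codon from the standard genetic code (the
#' fraction of the three alternative nucleotides per position that preserve
#' the amino acid; changes to stop codons count as nonsynonymous) and
#' synonymous differences between codon pairs, averaging multi-difference
#' codons over all orderings of single-nucleotide steps with equal weight.
#' `S` is the mean of the two sequences' synonymous-site totals,
#' `pS = Sd / S`, and `dS = -3/4 log(1 - 4/3 pS)` (Jukes-Cantor).
#'
#' Codons containing gaps or ambiguous bases in either sequence are skipped
#' pairwise; internal stop codons among counted codons are an error. When
#' `pS >= 3/4` the JC correction saturates: `dS` is `NA` and `saturated`
#' is set.
#'
#' @param cds1,cds2 aligned, equal-length coding sequences (character,
#'   `DNAString` or single-element `DNAStringSet`).
#' @return list with `S`, `Sd`, `pS`, `dS`, `saturated`, `nCodons` (codons
#'   actually counted).
#' @examples
#' ng86Ds("GGTGGGGGA", "GGCGGGGGA")$dS  # one synonymous Gly change
#' @export
ng86Ds <- function(cds1, cds2) {
    tabs <- ng86Tables()
    co1 <- .toCodons(cds1)
    co2 <- .toCodons(cds2)
    if (length(co1) != length(co2))
        stop("sequences must have equal length")
    clean <- grepl("^[ACGT]{3}$", co1) & grepl("^[ACGT]{3}$", co2)
    co1 <- co1[clean]; co2 <- co2[clean]
    if (length(co1) == 0L) stop("no scorable codons")
    gcd <- Biostrings::GENETIC_CODE
    if (any(gcd[co1] == "*") || any(gcd[co2] == "*"))
        stop("internal stop codon among counted codons")
    S <- (sum(tabs$synSites[co1]) + sum(tabs$synSites[co2])) / 2
    Sd <- sum(tabs$SD[cbind(co1, co2)])
    pS <- Sd / S
    saturated <- pS >= 0.75
    dS <- if (saturated) NA_real_ else -0.75 * log(1 - 4 / 3 * pS)
    list(S = S, Sd = Sd, pS = pS, dS = dS, saturated = saturated,
         nCodons = length(co1))
}

#' Read a two-column WGD pair list
#'
#' Lines give the two member genes of each whole-genome-duplicate pair
#' (tab-separated). Pairs are deduplicated as unordered pairs; self-pairs
#' and genes appearing with two different partners are errors.
#'
#' @param path TSV path (no header; a header line starting with `#` is
#'   skipped).
#' @return data.frame with columns gene_a, gene_b (gene_a < gene_b).
#' @export
readWgdPairs <- function(path) {
    lines <- readLines(path)
    lines <- lines[!grepl("^#", lines)]
    lines <- lines[nzchar(trimws(lines))]
    parts <- strsplit(lines, "\t")
    bad <- which(lengths(parts) < 2L |
                 vapply(parts, function(p) any(!nzchar(trimws(p[1:2]))),
                        logical(1)))
    if (length(bad))
        stop("malformed pair line ", bad[1L], ": ", lines[bad[1L]])
    a <- trimws(vapply(parts, `[`, "", 1L))
    b <- trimws(vapply(parts, `[`, "", 2L))
    if (any(a == b))
        stop("self-pair at line ", which(a == b)[1L])
    lo <- pmin(a, b); hi <- pmax(a, b)
    keep <- !duplicated(paste(lo, hi, sep = "\r"))
    pairs <- data.frame(gene_a = lo[keep], gene_b = hi[keep],
                        stringsAsFactors = FALSE)
    g <- c(pairs$gene_a, pairs$gene_b)
    if (anyDuplicated(g))
        stop("conflicting pairing: gene ", g[duplicated(g)][1L],
             " appears in more than one pair")
    pairs[order(pairs$gene_a, pairs$gene_b), , drop = FALSE]
}

#' Read BLAST tabular output (outfmt 6)
#'
#' @param path path to a 12-column BLAST tabular file
#'   (qseqid sseqid pident length mismatch gapopen qstart qend sstart send
#'   evalue bitscore).
#' @return data.frame with all 12 standard columns.
#' @export
readBlastTab <- function(path) {
    cols <- c("qseqid", "sseqid", "pident", "length", "mismatch", "gapopen",
              "qstart", "qend", "sstart", "send", "evalue", "bitscore")
    hits <- tryCatch(
        utils::read.delim(path, header = FALSE, col.names = cols,
                          stringsAsFactors = FALSE),
        error = function(e) stop("unreadable BLAST table: ",
                                 conditionMessage(e)))
    if (any(is.na(hits$evalue)) || any(is.na(hits$bitscore)))
        stop("unreadable row: non-numeric evalue/bitscore at row ",
             which(is.na(hits$evalue) | is.na(hits$bitscore))[1L])
    hits
}

#' Reciprocal best hits from all-vs-all BLAST
#'
#' Drops self-hits and hits failing the E-value or bit-score cutoffs, takes
#' the best hit per query (highest bit score; ties broken by smaller
#' E-value, then lexicographic subject id), and retains the unordered pair
#' (A, B) when A's best hit is B and B's best hit is A. When several
#' subjects tie for best, all reciprocal candidates compete and the
#' highest-scoring reciprocal pair wins, keeping the output a matching.
#'
#' @param hits data.frame with at least qseqid, sseqid, evalue, bitscore
#'   (see [readBlastTab()]).
#' @param eMax maximum E-value retained (default 1e-5).
#' @param bitsMin minimum bit score retained (default 50).
#' @return data.frame with gene_a, gene_b (gene_a < gene_b) and the summed
#'   bit score of the two directions.
#' @export
reciprocalBestHits <- function(hits, eMax = 1e-5, bitsMin = 50) {
    need <- c("qseqid", "sseqid", "evalue", "bitscore")
    if (!all(need %in% colnames(hits)))
        stop("hits must have columns ", paste(need, collapse = ", "))
    h <- hits[hits$qseqid != hits$sseqid &
              hits$evalue <= eMax & hits$bitscore >= bitsMin, , drop = FALSE]
    empty <- data.frame(gene_a = character(), gene_b = character(),
                        score = numeric(), stringsAsFactors = FALSE)
    if (nrow(h) == 0L) return(empty)
    # order so the first row per query is its best hit under the tie rules
    h <- h[order(h$qseqid, -h$bitscore, h$evalue, h$sseqid), , drop = FALSE]
    keyBest <- !duplicated(h$qseqid)
    bestScore <- h$bitscore[keyBest]
    names(bestScore) <- h$qseqid[keyBest]
    # all tied-best rows per query
    isBest <- h$bitscore >= (bestScore[h$qseqid] - 1e-9)
    bb <- h[isBest, , drop = FALSE]
    key <- paste(bb$qseqid, bb$sseqid, sep = "\r")
    recip <- paste(bb$sseqid, bb$qseqid, sep = "\r") %in% key
    cand <- bb[recip & bb$qseqid < bb$sseqid, , drop = FALSE]
    if (nrow(cand) == 0L) return(empty)
    backBits <- stats::setNames(bb$bitscore, key)
    cand$score <- cand$bitscore +
        backBits[paste(cand$sseqid, cand$qseqid, sep = "\r")]
    cand <- cand[order(-cand$score, cand$qseqid, cand$sseqid), , drop = FALSE]
    used <- character(0)
    keep <- logical(nrow(cand))
    for (i in seq_len(nrow(cand))) {
        if (!(cand$qseqid[i] %in% used) && !(cand$sseqid[i] %in% used)) {
            keep[i] <- TRUE
            used <- c(used, cand$qseqid[i], cand$sseqid[i])
        }
    }
    out <- data.frame(gene_a = cand$qseqid[keep], gene_b = cand$sseqid[keep],
                      score = cand$score[keep], stringsAsFactors = FALSE)
    out[order(out$gene_a, out$gene_b), , drop = FALSE]
}

#' Filter SSD candidates by synonymous divergence similar to the WGD pool
#'
#' Retains candidate pairs whose dS lies within the central empirical
#' quantile window of the whole-genome-duplicate dS distribution, and
#' reports a two-sample Kolmogorov-Smirnov statistic between the retained
#' candidates and the reference as a diagnostic of distributional
#' similarity.
#'
#' @param candidateDs named numeric vector of candidate-pair dS values.
#' @param wgdDs numeric vector of reference (WGD) dS values.
#' @param qLow,qHigh quantile window bounds (defaults 0.025, 0.975).
#' @return list with `keep` (named logical), `window` (numeric length 2),
#'   `ks` and `ksP` (diagnostic KS statistic and p-value).
#' @export
filterSsdByDs <- function(candidateDs, wgdDs, qLow = 0.025, qHigh = 0.975) {
    if (length(wgdDs) == 0L) stop("empty reference dS distribution")
    if (length(candidateDs) == 0L) stop("no candidate dS values")
    window <- stats::quantile(wgdDs, c(qLow, qHigh), names = FALSE,
                              na.rm = TRUE)
    keep <- !is.na(candidateDs) & candidateDs >= window[1] &
        candidateDs <= window[2]
    names(keep) <- names(candidateDs)
    ks <- if (any(keep)) {
        suppressWarnings(stats::ks.test(candidateDs[keep], wgdDs))
    } else NULL
    list(keep = keep, window = window,
         ks = if (is.null(ks)) NA_real_ else unname(ks$statistic),
         ksP = if (is.null(ks)) NA_real_ else ks$p.value)
}

#' Assemble a GeneCatalog from pair lists
#'
#' Every gene of the universe is classified exactly once: WGD pairs first,
#' then SSD pairs (an SSD pair sharing a gene with a WGD pair is dropped
#' with a warning), remaining genes become singletons.
#'
#' @param genes character vector, the gene universe.
#' @param wgdPairs,ssdPairs data.frames with gene_a, gene_b (either may be
#'   NULL or empty).
#' @return a [GeneCatalog-class].
#' @export
assembleCatalog <- function(genes, wgdPairs = NULL, ssdPairs = NULL) {
    genes <- unique(as.character(genes))
    asPairs <- function(p) {
        if (is.null(p) || nrow(p) == 0L)
            return(data.frame(gene_a = character(), gene_b = character(),
                              stringsAsFactors = FALSE))
        data.frame(gene_a = as.character(p$gene_a),
                   gene_b = as.character(p$gene_b),
                   stringsAsFactors = FALSE)
    }
    wgd <- asPairs(wgdPairs)
    ssd <- asPairs(ssdPairs)
    inUniverse <- c(wgd$gene_a, wgd$gene_b, ssd$gene_a, ssd$gene_b)
    missing <- setdiff(inUniverse, genes)
    if (length(missing))
        stop("pair gene absent from the gene universe: ", missing[1L])
    wgdGenes <- c(wgd$gene_a, wgd$gene_b)
    if (anyDuplicated(wgdGenes))
        stop("gene in two WGD pairs: ", wgdGenes[duplicated(wgdGenes)][1L])
    conflict <- ssd$gene_a %in% wgdGenes | ssd$gene_b %in% wgdGenes
    if (any(conflict)) {
        warning(sum(conflict), " SSD pair(s) dropped: gene already in a ",
                "WGD pair (WGD takes precedence)")
        ssd <- ssd[!conflict, , drop = FALSE]
    }
    ssdGenes <- c(ssd$gene_a, ssd$gene_b)
    if (anyDuplicated(ssdGenes))
        stop("gene in two SSD pairs: ", ssdGenes[duplicated(ssdGenes)][1L])

    cls <- stats::setNames(rep("singleton", length(genes)), genes)
    pid <- stats::setNames(rep(NA_character_, length(genes)), genes)
    prt <- stats::setNames(rep(NA_character_, length(genes)), genes)
    addPairs <- function(p, class, prefix) {
        for (i in seq_len(nrow(p))) {
            id <- sprintf("%s%04d", prefix, i)
            a <- p$gene_a[i]; b <- p$gene_b[i]
            cls[c(a, b)] <<- class
            pid[c(a, b)] <<- id
            prt[a] <<- b; prt[b] <<- a
        }
    }
    addPairs(wgd, "WGD", "WGDP")
    addPairs(ssd, "SSD", "SSDP")
    new("GeneCatalog",
        info = DataFrame(gene = genes, class = unname(cls[genes]),
                         pair_id = unname(pid[genes]),
                         partner = unname(prt[genes])))
}
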