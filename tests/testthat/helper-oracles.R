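# Independent brute-force oracles, kept deliberately separate from the
# package implementations they check.

# NG86 oracle: per-codon synonymous sites and pathway-averaged difference
# counts computed from scratch with explicit loops and its own permutation
# enumeration (equal weight over all orderings; steps through stop codons
# count as nonsynonymous).
bruteNg86 <- function(s1, s2) {
    gc <- Biostrings::GENETIC_CODE
    nts <- c("A", "C", "G", "T")
    codonsOf <- function(s) {
        s <- toupper(s)
        substring(s, seq(1, nchar(s), 3), seq(3, nchar(s), 3))
    }
    synFrac <- function(cod) {
        tot <- 0
        for (pos in 1:3) {
            for (nt in nts) {
                if (nt == substr(cod, pos, pos)) next
                alt <- cod
                substr(alt, pos, pos) <- nt
                if (gc[[alt]] != "*" && gc[[alt]] == gc[[cod]])
                    tot <- tot + 1 / 3
            }
        }
        tot
    }
    permute <- function(v) {
        if (length(v) <= 1L) return(list(v))
        out <- list()
        for (i in seq_along(v))
            for (rest in permute(v[-i]))
                out[[length(out) + 1L]] <- c(v[i], rest)
        out
    }
    codonDiff <- function(c1, c2) {
        pos <- which(strsplit(c1, "")[[1]] != strsplit(c2, "")[[1]])
        if (length(pos) == 0L) return(c(0, 0))
        acc <- c(0, 0)
        paths <- permute(pos)
        for (ord in paths) {
            cur <- c1
            sd <- nd <- 0
            for (p in ord) {
                nxt <- cur
                substr(nxt, p, p) <- substr(c2, p, p)
                if (gc[[cur]] != "*" && gc[[nxt]] != "*" &&
                    gc[[cur]] == gc[[nxt]]) sd <- sd + 1 else nd <- nd + 1
                cur <- nxt
            }
            acc <- acc + c(sd, nd)
        }
        acc / length(paths)
    }
    co1 <- codonsOf(s1); co2 <- codonsOf(s2)
    S1 <- S2 <- Sd <- 0
    for (i in seq_along(co1)) {
        S1 <- S1 + synFrac(co1[i])
        S2 <- S2 + synFrac(co2[i])
        Sd <- Sd + codonDiff(co1[i], co2[i])[1]
    }
    S <- (S1 + S2) / 2
    pS <- Sd / S
    list(S = S, Sd = Sd, pS = pS,
         dS = if (pS < 0.75) -0.75 * log(1 - 4 / 3 * pS) else NA_real_)
}

# Fisher oracle: explicit enumeration of all 2x2 tables with the observed
# margins, probabilities from factorials.
bruteFisher <- function(tab) {
    r1 <- sum(tab[1, ]); r2 <- sum(tab[2, ])
    c1 <- sum(tab[, 1]); n <- sum(tab)
    prob <- function(a) {
        b <- r1 - a; c <- c1 - a; d <- r2 - c
        if (b < 0 || c < 0 || d < 0) return(0)
        exp(lfactorial(r1) + lfactorial(r2) + lfactorial(c1) +
                lfactorial(n - c1) - lfactorial(n) - lfactorial(a) -
                lfactorial(b) - lfactorial(c) - lfactorial(d))
    }
    pObs <- prob(tab[1, 1])
    tot <- 0
    for (a in 0:min(r1, c1)) {
        p <- prob(a)
        if (p <= pObs * (1 + 1e-7)) tot <- tot + p
    }
    min(1, tot)
}

# Exhaustive subset-mean tail probability for small pools.
bruteSubsetMeanP <- function(pool, subsetSize, observed,
                             direction = "greater") {
    combs <- utils::combn(length(pool), subsetSize)
    means <- apply(combs, 2L, function(idx) mean(pool[idx]))
    if (direction == "greater") mean(means >= observed)
    else mean(means <= observed)
}

# Random stop-free CDS of n codons.
randomCds <- function(nCodons) {
    gc <- Biostrings::GENETIC_CODE
    sense <- names(gc)[gc != "*"]
    paste(sample(sense, nCodons, replace = TRUE), collapse = "")
}

# Random single-nucleotide mutant of a CDS that keeps all codons sense
# (any amino-acid effect allowed).
mutateCds <- function(s, nMut) {
    gc <- Biostrings::GENETIC_CODE
    v <- strsplit(s, "")[[1]]
    nts <- c("A", "C", "G", "T")
    done <- 0
    while (done < nMut) {
        i <- sample(length(v), 1)
        old <- v[i]
        v[i] <- sample(setdiff(nts, old), 1)
        codIdx <- ((i - 1) %/% 3) * 3 + 1
        cod <- paste(v[codIdx:(codIdx + 2)], collapse = "")
        if (gc[[cod]] == "*") v[i] <- old else done <- done + 1
    }
    paste(v, collapse = "")
}
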