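---
title: "Quantifying transcriptional divergence between duplicate gene copies"
author: "dupliTD"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Quantifying transcriptional divergence between duplicate gene copies}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(dupliTD)
```

## The question and the statistic

Duplicated genes are retained in yeast genomes from two kinds of events:
the ancient whole-genome duplication (WGD pairs, also called ohnologs) and
local, small-scale duplications (SSD pairs). A recurring observation is
that the two copies of a pair drift apart in how strongly they are
transcribed, and that this *transcriptional divergence* (TD) interacts
with how the genome responds when the environment changes — here, the
switch from a fermentable carbon source (glucose medium, YPD) to a
non-fermentable one (ethanol medium, YPE).

For a duplicate pair with copy-wise mean expression $e_a$ and $e_b$ in a
reference background (a time point and medium, YPD by default), the TD
ratio is

$$\mathrm{TD} = \frac{\max(e_a, e_b)}{\min(e_a, e_b)} \ge 1,$$

and the pair is called transcriptionally diverged when
$\mathrm{TD} > \tau$ with $\tau = 1.25$ (a 25% difference; strict
inequality). Expression is the mean of normalized counts across
replicates with a 0.5 pseudocount; pairs whose two copies have zero raw
counts throughout the background are excluded and counted. The
background matters: divergence judged in the ancestral population and in
an ethanol-evolved population can differ, so `computeTD()` takes the
background as a parameter rather than fixing it.

Downstream of the TD ratio the package provides:

* **TDC labels** (`classifyTDC()`): within a diverged pair, a copy that
  responds to the medium shift is the *high-TDC* copy if it is the
  higher-expressed member and *low-TDC* otherwise.
* **Five-way pair categories** (`classifyPairCategory()`): BothUp,
  BothDown, Discordant, OneUpOneUnchanged, OneDownOneUnchanged (plus
  BothUnchanged), symmetric in the copies.
* **Enrichment tests**: Fisher's exact test on 2x2 tables
  (`fisherEnrichment()`, two-sided by hypergeometric summation, sample
  cross-product odds ratio with a Haldane correction at zero cells) and
  the exact binomial test (`binomialTdEnrichment()`) for whether
  responding duplicates are TD more often than the pool fraction $p_0$.
* **Resampling nulls** (`resamplingNullMean()`, `categoryCountNull()`):
  subset means and category counts against permutation/resampling nulls,
  one-sided empirical p with the +1 correction,
  $p = (1 + \#\{T^{null} \ge T^{obs}\})/(n_{iter} + 1)$. The null mean
  and sd are reported for a normal overlay, but the empirical p is the
  decision statistic.
* **Sensitivity sweep** (`tdThresholdSweep()`): the TD call repeated for
  $\tau$ from 1 (any inequality) to 4 (a four-fold difference), split by
  duplicate origin.

## Differential expression model

Counts are modeled as negative binomial with variance
$\mu + \phi \mu^2$. The caller is deliberately compact:

1. **Normalization** (`computeSizeFactors()`): median-of-ratios factors
   rescaled to geometric mean 1.
2. **Dispersion** (`estimateDispersions()`): per-gene method-of-moments
   estimates $\hat\phi_g = \max(0, (s^2 - m)/m^2)$ on normalized counts
   pooled within condition, shrunk toward a common dispersion with
   weight $w = n_{prior}/(n_{prior} + df_g)$, $n_{prior} = 10$ by
   default. The common value is the *mean* of the raw estimates over
   expressed genes: at three replicates per group the raw estimator is
   strongly right-skewed and its median sits well below the underlying
   dispersion (about 20% low in our simulations), which would make the
   Wald test anticonservative; the mean is close to unbiased and brings
   the raw-p type-I error at $\alpha = 0.05$ to 0.05-0.06 across
   dispersions 0.02-0.2.
3. **Test** (`nbTest()`): $\mathrm{lfc} = \log_2((\bar y_{YPE} + 0.5) /
   (\bar y_{YPD} + 0.5))$, delta-method standard error from the NB
   variance of each group mean, standard-normal reference, two-sided. A
   t reference with few degrees of freedom was considered and rejected:
   it trades a slightly conservative 0.05 level for a collapse of
   far-tail power, and the tests that matter here call genes at an FDR
   of 0.005.
4. **Calling** (`callDE()`): up requires linear fold change strictly
   above 1.25 *and* FDR strictly below 0.005; down symmetric. The FDR is
   Benjamini-Yekutieli by default (`adjustPvalues()`), the conservative
   choice appropriate for correlated genes.

The contrast is always YPE vs YPD within one time point; no multi-factor
model is attempted.

One subtlety worth knowing: with strongly one-sided differential
expression, median-of-ratios normalization absorbs part of the shift and
attenuates fold changes (about 15% at 20% of genes changed in one
direction). This is a property of every global-scaling normalization,
not of this implementation; the package's own recovery tests therefore
plant symmetric effects, which is also what the generator draws.

## Duplicate catalog

`readWgdPairs()` ingests a two-column WGD pair list.
`reciprocalBestHits()` screens all-vs-all BLASTP tabular output
(outfmt 6) with the conventional cutoffs E <= 1e-5 and bit score >= 50,
takes the best hit per query (ties broken by E-value, then subject id),
and keeps mutual best pairs; with tied best hits, the highest-scoring
reciprocal pair wins so the output stays a matching.

SSD candidates are then filtered on synonymous divergence
(`ng86Ds()` + `filterSsdByDs()`). dS uses Nei-Gojobori counting:
per-codon synonymous site fractions from the standard code (changes to
stop codons count as nonsynonymous), pairwise differences averaged over
all orderings of single-nucleotide steps with equal weight (steps
passing through a stop intermediate count as nonsynonymous changes), and
the Jukes-Cantor correction $d_S = -\tfrac34 \log(1 - \tfrac43 p_S)$,
undefined at saturation ($p_S \ge 3/4$). "Similar to the WGD
distribution" is operationalized as a central quantile window (2.5-97.5%
by default) of the WGD dS values, with a two-sample KS statistic
reported as a diagnostic; the original screen's exact rule is not
recorded anywhere, so the window is a declared choice and configurable.

## Growth curves

`fitLogistic()` fits $N(t) = K/(1 + ((K - N_0)/N_0)e^{-rt})$ by
Levenberg-Marquardt least squares, reporting $r$ as the maximum growth
rate $\mu_{max}$ (h$^{-1}$) and $K$ as the carrying capacity (OD600) —
the conventions of the usual logistic growth-curve tools. Initial
values come from the data (max OD, first positive OD, early log-linear
slope); ODs are floored at $10^{-4}$ before logs; blanks (uninoculated
controls) are subtracted when given; series with less than a 1.2-fold
dynamic range, failed optimizations, or non-positive parameters are
flagged rather than reported. `generationsFromBottleneck()` converts a
serial-transfer design into doublings:
$g = n_{passages}\log_2(1/f)$, e.g. 10 passages at a 10% bottleneck are
~33 generations, and 100 passages at 1% are ~660 (reported to two
significant figures above 100).

## Over-representation

`hypergeometricOra()` is a plain hypergeometric ORA against a
term-to-gene map, BH-adjusted, flagged at adjusted p < 0.01. The
universe defaults to the genes that entered the expression analysis
(the expression-background convention), not all annotated genes.

## What the generator emulates — and what it does not

`simulateCatalog()`/`simulateCounts()` produce a genome of singletons
plus WGD and SSD pairs with:

* copy-wise divergence planted in a fraction of pairs (default 0.8,
  echoing that roughly 80% of analyzed pairs were diverged in the
  ethanol study this package is built around); the log-ratio magnitude
  is $|N(0, \sigma)|$, default $\sigma = 0.5$, applied to a randomly
  chosen copy (the copies are exchangeable);
* condition effects $\log_2$-normal in size on a random subset of genes
  (default 20%), optionally coupled to TD-pair membership through a
  logistic tilt on the DE indicator (`deTdCoupling`, log-odds units; 0
  decouples them) — this is the dial the power tests use to plant or
  null out the divergence-response association;
* negative-binomial counts with a single dispersion (default 0.1, a
  typical bulk RNA-seq value for biological replicates), lognormal
  library-size factors (sd 0.15 on the log scale) so normalization is
  never trivial, and three replicates per condition — three biological
  replicates being the design of the evolution experiment, since the
  sequencing replicate count is not recorded;
* codon-pair material at a target dS (`simulateCdsPairs()`: synonymous
  single-nucleotide substitutions at distinct codons of a stop-free
  ancestor, so amino-acid sequences are preserved by construction);
* logistic OD600 curves on a 15-minute grid over 78 h with additive
  Gaussian noise.

Not emulated: read-level noise and mapping artifacts, gene-length and GC
biases, expression correlation along the genome, dispersion trends in
the mean, multiple-hit codon saturation, and real annotation structure.
Passing tests on this generator demonstrate the statistics are computed
correctly and are calibrated under the stated model — not that the model
captures every property of a real RNA-seq experiment.

## Numerical and design choices

* Strict thresholds everywhere ("more than 25%", "FDR below 0.005"),
  so boundary cases (ratio exactly 1.25) are negative.
* Pseudocount 0.5 in fold changes and TD expression means keeps zeros
  finite; both-zero pairs are excluded, not imputed.
* The binomial TD-enrichment default is the upper tail (`greater`),
  reported with its direction; the two-sided minimum-likelihood p is
  available and is what reproduces the published t0 value
  (`binomialTdEnrichment(274, 312, 867/1090, "two.sided")` gives
  1.846e-4; the upper tail on the same counts is 8.60e-5).
* Resampling defaults: 10,000 iterates, without replacement, mandatory
  seeds; empirical p never reaches 0 because of the +1 correction.
* Fisher ties use the customary $1 + 10^{-7}$ relative tolerance when
  summing probabilities "as extreme".
* RBH tie-breaking is fully deterministic (bit score, then E, then
  subject id).
* The Wilcoxon comparison enumerates exactly when both groups together
  hold at most 12 tie-free values and uses the tie-corrected normal
  approximation otherwise.

### Problem sizes used by the test suite

Simulation-based checks run at 2,000-6,000 genes with three replicates
per condition, 50-200 simulated datasets for calibration properties and
20 for power properties, and resampling nulls of a few thousand
iterates — sizes at which the asymptotic arguments above are visibly at
work and a full run remains comfortable on a laptop. The null-coupling
calibration uses a generator setting whose up-called duplicate fraction
(~13%) matches what the motivating experiment observed (312 of ~2,230
duplicate genes), because the exact binomial's discreteness makes its
rejection rate land visibly below nominal when responder counts are
small. The planted-coupling power check uses a strong, unambiguous
signal (coupling 4 on the log-odds scale, divergence sd 1.0): it is a
power property, and the generator's weaker defaults are the *null*
conditions, not the planted ones.

## Known limitations

* The DE caller is a two-group Wald test: no GLM covariates, no exact
  conditional test, no TMM. It is calibrated by simulation, not by
  equivalence to any specific published tool.
* dS is NG86 with equal-weight pathway averaging; no maximum-likelihood
  codon model, no transition/transversion weighting, and input CDS are
  assumed codon-aligned and equal-length.
* The TD ratio inherits sampling noise from both copies; near the
  threshold, pairs are misclassified in both directions at a rate set
  by replicate number and dispersion. The threshold sweep exists
  precisely to show conclusions are not artifacts of one $\tau$.
* ORA knows nothing about ontology structure (no term propagation or
  semantic similarity).

## A short tour

```{r tour, eval = FALSE}
cfg <- simConfig(nSingletons = 800, nWgdPairs = 300, nSsdPairs = 300,
                 fracDe = 0.3, seed = 1)
sim <- simulateCatalog(cfg)
dcs <- simulateCounts(sim$catalog, sim$truth, cfg)

de  <- runDGE(dcs, "t0")                      # YPE vs YPD at t0
td  <- computeTD(dcs, sim$catalog, "t0")      # TD in the YPD background
ok  <- td[!td$excluded, ]
pool <- c(ok$gene_a, ok$gene_b)
tdg  <- c(ok$gene_a[ok$td], ok$gene_b[ok$td])
resp <- pool[deCalls(de)[pool] == "up"]
binomialTdEnrichment(sum(resp %in% tdg), length(resp),
                     length(tdg) / length(pool))
```

Or the whole pipeline in one call:

```{r pipeline, eval = FALSE}
res <- runPipeline(pipelineConfig(seed = 1), "td-analysis")
```
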