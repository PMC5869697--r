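---
title: "Personalised drug repositioning by expression reversal: models and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Personalised drug repositioning by expression reversal: models and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(revcon)
```

## The problem

Gene-expression reversal ("connectivity mapping") ranks candidate
drugs by whether the expression changes a compound induces in cell
lines oppose the changes seen in diseased tissue. Almost all reversal
analyses aggregate a tumour cohort into one group signature, or a
handful of molecular subtype signatures, before scoring drugs. When
tumours are heterogeneous -- different samples perturbing different
pathways -- aggregation dilutes or masks exactly the programs a drug
would need to reverse. revcon implements the alternative: a signature
*per tumour sample*, each scored against every drug, with the
per-sample enrichment frequency as the drug-level statistic, and a
simulation machinery that asks whether the individual-sample results
could have arisen from a homogeneous (group- or subtype-level) cohort.

Because the real inputs (a tumour mRNA-seq cohort; a large drug
perturbation library) are external downloads, the package ships a
synthetic-data module that emulates their statistical structure with
known ground truth. Every stage of the pipeline is exercised offline
against planted effects.

## Models

### Tumour signatures

Counts are modelled per gene `g` and sample `i` as negative binomial,

    counts[g, i] ~ NB(mean = mu[g, i], variance = mu + phi * mu^2)
    log mu[g, i] = x_i' beta_g + offset_i

fitted by IRLS vectorized across genes, with a likelihood-ratio test
(chi-square, `df` = coefficient difference) for each contrast and
Benjamini-Hochberg FDR within each signature. Four families are
produced: group (all tumours vs all normals), subtype, per-sample (one
tumour vs all normals) and normal-control (each normal vs the
remaining normals -- the empirical false-positive yardstick).

Two numerical choices deserve explanation:

* **Offsets are upper-quartile effective library sizes**
  (`effective_lib_sizes()`), not raw column totals. RNA-seq baselines
  are heavy-tailed; a few dominant differentially expressed genes can
  shift a sample's total count by tens of percent and bias *every*
  fold change in that sample. The upper quartile of non-zero CPM is
  robust to this, and on synthetic data removes a systematic fold
  change bias of several tenths of a log2 unit.
* **The common dispersion is estimated from the normal samples only**
  (profile likelihood over a log-spaced grid, refined by
  golden-section search). The per-sample contrast asks whether one
  tumour observation is consistent with the *normal* condition, so the
  normal replicates supply the correct null variance. Estimating phi
  on the full cohort with a tissue-type design -- the other natural
  choice -- absorbs genuine tumour heterogeneity into phi (on
  synthetic data a true phi of 0.1 inflates to roughly 0.5 under
  strong planted heterogeneity) and collapses per-sample power. A
  single tumour sample can never inform its own dispersion, so phi is
  fixed at the cohort estimate for every contrast; this also keeps the
  per-sample likelihood-ratio tests well defined.

The per-sample contrast (intercept + one-sample indicator) is fitted
through an exact decomposition: the free indicator coefficient
saturates the singleton observation, so the full-model likelihood
separates into an intercept-only fit on the normals plus a point term.
This is algebraically identical to the general IRLS route (a test
asserts it) and makes scoring thousands of simulated samples feasible.
Genes with all-zero counts in a contrast get `p = 1` and `log2fc = 0`;
singleton fold changes floor the saturated count at 0.5 to stay
finite.

A power asymmetry is worth knowing about: a k-fold *loss* of
expression carries much less single-observation information than a
k-fold gain (the likelihood-ratio statistic for a 4-fold drop
saturates near 12.7 at phi = 0.1 regardless of depth), so per-sample
signatures recover down-regulated program genes less completely than
up-regulated ones, especially for read-starved genes. This is a
property of single-sample inference, not of the implementation.

### Drug signatures

Per drug, gene-wise ordinary least squares on log-scale expression
with concentration as a linear covariate (0 = vehicle control;
untransformed, with log-concentration available upstream as a
generator choice) and cell line, duration and batch as categorical
covariates. A categorical block enters only with more than one
distinct level; the ambiguous published phrasing about when duration
enters is resolved here as "more than one distinct duration" and not
reinterpreted elsewhere. Drugs without any control column, or whose
design is rank-deficient after level dropping, are flagged
UNPROCESSABLE -- the mechanism behind the small percentage of library
drugs excluded in practice.

Residual variances are moderated empirically: `s2_g` is modelled as a
scaled-F draw around a prior variance `s0_sq` with prior degrees of
freedom `d0`, estimated by matching the mean and variance of `log s2`
(digamma/trigamma moments; `d0` clamped to `[0.1, 1e6]` before the
infinite branch). The moderated t uses the posterior variance
`(d0 s0_sq + df s2)/(d0 + df)` with `d0 + df` degrees of freedom.
The percentage of genes under a (deliberately liberal) FDR of 50% --
`pct_deg` -- is the signature-quality covariate used downstream.

### Connectivity

A query is built from a tumour signature at FDR < 1%, split into up
and down sets weighted by `|log2fc|` (weight exponent 1: the published
description weights by the log2 fold differences and nothing more).
Genes absent from the drug platform are dropped rather than
zero-weighted; pairs sharing fewer than 5 genes are unscorable and
excluded from all frequencies. Each set is scored on the drug's
moderated-t ranking (ties broken by gene id) with a weighted
Kolmogorov-Smirnov running sum -- hits add `w/sum(w)`, misses subtract
`1/(N - N_hit)`, the score is the extremum of largest magnitude, the
positive extremum winning exact ties. The two sets combine as
`(es_up - es_down)/2` when their signs differ (or one is zero) and 0
otherwise, so a negative score means reversal.

P-values come from gene-label permutations (sample labels are not
exchangeable here: there is one signature per sample): gene sets of
the same sizes are redrawn from the platform, disjointly as real
queries are, with weights kept, and the two-sided
`p = (1 + #{|perm| >= |obs|}) / (n_perm + 1)`. The permutation kernel
is compiled (Rcpp) with a pure-R twin kept as the test oracle. One
consequence of the same-sign collapse is an atom of combined scores at
exactly 0: the permutation p is exactly uniform for one-set queries
and valid-but-conservative (super-uniform) for two-set queries; the
calibration tests assert precisely that. Negative enrichment is
`score < 0` and `p < 0.05`. Every permutation stream derives
deterministically from the global seed and the (sample, drug) pair.

### Summaries

Per drug: the fraction of scored samples negatively enriched; an
empirical cumulative P comparing that frequency against the "empty"
drugs (signatures whose DEG count falls below what uniform p-values
would produce 95% of the time, determined by Monte Carlo); and BH FDR
applied separately within each decile of `pct_deg`, so signature
quality cannot confound the correction. Deciles are assigned by rank
with ties broken by drug id. Both empirical P-values use the `+1`
convention to avoid zeros.

### The simulation null

To ask whether individual-sample enrichment could have arisen from a
homogeneous cohort, the fitted group (or subtype) model is inverted
into a generator: per-gene tumour-condition means at unit depth plus
`size = 1/phi` (phi = 0 flags the Poisson limit), with depth factors
resampled from the observed tumour depths. Batches of pseudo-samples
are drawn, and each batch runs the *full* per-sample pipeline --
signatures against the real normal samples (the normal-side intercept
is re-fitted within every contrast, the conservative reading of an
undocumented choice), queries, permutation-scored connectivity -- to
count negatively enriched samples per drug. The empirical 2.5%/97.5%
interval (type-1 percentiles, so two batches give min/max) locates the
observed count; fold ratios against both endpoints are reported.
Subtype nulls are mixtures drawn at the observed subtype proportions.

## The synthetic-data generator

The generator emulates the structure the analysis assumes, with
defaults matching the cohort the method was developed on: 534 tumour
and 72 normal samples, 11,333 genes, four subtypes, the published
stage distribution, and a small fraction of patients contributing two
tumour samples (shared subtype and group effects, independent private
programs -- the replicate-consistency arm). Counts are NB with
`variance = mu + phi mu^2`; baselines are log-normal
(meanlog 4, sdlog 1.5) to mimic the RNA-seq dynamic range so the CPM
filter behaves realistically; depths are log-uniform over a 4-fold
range; the default dispersion of 0.15 corresponds to a biological
coefficient of variation near 0.4, typical for human tissue. Planted
effects have fixed magnitude (default 1.5 log2 units, a strong but
common effect size) and random sign, so recovery tolerances stay
sharp; group, per-subtype and per-sample-private programs are drawn
independently and may overlap. Private program density can scale with
a planted stage covariate. Drug panels add per-gene cell-line, batch
and duration offsets (batch labels balanced-randomized within each
drug, since any cyclic assignment aliases batch with cell line for
some panel shapes), Gaussian noise, and a concentration-linear
effect that for "reversal" drugs is `-k` times a chosen planted
program; a configurable fraction of drugs lack control columns
(default 2%, the rate seen in the large public library).

What the generator does *not* emulate: landmark-gene imputation of the
L1000 platform, probe-level microarray artefacts, correlated gene-gene
structure, and batch effects in the tumour counts. Passing tests
therefore demonstrate correctness of the statistical machinery under
the stated model, not robustness to those real-data complications.

## Problem sizes used in the tests

The test-suite works at desk scale: cohorts of tens of samples and
150-2,000 genes, panels of up to 100 drugs, 100-1,000 permutations per
pair, and simulation nulls of 200 batches of 20 samples (the full
published budget of 10,000 batches of 530 samples is available through
the same arguments). The calibration, recovery and discrimination
checks were chosen so that their expected margins are wide at these
sizes; the dense-program, well-expressed-gene conditions used for the
query-recovery check reflect the power analysis above.

## Known limitations

* Per-sample inference is asymmetric in direction (above) and its
  chi-square p-values are slightly anti-conservative for very small
  comparison groups (the LRT calibration holds well from a few dozen
  samples upward).
* The equal weighting of experimental instances within a drug --
  pooling all cell lines, durations and concentrations into one
  linear fit -- is inherited from the published design and is a known
  simplification.
* Alternative connectivity scorers (cosine, rank-sum variants) and
  control-gene batch correction are out of scope.
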