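---
title: "pathdriver: models, synthetic study conditions, and numerical choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{pathdriver: models, synthetic study conditions, and numerical choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

`pathdriver` implements a tumor-driver discovery pipeline spanning bulk
survival genomics and single-cell analysis. This vignette is the package's
account of the underlying models: what each stage assumes, which parameters
matter and why their defaults are what they are, what the synthetic-data
generators do and do not emulate, and where the design was genuinely open.

## Pathway scoring

**ssGSEA.** For a sample with `N` genes ranked by expression descending
(ties broken lexicographically by gene id, so results are identical across
platforms), the enrichment score of a set `S` is

    ES = sum_{i=1..N} [ P_hit(i) - P_miss(i) ]

where `P_hit(i)` is the cumulative sum of weights `(N - pos + 1)^alpha`
over in-set genes at positions `<= i`, normalized by the total in-set
weight, and `P_miss(i)` is the uniform cumulative fraction of out-of-set
genes. `alpha` defaults to 0.25, the common single-sample convention; it is
exposed because no single value is canonical. NES divides every ES by the
global `max(ES) - min(ES)` of the matrix — an affine rescaling, so sample
orderings within a set are preserved exactly. Sets sharing fewer than
`min_overlap` (default 5) genes with the matrix are skipped with a warning.

**AUCell.** Per cell, the score is the area under the set-gene recovery
curve over the top `ceiling(top_fraction * N)` ranks, divided by the
maximal attainable area; it is 1 when the set fully occupies the top ranks
and 0 when it is entirely outside them. `top_fraction` defaults to 0.05:
single-cell rankings are only informative near the top because of dropout.
Both scores are rank statistics, hence invariant to any strictly monotone
transformation of a sample's expression — normalization choices upstream
cannot change them.

## Survival framework

The cohort splitter reserves subjects followed to approximately 1, 3 and
5 years (±90 days; the tolerance is a package decision, recorded in the
result) so that both partitions contain the subjects that anchor landmark
analyses, then assigns the rest by an event-stratified draw at the 7:3
ratio.

Cox models use Breslow tie handling throughout (it matches the elastic-net
Cox convention and has a simple closed-form partial likelihood that the
test suite checks against a grid-search maximizer). Fits that leave a
coefficient above 20 in magnitude are rejected as monotone-likelihood
(separation) cases rather than reported.

The univariate screen fits one Cox model per pathway and controls FDR by
Benjamini–Hochberg at 0.05. Zero-variance features are reported as skipped,
not failed, so a degenerate pathway cannot abort a screen.

**Stability selection** refits an elastic-net Cox model (`l1_ratio = 0.1`)
on bootstrap resamples (70% of subjects, drawn with replacement; 1,000
resamples by default) over a 50-point log-spaced lambda path from the
data-derived maximum down to 1% of it, and counts a feature as selected
when its coefficient is non-zero at *any* lambda. A caveat discovered while
validating this stage on synthetic cohorts: the any-lambda rule is
permissive by construction. Near the low end of the path the model is only
lightly penalized, so whenever subjects comfortably outnumber features
almost every feature enters somewhere on the path and selection frequencies
concentrate near 1 for nulls as well as for true signals. Frequencies from
this rule are therefore a ceiling-saturated stability measure — genuinely
prognostic features reach exactly 1, but a frequency near 1 is not by
itself evidence — and sharper contrast requires a shorter path
(`lambda_min_ratio`) or a fixed-lambda variant. We keep the declared rule
as the default rather than silently substituting a better-behaved one.

**Metrics.** Harrell's C uses event-anchored comparable pairs with risk
ties counted 0.5. The time-dependent AUC is the cumulative-case /
dynamic-control estimator with inverse-probability-of-censoring weights
from the Kaplan–Meier censoring estimator evaluated left-continuously;
horizons beyond follow-up are reported `NA` rather than extrapolated.
Default horizons are 12, 36 and 60 months at 30.4375 days/month.

**Benchmarking.** Learners plug into a declared contract — `fit(features,
surv, params)` and `risk(model, features)`, higher risk = worse — and are
tuned by seeded uniform random search (the tuning strategy is deliberately
simple and reproducible; the search space, not the optimizer, is the
scientifically meaningful input). The objective is the mean 5-fold CV
C-index. The shipped reference learner is a penalized Cox model; random
survival forests or boosted models can be supplied through the same
contract without changes to the harness.

**Attribution.** Per-patient Shapley values are estimated by sampling
feature orderings and crediting each feature with the change in predicted
risk when the patient's value replaces the baseline (training-mean) value.
For additive models this reduces exactly to `coef * (x - baseline)`; the
test suite checks the sampled estimate against exhaustive ordering
enumeration at four features. Positive mean attribution marks a
risk-increasing feature.

**Cutpoints.** `optimal_cutpoint` scans all admissible midpoints
(≥10% of subjects per arm) and maximizes the log-rank statistic. The
returned p-value is flagged selection-biased: a maximally selected
statistic needs external validation, and the package says so in the result
object rather than leaving it implicit.

## Single-cell CNV and malignancy

QC follows the standard thresholds (200–10,000 detected genes per cell,
≤20% mitochondrial fraction, ≤15% hemoglobin fraction, genes detected in
≥50 cells). The CNV profile subtracts the reference-cell mean per gene,
clamps residuals at ±3 (so a single outlying gene cannot mimic a focal
event), and takes a centered running mean over 100 genes in genomic order
within each chromosome, truncating windows at chromosome ends (minimum one
gene; chromosomes with fewer than 10 annotated genes are excluded). The
per-cell CNV score is the mean squared smoothed deviation — a declared
convention, since "CNV score" has no single standard formula.

Focal driver calls are robust Z-scores against the reference: per gene,
`Z = (value - median_ref) / (1.4826 * MAD_ref)`, with the MAD floored at
1e-6 so constant references degrade to sign calls instead of dividing by
zero. Thresholds default to ±2 robust SDs, the conventional outlier cut;
note that a two-sided 2-SD cut implies roughly 4.6% of genuinely neutral
reference cells will be called non-neutral at any one gene, and reference
heterogeneity (distinct cell types in the reference pool) pushes this
slightly higher — so per-gene call rates in the few-percent range in
reference cells are expected behavior, not contamination.

Clustering resolution is chosen by scanning a grid (default 0.2–2.0 in
steps of 0.1) with a seeded, resolution-parameterized community detection
(Leiden over modularity by default; the partitioner is injectable, so any
deterministic graph partitioner can stand in) and picking the resolution
maximizing the mean silhouette on the supplied embedding; single-cluster
partitions score −1 and ties go to the smallest resolution. Whether the
embedding is CNV-derived or expression-derived is the caller's choice and
is recorded with the result.

A cluster is labeled tumor-like when its mean CNV score exceeds the
reference mean by ≥2 reference SDs *or* ≥30% of its cells carry any
non-neutral driver call. Both thresholds are package decisions — the
labeling concept is qualitative in the underlying methodology — and both
are parameters.

## Co-expression modules

The network is unsigned: adjacency `|cor|^beta` with `beta` chosen as the
smallest power whose scale-free fit index reaches 0.85 (the index is the
signed R² of `log10 p(k)` on `log10 k` over at least five occupied
connectivity bins; if no power reaches the target the argmax is returned
with a warning flag). Modules come from average-linkage clustering of
topological-overlap dissimilarity with a *static* tree cut at height 0.99 —
dynamic tree cutting has more recall on nested modules but is
under-specified for oracle testing; the static cut is fully reproducible
and its behavior at the cut height is documented: branches whose
between-gene TOM dissimilarity approaches 0.99 (correlations of roughly
0.4 at power 6) may merge at the tree-cut stage before eigengene merging is
reached. Branches below 30 genes go to grey. Module pairs whose eigengenes
correlate above `1 - 0.25` merge iteratively. Eigengenes are first
principal components sign-oriented so mean member correlation is positive,
which makes kME signs interpretable.

## Prioritization

Differential expression is a Welch t-test on log-scale values with BH
adjustment; the single-cell and bulk threshold presets (q < 0.05 with
|log2FC| > 1 and > 0.5 respectively) are the catalog-defining rules, and
the pass flag reproduces them exactly. Moderated (empirical-Bayes) tests
would gain power at very small n but the thresholds, not the moderation,
drive the downstream intersection; this is a declared simplification.

Diffusion pseudotime builds a Gaussian-kernel transition matrix on the kNN
graph of the top principal components (adaptive bandwidth = distance to the
k-th neighbor, k = 15), takes the symmetrized eigendecomposition, and
accumulates diffusion distance from the root over the leading components
weighted by `lambda / (1 - lambda)`; pseudotime is scaled to [0, 1] with
the root at 0. The root must be supplied explicitly or via a potency score
(`root = "auto"`) — automated potency inference is out of scope, and hiding
the root choice would hide the main degree of freedom. Disconnected kNN
graphs are an error (advising a larger k), not a silent multi-component
ordering.

Trend tests are Spearman correlations against pseudotime with t-approximate
p-values — invariant to monotone reparameterization of pseudotime, which
matters because pseudotime is only ordinally meaningful. Constant rows are
excluded from BH rather than diluting it.

The evidence intersection is deliberately trivial machinery: four
membership flags, an evidence count, and a core flag that is true exactly
for four-of-four genes (optionally restricted to a catalog such as a
deubiquitinase list). Its value is the contract — deterministic ordering,
commutativity in the four sets, and empty-set behavior — not cleverness.

## Communication and motifs

The ligand–receptor score is `mean(ligand | sender) * mean(receptor |
receiver)` against a null that permutes group labels across all cells; the
p-value uses the add-one estimator `(1 + #{null >= obs}) / (1 + B)` so it
is never exactly zero, and significance additionally requires ligand
log2FC > 1 in the sender versus all other cells (pseudocount 1 in the
ratio). This single-score permutation construction replaces multi-method
meta-aggregation; the permutation null and the joint significance rule are
the load-bearing parts.

The composite receptor-to-TF axis score is the per-cell mean of
min-max-scaled expression over the available axis genes; absent and
constant-range genes are dropped and recorded. The definition is declared
prominently because "axis score" has no canonical formula; min-max scaling
makes the score invariant to per-gene affine rescaling and bounded in
[0, 1].

Promoters are `[TSS - 1000, TSS + 100)` on the plus strand and the
strand-mirrored window, reverse-complemented, on the minus strand; all
coordinates are 0-based half-open end to end, which removes every ±1
ambiguity. Motif scanning integerizes per-position log2 odds at scale 1000
(rounding error below 0.001 bits per position) and convolves the exact
null score distribution under the background by dynamic programming; a
window is a hit when the exact tail probability is below 0.01. `N` bases
contribute zero (background). Note what an exact per-window p < 0.01
guarantees: the *per-window* false rate is below 0.01, so long background
sequences accrue false hits in proportion to their length — genome-scale
scanning needs multiplicity control on top, which is out of scope here.
PWM parsing applies a pseudocount of 0.5 per cell to count matrices
(Laplace smoothing); probability matrices pass through unchanged.

## Synthetic study conditions

The generators define the conditions under which the pipeline is tested:

* **Bulk cohorts**: pathway latent activities are standard normal per
  sample, mapped additively onto 10–20 member genes with log-scale noise
  (SD 1); survival is exponential proportional hazards with linear
  predictor `sum(theta_p * activity_p)`, baseline rate 1/730 days, and
  independent exponential censoring calibrated numerically to the target
  censoring fraction (default 30%). Default planted effect `theta = 0.8`
  per unit activity with n = 300 — a strong but realistic pathway-level
  hazard ratio (~2.2 per SD).
* **Single-cell data**: negative-binomial counts (dispersion 0.1, log-normal
  library factors, SD 0.2 on the log scale) over cell types with 5% of
  genes elevated 4x as markers; malignant cells multiply block means by the
  planted CNV fold across contiguous gene runs (default test block: 300
  genes at 2x, plus a 120-gene 0.5x loss), shift DE genes by planted
  log2FC, and follow trend curves (logistic late-up/down, Gaussian
  early-peak, amplitude 4x) in a uniform latent pseudotime. Genes sit on
  synthetic chromosomes of 500 in genomic order.
* **Promoters**: i.i.d. uniform background with one consensus-sampled motif
  instance at a recorded offset in a planted fraction of sequences.

What the generators do *not* emulate — batch effects, doublets, ambient
RNA, spatial structure, gene-length effects, overdispersed pathway
cross-talk — bounds what the passing tests show: the pipeline recovers its
own planted model faithfully, which validates the computation, not the
biology of any particular dataset. One interaction worth knowing about:
planted trend genes change cell library sizes, so total-count normalization
induces weak opposite-signed trends in all other genes (a compositional
effect that is equally present in real data); with a realistically sized
gene universe it stays below the FDR threshold.

Every generator is a pure function of its config including the seed, and
restores the caller's RNG state.

## Problem sizes

The test suite and the acceptance script run at desk scale, chosen so the
full suite completes in well under a minute of compute per stage: bulk
cohorts of n = 200–300 with 50 pathways; 100 replicate cohorts for coverage
checks; single-cell datasets of 500–1,300 cells by 1,000 genes; 100–200
bootstrap resamples for stability selection; 8 random-search draws for the
benchmarking harness; 1,000 permutations for ligand–receptor tests; 100
promoters of 500 bp for motif recovery.

## Known limitations

* Static tree cut (not dynamic) for module detection; nested or
  close-to-threshold modules may merge at the cut stage.
* The any-lambda stability-selection rule saturates when subjects outnumber
  features (discussed above).
* Bulk DE uses Welch t rather than empirical-Bayes moderation.
* Pseudotime roots are user-supplied; no potency inference.
* The maximally selected cutpoint p-value is reported but selection-biased.
* Motif hits control per-window, not per-genome, error.
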