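# pathdriver

Pathway-level survival modeling and multi-evidence tumor-driver
prioritization for bulk and single-cell transcriptomics.

`pathdriver` is an R implementation of a multi-omics discovery pipeline of
the kind used to nominate candidate driver genes in pancreatic ductal
adenocarcinoma: bulk cohorts are summarized into pathway activity scores and
screened for prognostic signal, single-cell data are sifted for malignant
cells by copy-number inference, co-expression modules and pseudotime trends
narrow the candidate space, and a four-way evidence intersection nominates
the final driver candidates. Every stage is exercised end-to-end on
synthetic cohorts with planted, recoverable ground truth, so the whole
pipeline is testable without access to patient data.

## What it computes

**Gene-set activity scoring.** Per-sample ssGSEA: genes are ranked by
expression within each sample and the enrichment score is the accumulated
difference between the weighted in-set cumulative fraction (weights
`|rank value|^alpha`, default `alpha = 0.25`) and the uniform out-of-set
fraction; NES divides all ES by the global range. Per-cell AUCell: the area
under the set-gene recovery curve within the top fraction (default 5%) of a
cell's expression ranking, normalized to [0, 1].

**Pathway-level survival framework.** Landmark-stratified 7:3 cohort
splitting (subjects followed to ~1/3/5 years represented in both arms);
univariate Cox screening per pathway with Benjamini–Hochberg FDR control;
bootstrap stability selection with an elastic-net Cox model (`l1_ratio` =
0.1, 1,000 resamples of 70% drawn with replacement, selection = non-zero
coefficient anywhere on a 50-point lambda path); a learner-benchmarking
harness (seeded random search, 5-fold CV on Harrell's C-index) with
concordance and IPCW time-dependent AUC metrics; Monte-Carlo Shapley
attribution of per-patient risk; Kaplan–Meier/log-rank stratification with
maximally selected cutpoints.

**Single-cell malignancy calling.** QC filtering (200–10,000 detected genes,
≤20% mitochondrial, ≤15% hemoglobin fraction, ≥50 cells per gene);
reference-anchored CNV profiles via a 100-gene sliding window over
genomically ordered, clamped residuals; per-cell CNV scores; robust-Z focal
gain/loss calls at driver genes (median/MAD, scale 1.4826, thresholds ±2);
silhouette-guided Leiden resolution selection over a 0.2–2.0 grid; and
tumor-like vs normal-like cluster labeling from CNV burden and driver-call
fractions.

**Co-expression modules.** WGCNA-style unsigned networks: soft threshold by
the scale-free topology criterion (R² ≥ 0.85), topological overlap,
average-linkage modules (minModuleSize 30, mergeCutHeight 0.25), eigengenes,
module–trait correlations, kME and gene significance.

**Prioritization.** Welch-t differential expression at single-cell
(q < 0.05, |log2FC| > 1) and bulk (q < 0.05, |log2FC| > 0.5) thresholds;
diffusion pseudotime from a root cell with Spearman trend tests; and the
four-set evidence intersection (module genes ∩ single-cell DE ∩ up in two
independent cohorts, optionally restricted to a gene catalog).

**Cell communication and motifs.** Permutation ligand–receptor scoring
(sender-ligand mean × receiver-receptor mean against a label-permutation
null, significant at p < 0.05 and ligand log2FC > 1); a composite
receptor-to-TF axis score (mean of min-max-scaled axis-gene expression);
strand-aware promoter extraction (−1 kb to +100 bp around the TSS); and PWM
motif scanning with exact p-values from a dynamic-programming null score
distribution (hits at p < 0.01).

## Worked example

Simulate a 200-patient bulk cohort in which two of fifty pathways carry a
log hazard ratio of 0.8 per unit activity, score pathways, and screen them:

```r
library(pathdriver)

cfg <- bulk_sim_config(n_samples = 200, n_genes = 500, n_pathways = 50,
                       genes_per_pathway = 10,
                       planted_pathways = c("1" = 0.8, "2" = 0.8), seed = 1)
sim <- simulate_bulk_cohort(cfg)

nes <- ssgsea_scores(sim$expr, sim$sets)
#> pathway_scores: 50 sets x 200 samples (alpha = 0.25)

scr <- univariate_cox_screen(nes, sim$surv)
#> screen_result: 2/50 features retained at FDR 0.05 (0 skipped)
head(scr$table, 4)
#>   feature       coef            p            q
#> 1     PW1  1.9737329 5.111477e-06 0.0002555738
#> 2     PW2  1.8539101 4.597404e-05 0.0011493511
#> 3    PW36 -1.1509389 1.257984e-02 0.2096639231
#> 4     PW3 -0.8849775 3.865978e-02 0.4164307588
```

Exactly the two planted pathways survive the FDR screen, with positive
log hazard ratios (the screen works on NES, so coefficients are per-NES-unit
and larger than the per-activity-unit plant). Splitting and benchmarking:

```r
landmark_stratified_split(sim$surv, seed = 1)
#> cohort_split: 140 train / 60 validation (ratio 0.70)

benchmark_models(nes, sim$surv, n_search = 8, seed = 1)
#> coxnet: CV C-index 0.613 (train C-index 0.725)
```

The cross-validated C-index of 0.613 reflects two informative pathways among
fifty noisy NES features; on the true latent activities it exceeds 0.75.

A command-line dispatcher over the same functions ships at
`inst/cli/pathdriver.R`
(`Rscript pathdriver.R simulate-bulk --out dir --seed 1`, plus `ssgsea`,
`aucell`, `screen`, `cnv`, `motif`, `intersect`, and other subcommands);
fixed-seed runs are byte-identical.

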