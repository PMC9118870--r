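# resteeg

Case–control analysis of resting-state EEG, built as a reusable R package
plus a numbered analysis workflow. It targets the study design common in
large multi-site autism cohorts: alternating eyes-open (EO) / eyes-closed
(EC) resting blocks, spectral power and functional connectivity features in
source space, mixed-effects group statistics with cluster-based permutation
correction, multivariate classification, and a train/validation replication
layer. Because raw recordings from such cohorts are access-restricted, the
package ships a first-class synthetic cohort generator that emulates the
data structure (1/f background, age-dependent alpha oscillators, lagged
pairwise coupling, site offsets, Table-style demographics), so every stage
is testable end to end.

## What it computes

**Summary alpha measures.** Welch spectra (2.5 s Hann windows, 75% overlap);
the EC occipital spectrum (O1, O2, Oz, PO3, PO4, POz) is fit as a Gaussian
peak over a power-law background, P(f) = a·f^(−b) + A·exp(−(f−f_p)²/2σ²),
with f_p ∈ [6, 13] Hz. Alpha power is the absolute power in
[f_p − 2, f_p + 2] Hz; reactivity to eye opening is R = 1 − P_EO/P_EC.

**Spectral and connectivity features.** Morlet wavelets with f/σ_f = 4.88 on
the 27-point grid f = 2^(1+0.15k) Hz, k = 0..26; relative power normalized
over the [2, 32] Hz grid. LCMV beamforming (5% regularization, common EO+EC
filter, max-power orientation) projects sensors onto a supplied leadfield;
sources are grouped into mirror-symmetric ROIs by k-means and summarized by
their first principal component. Connectivity per ROI pair and frequency:
wPLI = |E Im X| / E|Im X| with a bias-avoiding estimator (15 epochs drawn
100 times and averaged), orthogonalized power correlations, and the controls
PowCorr, COH, iCOH, PLV. Feature-count identities: 365 sources × 27
frequencies × 2 conditions = 19,710 power features; C(50,2) = 1225 links ×
27 × 2 = 66,150 connectivity features.

**Group statistics.** Three nested mixed models per feature
(y ~ 1 + age + sex + IQ + (1|site); + group and its interactions; + group-
specific residual variances), fit by direct likelihood maximization. The
mean test is the model-2-vs-1 likelihood ratio (χ², 4 df), the variance test
model 3 vs 2 (χ², 1 df), confirmed by REML F tests. Multiple comparisons
over link × frequency graphs are controlled by max-cluster permutation tests
(group labels shuffled, covariates kept).

**Classification and replication.** Features are residualized against
age/sex/IQ/site, reduced by PCA to 98% variance, and classified by linear
SVC, elastic-net logistic regression, or Boruta-selected RBF SVC, tuned by
nested CV maximizing the S1 score (harmonic mean of sensitivity and
specificity) over 15 stratified 80/20 splits, with label-permutation
significance. Replication tools: stratified 70/30 splits (site × age group ×
diagnosis), Fisher-z prediction intervals for correlations and their
standardized-mean-difference analogue, and analytic/simulated power.

## Worked example

The numbered scripts under `analysis/` run the whole study on a 40-subject
synthetic cohort with two injected effects: a group-by-age interaction on
reactivity (NT slope 0.014/yr vs ASD 0.002/yr) and one ASD-only
interhemispheric coupled source pair at 10 Hz:

```sh
Rscript analysis/01_simulate_cohort.R
Rscript analysis/02_preprocess_quality.R
Rscript analysis/03_alpha_metrics.R
Rscript analysis/04_source_connectivity.R
Rscript analysis/05_group_stats_clusters.R
Rscript analysis/06_classification_replication.R
```

Stage 3 prints (seed 1):

```
alpha peak frequency: age beta 0.737 (SE 0.053) Hz per SD of age
reactivity: mean-test p = 0.000, variance-test p = 0.000
group:age interaction: F = 11.94, p = 0.002 (injected: weaker ASD slope)
```

i.e. the generator's age-dependent alpha peak is recovered as a positive age
coefficient, and the injected interaction surfaces with the right sign.
Stage 5 prints the cluster table; with seed 1 the top cluster (35
link-frequency nodes, corrected p = 0.002) contains the injected link at
10 Hz and nothing else reaches significance. Stage 6 reports the PCA
dimension, classifier metrics with permutation p-values, the 28/12
stratified split, the replication prediction interval for r = 0.10 with
n = 183 → 212 ([−0.10, 0.29]) and the two-sample power 0.79 for d = 0.5 at
group sizes 65/59.

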