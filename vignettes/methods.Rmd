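---
title: "Models and methods behind resteeg"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and methods behind resteeg}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

This vignette explains the statistical models, signal-processing choices and
design decisions in `resteeg`, in the order a study would use them. The
package analyses case–control resting-state EEG: alternating 30 s
eyes-open/eyes-closed blocks totalling four minutes per subject, 61-channel
recordings, two diagnostic groups (ASD and neurotypical controls) spanning
ages 6–32 recruited at several sites, with age, sex, full-scale IQ (> 75 by
inclusion) and site as covariates.

## The synthetic cohort generator

Raw recordings from the cohorts this design describes are access-restricted,
so the generator is a first-class module, not a test fixture. It emulates
what the downstream statistics assume:

* **Background**: 1/f^χ noise per channel (spectrally shaped Gaussian noise
  via inverse FFT; flat below 1 Hz so the variance is finite), χ = 1 by
  default, RMS 10 µV. A log–log regression of the generated spectrum over
  2–32 Hz recovers χ within 0.1.
* **Alpha**: a narrowband oscillator — Gaussian spectral profile of 0.5 Hz
  SD, roughly 1 Hz bandwidth — at a subject-specific peak frequency
  f_p(age) = 8 + 0.1(age − 6) Hz capped at 11 Hz plus 0.3 Hz of
  between-subject jitter. Narrowband *noise* rather than a sine is essential:
  envelope correlations are otherwise undefined. Occipital channels carry the
  full alpha amplitude, all others a quarter of it.
* **Reactivity**: each subject receives a target
  R = 0.5 + slope_group · (age − 19) ± 0.08, and the eyes-open alpha power is
  set so that the *measured* occipital band power realizes that target — the
  background power inside [f_p − 2, f_p + 2] is compensated analytically, and
  the alpha series is rescaled to its exact per-condition RMS because the
  sample variance of a 1 Hz-wide process fluctuates by ~10 % over 2-minute
  stretches, which would otherwise dominate the injection error. Measured
  reactivity matches the target at the Monte-Carlo error scale of a 2-minute
  estimate (mean |error| < 0.04).
* **Coupling**: each coupling-plan entry adds a shared narrowband oscillator
  to two nodes with a fixed phase lag in (−π, π] and a chosen envelope
  correlation (the second node mixes the shared and an independent process).
  A noiseless pair at lag π/2 yields wPLI ≈ 1 by construction.
* **Group and site effects**: a standardized mean shift d and a residual-SD
  ratio act on log eyes-closed alpha power (between-subject SD 0.5 log
  units); site offsets are additive on log power. Demographics follow the
  study margins: age uniform on [6, 32], ~72 % male, IQ ~ N(106, 14²)
  truncated at 75, medication 37 %/6 % by group.
* **Source mode**: given a leadfield, the same construction happens at
  source level and sensors observe `gain %*% sources` plus 10 % sensor
  noise, so beamforming has something real to invert. The synthetic
  leadfield uses homogeneous-conductor dipole gains, sensors on a 95 mm
  upper hemisphere, and a mirror-symmetric diamond-style grid with 1.5 cm
  spacing; when fewer sources than grid points are requested the selection
  is spread over all depths (a center-out fill would put every source deep,
  where beamformers resolve worst).

All randomness flows from one master seed through `substream_seed()`, so
cohorts are bit-reproducible and per-subject streams independent.

What the generator does *not* emulate: ocular/muscle artifacts, realistic
volume conduction (no FEM head model), inter-channel background correlation
beyond the explicit coupling plan, and non-stationarities other than the
block structure. Passing tests therefore demonstrate correctness of the
*pipeline*, not robustness to artifactual real-world data.

## Preprocessing

The band-pass filter is an order-2000 Hamming-window FIR with a [1, 32] Hz
passband (at 1000 Hz sampling; the demo uses order 500 at 250 Hz, the same
2 s impulse-response span). It is applied per resting-state block with 2 s of
padding on each side — neighboring recording samples where available, mirror
reflection at the edges — and realized zero-phase by compensating the
linear-phase group delay. Zero phase matters: a condition-dependent phase
shift would bias every phase-sensitive connectivity metric. Resampling is
Fourier-domain (spectrum truncation/extension), which preserves passband
amplitude essentially exactly. Epochs of 2.5 s are tiled from each block
start; a tail shorter than one epoch is dropped, and epochs touching an
artifact-mask interval are skipped. The average reference zeroes the
instantaneous channel mean and is idempotent.

Subject inclusion mirrors the three rules used with such cohorts: at least
15 clean 2.5 s epochs per condition; at least 51 usable channels of 61 and
no more than 3 *neighboring* channels eliminated (implemented as the largest
connected component of bad channels in the channel adjacency graph — the
rule's wording does not say contiguous run, and the component reading is the
conservative one); and good channels minus removed independent components at
least 35. ICA itself is a manual step and out of scope; the component count
enters as an input so the rule stays checkable.

## Spectra

Welch spectra use 2.5 s Hann windows with 75 % overlap (0.4 Hz resolution),
scaled as one-sided densities so that white noise of unit variance
integrates to 1 (Parseval) and a sine of amplitude a carries a²/2.

The Morlet grid is 2^(1+0.15k) Hz for k = 0..26 — 27 frequencies, the only
endpoint reading consistent with the 19,710 = 365·27·2 and 66,150 = 1225·27·2
feature counts. Wavelets have σ_f = f/4.88, σ_t = 1/(2πσ_f), a 5σ_t window,
and 90 % overlap between windows *of the full 5σ_t length* (the open
alternative — overlap of σ_t — would give ten times fewer samples).
Coefficients are normalized so a unit-amplitude sinusoid at center frequency
gives |coeff|² = 0.5; windows that would cross an epoch edge are dropped
rather than padded. At 2 Hz the wavelet spans 1.94 s and still fits a 2.5 s
epoch. Relative power divides by the plain sum over the 27 grid points
(`weights = "uniform"`), the simplest reading of normalizing by overall
power on a fixed grid; trapezoidal integration is available as a switch.

## Alpha-peak fitting

The occipital eyes-closed spectrum over [2, 20] Hz is fit in the *log-power*
domain (least squares on log P equalizes the huge dynamic range of 1/f
backgrounds) with f_p bounded to [6, 13] Hz and multiple starts. A peak is
accepted only if the optimizer converged, the Gaussian amplitude exceeds
10 % of the background at the peak (config-exposed), and f_p is not pinned
at a range boundary — the optimizer parks the Gaussian at an edge when no
real peak exists. Subjects without an acceptable peak are flagged rather
than given a value, and a manual-override table (subject → f_p) substitutes
for the visual refinement step used in practice. One peak per subject serves
both conditions; band power integrates the PSD trapezoidally over
[f_p − 2, f_p + 2].

The fourth-power normality transform conventionally applied to reactivity
destroys sign information for negative R (alpha increasing with eye
opening). It is applied as specified, with a warning; this is a documented
hazard of the convention, not of the implementation.

## Source reconstruction

The LCMV beamformer uses C_reg = C + 0.05·(tr C/n)·I with one covariance
pooled over both conditions (a *common filter*, so condition contrasts are
not confounded by filter differences). Per source, the orientation is the
dominant eigenvector of (LᵀC_reg⁻¹L)⁻¹ — the max-power convention — and the
final filter satisfies wᵀLθ = 1 exactly. ROI definition clusters one
hemisphere's positions by k-means and mirrors the labels, which is our
construction for "symmetric ROIs" (the mechanism is not otherwise
specified); midline sources join the nearest right-hemisphere ROI that has
room. A greedy repair moves boundary sources so ROI sizes stay within the
4–13 range the 365-source grid should produce. ROI time series are first
principal components with the sign fixed by positive correlation with the
mean member series — PCA signs are otherwise arbitrary and would break
reproducibility.

## Connectivity

All metrics are computed from pooled epoch × window wavelet coefficient
samples per condition. wPLI is the unsigned version |E Im X|/E|Im X| (range
[0, 1]; the x^0.11 normality transform downstream presumes non-negative
values), with the convention that an identically-zero imaginary part gives
0. Because the plain estimator's positive bias depends on the number of
samples, between-subject comparability requires the subsampled estimator:
wPLI on 15 randomly drawn epochs, repeated 100 times and averaged. Its mean
is invariant to how many epochs a subject has; the naive estimator's is not
— both facts are asserted by simulation in the tests.

Orthogonalized power correlation removes the instantaneous (zero-lag,
volume-conducted) component of one signal relative to the other per sample,
then correlates *log* power envelopes, averaged over both directions.
Self-orthogonalization is identically zero; a degenerate (identical-signal)
pair returns 0 with a flag rather than a missing value so tensors stay
dense. Whether to pool windows across epochs or correlate within epochs and
average was open; pooling is implemented (it is the higher-powered choice
for short epochs) and the within-epoch route can be added behind the same
surface. The robustness contrast — wPLI/iCOH unmoved by an added common
zero-lag signal while COH/PLV inflate — holds at the null level in
expectation and is asserted on a constructed triple; only the
identical-channel case makes wPLI zero *exactly*.

## Group statistics

The three models per feature are

* model 1: y ~ 1 + age + sex + IQ + (1|site), homoscedastic;
* model 2: + group + group:age + group:sex + group:IQ, homoscedastic;
* model 3: model 2 with residual SD σ·δ^{[group=ASD]}.

Age and IQ are standardized, sex coded M = 0, group NT = 0. The likelihood
is implemented directly rather than delegated because group-specific
residual variances plus a site random intercept must live in one
optimizable framework: per site block the covariance is D + τ·11ᵀ
(Woodbury rank-one solves), σ² is profiled out, and the remaining one or
two parameters (log τ, log δ) are maximized by L-BFGS-B from five starts.
The implementation reproduces the reference mixed-model package's ML and
REML log-likelihoods, coefficients and standard errors to 1e−6 (asserted in
the tests), and a closed-form GLS oracle at fixed variance components to
1e−6 in β.

The mean test compares models 2 vs 1 (χ², 4 df), the variance test 3 vs 2
(χ², 1 df); both are mildly anticonservative as likelihood-ratio tests, so
REML F tests on the individual group coefficients are reported as
confirmation, with between-within denominator degrees of freedom
n − n_sites − (p − 1), the convention of the reference package. Transform
selection standardizes each candidate-transformed sample and picks the
largest Kolmogorov–Smirnov p against the standard normal; the canonical
per-family choices (log for absolute power, x⁴ for reactivity, atanh for
orthogonalized power correlations, x^0.11 for wPLI) are built in.

## Cluster-based permutation correction

Features form a graph: frequency neighbors are consecutive grid points;
spatial neighbors are adjacent sources, or — for connectivity — links
sharing one ROI whose other two ROIs are adjacent (ROIs are adjacent when
any cross pair of member sources is within 1.5 grid spacings). Clusters are
connected components of nodes with uncorrected p < 0.05; inference compares
observed cluster sizes against the permutation distribution of the maximal
cluster under group-label shuffles that keep covariates with their
subjects. Per-node tests are unsigned (the likelihood-ratio p carries no
direction), so clustering is unsigned.

Two numerical choices deserve emphasis. First, the corrected p-value: the
literal rule "proportion of randomizations with a strictly larger cluster"
is measurably anticonservative on desk-scale graphs — integer cluster sizes
tie heavily, and the strict inequality turns every tie into evidence; we
measured family-wise error 0.10 at nominal 0.05 (405-node graph, 400 null
cohorts). Counting ties as exceedances with the +1 correction instead
over-corrects (0.02 band floor missed at 0.01). The default therefore
compares clusters lexicographically by (size, summed −log p mass) — the
mass term only breaks integer ties — with the exact Monte-Carlo formula
p = (1 + #{null > observed})/(n_perm + 1); measured family-wise error 0.04.
The literal rule remains available (`p_rule = "strict"`) for matching the
printed definition on large graphs, where the discrepancy vanishes.

Second, the permutation engine: refitting three mixed models per node per
permutation is prohibitively slow, so the default engine inside the loop
uses whitened least squares with site as fixed effects — an F test for the
mean contrast and a Bartlett-corrected two-group variance test on full-model
residuals. On large samples it agrees with the mixed-model p-values where
thresholding happens (below p ≈ 0.15, within 0.015; asserted in tests), and
permutation inference is valid for any fixed statistic regardless. The full
mixed-model engine (`engine = "lme"`) remains available for small graphs.

## Classification

Residualization subtracts each feature's model-1 fixed effects and the
site-intercept BLUP. PCA keeps the smallest number of components reaching
98 % cumulative variance. Three classifiers are provided: L2 linear SVC,
elastic-net logistic regression, and an RBF SVC preceded by a Boruta-style
shadow-feature selection (random-forest importances against column-shuffled
shadows, binomial confirmation over 50 iterations, 100-tree forests).
Because the exact hyperparameter grids of the original analysis are not
public, the defaults are standard log-spaced ranges (linear C ∈ 10^{−3..2};
elastic-net inverse regularization 10^{−3..2} × l1 ratio {0.1, 0.5, 0.9};
RBF C ∈ 10^{−1..2} with a median-heuristic kernel width scaled by
{0.5, 1, 2}), overridable per call. Tuning maximizes S1 in stratified
10-fold inner CV; evaluation uses 15 stratified 80/20 splits and unweighted
mean rates; significance is the proportion of label-randomized runs with S1
at least as large.

The default "replicate" mode residualizes and reduces on the full sample
before splitting, matching the original pipeline's order of operations; the
"strict" mode refits residualization and PCA inside every training part and
projects held-out subjects through them. The two answer different
questions — pipeline reproduction versus leakage-free estimation — and the
mode is recorded in the report.

## Replication statistics

Stratified 70/30 splits randomize within site × age group (children 6–11,
adolescents 12–17, adults 18+) × diagnosis cells, rounding the training
share per cell; singleton cells go to training with a warning. The
correlation prediction interval is Fisher-z based,
tanh(atanh r ± z·√(1/(n₁−3) + 1/(n₂−3))), with the normal quantile — this
choice reproduces the printed −0.10 lower bound for r = 0.10 at
n = 183 → 212, while the printed upper bound (0.30) is 0.29 here under
every variant tried; the discrepancy is a rounding we cannot reproduce and
is documented rather than fudged. The standardized-mean-difference interval
uses v = (n₁+n₂)/(n₁n₂) + d²/(2(n₁+n₂)) per study. Analytic two-sample
power uses the noncentral t (checked against a 20,000-replicate Monte-Carlo
oracle); simulation-based power for the mixed-model mean test runs the
feature-level generator through the full test. The power figures printed in
the original analysis came from unavailable supplementary procedures; ours
operationalize the same questions and are not claimed to reproduce those
numbers.

## Problem sizes

The test-suite and demo sizes are the package's own choices: a 40-subject
cohort on a 32-sensor/60-source/10-ROI head (1215 link-frequency nodes, 500
permutations, 20 wPLI repetitions); calibration suites use 400 null cohorts
at n = 60 with 200 permutations, 2000 variance-test null simulations at
n = 200, and 200 recovery replicates at n = 400. The full-scale geometry
(61 sensors, 365 sources, 50 ROIs) is exercised where it is cheap: grid and
ROI construction, and the feature-count identities.

## Known limitations

* No artifact simulation and no ICA: the preprocessing quality rules are
  exercised with clean synthetic data and user-supplied component counts.
* The synthetic leadfield is a homogeneous-conductor approximation; the
  age-dependent skull-conductivity formula is implemented for completeness
  but no FEM forward solve consumes it.
* Negative reactivity values lose their sign under the x⁴ transform, as in
  the convention followed.
* EDF+/BrainVision ingestion is not implemented (no suitable reader in the
  dependency set); recordings are exchanged as TSV + JSON sidecar, and the
  container API is format-agnostic.
* The classification harness reproduces the *procedure*; with the demo's
  deliberately strong injected coupling it saturates, which is a property of
  the demo conditions, not a performance claim about real data.
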