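Package: resteeg
Title: Resting-State EEG Spectral Power and Connectivity Case-Control Analysis
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: A tested re-implementation of a cross-sectional resting-state EEG
    case-control analysis pipeline: synthetic cohort generation (1/f background,
    age-dependent alpha oscillators, lagged coupling, site and group effects),
    deterministic preprocessing with subject-inclusion bookkeeping, Welch and
    Morlet spectral estimation, alpha-peak metrics (peak frequency, band power,
    reactivity to eye opening), LCMV beamformer source projection with k-means
    region definition, six spectral connectivity metrics including a
    subsampled weighted phase lag index estimator and orthogonalized power
    correlations, heteroscedastic linear mixed-effects mean and variance group
    tests with cluster-based permutation correction over link-frequency graphs,
    a multivariate classification harness with residualization, PCA and
    label-permutation significance, and train/validation replication statistics
    (stratified splits, effect-size prediction intervals, power).
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    signal,
    e1071,
    glmnet,
    ranger,
    jsonlite,
    yaml
Suggests:
    nlme,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
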