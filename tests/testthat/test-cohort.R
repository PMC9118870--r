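test_that("cohort spec validates its parameters", {
  expect_error(cohort_spec(effect_variance_ratio = 0), "positive")
  cp <- data.frame(node_i = "C3", node_j = "C4", freq = 10, lag = 3 * pi / 2,
                   env_corr = 0.5, strength_asd = 1, strength_nt = 1)
  expect_error(cohort_spec(coupling_plan = cp), "lag")
})

test_that("subject metadata respects inclusion rules and site coverage", {
  spec <- cohort_spec(n_per_group = 30, seed = 5)
  meta <- generate_subject_meta(spec)
  expect_equal(nrow(meta), 60)
  expect_true(all(meta$age >= 6 & meta$age <= 32))
  expect_true(all(meta$iq > 75))
  expect_true(all(table(meta$site, meta$group) >= 1))
  # deterministic given seed
  expect_identical(meta, generate_subject_meta(spec))
})

test_that("recordings are deterministic given the seed", {
  spec <- cohort_spec(n_per_group = 3, seed = 11, n_blocks = 2)
  meta <- generate_subject_meta(spec)
  r1 <- generate_recording(meta[1, ], spec, 1)
  r2 <- generate_recording(meta[1, ], spec, 1)
  expect_identical(r1$data, r2$data)
  r3 <- generate_recording(meta[1, ], spec, 2)
  expect_false(identical(r1$data, r3$data))
})

test_that("background spectral slope matches the requested exponent", {
  for (chi in c(0.8, 1, 1.4)) {
    set.seed(31)
    bg <- resteeg:::gen_background(1, 60000, fs_test, chi, 10)
    ep <- epoch_set(array(bg[1, ], c(1, 625, 96)), rep("EO", 96), fs_test, "x")
    ps <- welch_psd(ep)
    sel <- ps$freqs >= 2 & ps$freqs <= 32
    slope <- -coef(lm(log(ps$power[1, sel]) ~ log(ps$freqs[sel])))[[2]]
    expect_equal(slope, chi, tolerance = 0.1)
  }
})

test_that("measured reactivity tracks the injected target across subjects", {
  spec <- cohort_spec(n_per_group = 4, seed = 13)
  meta <- generate_subject_meta(spec)
  err <- vapply(1:4, function(i) {
    rec <- generate_recording(meta[i, ], spec, i)
    al <- alpha_summary(epoch_recording(rec))
    al$R - attr(rec, "target_reactivity")
  }, numeric(1))
  # agreement at the Monte-Carlo error scale of a 2-minute estimate
  expect_lt(mean(abs(err)), 0.04)
  expect_lt(max(abs(err)), 0.06)
})

test_that("a coupled pair at lag pi/2 yields near-unit wPLI, others near zero", {
  cp <- data.frame(node_i = "C3", node_j = "C4", freq = 10, lag = pi / 2,
                   env_corr = 0.8, strength_asd = 60, strength_nt = 60)
  spec <- cohort_spec(n_per_group = 3, seed = 7, coupling_plan = cp,
                      bg_sd = 1, n_blocks = 4)
  meta <- generate_subject_meta(spec)
  rec <- generate_recording(meta[1, ], spec, 1)
  ep <- subset_epochs(epoch_recording(rec), "EO")
  keep <- match(c("C3", "C4", "Fp1", "F3"), MONTAGE_61)
  ep_small <- epoch_set(ep$data[keep, , , drop = FALSE], ep$condition,
                        ep$srate, MONTAGE_61[keep])
  wc <- morlet_transform(ep_small)
  fi <- which.min(abs(wc$freqs - 10))
  x_cpl <- cross_spectra(wc$coeffs[[fi]][1, ], wc$coeffs[[fi]][2, ])
  x_unc <- cross_spectra(wc$coeffs[[fi]][3, ], wc$coeffs[[fi]][4, ])
  expect_gt(wpli(x_cpl), 0.9)
  expect_lt(wpli(x_unc), 0.35)
  # lag direction is encoded in the mean cross-spectrum phase
  expect_equal(Arg(mean(x_cpl)), pi / 2, tolerance = 0.3)
})

test_that("injected group mean shift is recovered by the group tests", {
  # 95% CI of the group coefficient covers the injected d in most cohorts
  meta <- make_meta(60, seed = 3)
  hits <- vapply(1:60, function(b) {
    tab <- simulate_feature_table(meta, d = 0.5, beta = c(age = 0, sex = 0, iq = 0),
                                  site_sd = 0.2, seed = 100 + b)
    f2 <- fit_lme(prepare_feature_table(tab), 2, "REML")
    abs(f2$beta[["group"]] - 0.5) < 1.96 * f2$se[["group"]]
  }, logical(1))
  expect_gte(mean(hits), 0.85)
})

test_that("synthetic leadfield has the documented geometry and determinism", {
  lf <- generate_leadfield(61, 365, seed = 3)
  expect_equal(dim(lf$gain), c(61, 365, 3))
  expect_equal(nrow(lf$positions), 365)
  # mirror symmetry about x = 0
  key <- function(p) paste(round(p[, 1], 3), round(p[, 2], 3), round(p[, 3], 3))
  mirrored <- lf$positions
  mirrored[, 1] <- -mirrored[, 1]
  expect_true(all(key(mirrored) %in% key(lf$positions)))
  # determinism and shape for the minimal case
  lf2 <- generate_leadfield(3, 1, seed = 9)
  expect_equal(dim(lf2$gain), c(3, 1, 3))
  expect_identical(generate_leadfield(3, 1, seed = 9)$gain, lf2$gain)
  expect_error(generate_leadfield(2, 1), "n_sensors")
})

test_that("cohort spec round-trips through YAML", {
  cp <- data.frame(node_i = 3, node_j = 9, freq = 10, lag = pi / 2,
                   env_corr = 0.5, strength_asd = 60, strength_nt = 0)
  spec <- cohort_spec(n_per_group = 5, coupling_plan = cp, seed = 4)
  path <- tempfile(fileext = ".yaml")
  write_cohort_spec_yaml(spec, path)
  spec2 <- read_cohort_spec_yaml(path)
  expect_equal(spec2$n_per_group, spec$n_per_group)
  expect_equal(spec2$coupling_plan$lag, spec$coupling_plan$lag)
  expect_equal(spec2$site_offsets, spec$site_offsets)
  meta1 <- generate_subject_meta(spec)
  expect_identical(generate_subject_meta(spec2), meta1)
})

test_that("recordings round-trip through the TSV writer", {
  spec <- cohort_spec(n_per_group = 3, seed = 2, n_blocks = 2,
                      channels = c("O1", "O2", "Oz", "PO3", "PO4", "POz"))
  meta <- generate_subject_meta(spec)
  rec <- generate_recording(meta[1, ], spec, 1)
  path <- tempfile(fileext = ".tsv")
  write_recording_tsv(rec, path)
  rec2 <- read_recording_tsv(path)
  expect_equal(rec2$srate, rec$srate)
  expect_equal(rec2$channels, rec$channels)
  expect_equal(rec2$blocks$condition, rec$blocks$condition)
  expect_equal(rec2$data, rec$data, tolerance = 1e-6)
})
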