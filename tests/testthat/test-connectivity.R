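make_pair <- function(n, kind = c("lag90", "identical", "independent"),
                      seed = 1) {
  set.seed(seed)
  z <- complex(real = rnorm(n), imaginary = rnorm(n))
  switch(match.arg(kind),
         lag90 = list(a = z, b = z * exp(-1i * pi / 2)),
         identical = list(a = z, b = z),
         independent = list(a = z, b = complex(real = rnorm(n),
                                               imaginary = rnorm(n))))
}

test_that("cross-spectra have the conjugate symmetry and encode lags", {
  p <- make_pair(500, "lag90")
  x <- cross_spectra(p$a, p$b)
  expect_equal(cross_spectra(p$b, p$a), Conj(x))
  expect_true(all(Im(cross_spectra(p$a, p$a)) == 0))
  expect_equal(Arg(mean(x)), pi / 2, tolerance = 1e-9)
})

test_that("wPLI closed-form cases: unit at pure lag, zero at zero lag", {
  p <- make_pair(1000, "lag90")
  expect_equal(wpli(cross_spectra(p$a, p$b)), 1)
  q <- make_pair(1000, "identical")
  expect_equal(wpli(cross_spectra(q$a, q$b)), 0)
  r <- make_pair(1000, "independent")
  expect_lt(wpli(cross_spectra(r$a, r$b)), 0.1)
})

test_that("subsampled wPLI is unbiased across epoch counts; naive is not", {
  # under independence the fixed-15-epoch estimator has the same mean whether
  # 15 or 60 epochs are available, while the naive all-epoch wPLI shrinks
  n_win <- 10
  runs <- 120
  est <- function(n_ep, b, fixed) {
    set.seed(4000 + b)
    x <- complex(real = rnorm(n_ep * n_win), imaginary = rnorm(n_ep * n_win)) *
      Conj(complex(real = rnorm(n_ep * n_win), imaginary = rnorm(n_ep * n_win)))
    ep <- rep(seq_len(n_ep), each = n_win)
    if (fixed) wpli_subsampled(x, ep, 15, 30, seed = b) else wpli(x)
  }
  m15 <- mean(vapply(1:runs, function(b) est(15, b, TRUE), 1))
  m60 <- mean(vapply(1:runs, function(b) est(60, runs + b, TRUE), 1))
  naive15 <- mean(vapply(1:runs, function(b) est(15, 2 * runs + b, FALSE), 1))
  naive60 <- mean(vapply(1:runs, function(b) est(60, 3 * runs + b, FALSE), 1))
  expect_lt(abs(m15 - m60), 0.02)
  expect_gt(naive15 - naive60, 0.03)
  # exactly 15 epochs available: every draw is the full set
  set.seed(1)
  x <- complex(real = rnorm(150), imaginary = rnorm(150))
  ep <- rep(1:15, each = 10)
  expect_equal(wpli_subsampled(x, ep, 15, 5, seed = 2), wpli(x))
  expect_error(wpli_subsampled(x[1:100], ep[1:100], 15, 5), "epochs")
  # deterministic given seed
  expect_identical(wpli_subsampled(x, ep, 10, 20, seed = 3),
                   wpli_subsampled(x, ep, 10, 20, seed = 3))
})

test_that("orthogonalized power correlation nulls and monotonicity", {
  p <- make_pair(2000, "identical")
  expect_equal(as.numeric(orth_pow_corr(p$a, p$b)), 0)
  r <- make_pair(2000, "independent", seed = 2)
  expect_lt(abs(orth_pow_corr(r$a, r$b)), 0.1)
  # shared envelopes with independent phases: positive and increasing
  set.seed(3)
  n <- 3000
  vals <- vapply(c(0.2, 0.5, 0.8), function(rho) {
    le1 <- rnorm(n)
    le2 <- rho * le1 + sqrt(1 - rho^2) * rnorm(n)
    a <- exp(le1 / 2) * exp(1i * runif(n, 0, 2 * pi))
    b <- exp(le2 / 2) * exp(1i * runif(n, 0, 2 * pi))
    orth_pow_corr(a, b)
  }, numeric(1))
  expect_true(all(vals > 0))
  expect_true(all(diff(vals) > 0))
})

test_that("control metrics match closed forms and independence nulls", {
  q <- make_pair(2000, "identical")
  cm <- control_metrics(q$a, q$b)
  expect_equal(unname(cm[c("COH", "PLV")]), c(1, 1))
  expect_equal(unname(cm["iCOH"]), 0)
  p <- make_pair(2000, "lag90")
  cm90 <- control_metrics(p$a, p$b)
  expect_equal(unname(cm90["iCOH"]), unname(cm90["COH"]))
  r <- make_pair(2000, "independent", seed = 5)
  cmr <- control_metrics(r$a, r$b)
  expect_lt(max(abs(cmr[c("COH", "iCOH", "PLV")])), 0.1)
  expect_lt(abs(cmr["PowCorr"]), 0.1)
  expect_error(control_metrics(q$a * 0, q$b), "zero-power")
})

test_that("volume-conduction robustness on a constructed triple", {
  set.seed(6)
  n <- 4000
  a0 <- complex(real = rnorm(n), imaginary = rnorm(n))
  b0 <- complex(real = rnorm(n), imaginary = rnorm(n))
  common <- complex(real = rnorm(n), imaginary = rnorm(n))
  lam <- 3
  a <- a0 + lam * common
  b <- b0 + lam * common
  # wPLI and iCOH stay at their null level; COH and PLV inflate
  expect_lt(wpli(cross_spectra(a, b)), 0.1)
  cm <- control_metrics(a, b)
  expect_lt(abs(cm[["iCOH"]]), 0.1)
  expect_gt(cm[["COH"]], 0.5)
  expect_gt(cm[["PLV"]], 0.5)
  # identical channels plus common signal: wPLI exactly zero
  expect_equal(wpli(cross_spectra(a0 + common, a0 + common)), 0)
})

test_that("fc tensor is symmetric in construction and counts links", {
  expect_equal(nrow(link_table(50)), 1225)
  expect_equal(1225 * 27 * 2, 66150)
  ep <- make_noise_epochs(n_ch = 4, n_ep = 16, seed = 7)
  wc <- morlet_transform(ep)
  fc <- fc_tensor(wc, metrics = c("wPLI", "orthPowCorr", "COH"),
                  wpli_epochs = 8, wpli_reps = 5, seed = 2)
  expect_equal(dim(fc$values), c(6, 27, 2, 3))
  expect_true(all(fc$values[, , , "wPLI"] >= 0 & fc$values[, , , "wPLI"] <= 1))
  expect_true(all(fc$values[, , , "COH"] >= 0 & fc$values[, , , "COH"] <= 1))
  expect_true(all(abs(fc$values[, , , "orthPowCorr"]) <= 1))
})
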