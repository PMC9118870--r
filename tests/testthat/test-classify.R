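test_that("residualization removes covariate structure", {
  meta <- make_meta(60, seed = 30)
  set.seed(31)
  feats <- cbind(2 * scale(meta$age) + rnorm(120, 0, 0.5),  # age-driven
                 rnorm(120),                                 # independent
                 rep(1, 120))                                # constant
  res <- residualize(feats, meta)
  expect_lt(abs(cor(res$matrix[, 1], meta$age)), 0.05)
  expect_lt(abs(cor(res$matrix[, 1], meta$iq)), 0.1)
  # independent feature: residual is close to the centered feature
  expect_gt(cor(res$matrix[, 2], feats[, 2] - mean(feats[, 2])), 0.95)
  # constant feature: all-zero residuals
  expect_true(all(res$matrix[, 3] == 0))
})

test_that("PCA reduction respects rank and the variance accounting identity", {
  set.seed(32)
  # rank-2 data
  u <- matrix(rnorm(40 * 2), 40)
  x <- u %*% matrix(rnorm(2 * 30), 2)
  pc <- pca_reduce(x, 0.98)
  expect_lte(pc$k, 2)
  pc_full <- pca_reduce(x, 1)
  expect_equal(pc_full$k, qr(scale(x, scale = FALSE))$rank)
  # isotropic 10-dim Gaussian: k = 10 needed for 98%
  z <- matrix(rnorm(500 * 10), 500)
  expect_equal(pca_reduce(z, 0.98)$k, 10)
  # reconstruction captures >= the requested variance fraction
  xc <- sweep(x, 2, pc$center)
  recon <- pc$scores %*% t(pc$loadings)
  frac <- 1 - sum((xc - recon)^2) / sum(xc^2)
  expect_gte(frac, 0.98)
})

test_that("S1 score is the harmonic mean with its boundary conventions", {
  expect_equal(s1_score(0.5, 0.5), 0.5)
  expect_equal(round(s1_score(0.55, 0.59), 2), 0.57)
  expect_equal(s1_score(0, 0.9), 0)
  expect_equal(s1_score(0, 0), 0)
  # harmonic <= arithmetic, equality iff equal rates
  for (p in list(c(0.3, 0.9), c(0.7, 0.7), c(0.1, 0.2))) {
    expect_lte(s1_score(p[1], p[2]), mean(p) + 1e-12)
    if (p[1] == p[2]) expect_equal(s1_score(p[1], p[2]), mean(p))
  }
})

test_that("classifiers separate separable data and hover at chance on noise", {
  set.seed(33)
  n <- 60
  x <- rbind(matrix(rnorm(n / 2 * 4, 3), ncol = 4),
             matrix(rnorm(n / 2 * 4, -3), ncol = 4))
  ylab <- rep(c(1, 0), each = n / 2)
  for (mid in c("linsvc", "enet")) {
    rep_ <- evaluate_models(x, ylab, mid, n_splits = 5,
                            grid = default_grids()[[mid]][
                              default_grids()[[mid]]$C == 1, , drop = FALSE],
                            seed = 34)
    expect_gte(rep_$aggregated[["acc"]], 0.95)
  }
  # null data: accuracy near chance
  xn <- matrix(rnorm(80 * 5), 80)
  yn <- rep(c(1, 0), 40)
  rep_n <- evaluate_models(xn, yn, "linsvc", n_splits = 8,
                           grid = data.frame(C = 1), seed = 35)
  expect_gte(rep_n$aggregated[["acc"]], 0.3)
  expect_lte(rep_n$aggregated[["acc"]], 0.7)
  # deterministic given seed
  rep_n2 <- evaluate_models(xn, yn, "linsvc", n_splits = 8,
                            grid = data.frame(C = 1), seed = 35)
  expect_identical(rep_n$aggregated, rep_n2$aggregated)
})

test_that("boruta-style selection finds informative features", {
  set.seed(36)
  n <- 80
  x <- matrix(rnorm(n * 10), n)
  ylab <- rep(c(0, 1), each = n / 2)
  x[, 3] <- x[, 3] + 1.5 * ylab
  x[, 7] <- x[, 7] - 1.5 * ylab
  sel <- boruta_select(x, ylab, n_iter = 25, n_trees = 60, seed = 37)
  expect_true(all(c(3, 7) %in% sel))
  expect_lte(length(sel), 6)
})

test_that("rbf classifier with boruta selection learns a nonlinear boundary", {
  set.seed(38)
  n <- 80
  x <- matrix(rnorm(n * 4), n)
  ylab <- as.integer(x[, 1]^2 + x[, 2]^2 > 2)  # ring structure
  rep_ <- evaluate_models(x, ylab, "boruta_rbf", n_splits = 3,
                          grid = data.frame(C = 10, gamma_mult = 1),
                          seed = 39)
  expect_gte(rep_$aggregated[["acc"]], 0.7)
})

test_that("label permutation p is small for signal, moderate for noise", {
  set.seed(40)
  n <- 60
  x <- rbind(matrix(rnorm(n / 2 * 3, 2), ncol = 3),
             matrix(rnorm(n / 2 * 3, -2), ncol = 3))
  ylab <- rep(c(1, 0), each = n / 2)
  ps <- permutation_significance(x, ylab, "linsvc", n_perm = 39,
                                 n_splits = 3, grid = data.frame(C = 1),
                                 seed = 41)
  expect_lte(ps$p, 1 / 39)
  xn <- matrix(rnorm(n * 3), n)
  psn <- permutation_significance(xn, ylab, "linsvc", n_perm = 39,
                                  n_splits = 3, grid = data.frame(C = 1),
                                  seed = 42)
  expect_gte(psn$p, 0.05)
})

test_that("strict mode refits preprocessing inside splits and stays near chance on null data", {
  meta <- make_meta(30, seed = 43)
  set.seed(44)
  feats <- matrix(rnorm(60 * 12), 60)
  rep_s <- classify_features(feats, meta, "linsvc", mode = "strict",
                             n_splits = 4, grid = data.frame(C = 1),
                             seed = 45)
  expect_equal(rep_s$mode, "strict")
  expect_gte(rep_s$aggregated[["acc"]], 0.25)
  expect_lte(rep_s$aggregated[["acc"]], 0.75)
})
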