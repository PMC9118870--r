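test_that("model fits agree with a closed-form GLS oracle at fixed variances", {
  meta <- make_meta(50, seed = 2)
  tab <- prepare_feature_table(
    simulate_feature_table(meta, d = 0.3, seed = 3))
  f <- fit_lme(tab, 2, "ML")
  # GLS at the fitted variance components must reproduce beta exactly
  x <- resteeg:::lme_design(tab, 2)
  z <- model.matrix(~ 0 + site, tab)
  v <- f$sigma2 * diag(nrow(tab)) + f$sigma_site2 * tcrossprod(z)
  vinv <- solve(v)
  beta_gls <- solve(crossprod(x, vinv %*% x), crossprod(x, vinv %*% tab$y))
  expect_equal(unname(f$beta), unname(drop(beta_gls)), tolerance = 1e-6)
})

test_that("fits agree with the reference mixed-model implementation", {
  skip_if_not_installed("nlme")
  meta <- make_meta(100, seed = 2)
  tab <- prepare_feature_table(
    simulate_feature_table(meta, d = 0.5, variance_ratio = 1.3, seed = 11))
  f3 <- fit_lme(tab, 3, "ML")
  m3 <- nlme::lme(y ~ age_s + sex01 + iq_s + asd + asd:age_s + asd:sex01 +
                    asd:iq_s,
                  random = ~ 1 | site, data = tab, method = "ML",
                  weights = nlme::varIdent(form = ~ 1 | asd))
  expect_equal(f3$loglik, as.numeric(stats::logLik(m3)), tolerance = 1e-6)
  expect_equal(unname(f3$beta), unname(nlme::fixef(m3)), tolerance = 1e-5)
  # nlme parameterizes the ratio relative to the first group's stratum
  delta_ref <- unname(stats::coef(m3$modelStruct$varStruct,
                                  unconstrained = FALSE))
  expect_equal(f3$delta, 1 / delta_ref, tolerance = 1e-4)
  fr <- fit_lme(tab, 2, "REML")
  mr <- nlme::lme(y ~ age_s + sex01 + iq_s + asd + asd:age_s + asd:sex01 +
                    asd:iq_s,
                  random = ~ 1 | site, data = tab, method = "REML")
  expect_equal(fr$loglik, as.numeric(stats::logLik(mr)), tolerance = 1e-6)
  expect_equal(unname(fr$se), unname(sqrt(diag(stats::vcov(mr)))),
               tolerance = 1e-5)
})

test_that("log-likelihood is non-decreasing along the model nesting", {
  meta <- make_meta(40, seed = 4)
  for (b in 1:5) {
    tab <- simulate_feature_table(meta, d = 0.2 * (b %% 2),
                                  variance_ratio = 1 + 0.2 * (b %% 3),
                                  seed = 50 + b)
    f1 <- fit_lme(tab, 1, "ML")
    f2 <- fit_lme(tab, 2, "ML")
    f3 <- fit_lme(tab, 3, "ML")
    expect_gte(f2$loglik, f1$loglik - 1e-6)
    expect_gte(f3$loglik, f2$loglik - 1e-6)
  }
})

test_that("heteroscedastic fit recovers injected parameters", {
  meta <- make_meta(200, seed = 6)
  est <- t(vapply(1:30, function(b) {
    tab <- simulate_feature_table(meta, d = 0.5, variance_ratio = 1.3,
                                  seed = 200 + b)
    f3 <- fit_lme(tab, 3, "ML")
    c(f3$beta[["group"]], f3$delta)
  }, numeric(2)))
  expect_equal(mean(est[, 1]), 0.5, tolerance = 0.05)
  expect_equal(mean(est[, 2]), 1.3, tolerance = 0.05)
})

test_that("zero site variance hits the boundary without failing", {
  meta <- make_meta(50, seed = 8)
  tab <- simulate_feature_table(meta, site_sd = 0, seed = 9)
  f <- fit_lme(tab, 1, "ML")
  expect_lt(f$sigma_site2, 0.05)
  expect_true(is.finite(f$loglik))
})

test_that("group tests give the expected p-values and effect sizes", {
  meta <- make_meta(200, seed = 10)
  # strong mean effect detected, variance effect near null
  tab <- simulate_feature_table(meta, d = 0.8, seed = 11)
  gt <- group_tests(tab)
  expect_lt(gt$p_mean, 0.01)
  expect_equal(nrow(gt$f_tests), 4)
  expect_lt(gt$f_tests$p[gt$f_tests$term == "group"], 0.05)
  # variance effect detected by the model-3 test
  tab2 <- simulate_feature_table(meta, variance_ratio = 1.5, seed = 12)
  gt2 <- group_tests(tab2)
  expect_lt(gt2$p_var, 0.05)
  # duplicated groups: zero effect size by construction
  half <- meta[meta$group == "ASD", ]
  dup <- rbind(half, transform(half, group = "NT", id = paste0(id, "b")))
  dup_tab <- simulate_feature_table(meta, seed = 13)
  dup_tab$y[dup_tab$group == "NT"] <- dup_tab$y[dup_tab$group == "ASD"]
  expect_equal(group_tests(dup_tab)$cohens_d, 0)
})

test_that("variance-test power at delta 1.5, n = 400", {
  meta <- make_meta(200, seed = 14)
  rej <- vapply(1:25, function(b) {
    tab <- simulate_feature_table(meta, variance_ratio = 1.5, seed = 400 + b)
    group_tests(tab)$p_var < 0.05
  }, logical(1))
  expect_gte(mean(rej), 0.8)
})

test_that("Cohen's d matches the summary-statistic closed form", {
  expect_equal(cohens_d(1, 1, 10, 1, 1, 10), 0)
  expect_equal(cohens_d(2, 3, 50, 1, 3, 50), 1 / 3)
  # the cohort IQ row: 104.0 +/- 14.5 (n = 212) vs 107.9 +/- 13.1 (n = 199)
  expect_equal(round(cohens_d(104.0, 14.5, 212, 107.9, 13.1, 199), 2), -0.28)
})

test_that("transform selection prefers the normalizing family", {
  set.seed(15)
  x <- exp(rnorm(500))
  sel <- select_transform(x, transform_families()[c("identity", "log")])
  expect_equal(sel$name, "log")
  z <- rnorm(500)
  sel2 <- select_transform(z, transform_families()[c("identity", "log", "x4")])
  expect_equal(sel2$name, "identity")
  expect_error(select_transform(rep(1, 30)), "constant")
  # atanh transform clips out-of-range values with a warning
  expect_warning(transform_families()$atanh(c(0.5, 1)), "clipped")
  expect_warning(transform_families()$x4(c(-0.2, 0.5)), "sign")
})
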