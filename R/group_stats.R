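#' Prepare a feature table for modeling
#'
#' Standardizes age and IQ (mean 0, SD 1), codes sex as 0/1 (male = 0) and
#' group as 0/1 (NT = 0), and keeps site as a factor.
#'
#' @param table data.frame with columns y, age, sex, iq, site, group.
#' @return data.frame with added columns `age_s`, `iq_s`, `sex01`, `asd`.
#' @export
prepare_feature_table <- function(table) {
  stopifnot(all(c("age", "sex", "iq", "site", "group") %in% names(table)))
  table$age_s <- as.numeric(scale(table$age))
  table$iq_s <- as.numeric(scale(table$iq))
  table$sex01 <- as.numeric(table$sex != "M")
  table$asd <- as.numeric(table$group == "ASD")
  table$site <- factor(table$site)
  table
}

# internal: fixed-effect design matrix for the three model variants
lme_design <- function(tab, model) {
  x <- cbind(`(Intercept)` = 1, age = tab$age_s, sex = tab$sex01, iq = tab$iq_s)
  if (model >= 2)
    x <- cbind(x, group = tab$asd, `group:age` = tab$asd * tab$age_s,
               `group:sex` = tab$asd * tab$sex01,
               `group:iq` = tab$asd * tab$iq_s)
  x
}

# internal: profiled Gaussian log-likelihood machinery for
#   y ~ N(X beta, sigma^2 (D + tau Z Z'))
# with D = diag(delta^(2*asd)) and Z the site-intercept indicator. Everything
# is computed per site block with the rank-one Woodbury identity, and sigma^2
# is profiled out, leaving a 1-d (models 1-2) or 2-d (model 3) optimization.
lme_profile <- function(y, x, site, asd, log_tau, log_delta, reml = FALSE) {
  tau <- exp(log_tau)
  delta <- exp(log_delta)
  n <- length(y)
  p <- ncol(x)
  d <- delta^(2 * asd)        # per-observation residual variance weight
  xtax <- matrix(0, p, p)
  xtay <- numeric(p)
  ytay <- 0
  logdet <- 0
  for (s in levels(site)) {
    idx <- which(site == s)
    di <- 1 / d[idx]
    ssum <- sum(di)
    # (D + tau 11')^-1 = D^-1 - tau D^-1 1 1' D^-1 / (1 + tau s)
    f <- tau / (1 + tau * ssum)
    ys <- y[idx]; xs <- x[idx, , drop = FALSE]
    wy <- di * ys
    wx <- di * xs
    xtax <- xtax + crossprod(xs, wx) - f * tcrossprod(colSums(wx))
    xtay <- xtay + crossprod(xs, wy) - f * colSums(wx) * sum(wy)
    ytay <- ytay + sum(ys * wy) - f * sum(wy)^2
    logdet <- logdet + sum(log(d[idx])) + log(1 + tau * ssum)
  }
  ch <- tryCatch(chol(xtax), error = function(e) NULL)
  if (is.null(ch)) return(list(ok = FALSE))
  beta <- backsolve(ch, forwardsolve(t(ch), xtay))
  rss <- ytay - sum(xtay * beta)        # r' A^-1 r at the GLS solution
  rss <- max(rss, 1e-12)
  if (reml) {
    sigma2 <- rss / (n - p)
    ll <- -0.5 * ((n - p) * log(2 * pi * sigma2) + logdet +
                    2 * sum(log(diag(ch))) + (n - p))
  } else {
    sigma2 <- rss / n
    ll <- -0.5 * (n * log(2 * pi * sigma2) + logdet + n)
  }
  list(ok = TRUE, beta = beta, sigma2 = sigma2, loglik = ll,
       cov_unscaled = chol2inv(ch), logdet = logdet)
}

#' Fit a site-random-intercept mixed model, optionally heteroscedastic
#'
#' Fits one of three nested linear mixed-effects models for a per-subject
#' feature: model 1 `y ~ 1 + age + sex + iq + (1|site)`; model 2 adds group
#' and its interactions with age, sex and IQ; model 3 is model 2 with
#' group-specific residual variances (residual SD multiplied by `delta` in
#' the ASD group). The Gaussian likelihood is maximized directly: the
#' residual variance is profiled out and the remaining one or two variance
#' parameters (site-to-residual variance ratio; log delta) are optimized
#' numerically with multiple restarts.
#'
#' @param table a [prepare_feature_table()] data.frame with a `y` column (or
#'   raw columns, which are prepared on the fly).
#' @param model 1, 2 or 3.
#' @param method "ML" (default) or "REML".
#' @return list of class `lme_fit`: `beta` (named fixed effects),
#'   `sigma_site2`, `sigma2` (NT residual variance), `delta` (ASD/NT residual
#'   SD ratio; 1 for models 1-2), `loglik`, `method`, `se` (fixed-effect
#'   standard errors), `df_denom` (between-within denominator df), `n`.
#' @export
fit_lme <- function(table, model = 1, method = c("ML", "REML")) {
  method <- match.arg(method)
  stopifnot(model %in% 1:3)
  if (is.null(table$age_s)) table <- prepare_feature_table(table)
  y <- table$y
  stopifnot(is.numeric(y), !anyNA(y))
  site <- factor(table$site)
  if (nlevels(site) < 2) {
    warning("single site: random intercept dropped")
  }
  if (model >= 2 && length(unique(table$asd)) < 2)
    stop("both groups must be present for models 2 and 3")
  x <- lme_design(table, model)
  asd <- if (model == 3) table$asd else rep(0, length(y))
  reml <- method == "REML"
  obj <- function(par) {
    pr <- lme_profile(y, x, site, asd, par[1], if (model == 3) par[2] else 0,
                      reml = reml)
    if (!pr$ok) return(1e10)
    -pr$loglik
  }
  starts <- if (model == 3)
    list(c(-1, 0), c(-4, 0), c(0, 0.3), c(0, -0.3), c(-8, 0))
  else list(-1, -4, 0, 2, -8)
  best <- NULL
  for (st in starts) {
    fit <- try(stats::optim(unlist(st), obj, method = "L-BFGS-B",
                            lower = rep(-20, length(st)),
                            upper = rep(10, length(st)),
                            control = list(maxit = 500, factr = 1e7)),
               silent = TRUE)
    if (inherits(fit, "try-error") || !is.finite(fit$value)) next
    if (is.null(best) || fit$value < best$value - 1e-10) best <- fit
  }
  if (is.null(best)) stop("mixed-model optimization failed to converge")
  log_tau <- best$par[1]
  log_delta <- if (model == 3) best$par[2] else 0
  pr <- lme_profile(y, x, site, asd, log_tau, log_delta, reml = reml)
  beta <- drop(pr$beta)
  names(beta) <- colnames(x)
  se <- sqrt(pr$sigma2 * diag(pr$cov_unscaled))
  names(se) <- colnames(x)
  n <- length(y)
  p <- ncol(x)
  structure(list(beta = beta, sigma_site2 = exp(log_tau) * pr$sigma2,
                 sigma2 = pr$sigma2, delta = exp(log_delta),
                 loglik = pr$loglik, method = method, se = se,
                 df_denom = n - nlevels(site) - (p - 1), n = n,
                 model = model),
            class = "lme_fit")
}

#' Mean and variance group tests for one feature
#'
#' Fits models 1-3 by maximum likelihood; the mean test is the likelihood
#' ratio of models 2 vs 1 (chi-squared, 4 df: group and its three
#' interactions), the variance test is models 3 vs 2 (chi-squared, 1 df).
#' Because likelihood-ratio tests on fixed effects can be anticonservative,
#' per-coefficient F tests from a REML fit of model 2 are reported as
#' confirmation, with between-within denominator degrees of freedom. The raw
#' (covariate-unadjusted) Cohen's d is attached for reference.
#'
#' @param table feature table with y and covariates.
#' @return list of class `group_test`: `p_mean`, `p_var`, `f_tests`
#'   (data.frame: term, F, df1, df2, p), `cohens_d`, `fits` (the three ML
#'   fits).
#' @export
group_tests <- function(table) {
  table <- prepare_feature_table(table)
  f1 <- fit_lme(table, 1, "ML")
  f2 <- fit_lme(table, 2, "ML")
  f3 <- fit_lme(table, 3, "ML")
  lr_mean <- max(0, 2 * (f2$loglik - f1$loglik))
  lr_var <- max(0, 2 * (f3$loglik - f2$loglik))
  p_mean <- stats::pchisq(lr_mean, df = 4, lower.tail = FALSE)
  p_var <- stats::pchisq(lr_var, df = 1, lower.tail = FALSE)
  fr <- fit_lme(table, 2, "REML")
  terms <- c("group", "group:age", "group:sex", "group:iq")
  fstat <- (fr$beta[terms] / fr$se[terms])^2
  f_tests <- data.frame(term = terms, F = unname(fstat), df1 = 1,
                        df2 = fr$df_denom,
                        p = stats::pf(unname(fstat), 1, fr$df_denom,
                                      lower.tail = FALSE))
  g1 <- table$y[table$asd == 1]
  g0 <- table$y[table$asd == 0]
  d <- cohens_d(mean(g1), stats::sd(g1), length(g1),
                mean(g0), stats::sd(g0), length(g0))
  structure(list(p_mean = p_mean, p_var = p_var, f_tests = f_tests,
                 cohens_d = d, fits = list(f1, f2, f3)),
            class = "group_test")
}

#' Cohen's d from group summary statistics
#'
#' Pooled-SD standardized mean difference
#' `(m1 - m2) / sqrt(((n1-1) s1^2 + (n2-1) s2^2) / (n1+n2-2))`.
#'
#' @param mean1,sd1,n1 first group summary.
#' @param mean2,sd2,n2 second group summary.
#' @return dimensionless effect size.
#' @export
cohens_d <- function(mean1, sd1, n1, mean2, sd2, n2) {
  stopifnot(sd1 > 0 || sd2 > 0, n1 >= 2, n2 >= 2)
  sp <- sqrt(((n1 - 1) * sd1^2 + (n2 - 1) * sd2^2) / (n1 + n2 - 2))
  (mean1 - mean2) / sp
}

#' Normalizing transforms used for the feature families
#'
#' `log` for absolute power, the fourth power for reactivity (note: this
#' transform discards the sign of negative reactivities, which is applied as
#' specified but warned about), `atanh` for orthogonalized power correlations
#' (values clipped just inside (-1, 1)) and `x^0.11` for wPLI.
#'
#' @return named list of transform functions.
#' @export
transform_families <- function() {
  list(
    identity = function(x) x,
    log = function(x) log(x),
    x4 = function(x) {
      if (any(x < 0))
        warning("fourth-power transform discards the sign of negative values")
      x^4
    },
    atanh = function(x) {
      if (any(abs(x) >= 1)) {
        warning("values clipped to (-1, 1) before atanh")
        x <- pmin(pmax(x, -(1 - 1e-6)), 1 - 1e-6)
      }
      atanh(x)
    },
    x011 = function(x) x^0.11
  )
}

#' Select the transform that best normalizes a sample
#'
#' Applies each candidate monotone transform, standardizes, and evaluates a
#' Kolmogorov-Smirnov goodness-of-fit test against the standard normal; the
#' candidate with the largest KS p-value wins. Candidates whose domain the
#' sample violates (log of non-positives) are skipped.
#'
#' @param values numeric sample (at least 20 values, non-constant).
#' @param candidates named list of transform functions (default
#'   [transform_families()]).
#' @return list: `name`, `transform` (function), `ks_p` (named vector of all
#'   candidate p-values).
#' @export
select_transform <- function(values, candidates = transform_families()) {
  stopifnot(length(values) >= 20)
  if (stats::sd(values) == 0) stop("constant sample: transform selection undefined")
  ps <- vapply(names(candidates), function(nm) {
    tx <- suppressWarnings(candidates[[nm]](values))
    if (any(!is.finite(tx)) || stats::sd(tx) == 0) return(NA_real_)
    z <- (tx - mean(tx)) / stats::sd(tx)
    suppressWarnings(stats::ks.test(z, "pnorm")$p.value)
  }, numeric(1))
  if (all(is.na(ps))) stop("no candidate transform applicable")
  best <- names(which.max(ps))
  list(name = best, transform = candidates[[best]], ks_p = ps)
}
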