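#' Age group of a subject
#'
#' Children are 6-11 years, adolescents 12-17, adults 18 and above.
#'
#' @param age numeric ages in years.
#' @return factor with levels child/adolescent/adult.
#' @export
age_group <- function(age) {
  cut(age, c(-Inf, 12, 18, Inf), labels = c("child", "adolescent", "adult"),
      right = FALSE)
}

#' Stratified train/validation split
#'
#' Random assignment within strata defined by site x age group x diagnosis;
#' within each stratum, `round(train_frac * n)` subjects go to training.
#' Singleton strata are assigned to training with a warning.
#'
#' @param meta covariate data.frame with site, age and group columns.
#' @param train_frac training fraction (default 0.7).
#' @param seed integer seed.
#' @return list of class `split_assignment`: `assignment`
#'   (character vector "train"/"validation"), `strata` (per-subject labels).
#' @export
stratified_split <- function(meta, train_frac = 0.7, seed = 1) {
  stopifnot(train_frac > 0, train_frac < 1)
  strata <- interaction(meta$site, age_group(meta$age), meta$group, drop = TRUE)
  set.seed(seed)
  assignment <- rep("train", nrow(meta))
  for (st in levels(strata)) {
    idx <- which(strata == st)
    n <- length(idx)
    if (n == 1L) {
      warning(sprintf("stratum %s has a single subject: assigned to training", st))
      next
    }
    n_tr <- round(train_frac * n)
    val <- sample(idx, n - n_tr)
    assignment[val] <- "validation"
  }
  structure(list(assignment = assignment, strata = strata),
            class = "split_assignment")
}

#' Replication prediction interval for a correlation
#'
#' Fisher-z interval for the correlation a replication study should observe
#' given the original estimate and both sample sizes:
#' `tanh(atanh(r) +/- z * sqrt(1/(n_orig - 3) + 1/(n_rep - 3)))`.
#'
#' @param r original correlation (|r| < 1).
#' @param n_orig,n_rep sample sizes (each > 3).
#' @param level confidence level (default 0.95).
#' @return list of class `prediction_interval`: `lo`, `hi`, `level`,
#'   `kind = "correlation"`.
#' @export
prediction_interval_r <- function(r, n_orig, n_rep, level = 0.95) {
  stopifnot(abs(r) < 1)
  if (n_orig <= 3 || n_rep <= 3) stop("sample sizes must exceed 3")
  z <- atanh(r)
  hw <- stats::qnorm((1 + level) / 2) * sqrt(1 / (n_orig - 3) + 1 / (n_rep - 3))
  structure(list(lo = tanh(z - hw), hi = tanh(z + hw), level = level,
                 kind = "correlation"), class = "prediction_interval")
}

#' Replication prediction interval for a standardized mean difference
#'
#' Uses the large-sample variance of Cohen's d,
#' `v = (n1 + n2) / (n1 n2) + d^2 / (2 (n1 + n2))`, in both the original and
#' the replication sample: `d +/- z sqrt(v_orig + v_rep)`.
#'
#' @param d original standardized mean difference.
#' @param n1o,n2o group sizes in the original sample.
#' @param n1r,n2r group sizes in the replication sample.
#' @param level confidence level (default 0.95).
#' @return a `prediction_interval` with `kind = "smd"`.
#' @export
prediction_interval_d <- function(d, n1o, n2o, n1r, n2r, level = 0.95) {
  stopifnot(n1o >= 2, n2o >= 2, n1r >= 2, n2r >= 2)
  vd <- function(n1, n2) (n1 + n2) / (n1 * n2) + d^2 / (2 * (n1 + n2))
  hw <- stats::qnorm((1 + level) / 2) * sqrt(vd(n1o, n2o) + vd(n1r, n2r))
  structure(list(lo = d - hw, hi = d + hw, level = level, kind = "smd"),
            class = "prediction_interval")
}

#' Power of the two-sided two-sample t test
#'
#' Exact noncentral-t power for detecting a standardized mean difference `d`
#' with group sizes `n1`, `n2` at level `alpha`.
#'
#' @param d standardized mean difference.
#' @param n1,n2 group sizes.
#' @param alpha two-sided significance level (default 0.05).
#' @return power as a fraction.
#' @export
power_twosample <- function(d, n1, n2, alpha = 0.05) {
  stopifnot(alpha > 0, alpha < 1, n1 >= 2, n2 >= 2)
  df <- n1 + n2 - 2
  ncp <- d * sqrt(n1 * n2 / (n1 + n2))
  tc <- stats::qt(1 - alpha / 2, df)
  stats::pt(-tc, df, ncp) + stats::pt(tc, df, ncp, lower.tail = FALSE)
}

#' Simulated power of the mixed-model mean test
#'
#' Simulates feature-level cohorts from the generator's statistical model
#' and reports the fraction with a mean-test p below `alpha`, with a binomial
#' confidence interval.
#'
#' @param spec a [cohort_spec()] (its effect sizes and sample size are used).
#' @param n_sim number of simulated cohorts (at least 100).
#' @param alpha test level (default 0.05).
#' @param seed integer seed.
#' @return list: `power`, `ci` (95 percent binomial), `n_sim`.
#' @export
power_lme_sim <- function(spec, n_sim = 200, alpha = 0.05, seed = 1) {
  stopifnot(n_sim >= 100)
  hits <- logical(n_sim)
  for (b in seq_len(n_sim)) {
    sp <- spec
    sp$seed <- substream_seed(seed, b)
    meta <- generate_subject_meta(sp)
    tab <- simulate_feature_table(meta, d = spec$effect_mean,
                                  variance_ratio = spec$effect_variance_ratio,
                                  seed = substream_seed(seed, b + n_sim))
    hits[b] <- group_tests(tab)$p_mean < alpha
  }
  ci <- stats::binom.test(sum(hits), n_sim)$conf.int
  list(power = mean(hits), ci = as.numeric(ci), n_sim = n_sim)
}
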