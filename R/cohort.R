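#' Standard 61-channel montage labels
#'
#' The 10-10 subset used for the synthetic recordings, including the occipital
#' set entering the summary alpha measures.
#' @export
MONTAGE_61 <- c(
  "Fp1", "Fpz", "Fp2",
  "AF7", "AF3", "AFz", "AF4", "AF8",
  "F7", "F5", "F3", "F1", "Fz", "F2", "F4", "F6", "F8",
  "FT7", "FC5", "FC3", "FC1", "FCz", "FC2", "FC4", "FC6", "FT8",
  "T7", "C5", "C3", "C1", "Cz", "C2", "C4", "C6", "T8",
  "TP7", "CP5", "CP3", "CP1", "CPz", "CP2", "CP4", "CP6", "TP8",
  "P7", "P5", "P3", "P1", "Pz", "P2", "P4", "P6", "P8",
  "PO7", "PO3", "POz", "PO4", "PO8",
  "O1", "Oz", "O2")

#' Specification of a synthetic cohort
#'
#' Bundles the controllable parameters of the cohort generator: sample size,
#' standardized group mean shift on eyes-closed log alpha power, residual
#' variance ratio, per-group age slopes of the reactivity to eye opening, a
#' coupling plan for lagged pairwise interactions, per-site log-power offsets,
#' and the signal-level parameters of the recordings.
#'
#' @param n_per_group subjects per group (default 20).
#' @param effect_mean standardized mean difference (Cohen's d, ASD minus NT)
#'   injected on eyes-closed log alpha power (default 0).
#' @param effect_variance_ratio ASD/NT residual SD ratio on the same feature
#'   (default 1; must be positive).
#' @param age_slope_by_group named vector `c(ASD = , NT = )` of linear age
#'   slopes of reactivity per year (default both 0.008).
#' @param coupling_plan data.frame with columns `node_i`, `node_j` (channel
#'   labels, or source indices when generating through a leadfield), `freq`
#'   (Hz), `lag` (radians in (-pi, pi]), `env_corr` (amplitude-envelope
#'   correlation in [0, 1]), `strength_asd`, `strength_nt` (oscillation RMS
#'   amplitude in microvolts per group). Default: none.
#' @param site_offsets named numeric vector of additive log-power site
#'   offsets; sites are taken from its names (default 3 sites, 0 and +/-0.1).
#' @param seed integer seed; all randomness derives from it, with per-subject
#'   substreams indexed by subject.
#' @param srate sampling rate of the generated recordings in Hz (default 250).
#' @param n_blocks,block_dur block layout: `n_blocks` alternating EO/EC
#'   blocks of `block_dur` seconds, starting with EO (defaults 8 x 30 s,
#'   i.e. 2 min per condition).
#' @param channels channel labels (default [MONTAGE_61]).
#' @param chi spectral slope of the 1/f^chi background (default 1).
#' @param bg_sd background RMS amplitude in microvolts (default 10).
#' @param alpha_snr ratio of eyes-closed occipital alpha band power to
#'   background band power (default 9).
#' @param base_reactivity mean reactivity at the cohort mean age of 19 years
#'   (default 0.5).
#' @param reactivity_sd between-subject SD of reactivity around its age trend
#'   (default 0.08).
#' @param alpha_logpow_sd between-subject SD of eyes-closed log alpha power,
#'   the scale on which `effect_mean` and `effect_variance_ratio` act
#'   (default 0.5).
#' @return a list of class `cohort_spec`.
#' @export
cohort_spec <- function(n_per_group = 20, effect_mean = 0,
                        effect_variance_ratio = 1,
                        age_slope_by_group = c(ASD = 0.008, NT = 0.008),
                        coupling_plan = NULL,
                        site_offsets = c(siteA = 0, siteB = 0.1, siteC = -0.1),
                        seed = 1, srate = 250, n_blocks = 8, block_dur = 30,
                        channels = MONTAGE_61, chi = 1, bg_sd = 10,
                        alpha_snr = 9, base_reactivity = 0.5,
                        reactivity_sd = 0.08, alpha_logpow_sd = 0.5) {
  if (effect_variance_ratio <= 0) stop("effect_variance_ratio must be positive")
  if (!is.null(coupling_plan)) {
    coupling_plan <- as.data.frame(coupling_plan)
    need <- c("node_i", "node_j", "freq", "lag", "env_corr",
              "strength_asd", "strength_nt")
    stopifnot(all(need %in% names(coupling_plan)))
    if (any(coupling_plan$lag <= -pi | coupling_plan$lag > pi))
      stop("coupling lags must lie in (-pi, pi]")
    stopifnot(all(coupling_plan$env_corr >= 0 & coupling_plan$env_corr <= 1))
  }
  stopifnot(all(c("ASD", "NT") %in% names(age_slope_by_group)),
            length(site_offsets) >= 1, !is.null(names(site_offsets)))
  structure(mget(names(formals())), class = "cohort_spec")
}

#' Sample subject-level covariates
#'
#' Demographics follow the margins of the study cohort: age uniform on
#' [6, 32] years, about 72 percent male, full-scale IQ normal with mean 106
#' and SD 14 truncated at the inclusion bound of 75, medication more frequent
#' in the ASD group. Sites are assigned in rotation within each group so that
#' every site contains at least one subject per group.
#'
#' @param spec a [cohort_spec()].
#' @return data.frame with columns id, group, age, sex, iq, site, medication.
#' @export
generate_subject_meta <- function(spec) {
  stopifnot(inherits(spec, "cohort_spec"))
  n <- 2L * spec$n_per_group
  set.seed(substream_seed(spec$seed, 0L))
  group <- rep(c("ASD", "NT"), each = spec$n_per_group)
  age <- stats::runif(n, 6, 32)
  sex <- ifelse(stats::runif(n) < 0.72, "M", "F")
  iq <- stats::qnorm(stats::runif(n, stats::pnorm(75, 106, 14), 1), 106, 14)
  sites <- names(spec$site_offsets)
  site <- character(n)
  for (g in c("ASD", "NT")) {
    idx <- which(group == g)
    site[idx] <- rep_len(sites, length(idx))[sample.int(length(idx))]
  }
  if (spec$n_per_group < length(sites))
    stop("need at least one subject per group per site")
  medication <- stats::runif(n) < ifelse(group == "ASD", 0.37, 0.056)
  data.frame(id = sprintf("S%03d", seq_len(n)), group = group, age = age,
             sex = sex, iq = iq, site = site, medication = medication,
             stringsAsFactors = FALSE)
}

# internal: spectral shaping weights |H(k)| for 1/f^chi background on an
# n-point FFT grid; flat below 1 Hz to keep the variance finite
bg_shape <- function(n, srate, chi) {
  f <- (0:(n - 1)) * srate / n
  f[f > srate / 2] <- srate - f[f > srate / 2]
  h <- pmax(f, 1)^(-chi / 2)
  h[1] <- 0
  h
}

# internal: one realization of 1/f^chi noise with RMS sd (vectorized over
# channels: returns n_ch x n matrix)
gen_background <- function(n_ch, n, srate, chi, sd) {
  h <- bg_shape(n, srate, chi)
  out <- matrix(0, n_ch, n)
  for (ch in seq_len(n_ch)) {
    z <- complex(real = stats::rnorm(n), imaginary = stats::rnorm(n))
    x <- Re(stats::fft(z * h, inverse = TRUE))
    out[ch, ] <- x / stats::sd(x) * sd
  }
  out
}

# internal: fraction of background power falling in [lo, hi] Hz
bg_band_fraction <- function(n, srate, chi, lo, hi) {
  h <- bg_shape(n, srate, chi)
  f <- (0:(n - 1)) * srate / n
  f[f > srate / 2] <- srate - f[f > srate / 2]
  sum(h[f >= lo & f <= hi]^2) / sum(h^2)
}

# internal: complex analytic narrowband noise, unit RMS of its real part,
# Gaussian spectral profile centered at f0 with SD sigma_f (Hz)
gen_narrowband <- function(n, srate, f0, sigma_f = 0.5) {
  f <- (0:(n - 1)) * srate / n
  w <- exp(-(f - f0)^2 / (2 * sigma_f^2))
  w[f > srate / 2] <- 0  # one-sided: analytic signal
  z <- complex(real = stats::rnorm(n), imaginary = stats::rnorm(n))
  zt <- stats::fft(z * w, inverse = TRUE)
  zt / stats::sd(Re(zt))
}

#' Generate one synthetic resting-state recording
#'
#' The recording is a 1/f^chi background plus narrowband (1 Hz bandwidth)
#' alpha oscillators at the subject's age-dependent peak frequency, stronger
#' during eyes-closed blocks so that the measured occipital reactivity matches
#' the subject's target (the eyes-open amplitude is compensated for the
#' background power inside the alpha band). Coupled pairs from the coupling
#' plan share a narrowband oscillator with a fixed phase lag and correlated
#' envelopes. Site offsets and group effects act multiplicatively on
#' amplitude (additively on log power).
#'
#' @param meta_row one row of [generate_subject_meta()].
#' @param spec the [cohort_spec()].
#' @param index subject index (selects the random substream).
#' @param leadfield optional [generate_leadfield()] result; when supplied,
#'   signals are generated at the source level and projected through the
#'   (radially oriented) gain matrix, plus a small amount of sensor noise,
#'   and `node_i`/`node_j` in the coupling plan are source indices.
#' @return a [recording()], with attributes `target_reactivity` and `f_p`.
#' @export
generate_recording <- function(meta_row, spec, index = 1L, leadfield = NULL) {
  stopifnot(inherits(spec, "cohort_spec"))
  set.seed(substream_seed(spec$seed, index))
  fs <- spec$srate
  n <- round(spec$n_blocks * spec$block_dur * fs)
  blocks <- data.frame(
    condition = rep(c("EO", "EC"), length.out = spec$n_blocks),
    start = (seq_len(spec$n_blocks) - 1) * spec$block_dur,
    duration = spec$block_dur)
  is_asd <- meta_row$group == "ASD"

  # subject-level alpha parameters
  f_p <- min(8 + 0.1 * (meta_row$age - 6), 11) + stats::rnorm(1, 0, 0.3)
  f_p <- min(max(f_p, 6.5), 12)
  slope <- spec$age_slope_by_group[[meta_row$group]]
  r_target <- spec$base_reactivity + slope * (meta_row$age - 19) +
    stats::rnorm(1, 0, spec$reactivity_sd)
  r_target <- min(max(r_target, -0.5), spec$alpha_snr / (spec$alpha_snr + 1) - 0.02)

  # eyes-closed alpha power on the log scale: site offset, group shift
  # d * sd, group-specific residual SD
  res_sd <- spec$alpha_logpow_sd * if (is_asd) spec$effect_variance_ratio else 1
  lp <- stats::rnorm(1, 0, res_sd) +
    (if (is_asd) spec$effect_mean * spec$alpha_logpow_sd else 0) +
    spec$site_offsets[[meta_row$site]]

  # nodes: channels, or sources projected through the leadfield
  if (is.null(leadfield)) {
    labels <- spec$channels
    n_nodes <- length(labels)
    occ <- which(labels %in% OCCIPITAL_SET)
  } else {
    n_nodes <- nrow(leadfield$positions)
    labels <- NULL
    occ <- which(leadfield$positions[, 2] <
                   stats::quantile(leadfield$positions[, 2], 0.25))
  }
  x <- gen_background(n_nodes, n, fs, spec$chi, spec$bg_sd)

  # per-block amplitude gains realizing the target reactivity at occipital
  # nodes, compensating for background power inside [f_p - 2, f_p + 2]
  band_frac <- bg_band_fraction(n, fs, spec$chi, f_p - 2, f_p + 2)
  p_bg <- spec$bg_sd^2 * band_frac
  p_alpha_ec <- spec$alpha_snr * p_bg * exp(lp)
  p_alpha_eo <- max(0, (1 - r_target) * (p_alpha_ec + p_bg) - p_bg)
  tvec <- (seq_len(n) - 1) / fs
  is_ec <- logical(n)
  for (k in seq_len(nrow(blocks))) {
    sel <- tvec >= blocks$start[k] & tvec < blocks$start[k] + blocks$duration[k]
    if (blocks$condition[k] == "EC") is_ec[sel] <- TRUE
  }
  w_node <- rep(0.25, n_nodes)
  w_node[occ] <- 1
  for (nd in seq_len(n_nodes)) {
    z <- Re(gen_narrowband(n, fs, f_p))
    # exact per-condition RMS so the realized reactivity matches the target
    # (the sample variance of a 1 Hz-wide process fluctuates considerably
    # over 2-minute stretches)
    z[is_ec] <- z[is_ec] / stats::sd(z[is_ec]) * sqrt(p_alpha_ec)
    z[!is_ec] <- z[!is_ec] / stats::sd(z[!is_ec]) *
      sqrt(max(p_alpha_eo, 1e-12))
    x[nd, ] <- x[nd, ] + w_node[nd] * z
  }

  # lagged coupled pairs
  cp <- spec$coupling_plan
  if (!is.null(cp) && nrow(cp)) {
    for (k in seq_len(nrow(cp))) {
      s <- if (is_asd) cp$strength_asd[k] else cp$strength_nt[k]
      i <- if (is.null(labels)) cp$node_i[k] else match(cp$node_i[k], labels)
      j <- if (is.null(labels)) cp$node_j[k] else match(cp$node_j[k], labels)
      z <- gen_narrowband(n, fs, cp$freq[k])
      z2 <- gen_narrowband(n, fs, cp$freq[k])
      rho <- cp$env_corr[k]
      zj <- (rho * z + sqrt(1 - rho^2) * z2) * exp(-1i * cp$lag[k])
      if (s > 0) {
        x[i, ] <- x[i, ] + s * Re(z)
        x[j, ] <- x[j, ] + s * Re(zj)
      }
    }
  }

  if (!is.null(leadfield)) {
    g <- leadfield_fixed_gain(leadfield)
    g <- g / stats::median(abs(g)) / sqrt(n_nodes)  # keep sensor scale O(bg_sd)
    sens <- g %*% x + gen_background(nrow(g), n, fs, spec$chi, 0.1 * spec$bg_sd)
    rec <- recording(sens, fs, paste0("ch", seq_len(nrow(g))), blocks)
  } else {
    rec <- recording(x, fs, labels, blocks)
  }
  attr(rec, "target_reactivity") <- r_target
  attr(rec, "f_p") <- f_p
  rec
}

#' Generate a full synthetic cohort
#'
#' @param spec a [cohort_spec()].
#' @param leadfield optional leadfield for source-level generation (see
#'   [generate_recording()]).
#' @return list with `meta` (covariate data.frame) and `recordings` (list of
#'   [recording()]s in the same order). Deterministic given `spec$seed`.
#' @export
generate_cohort <- function(spec, leadfield = NULL) {
  meta <- generate_subject_meta(spec)
  recs <- lapply(seq_len(nrow(meta)), function(i)
    generate_recording(meta[i, ], spec, index = i, leadfield = leadfield))
  list(meta = meta, recordings = recs)
}

#' Simulate a feature-level cohort table
#'
#' Draws one feature per subject directly from the mixed-effects data model:
#' fixed covariate effects, a site random intercept, a group mean shift in
#' units of the residual SD, and a group-specific residual SD ratio. Used to
#' exercise the group statistics and permutation machinery at scale without
#' generating raw signals.
#'
#' @param meta covariate data.frame (from [generate_subject_meta()], or any
#'   table with group/age/sex/iq/site columns).
#' @param d standardized group mean difference (ASD minus NT).
#' @param variance_ratio ASD/NT residual SD ratio.
#' @param beta fixed effects `c(age, sex, iq)` on the standardized covariate
#'   scale (default c(0.3, 0.1, 0.1)).
#' @param interaction group-by-age interaction coefficient (default 0).
#' @param site_sd SD of the site random intercept (default 0.3).
#' @param sigma NT residual SD (default 1).
#' @param n_features number of independent feature columns (default 1).
#' @param seed integer seed.
#' @return data.frame with covariates and feature columns `y1..yk` (named `y`
#'   if a single feature).
#' @export
simulate_feature_table <- function(meta, d = 0, variance_ratio = 1,
                                   beta = c(age = 0.3, sex = 0.1, iq = 0.1),
                                   interaction = 0, site_sd = 0.3, sigma = 1,
                                   n_features = 1, seed = 1) {
  set.seed(seed)
  n <- nrow(meta)
  age_s <- as.numeric(scale(meta$age))
  iq_s <- as.numeric(scale(meta$iq))
  sex01 <- as.numeric(meta$sex != "M")
  asd <- as.numeric(meta$group == "ASD")
  sites <- unique(meta$site)
  b_site <- stats::rnorm(length(sites), 0, site_sd)
  mu <- beta[["age"]] * age_s + beta[["sex"]] * sex01 + beta[["iq"]] * iq_s +
    b_site[match(meta$site, sites)] + d * sigma * asd +
    interaction * asd * age_s
  res_sd <- sigma * ifelse(asd == 1, variance_ratio, 1)
  y <- matrix(stats::rnorm(n * n_features, 0, 1), n, n_features) * res_sd + mu
  out <- data.frame(meta, stringsAsFactors = FALSE)
  if (n_features == 1) out$y <- y[, 1]
  else for (k in seq_len(n_features)) out[[paste0("y", k)]] <- y[, k]
  out
}
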