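#' Occipital channel set used for the summary alpha measures
#' @export
OCCIPITAL_SET <- c("O1", "O2", "Oz", "PO4", "PO3", "POz")

#' Fit an alpha peak over a power-law background
#'
#' Nonlinear least squares of `P(f) = a f^-b + A exp(-(f - f_p)^2 / (2 s^2))`
#' on the occipital-average eyes-closed spectrum over the fit range, in the
#' log-power domain (which equalizes the dynamic range of 1/f backgrounds).
#' The peak frequency is constrained to [6, 13] Hz. A peak is accepted when
#' the fit converges, the Gaussian amplitude is positive, and its prominence
#' at the peak exceeds `prominence` times the background there.
#'
#' @param psd_ec a [welch_psd()] result for the eyes-closed condition.
#' @param occipital channels to average (default [OCCIPITAL_SET]; all must be
#'   present).
#' @param fit_range frequency range in Hz used in the fit (default c(2, 20)).
#' @param peak_range allowed peak-frequency range (default c(6, 13)).
#' @param prominence minimum Gaussian amplitude relative to the background at
#'   the peak (default 0.1).
#' @return list of class `alpha_fit`: `f_p`, `gauss_amp`, `gauss_sigma`,
#'   `powerlaw_a`, `powerlaw_b`, `converged`, `has_peak`.
#' @export
fit_alpha_peak <- function(psd_ec, occipital = OCCIPITAL_SET,
                           fit_range = c(2, 20), peak_range = c(6, 13),
                           prominence = 0.1) {
  stopifnot(inherits(psd_ec, "psd"))
  miss <- setdiff(occipital, psd_ec$channels)
  if (length(miss)) stop("missing occipital channels: ", paste(miss, collapse = ", "))
  sel <- psd_ec$freqs >= fit_range[1] & psd_ec$freqs <= fit_range[2]
  f <- psd_ec$freqs[sel]
  p <- colMeans(psd_ec$power[match(occipital, psd_ec$channels), sel, drop = FALSE])
  if (any(p <= 0)) p <- pmax(p, 1e-12 * max(p))
  logp <- log(p)
  model <- function(th) {
    # th = (log a, b, log A, f_p, log sigma)
    bg <- exp(th[1]) * f^(-th[2])
    pk <- exp(th[3]) * exp(-(f - th[4])^2 / (2 * exp(th[5])^2))
    log(bg + pk)
  }
  obj <- function(th) sum((model(th) - logp)^2)
  # power-law-only start from log-log regression
  bgfit <- stats::lm(logp ~ log(f))
  a0 <- unname(bgfit$coefficients[1])
  b0 <- -unname(bgfit$coefficients[2])
  in_band <- f >= peak_range[1] & f <= peak_range[2]
  resid0 <- logp - stats::fitted(bgfit)
  f_p0 <- f[in_band][which.max(resid0[in_band])]
  amp0 <- max(stats::median(p) * 0.5,
              max(p[in_band]) - exp(a0) * f_p0^(-b0))
  best <- NULL
  for (st in list(c(a0, b0, log(max(amp0, 1e-8)), f_p0, log(1)),
                  c(a0, b0, log(max(amp0, 1e-8)), 10, log(2)),
                  c(a0, b0, log(stats::median(p)), 8, log(1.5)))) {
    fit <- try(stats::optim(st, obj, method = "L-BFGS-B",
                            lower = c(-30, -2, -30, peak_range[1], log(0.3)),
                            upper = c(30, 6, 30, peak_range[2], log(5)),
                            control = list(maxit = 500)), silent = TRUE)
    if (inherits(fit, "try-error")) next
    if (is.null(best) || fit$value < best$value) best <- fit
  }
  if (is.null(best))
    return(structure(list(f_p = NA_real_, gauss_amp = NA_real_,
                          gauss_sigma = NA_real_, powerlaw_a = NA_real_,
                          powerlaw_b = NA_real_, converged = FALSE,
                          has_peak = FALSE), class = "alpha_fit"))
  th <- unname(best$par)
  A <- exp(th[3]); f_p <- th[4]
  bg_at_peak <- exp(th[1]) * f_p^(-th[2])
  # reject boundary-pinned "peaks": the optimizer parks the Gaussian at a
  # range edge when no real peak exists
  at_edge <- min(f_p - peak_range[1], peak_range[2] - f_p) < 1e-3
  has_peak <- best$convergence == 0 && A > prominence * bg_at_peak && !at_edge
  structure(list(f_p = if (has_peak) f_p else NA_real_, gauss_amp = A,
                 gauss_sigma = exp(th[5]), powerlaw_a = exp(th[1]),
                 powerlaw_b = th[2], converged = best$convergence == 0,
                 has_peak = has_peak),
            class = "alpha_fit")
}

#' Absolute alpha-band power around the individual peak
#'
#' Integrates the PSD over `[f_p - 2, f_p + 2]` Hz and averages over the
#' occipital channels. The same (eyes-closed) peak frequency is used for both
#' conditions.
#'
#' @param psd a [welch_psd()] result.
#' @param f_p individual alpha peak frequency in Hz.
#' @param occipital occipital channel labels.
#' @param halfwidth half band width in Hz (default 2).
#' @return scalar absolute band power in microvolts squared.
#' @export
alpha_band_power <- function(psd, f_p, occipital = OCCIPITAL_SET,
                             halfwidth = 2) {
  stopifnot(inherits(psd, "psd"), is.finite(f_p))
  miss <- setdiff(occipital, psd$channels)
  if (length(miss)) stop("missing occipital channels: ", paste(miss, collapse = ", "))
  if (f_p - halfwidth < min(psd$freqs) || f_p + halfwidth > max(psd$freqs))
    stop("alpha band extends outside the PSD frequency range")
  sel <- which(psd$freqs >= f_p - halfwidth - 1e-9 &
                 psd$freqs <= f_p + halfwidth + 1e-9)
  df <- diff(psd$freqs)[1]
  p <- psd$power[match(occipital, psd$channels), sel, drop = FALSE]
  # trapezoidal integration over the band
  mean(rowSums(p) - (p[, 1] + p[, ncol(p)]) / 2) * df
}

#' Reactivity to eye opening
#'
#' `R = 1 - P_EO / P_EC`: the relative suppression of occipital alpha power
#' when the eyes open. Negative values (more alpha with eyes open) are
#' permitted.
#'
#' @param p_eo,p_ec absolute alpha-band power for eyes open / closed.
#' @return dimensionless reactivity, at most 1.
#' @export
reactivity <- function(p_eo, p_ec) {
  if (any(p_ec <= 0)) stop("eyes-closed power must be positive")
  1 - p_eo / p_ec
}

#' Summary alpha measures for one subject
#'
#' Fits the eyes-closed occipital alpha peak, then derives band power in both
#' conditions around the single peak frequency and the reactivity to eye
#' opening. An `override_fp` (peak frequency fixed by manual review) replaces
#' the fitted value.
#'
#' @param epochs an [epoch_set()] with both conditions.
#' @param occipital occipital channel labels.
#' @param override_fp optional manual peak frequency in Hz.
#' @return list: `f_p`, `P_EO`, `P_EC`, `R`, `fit` (the `alpha_fit`).
#' @export
alpha_summary <- function(epochs, occipital = OCCIPITAL_SET,
                          override_fp = NULL) {
  psd_ec <- welch_psd(subset_epochs(epochs, "EC"))
  psd_eo <- welch_psd(subset_epochs(epochs, "EO"))
  fit <- fit_alpha_peak(psd_ec, occipital)
  f_p <- if (!is.null(override_fp)) override_fp else fit$f_p
  if (!is.finite(f_p))
    return(list(f_p = NA_real_, P_EO = NA_real_, P_EC = NA_real_,
                R = NA_real_, fit = fit))
  p_ec <- alpha_band_power(psd_ec, f_p, occipital)
  p_eo <- alpha_band_power(psd_eo, f_p, occipital)
  list(f_p = f_p, P_EO = p_eo, P_EC = p_ec, R = reactivity(p_eo, p_ec),
       fit = fit)
}
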