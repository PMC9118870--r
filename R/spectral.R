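#' Welch power spectral density
#'
#' Hann-tapered segment periodograms averaged across segments and epochs,
#' scaled as a one-sided density in microvolts squared per Hz. With the
#' default 2.5 s windows the frequency resolution is 0.4 Hz.
#'
#' @param epochs an [epoch_set()]; usually pre-subset to one condition with
#'   [subset_epochs()].
#' @param window taper window length in seconds (default 2.5). Must not
#'   exceed the epoch length.
#' @param overlap fractional overlap between successive windows within an
#'   epoch (default 0.75).
#' @return a list of class `psd` with `power` (channels x frequencies),
#'   `freqs` (Hz) and `condition`.
#' @export
welch_psd <- function(epochs, window = 2.5, overlap = 0.75) {
  stopifnot(inherits(epochs, "epoch_set"))
  fs <- epochs$srate
  nw <- round(window * fs)
  n <- dim(epochs$data)[2]
  if (nw > n) stop("epoch shorter than the Welch window")
  step <- max(1L, round(nw * (1 - overlap)))
  starts <- seq(1L, n - nw + 1L, by = step)
  w <- 0.5 - 0.5 * cos(2 * pi * seq_len(nw) / (nw + 1))  # Hann taper
  u <- sum(w^2)
  nf <- nw %/% 2L + 1L
  n_ch <- dim(epochs$data)[1]
  acc <- matrix(0, n_ch, nf)
  nseg <- 0L
  for (e in seq_len(dim(epochs$data)[3])) {
    for (s in starts) {
      seg <- matrix(epochs$data[, s:(s + nw - 1L), e], nrow = n_ch) *
        rep(w, each = n_ch)
      sp <- stats::mvfft(t(seg))[seq_len(nf), , drop = FALSE]
      p <- Mod(sp)^2 / (fs * u)
      p[c(-1L, -nf), ] <- 2 * p[c(-1L, -nf), ]  # one-sided
      acc <- acc + t(p)
      nseg <- nseg + 1L
    }
  }
  cond <- unique(epochs$condition)
  structure(list(power = acc / max(nseg, 1L),
                 freqs = (seq_len(nf) - 1L) * fs / nw,
                 condition = if (length(cond) == 1L) cond else NA_character_,
                 channels = epochs$channels),
            class = "psd")
}

#' Morlet frequency grid
#'
#' The 27-point dyadic grid `2^(1 + 0.15 k)`, k = 0..26, spanning 2 Hz to
#' about 29.9 Hz (the largest exponent not exceeding 5).
#'
#' @return numeric vector of 27 frequencies in Hz.
#' @export
morlet_grid <- function() 2^seq(1, 4.9, by = 0.15)

# internal: complex Morlet kernel at frequency f, scaled so a unit-amplitude
# sinusoid at f yields |coefficient|^2 = 0.5
morlet_kernel <- function(f, q, window_sigmas, srate) {
  sigma_t <- q / (2 * pi * f)   # sigma_f = f / q, sigma_t = 1 / (2 pi sigma_f)
  half <- floor(window_sigmas * sigma_t * srate / 2)
  t <- (-half:half) / srate
  env <- exp(-t^2 / (2 * sigma_t^2))
  (sqrt(2) / sum(env)) * env * exp(2i * pi * f * t)
}

#' Morlet wavelet transform on the dyadic grid
#'
#' Convolves every channel and epoch with complex Morlet wavelets of constant
#' spectral resolution `q = f / sigma_f` on the [morlet_grid()] frequencies.
#' Coefficients are sampled at window centers stepped by
#' `(1 - overlap) * window_sigmas * sigma_t`; windows that would extend past
#' an epoch edge are dropped.
#'
#' @param epochs an [epoch_set()].
#' @param q spectral resolution f / sigma_f (default 4.88, i.e. 0.6 octave).
#' @param window_sigmas wavelet window length in units of sigma_t (default 5).
#' @param overlap fractional overlap between successive windows (default 0.9).
#' @param freqs frequency grid in Hz (default [morlet_grid()]).
#' @return a list of class `wavelet_coeffs` with per-frequency complex
#'   coefficient matrices (channels x windows), the epoch index of every
#'   window, and per-epoch condition labels.
#' @export
morlet_transform <- function(epochs, q = 4.88, window_sigmas = 5,
                             overlap = 0.9, freqs = morlet_grid()) {
  stopifnot(inherits(epochs, "epoch_set"), q > 0, overlap >= 0, overlap < 1)
  fs <- epochs$srate
  n <- dim(epochs$data)[2]
  n_ch <- dim(epochs$data)[1]
  n_ep <- dim(epochs$data)[3]
  kernels <- lapply(freqs, morlet_kernel, q = q, window_sigmas = window_sigmas,
                    srate = fs)
  lens <- lengths(kernels)
  too_long <- lens > n
  if (any(too_long))
    stop(sprintf("wavelet longer than epoch at %.2f Hz (%d > %d samples)",
                 freqs[which(too_long)[1]], lens[which(too_long)[1]], n))
  # valid, stride-sampled center positions per frequency (1-based samples)
  centers <- lapply(seq_along(freqs), function(fi) {
    half <- (lens[fi] - 1L) %/% 2L
    step <- max(1L, round((1 - overlap) * lens[fi]))
    if (n - half < half + 1L) integer(0) else seq(half + 1L, n - half, by = step)
  })
  nfft <- stats::nextn(n + max(lens) - 1L, 2)
  # cross-correlation kernel g[m] = Conj(psi[-m]), zero-padded to nfft
  kf <- lapply(seq_along(freqs), function(fi) {
    k <- kernels[[fi]]
    stats::fft(c(Conj(rev(k)), complex(real = numeric(nfft - lens[fi]))))
  })
  coeffs <- lapply(seq_along(freqs), function(fi)
    matrix(complex(real = 0), n_ch, length(centers[[fi]]) * n_ep))
  for (e in seq_len(n_ep)) {
    xe <- matrix(epochs$data[, , e], nrow = n_ch)
    xf <- stats::mvfft(rbind(t(xe), matrix(0, nfft - n, n_ch)))
    for (fi in seq_along(freqs)) {
      cs <- centers[[fi]]
      if (!length(cs)) next
      y <- stats::mvfft(xf * kf[[fi]], inverse = TRUE) / nfft
      # full-convolution index of center c is c + len - 1 - half
      half <- (lens[fi] - 1L) %/% 2L
      idx <- cs + lens[fi] - 1L - half
      coeffs[[fi]][, (e - 1L) * length(cs) + seq_along(cs)] <- t(y[idx, , drop = FALSE])
    }
  }
  structure(list(coeffs = coeffs, freqs = freqs, q = q,
                 epoch = lapply(seq_along(freqs), function(fi)
                   rep(seq_len(n_ep), each = length(centers[[fi]]))),
                 condition = epochs$condition, srate = fs,
                 channels = epochs$channels),
            class = "wavelet_coeffs")
}

#' Mean wavelet power by space, frequency and condition
#'
#' @param wc a [morlet_transform()] result.
#' @return numeric array space x frequency x condition of mean `|coeff|^2`.
#' @export
wavelet_power <- function(wc) {
  conds <- sort(unique(wc$condition))
  out <- array(NA_real_, c(length(wc$channels), length(wc$freqs), length(conds)),
               dimnames = list(wc$channels, NULL, conds))
  for (ci in seq_along(conds)) {
    ep_in <- which(wc$condition == conds[ci])
    for (fi in seq_along(wc$freqs)) {
      sel <- wc$epoch[[fi]] %in% ep_in
      out[, fi, ci] <- rowMeans(Mod(wc$coeffs[[fi]][, sel, drop = FALSE])^2)
    }
  }
  out
}

#' Relative power spectrum
#'
#' Normalizes mean wavelet power by the total power over the frequency grid,
#' separately for every space x condition cell, so relative values sum to one
#' across frequencies. This removes the depth-dependent amplitude bias of
#' beamformer source reconstructions.
#'
#' @param wc a [morlet_transform()] result.
#' @param weights `"uniform"` (default) sums power over the grid points;
#'   `"trapezoid"` integrates with trapezoidal weights in Hz.
#' @return a list of class `spectral_tensor` with `values`
#'   (space x frequency x condition), `freqs` and `kind = "relative"`.
#' @export
relative_power <- function(wc, weights = c("uniform", "trapezoid")) {
  weights <- match.arg(weights)
  p <- wavelet_power(wc)
  wt <- if (weights == "uniform") rep(1, length(wc$freqs)) else {
    f <- wc$freqs
    c(diff(f)[1] / 2, (diff(f)[-1] + diff(f)[-length(diff(f))]) / 2,
      diff(f)[length(f) - 1] / 2)
  }
  tot <- apply(sweep(p, 2, wt, "*"), c(1, 3), sum)
  if (any(tot <= 0)) stop("all-zero power in at least one space x condition cell")
  vals <- p
  for (ci in seq_len(dim(p)[3])) vals[, , ci] <- p[, , ci] / tot[, ci]
  structure(list(values = vals, freqs = wc$freqs, kind = "relative",
                 channels = wc$channels),
            class = "spectral_tensor")
}
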