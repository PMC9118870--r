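#' Design the band-pass FIR filter
#'
#' Linear-phase Hamming-window FIR band-pass design. The default order-2000
#' filter with a [1, 32] Hz passband matches the pipeline defaults used for
#' 1000 Hz data.
#'
#' @param lo,hi band edges in Hz.
#' @param order filter order (number of taps minus one). Must be even so the
#'   group delay is an integer number of samples.
#' @param srate sampling rate in Hz.
#' @return numeric vector of `order + 1` symmetric filter coefficients.
#' @export
design_bandpass_fir <- function(lo = 1, hi = 32, order = 2000, srate = 1000) {
  stopifnot(lo > 0, hi > lo, srate > 2 * hi, order %% 2 == 0)
  signal::fir1(order, c(lo, hi) / (srate / 2), type = "pass")
}

# internal: zero-phase FIR filtering of a channels x samples matrix by FFT
# convolution with compensation of the (order/2)-sample group delay.
fir_filter_zero_phase <- function(x, b) {
  n <- ncol(x)
  nb <- length(b)
  delay <- (nb - 1L) %/% 2L
  nfft <- stats::nextn(n + nb - 1L, 2)
  bf <- stats::fft(c(b, numeric(nfft - nb)))
  out <- matrix(0, nrow(x), n)
  for (ch in seq_len(nrow(x))) {
    xf <- stats::fft(c(x[ch, ], numeric(nfft - n)))
    y <- Re(stats::fft(xf * bf, inverse = TRUE)) / nfft
    out[ch, ] <- y[(delay + 1L):(delay + n)]
  }
  out
}

#' Band-pass filter a recording block by block
#'
#' Applies a zero-phase realization of a linear-phase FIR band-pass filter to
#' each resting-state block. Each block is padded at both edges before
#' filtering (with neighboring recording samples where available, mirror
#' reflection otherwise) and trimmed afterwards, so filter transients fall in
#' the padding.
#'
#' @param rec a [recording()].
#' @param lo,hi passband edges in Hz (defaults 1 and 32).
#' @param order FIR filter order (default 2000).
#' @param pad padding at each block edge in seconds (default 2).
#' @return the filtered `recording`.
#' @export
bandpass_fir <- function(rec, lo = 1, hi = 32, order = 2000, pad = 2) {
  stopifnot(inherits(rec, "recording"))
  fs <- rec$srate
  b <- design_bandpass_fir(lo, hi, order, fs)
  pad_n <- round(pad * fs)
  n <- ncol(rec$data)
  out <- rec$data
  for (k in seq_len(nrow(rec$blocks))) {
    blk <- rec$blocks[k, ]
    i0 <- round(blk$start * fs) + 1L
    i1 <- min(n, round((blk$start + blk$duration) * fs))
    blk_len <- i1 - i0 + 1L
    if (blk_len + 2L * pad_n < order + 1L)
      stop(sprintf("block %d (%s, %.1f s) too short for order-%d filter with %g s padding",
                   k, blk$condition, blk$duration, order, pad))
    # left context: real samples, mirror-extended if the recording edge is hit
    lctx <- rec$data[, max(1L, i0 - pad_n):(i0 - 1L), drop = FALSE]
    if (i0 == 1L) lctx <- rec$data[, integer(0), drop = FALSE]
    if (ncol(lctx) < pad_n) {
      need <- pad_n - ncol(lctx)
      seg <- rec$data[, i0:(i0 + need - 1L), drop = FALSE]
      lctx <- cbind(seg[, rev(seq_len(need)), drop = FALSE], lctx)
    }
    rctx <- if (i1 < n) rec$data[, (i1 + 1L):min(n, i1 + pad_n), drop = FALSE]
            else rec$data[, integer(0), drop = FALSE]
    if (ncol(rctx) < pad_n) {
      need <- pad_n - ncol(rctx)
      seg <- rec$data[, (i1 - need + 1L):i1, drop = FALSE]
      rctx <- cbind(rctx, seg[, rev(seq_len(need)), drop = FALSE])
    }
    xpad <- cbind(lctx, rec$data[, i0:i1, drop = FALSE], rctx)
    y <- fir_filter_zero_phase(xpad, b)
    out[, i0:i1] <- y[, (pad_n + 1L):(pad_n + blk_len), drop = FALSE]
  }
  recording(out, fs, rec$channels, rec$blocks)
}

#' Resample a recording
#'
#' Fourier-domain resampling: the spectrum is truncated (anti-aliasing) or
#' zero-extended to the target Nyquist and inverse-transformed at the new
#' length, preserving passband amplitudes essentially exactly. Duration is
#' preserved to within one sample at the target rate.
#'
#' @param rec a [recording()].
#' @param target target sampling rate in Hz (default 1000).
#' @return the resampled `recording`.
#' @export
resample_recording <- function(rec, target = 1000) {
  stopifnot(inherits(rec, "recording"), target > 0)
  if (target == rec$srate) return(rec)
  n <- ncol(rec$data)
  m <- round(n * target / rec$srate)
  out <- t(apply(rec$data, 1, .fft_resample, m = m))
  recording(out, target, rec$channels, rec$blocks)
}

# internal: FFT resampling of one vector to length m
.fft_resample <- function(x, m) {
  n <- length(x)
  xf <- stats::fft(x)
  yf <- complex(real = numeric(m))
  half <- min(n, m) %/% 2L
  yf[1:(half + 1L)] <- xf[1:(half + 1L)]
  if (half > 1L) yf[m - (1:(half - 1L)) + 1L] <- xf[n - (1:(half - 1L)) + 1L]
  # keep the result real: split any unpaired Nyquist bin energy
  if (min(n, m) %% 2L == 0L && half >= 1L) {
    yf[half + 1L] <- yf[half + 1L] / 2
    yf[m - half + 1L] <- Conj(yf[half + 1L])
  }
  # unnormalized inverse transform: divide by the original length so
  # passband amplitudes are preserved
  Re(stats::fft(yf, inverse = TRUE)) / n
}

#' Cut a recording into fixed-length epochs
#'
#' Non-overlapping epochs are tiled within each block, anchored at the block
#' start; a leftover tail shorter than one epoch is dropped. Epochs
#' intersecting any artifact-mask interval are skipped. Each epoch inherits
#' its block's condition label.
#'
#' @param rec a [recording()].
#' @param length epoch length in seconds (default 2.5).
#' @param artifact_mask optional data.frame with `onset` and `duration`
#'   columns (seconds) marking artifactual intervals.
#' @return an [epoch_set()]; zero clean epochs yields an empty set with a
#'   warning.
#' @export
epoch_recording <- function(rec, length = 2.5, artifact_mask = NULL) {
  stopifnot(inherits(rec, "recording"), length > 0)
  fs <- rec$srate
  len_n <- round(length * fs)
  starts <- numeric(0)
  conds <- character(0)
  for (k in seq_len(nrow(rec$blocks))) {
    blk <- rec$blocks[k, ]
    n_ep <- floor(blk$duration / length + 1e-9)
    if (n_ep < 1) next
    s <- blk$start + (seq_len(n_ep) - 1) * length
    starts <- c(starts, s)
    conds <- c(conds, rep(blk$condition, n_ep))
  }
  if (!is.null(artifact_mask) && nrow(artifact_mask) > 0) {
    keep <- vapply(starts, function(s) {
      !any(s < artifact_mask$onset + artifact_mask$duration &
             s + length > artifact_mask$onset)
    }, logical(1))
    starts <- starts[keep]
    conds <- conds[keep]
  }
  n_total <- ncol(rec$data)
  ok <- round(starts * fs) + len_n <= n_total
  starts <- starts[ok]; conds <- conds[ok]
  if (!length(starts)) {
    warning("no clean epochs")
    return(epoch_set(array(0, c(nrow(rec$data), len_n, 0)), character(0),
                     fs, rec$channels))
  }
  arr <- array(0, c(nrow(rec$data), len_n, base::length(starts)))
  for (e in seq_along(starts)) {
    i0 <- round(starts[e] * fs) + 1L
    arr[, , e] <- rec$data[, i0:(i0 + len_n - 1L)]
  }
  out <- epoch_set(arr, conds, fs, rec$channels)
  out$starts <- starts
  out
}

#' Re-reference epochs to the channel average
#'
#' Subtracts, at every sample, the instantaneous mean across channels, so the
#' per-sample channel mean of the output is zero. Idempotent.
#'
#' @param epochs an [epoch_set()].
#' @return the re-referenced `epoch_set`.
#' @export
average_reference <- function(epochs) {
  stopifnot(inherits(epochs, "epoch_set"), length(epochs$channels) >= 2)
  d <- epochs$data
  for (e in seq_len(dim(d)[3])) {
    m <- colMeans(d[, , e, drop = FALSE][, , 1])
    d[, , e] <- sweep(d[, , e], 2, m)
  }
  out <- epochs
  out$data <- d
  out
}

#' Size of the largest group of neighboring bad channels
#'
#' Computes the largest connected component of the bad channels in the channel
#' adjacency graph, the quantity entering the channel-based inclusion rule.
#'
#' @param bad logical vector (or channel-name vector) of bad channels.
#' @param adjacency symmetric logical/numeric channel adjacency matrix.
#' @return integer, size of the largest connected bad-channel component.
#' @export
max_adjacent_bad <- function(bad, adjacency) {
  if (is.character(bad)) bad <- rownames(adjacency) %in% bad
  stopifnot(length(bad) == nrow(adjacency))
  idx <- which(bad)
  if (!length(idx)) return(0L)
  adj <- adjacency[idx, idx, drop = FALSE] != 0
  seen <- rep(FALSE, length(idx))
  best <- 0L
  for (s in seq_along(idx)) {
    if (seen[s]) next
    comp <- s
    frontier <- s
    seen[s] <- TRUE
    while (length(frontier)) {
      nb <- which(colSums(adj[frontier, , drop = FALSE]) > 0 & !seen)
      seen[nb] <- TRUE
      comp <- c(comp, nb)
      frontier <- nb
    }
    best <- max(best, length(comp))
  }
  best
}

#' Subject-inclusion check
#'
#' Applies the three inclusion criteria: (1) at least 15 clean 2.5 s epochs in
#' each of the eyes-open and eyes-closed conditions; (2) at least 51 usable
#' channels and no more than 3 neighboring channels eliminated; (3) number of
#' good channels minus number of artifactual independent components at least
#' 35. Independent-component counting is manual upstream, so it enters as an
#' input.
#'
#' @param epochs an [epoch_set()] (only the per-condition epoch counts are
#'   used).
#' @param n_usable_channels number of usable channels.
#' @param max_adjacent_bad size of the largest group of neighboring eliminated
#'   channels (see [max_adjacent_bad()]).
#' @param n_artifact_ics number of artifactual independent components removed.
#' @param n_good_channels number of good channels.
#' @param min_epochs,min_usable,max_neighbors,min_good_minus_ics criterion
#'   thresholds (defaults 15, 51, 3, 35).
#' @return a list of class `quality_report` with the counts, the `included`
#'   flag and the `reasons` for exclusion (empty if included).
#' @export
inclusion_check <- function(epochs, n_usable_channels, max_adjacent_bad,
                            n_artifact_ics, n_good_channels,
                            min_epochs = 15, min_usable = 51,
                            max_neighbors = 3, min_good_minus_ics = 35) {
  cnt <- count_epochs(epochs)
  stopifnot(n_usable_channels >= 0, max_adjacent_bad >= 0,
            n_artifact_ics >= 0, n_good_channels >= 0)
  reasons <- character(0)
  if (min(cnt) < min_epochs) reasons <- c(reasons, "epochs")
  if (n_usable_channels < min_usable || max_adjacent_bad > max_neighbors)
    reasons <- c(reasons, "channels")
  if (n_good_channels - n_artifact_ics < min_good_minus_ics)
    reasons <- c(reasons, "components")
  structure(list(n_epochs_eo = unname(cnt["EO"]), n_epochs_ec = unname(cnt["EC"]),
                 n_usable_channels = n_usable_channels,
                 max_adjacent_bad = max_adjacent_bad,
                 n_good_minus_ics = n_good_channels - n_artifact_ics,
                 included = length(reasons) == 0L, reasons = reasons),
            class = "quality_report")
}
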