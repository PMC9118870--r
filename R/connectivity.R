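#' Unordered link index for a set of regions
#'
#' @param n_space number of regions (ROIs/channels).
#' @return data.frame with columns `i`, `j` (i < j), one row per link;
#'   `C(n, 2)` rows.
#' @export
link_table <- function(n_space) {
  idx <- which(upper.tri(matrix(0, n_space, n_space)), arr.ind = TRUE)
  data.frame(i = idx[, "row"], j = idx[, "col"])[order(idx[, "row"], idx[, "col"]), ]
}

#' Cross-spectral samples for one pair
#'
#' `X(n) = c_i(n) conj(c_j(n))` over all epoch-by-time coefficient samples at
#' one frequency.
#'
#' @param ci,cj complex coefficient vectors of equal length.
#' @return complex vector of cross-spectral samples.
#' @export
cross_spectra <- function(ci, cj) {
  stopifnot(length(ci) == length(cj))
  ci * Conj(cj)
}

#' Weighted phase lag index
#'
#' `|mean(Im X)| / mean(|Im X|)`, zero when the imaginary parts vanish (the
#' zero-lag convention). Insensitive to zero-lag (volume-conducted) coupling.
#'
#' @param x complex cross-spectral samples (at least 2).
#' @return value in [0, 1].
#' @export
wpli <- function(x) {
  stopifnot(length(x) >= 2)
  im <- Im(x)
  denom <- mean(abs(im))
  if (denom == 0) return(0)
  abs(mean(im)) / denom
}

#' Subsampled wPLI estimator
#'
#' Estimates wPLI on fixed-size subsets of epochs (15 by default), repeated
#' `n_reps` times with uniform sampling without replacement, and averages the
#' repetitions. Holding the epoch count fixed removes the sample-size bias of
#' the plain estimator, so subjects with different amounts of clean data are
#' comparable.
#'
#' @param x complex cross-spectral samples.
#' @param epoch integer epoch index per sample.
#' @param n_epochs epochs per draw (default 15).
#' @param n_reps number of repetitions (default 100).
#' @param seed integer seed.
#' @return averaged wPLI value.
#' @export
wpli_subsampled <- function(x, epoch, n_epochs = 15, n_reps = 100, seed = 1) {
  eps <- unique(epoch)
  if (length(eps) < n_epochs)
    stop(sprintf("only %d epochs available, %d required", length(eps), n_epochs))
  im <- Im(x)
  s_num <- rowsum(im, epoch)              # per-epoch sum of Im X
  s_den <- rowsum(abs(im), epoch)         # per-epoch sum of |Im X|
  set.seed(seed)
  vals <- vapply(seq_len(n_reps), function(r) {
    pick <- sample(length(eps), n_epochs)
    d <- sum(s_den[pick])
    if (d == 0) 0 else abs(sum(s_num[pick])) / d
  }, numeric(1))
  mean(vals)
}

#' Orthogonalized power correlation
#'
#' Per sample, the component of `c_j` orthogonal to `c_i` is
#' `Im(c_j conj(c_i) / |c_i|)`; the metric is the Pearson correlation of
#' `log |c_i|^2` with `log |y_orth|^2`, averaged over the two orthogonalization
#' directions. Removing the instantaneously shared (zero-lag) component makes
#' the envelope correlation robust to volume conduction; a signal is never
#' correlated with itself (self-orthogonalization gives zero).
#'
#' @param ci,cj complex coefficient vectors.
#' @param eps floor on the orthogonalized magnitude, relative to its largest
#'   value, guarding the logarithm (default 1e-12).
#' @return value in [-1, 1]; 0 (with attribute `degenerate`) when the
#'   orthogonalized residual vanishes.
#' @export
orth_pow_corr <- function(ci, cj, eps = 1e-12) {
  stopifnot(length(ci) == length(cj), length(ci) >= 3)
  one_dir <- function(a, b) {
    y <- Im(b * Conj(a) / Mod(a))
    m <- max(abs(y))
    if (m == 0) return(NA_real_)
    y2 <- pmax(abs(y), eps * m)
    stats::cor(log(Mod(a)^2), log(y2^2))
  }
  d1 <- one_dir(ci, cj)
  d2 <- one_dir(cj, ci)
  if (is.na(d1) && is.na(d2)) {
    out <- 0
    attr(out, "degenerate") <- TRUE
    return(out)
  }
  mean(c(d1, d2), na.rm = TRUE)
}

#' Control connectivity metrics
#'
#' Direct log-power envelope correlation (PowCorr), magnitude coherence
#' (COH), imaginary coherence (iCOH) and phase locking value (PLV) for one
#' pair at one frequency.
#'
#' @param ci,cj complex coefficient vectors.
#' @return named numeric vector `c(PowCorr, COH, iCOH, PLV)`.
#' @export
control_metrics <- function(ci, cj) {
  pi2 <- Mod(ci)^2
  pj2 <- Mod(cj)^2
  if (all(pi2 == 0) || all(pj2 == 0)) stop("zero-power series")
  x <- ci * Conj(cj)
  denom <- sqrt(mean(pi2) * mean(pj2))
  coherency <- mean(x) / denom
  xn <- x / Mod(x)
  xn[Mod(x) == 0] <- 0
  c(PowCorr = stats::cor(log(pmax(pi2, 1e-300)), log(pmax(pj2, 1e-300))),
    COH = Mod(coherency),
    iCOH = Im(coherency),
    PLV = Mod(mean(xn)))
}

#' Connectivity tensor over links, frequencies and conditions
#'
#' Computes the requested metrics from wavelet coefficients for every
#' unordered pair of spaces. Samples are pooled over epochs and time windows
#' within each condition; wPLI additionally uses the fixed-epoch-count
#' subsampled estimator.
#'
#' @param wc a [morlet_transform()] result (spaces are ROIs or channels).
#' @param metrics subset of `c("wPLI", "orthPowCorr", "PowCorr", "COH",
#'   "iCOH", "PLV")`.
#' @param wpli_epochs,wpli_reps subsampling parameters for wPLI (defaults 15
#'   and 100).
#' @param seed integer seed for the wPLI subsampling.
#' @return list of class `fc_tensor`: `values` (link x frequency x condition
#'   x metric array), `links` (the [link_table()]), `freqs`, `conditions`,
#'   `metrics`.
#' @export
fc_tensor <- function(wc, metrics = c("wPLI", "orthPowCorr"),
                      wpli_epochs = 15, wpli_reps = 100, seed = 1) {
  stopifnot(inherits(wc, "wavelet_coeffs"))
  metrics <- match.arg(metrics, c("wPLI", "orthPowCorr", "PowCorr", "COH",
                                  "iCOH", "PLV"), several.ok = TRUE)
  n_space <- length(wc$channels)
  links <- link_table(n_space)
  conds <- sort(unique(wc$condition))
  vals <- array(NA_real_, c(nrow(links), length(wc$freqs), length(conds),
                            length(metrics)),
                dimnames = list(NULL, NULL, conds, metrics))
  ctrl <- intersect(metrics, c("PowCorr", "COH", "iCOH", "PLV"))
  for (ci_ in seq_along(conds)) {
    ep_in <- which(wc$condition == conds[ci_])
    for (fi in seq_along(wc$freqs)) {
      sel <- wc$epoch[[fi]] %in% ep_in
      cf <- wc$coeffs[[fi]][, sel, drop = FALSE]
      epv <- wc$epoch[[fi]][sel]
      for (lk in seq_len(nrow(links))) {
        a <- cf[links$i[lk], ]
        b <- cf[links$j[lk], ]
        x <- a * Conj(b)
        if ("wPLI" %in% metrics)
          vals[lk, fi, ci_, "wPLI"] <- wpli_subsampled(
            x, epv, n_epochs = min(wpli_epochs, length(unique(epv))),
            n_reps = wpli_reps,
            seed = substream_seed(seed, lk * 1000L + fi * 10L + ci_))
        if ("orthPowCorr" %in% metrics)
          vals[lk, fi, ci_, "orthPowCorr"] <- orth_pow_corr(a, b)
        if (length(ctrl)) {
          cm <- control_metrics(a, b)
          for (m in ctrl) vals[lk, fi, ci_, m] <- cm[[m]]
        }
      }
    }
  }
  structure(list(values = vals, links = links, freqs = wc$freqs,
                 conditions = conds, metrics = metrics),
            class = "fc_tensor")
}
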