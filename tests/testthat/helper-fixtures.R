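# shared miniature fixtures, all generated in code

fs_test <- 250

make_sine_recording <- function(freqs, amps = rep(1, length(freqs)),
                                n_chan = 2, dur = 60, srate = fs_test,
                                dc = 0) {
  t <- (seq_len(dur * srate) - 1) / srate
  x <- rowSums(vapply(seq_along(freqs),
                      function(k) amps[k] * sin(2 * pi * freqs[k] * t),
                      numeric(length(t)))) + dc
  blocks <- data.frame(condition = c("EO", "EC"),
                       start = c(0, dur / 2), duration = dur / 2)
  recording(matrix(rep(x, each = n_chan), n_chan), srate,
            paste0("ch", seq_len(n_chan)), blocks)
}

make_noise_epochs <- function(n_ch = 1, n_ep = 10, len = 2.5, srate = fs_test,
                              cond = rep(c("EO", "EC"), length.out = n_ep),
                              seed = 1) {
  set.seed(seed)
  ns <- round(len * srate)
  epoch_set(array(rnorm(n_ch * ns * n_ep), c(n_ch, ns, n_ep)), cond, srate,
            paste0("ch", seq_len(n_ch)))
}

# occipital-complete psd object from an analytic spectral shape
make_analytic_psd <- function(shape_fun, fmax = 30, df = 0.4, cond = "EC") {
  f <- seq(df, fmax, by = df)
  p <- shape_fun(f)
  structure(list(power = matrix(rep(p, 6), 6, byrow = TRUE), freqs = f,
                 condition = cond,
                 channels = c("O1", "O2", "Oz", "PO4", "PO3", "POz")),
            class = "psd")
}

# small covariate table without running the full generator
make_meta <- function(n_per_group = 30, n_sites = 3, seed = 1) {
  set.seed(seed)
  n <- 2 * n_per_group
  data.frame(id = sprintf("S%03d", 1:n),
             group = rep(c("ASD", "NT"), each = n_per_group),
             age = runif(n, 6, 32),
             sex = ifelse(runif(n) < 0.72, "M", "F"),
             iq = 106 + 14 * rnorm(n),
             site = rep_len(paste0("site", seq_len(n_sites)), n),
             medication = FALSE, stringsAsFactors = FALSE)
}
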