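#!/usr/bin/env Rscript
# Stage 4: source projection, spectra and connectivity features.
#
# Per subject: LCMV common filter from the pooled sensor covariance, ROI
# first principal components, Morlet decomposition on the 27-point grid,
# relative power per ROI, and the subsampled wPLI tensor over all ROI links.
# Writes the per-subject feature matrices used by the group statistics.

suppressMessages(library(resteeg))
dir.create("results", showWarnings = FALSE)

seed <- 1
cfg <- demo_config(seed = seed, n_per_group = 20)
cohort <- generate_cohort(cfg$spec, leadfield = cfg$leadfield)
n <- nrow(cohort$meta)
n_freq <- length(morlet_grid())

fc_ec <- NULL
ps_rel <- NULL
for (i in seq_len(n)) {
  rec <- cohort$recordings[[i]]
  rec$channels <- cfg$sensor_names
  rec <- bandpass_fir(rec, 1, 32, order = 500, pad = 2)
  ep <- average_reference(epoch_recording(rec, 2.5))
  flt <- lcmv_filters(sensor_covariance(ep), cfg$leadfield)
  roi_ep <- roi_epochs(apply_lcmv(ep, flt), cfg$rois)
  wc <- morlet_transform(roi_ep)
  rp <- relative_power(wc)
  fc <- fc_tensor(wc, metrics = "wPLI", wpli_reps = 20,
                  seed = substream_seed(seed, i))
  if (is.null(fc_ec)) {
    fc_ec <- matrix(0, n, nrow(fc$links) * n_freq)
    ps_rel <- matrix(0, n, length(cfg$rois$sizes) * n_freq * 2)
  }
  fc_ec[i, ] <- as.vector(t(fc$values[, , "EC", "wPLI"]))
  ps_rel[i, ] <- as.vector(rp$values)
  cohort$recordings[[i]] <- NA
}
write.table(cbind(id = cohort$meta$id, as.data.frame(fc_ec)),
            "results/fc_wpli_ec.tsv", sep = "\t", row.names = FALSE,
            quote = FALSE)
write.table(cbind(id = cohort$meta$id, as.data.frame(ps_rel)),
            "results/ps_relative.tsv", sep = "\t", row.names = FALSE,
            quote = FALSE)
cat(sprintf("features per subject: %d wPLI link-frequency (EC), %d relative-power\n",
            ncol(fc_ec), ncol(ps_rel)))
cat(sprintf("full-scale identities: 365 x %d x 2 = %d PS features, C(50,2) x %d x 2 = %d FC features\n",
            n_freq, 365 * n_freq * 2, n_freq, nrow(link_table(50)) * n_freq * 2))
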