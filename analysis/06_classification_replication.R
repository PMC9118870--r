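#!/usr/bin/env Rscript
# Stage 6: multivariate classification and replication statistics.
#
# Residualizes the wPLI features against age/sex/IQ/site, reduces them to
# principal components covering 98% of the variance, evaluates the linear
# SVC and elastic net over repeated stratified splits with label-permutation
# significance, and computes the train/validation machinery: stratified
# split, effect-size prediction intervals and power.

suppressMessages(library(resteeg))
dir.create("results", showWarnings = FALSE)

seed <- 1
cfg <- demo_config(seed = seed, n_per_group = 20)
meta <- generate_subject_meta(cfg$spec)
fc <- read.table("results/fc_wpli_ec.tsv", sep = "\t", header = TRUE)
y <- as.matrix(fc[, -1])^0.11

pc <- pca_reduce(residualize(y, meta), 0.98)
cat(sprintf("PCA: %d components for 98%% variance (of %d features)\n",
            pc$k, ncol(y)))

labels <- as.integer(meta$group == "ASD")
lines <- list()
for (mid in c("linsvc", "enet")) {
  ps <- permutation_significance(pc$scores, labels, mid, n_perm = 100,
                                 n_splits = 8,
                                 grid = default_grids()[[mid]][c(3, 4), ,
                                                               drop = FALSE],
                                 inner_folds = 5, seed = seed)
  agg <- ps$report$aggregated
  cat(sprintf("%s: acc %.2f sens %.2f spec %.2f S1 %.2f, permutation p = %.3f\n",
              mid, agg[["acc"]], agg[["sens"]], agg[["spec"]], agg[["s1"]],
              ps$p))
  lines[[mid]] <- data.frame(model = mid, t(agg), p_perm = ps$p)
}
write.table(do.call(rbind, lines), "results/classification.tsv", sep = "\t",
            row.names = FALSE, quote = FALSE)

# train/validation split machinery at the study's sample sizes
sp <- stratified_split(meta, 0.7, seed = seed)
cat(sprintf("split: %d train / %d validation\n",
            sum(sp$assignment == "train"), sum(sp$assignment == "validation")))
pi_r <- prediction_interval_r(0.10, 183, 212)
cat(sprintf("replication PI for r = 0.10 (183 -> 212): [%.2f, %.2f]\n",
            pi_r$lo, pi_r$hi))
pw <- power_twosample(0.5, 65, 59)
cat(sprintf("two-sample power for d = 0.5 at validation sizes (65/59): %.2f\n",
            pw))
jsonlite::write_json(
  list(split_train = sum(sp$assignment == "train"),
       split_validation = sum(sp$assignment == "validation"),
       pi_r010 = c(pi_r$lo, pi_r$hi), power_d05_validation = pw),
  "results/replication.json", auto_unbox = TRUE, digits = NA)
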