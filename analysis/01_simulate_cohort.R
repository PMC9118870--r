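#!/usr/bin/env Rscript
# Stage 1: generate the synthetic study cohort.
#
# Builds the demo head model (32 sensors, 60 sources on a mirror-symmetric
# 1.5 cm grid, 10 ROIs), the cohort specification (40 subjects, a
# group-by-age interaction on alpha reactivity, one ASD-only coupled
# interhemispheric source pair at 10 Hz), and writes the covariate table,
# the cohort specification and one example recording to results/.

suppressMessages(library(resteeg))
dir.create("results", showWarnings = FALSE)

seed <- 1
cfg <- demo_config(seed = seed, n_per_group = 20)
meta <- generate_subject_meta(cfg$spec)

write_covariates_tsv(meta, "results/covariates.tsv")
write_cohort_spec_yaml(cfg$spec, "results/cohort_spec.yaml")

rec <- generate_recording(meta[1, ], cfg$spec, 1, leadfield = cfg$leadfield)
rec$channels <- cfg$sensor_names
# a 10 s excerpt is enough to illustrate the format
excerpt <- recording(rec$data[, 1:(10 * rec$srate)], rec$srate, rec$channels,
                     data.frame(condition = "EO", start = 0, duration = 10))
write_recording_tsv(excerpt, "results/example_recording.tsv")

cat(sprintf("cohort: %d subjects (%d ASD / %d NT), %d sites\n",
            nrow(meta), sum(meta$group == "ASD"), sum(meta$group == "NT"),
            length(unique(meta$site))))
cat(sprintf("age %.1f-%.1f y, %.0f%% male, IQ %.0f +/- %.0f\n",
            min(meta$age), max(meta$age), 100 * mean(meta$sex == "M"),
            mean(meta$iq), sd(meta$iq)))
cat(sprintf("injected: ROI link %d-%d (sources %d/%d) at %g Hz, ASD only;\n",
            cfg$injected$link[1], cfg$injected$link[2],
            cfg$injected$sources[1], cfg$injected$sources[2],
            cfg$injected$freq))
cat(sprintf("reactivity age slopes: ASD %.3f, NT %.3f per year\n",
            cfg$spec$age_slope_by_group[["ASD"]],
            cfg$spec$age_slope_by_group[["NT"]]))
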