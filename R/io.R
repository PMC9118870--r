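#' Write / read a recording as plain text
#'
#' The data matrix goes to a TSV (channels as columns, samples as rows); the
#' sampling rate, channel order and block annotations go to a JSON sidecar
#' (`<path>.meta.json`).
#'
#' @param rec a [recording()].
#' @param path TSV file path.
#' @return `path`, invisibly.
#' @export
write_recording_tsv <- function(rec, path) {
  stopifnot(inherits(rec, "recording"))
  df <- as.data.frame(t(rec$data))
  names(df) <- rec$channels
  utils::write.table(df, path, sep = "\t", row.names = FALSE, quote = FALSE)
  meta <- list(srate = rec$srate, channels = rec$channels,
               blocks = rec$blocks)
  jsonlite::write_json(meta, paste0(path, ".meta.json"), auto_unbox = TRUE,
                       digits = NA)
  invisible(path)
}

#' @rdname write_recording_tsv
#' @export
read_recording_tsv <- function(path) {
  meta <- jsonlite::read_json(paste0(path, ".meta.json"), simplifyVector = TRUE)
  df <- utils::read.table(path, sep = "\t", header = TRUE, check.names = FALSE)
  recording(unname(t(as.matrix(df))), meta$srate, meta$channels,
            as.data.frame(meta$blocks))
}

#' Write subject covariates as TSV
#'
#' Columns: id, group, age, sex, iq, site, medication.
#'
#' @param meta covariate data.frame.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_covariates_tsv <- function(meta, path) {
  utils::write.table(meta, path, sep = "\t", row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Serialize / restore a cohort specification as YAML
#'
#' @param spec a [cohort_spec()].
#' @param path YAML file path.
#' @return `path` invisibly; `read_cohort_spec_yaml` returns the
#'   `cohort_spec`.
#' @export
write_cohort_spec_yaml <- function(spec, path) {
  stopifnot(inherits(spec, "cohort_spec"))
  lst <- unclass(spec)
  if (!is.null(lst$coupling_plan)) lst$coupling_plan <- as.list(lst$coupling_plan)
  # named vectors must become maps, not sequences
  lst$age_slope_by_group <- as.list(lst$age_slope_by_group)
  lst$site_offsets <- as.list(lst$site_offsets)
  yaml::write_yaml(lst, path, precision = 15)
  invisible(path)
}

#' @rdname write_cohort_spec_yaml
#' @export
read_cohort_spec_yaml <- function(path) {
  lst <- yaml::read_yaml(path)
  if (!is.null(lst$coupling_plan))
    lst$coupling_plan <- as.data.frame(lst$coupling_plan)
  for (nm in c("age_slope_by_group", "site_offsets"))
    lst[[nm]] <- unlist(lst[[nm]])
  do.call(cohort_spec, lst)
}

#' Write a quality report as JSON
#'
#' @param report an [inclusion_check()] result (or a list of them).
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_quality_json <- function(report, path) {
  jsonlite::write_json(unclass(report), path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}
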