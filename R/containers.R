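#' Construct a multichannel EEG recording
#'
#' A `recording` bundles a channels x samples data matrix (in microvolts), the
#' sampling rate, ordered channel labels and the block structure of the
#' resting-state session (alternating eyes-open / eyes-closed blocks).
#'
#' @param data numeric matrix, channels x samples, microvolts.
#' @param srate sampling rate in Hz.
#' @param channels character vector of channel labels, one per row of `data`.
#' @param blocks data.frame with columns `condition` ("EO"/"EC"), `start`
#'   (seconds from recording onset) and `duration` (seconds). Blocks must not
#'   overlap.
#' @return an object of class `recording`.
#' @export
recording <- function(data, srate, channels, blocks) {
  data <- as.matrix(data)
  stopifnot(is.numeric(data), srate > 0, nrow(data) == length(channels))
  blocks <- as.data.frame(blocks)
  stopifnot(all(c("condition", "start", "duration") %in% names(blocks)))
  stopifnot(all(blocks$condition %in% c("EO", "EC")), all(blocks$duration > 0))
  o <- order(blocks$start)
  blocks <- blocks[o, , drop = FALSE]
  if (nrow(blocks) > 1) {
    ends <- blocks$start[-nrow(blocks)] + blocks$duration[-nrow(blocks)]
    if (any(ends > blocks$start[-1] + 1e-9)) stop("blocks overlap")
  }
  rownames(blocks) <- NULL
  structure(list(data = data, srate = srate,
                 channels = as.character(channels), blocks = blocks),
            class = "recording")
}

#' @export
print.recording <- function(x, ...) {
  cat(sprintf("<recording> %d channels x %d samples @ %g Hz, %d blocks (%s)\n",
              nrow(x$data), ncol(x$data), x$srate, nrow(x$blocks),
              paste(x$blocks$condition, collapse = "/")))
  invisible(x)
}

#' Construct an epoch set
#'
#' Fixed-length epochs cut from a recording. Data are stored as a
#' channels x samples x epochs array; each epoch carries the condition label
#' of the block it was cut from.
#'
#' @param data numeric array, channels x samples x epochs, microvolts.
#' @param condition character vector ("EO"/"EC"), one entry per epoch.
#' @param srate sampling rate in Hz.
#' @param channels channel labels.
#' @return an object of class `epoch_set`.
#' @export
epoch_set <- function(data, condition, srate, channels) {
  stopifnot(length(dim(data)) == 3, dim(data)[3] == length(condition),
            dim(data)[1] == length(channels), srate > 0)
  structure(list(data = data, condition = as.character(condition),
                 srate = srate, channels = as.character(channels),
                 epoch_length = dim(data)[2] / srate),
            class = "epoch_set")
}

#' @export
print.epoch_set <- function(x, ...) {
  cat(sprintf("<epoch_set> %d epochs (%d EO, %d EC) x %d channels x %g s @ %g Hz\n",
              length(x$condition), sum(x$condition == "EO"),
              sum(x$condition == "EC"), length(x$channels),
              x$epoch_length, x$srate))
  invisible(x)
}

#' Subset an epoch set by condition or epoch index
#'
#' @param epochs an `epoch_set`.
#' @param condition optional condition label ("EO" or "EC") to keep.
#' @param idx optional integer vector of epoch indices to keep.
#' @return an `epoch_set` with the selected epochs.
#' @export
subset_epochs <- function(epochs, condition = NULL, idx = NULL) {
  keep <- seq_along(epochs$condition)
  if (!is.null(condition)) keep <- keep[epochs$condition[keep] %in% condition]
  if (!is.null(idx)) keep <- intersect(keep, idx)
  epoch_set(epochs$data[, , keep, drop = FALSE], epochs$condition[keep],
            epochs$srate, epochs$channels)
}

#' Number of epochs per condition
#' @param epochs an `epoch_set`.
#' @return named integer vector with counts for EO and EC.
#' @export
count_epochs <- function(epochs) {
  c(EO = sum(epochs$condition == "EO"), EC = sum(epochs$condition == "EC"))
}

#' Derive a bounded per-stream seed from a base seed and an index
#'
#' Keeps all derived seeds well inside the 32-bit integer range so one master
#' seed can drive independent substreams (per subject, per repetition).
#'
#' @param seed integer master seed.
#' @param index non-negative stream index.
#' @return integer seed.
#' @export
substream_seed <- function(seed, index) {
  (as.integer(seed) %% 1000003L) * 2011L + as.integer(index) * 7919L
}
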