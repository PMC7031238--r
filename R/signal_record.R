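#' Multichannel biosignal record
#'
#' Container for a synchronous multichannel recording: a channel-by-time
#' numeric matrix, the sampling rate, per-channel metadata (label, role,
#' units) and an append-only processing history. Channel roles follow the
#' walking-experiment montage: `eeg` (monopolar scalp channels),
#' `eeg_bipolar` (derived differential channels), `emg`, `emg_rect`,
#' `emg_demod`, and `footswitch`.
#'
#' @param samples Numeric matrix, channels in rows, samples in columns.
#' @param sample_rate_hz Sampling rate in Hz.
#' @param channels `data.frame` with columns `label`, `role`, `units`,
#'   one row per matrix row.
#' @param history Character vector of processing-step descriptors.
#' @return An object of class `signal_record`.
#' @export
signal_record <- function(samples, sample_rate_hz, channels,
                          history = character()) {
  samples <- as.matrix(samples)
  stopifnot(
    is.numeric(samples),
    is.numeric(sample_rate_hz), length(sample_rate_hz) == 1L,
    sample_rate_hz > 0,
    is.data.frame(channels),
    all(c("label", "role", "units") %in% names(channels)),
    nrow(channels) == nrow(samples),
    !anyDuplicated(channels$label)
  )
  rownames(samples) <- channels$label
  structure(
    list(
      samples = samples,
      sample_rate_hz = sample_rate_hz,
      channels = channels,
      history = as.character(history)
    ),
    class = "signal_record"
  )
}

#' @export
print.signal_record <- function(x, ...) {
  cat(sprintf(
    "<signal_record> %d channels x %d samples @ %g Hz (%.1f s)\n",
    nrow(x$samples), ncol(x$samples), x$sample_rate_hz,
    ncol(x$samples) / x$sample_rate_hz
  ))
  roles <- table(x$channels$role)
  cat("  roles:", paste(sprintf("%s=%d", names(roles), roles), collapse = ", "), "\n")
  if (length(x$history)) {
    cat("  history:\n")
    for (h in x$history) cat("   -", h, "\n")
  }
  invisible(x)
}

# Row indices of channels by role and/or label; errors on missing labels.
channel_index <- function(record, roles = NULL, labels = NULL) {
  idx <- seq_len(nrow(record$channels))
  if (!is.null(roles)) idx <- idx[record$channels$role[idx] %in% roles]
  if (!is.null(labels)) {
    miss <- setdiff(labels, record$channels$label)
    if (length(miss)) {
      stop("channel label(s) not found in record: ", paste(miss, collapse = ", "))
    }
    idx <- idx[record$channels$label[idx] %in% labels]
    idx <- idx[match(labels, record$channels$label[idx])]
  }
  idx
}

#' Extract one channel as a numeric vector
#'
#' @param record A [signal_record].
#' @param label Channel label.
#' @return Numeric vector of samples.
#' @export
get_channel <- function(record, label) {
  record$samples[channel_index(record, labels = label), ]
}

add_history <- function(record, step) {
  record$history <- c(record$history, step)
  record
}

#' Write a record as a TSV matrix with a JSON metadata sidecar
#'
#' The TSV holds one column per channel (header = channel labels) and one
#' row per sample; the sidecar (`<path>.json`) records channel labels,
#' roles, units, sampling rate and processing history.
#'
#' @param record A [signal_record].
#' @param path Path of the TSV file to write.
#' @return `path`, invisibly.
#' @export
write_record <- function(record, path) {
  sidecar <- paste0(path, ".json")
  ok <- tryCatch({
    utils::write.table(
      t(record$samples), file = path, sep = "\t",
      row.names = FALSE, col.names = record$channels$label, quote = FALSE
    )
    jsonlite::write_json(
      list(
        sample_rate_hz = record$sample_rate_hz,
        channels = record$channels,
        history = record$history
      ),
      sidecar, auto_unbox = TRUE, digits = NA
    )
    TRUE
  }, error = function(e) e)
  if (!isTRUE(ok)) {
    stop("failed to write record to '", path, "': ", conditionMessage(ok))
  }
  invisible(path)
}

#' Read a record written by [write_record()]
#'
#' @param path Path of the TSV file (sidecar expected at `<path>.json`).
#' @return A [signal_record].
#' @export
read_record <- function(path) {
  sidecar <- paste0(path, ".json")
  if (!file.exists(path) || !file.exists(sidecar)) {
    stop("record files not found: ", path, " (+ .json sidecar)")
  }
  meta <- jsonlite::read_json(sidecar, simplifyVector = TRUE)
  mat <- as.matrix(utils::read.table(path, header = TRUE, sep = "\t",
                                     check.names = FALSE))
  signal_record(
    samples = t(mat),
    sample_rate_hz = meta$sample_rate_hz,
    channels = as.data.frame(meta$channels),
    history = meta$history
  )
}
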