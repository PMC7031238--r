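#' Normalise channels to unit variance
#'
#' Divides each selected channel by its standard deviation so that signals
#' of different gain enter the spectral estimators on a common scale.
#'
#' @param record A [signal_record].
#' @param roles Channel roles to normalise (default EEG and EMG).
#' @return The updated record, with the per-channel divisors recorded in
#'   the processing history.
#' @export
normalize_variance <- function(record, roles = c("eeg", "emg")) {
  idx <- channel_index(record, roles = roles)
  for (i in idx) {
    s <- stats::sd(record$samples[i, ])
    if (!is.finite(s) || s == 0) {
      stop("zero-variance channel cannot be normalized: ",
           record$channels$label[i])
    }
    record$samples[i, ] <- record$samples[i, ] / s
  }
  add_history(record, sprintf("normalize_variance(roles=%s)",
                              paste(roles, collapse = "+")))
}

# zero-phase Butterworth application to a set of rows
filtfilt_rows <- function(record, idx, filt, pad) {
  for (i in idx) {
    record$samples[i, ] <- zero_phase(filt, record$samples[i, ], pad = pad)
  }
  record
}

#' Band-pass filter the EEG channels
#'
#' Zero-phase (forward-backward) 2nd-order Butterworth band-pass, default
#' 0.5-70 Hz, applied to channels with role `eeg`. Zero-phase application
#' preserves event-locked latencies.
#'
#' @param record A [signal_record].
#' @param low,high Band edges in Hz.
#' @param order Butterworth order of the underlying one-pass design.
#' @return The filtered record.
#' @export
filter_eeg <- function(record, low = 0.5, high = 70, order = 2) {
  fs <- record$sample_rate_hz
  if (fs <= 2 * high) {
    stop("sampling rate must exceed twice the upper band edge (", 2 * high, " Hz)")
  }
  idx <- channel_index(record, roles = "eeg")
  if (!length(idx)) stop("no EEG channels in record")
  filt <- signal::butter(order, c(low, high) / (fs / 2), type = "pass")
  # pad a few time constants of the slow (high-pass) corner per edge
  record <- filtfilt_rows(record, idx, filt, pad = round(3 * fs / low))
  add_history(record, sprintf("filter_eeg(%g-%g Hz, order %d, zero-phase)",
                              low, high, order))
}

#' Re-reference EEG to the common average
#'
#' Subtracts the per-sample mean across all channels with role `eeg` from
#' each of those channels; other roles are untouched.
#'
#' @param record A [signal_record].
#' @return The re-referenced record.
#' @export
rereference_car <- function(record) {
  idx <- channel_index(record, roles = "eeg")
  if (length(idx) < 2L) stop("common average reference needs >= 2 EEG channels")
  avg <- colMeans(record$samples[idx, , drop = FALSE])
  record$samples[idx, ] <- sweep(record$samples[idx, , drop = FALSE], 2, avg)
  add_history(record, "rereference_car")
}

#' Derive bipolar EEG channels
#'
#' Appends anode-minus-cathode difference channels (role `eeg_bipolar`).
#' A differential derivation suppresses far-field sources common to both
#' electrodes and is most sensitive to activity generated between them;
#' the sensorimotor pairs are C3-F3 (left hemisphere) and C4-F4 (right).
#'
#' @param record A [signal_record].
#' @param pairs Data frame with columns `anode`, `cathode` and optional
#'   `label` (default `"<anode>-<cathode>"`). Defaults to the two
#'   sensorimotor pairs.
#' @return The record with derived channels appended.
#' @export
bipolar_derive <- function(record,
                           pairs = data.frame(anode = c("C3", "C4"),
                                              cathode = c("F3", "F4"))) {
  if (is.null(pairs$label)) pairs$label <- paste0(pairs$anode, "-", pairs$cathode)
  for (k in seq_len(nrow(pairs))) {
    a <- get_channel(record, pairs$anode[k])
    c <- get_channel(record, pairs$cathode[k])
    record$samples <- rbind(record$samples, a - c)
    rownames(record$samples)[nrow(record$samples)] <- pairs$label[k]
    record$channels <- rbind(
      record$channels,
      data.frame(label = pairs$label[k], role = "eeg_bipolar", units =
                   record$channels$units[channel_index(record, labels = pairs$anode[k])])
    )
  }
  add_history(record, sprintf("bipolar_derive(%s)",
                              paste(pairs$label, collapse = ", ")))
}

#' Rectify and demodulate the EMG channels
#'
#' For every channel with role `emg` two derived channels are appended:
#'
#' * `<label>_rect` (role `emg_rect`): the Hilbert envelope, i.e. the
#'   modulus of the analytic signal of the zero-phase 20-Hz high-passed
#'   EMG. Used for envelope analysis and EMG power.
#' * `<label>_demod` (role `emg_demod`): the amplitude-demodulated signal,
#'   the real part of the analytic signal of the mean-subtracted rectified
#'   EMG divided by its instantaneous amplitude (floored at
#'   `eps_rel * median amplitude`). Instantaneous amplitude becomes ~1
#'   while instantaneous phase is preserved, removing the periodic
#'   amplitude modulation that would otherwise distort coherence
#'   estimates. Used for coherence and EMG inter-trial coherence.
#'
#' Mean subtraction precedes demodulation because the analytic phase of a
#' strictly positive signal is degenerate.
#'
#' @param record A [signal_record].
#' @param highpass_hz High-pass cut-off (default 20 Hz).
#' @param order Butterworth order of the high-pass (default 4).
#' @param eps_rel Relative demodulation floor (default 1e-8 of the median
#'   instantaneous amplitude).
#' @return The record with rectified and demodulated channels appended.
#' @export
preprocess_emg <- function(record, highpass_hz = 20, order = 4,
                           eps_rel = 1e-8) {
  fs <- record$sample_rate_hz
  idx <- channel_index(record, roles = "emg")
  if (!length(idx)) stop("no EMG channels in record")
  hp <- signal::butter(order, highpass_hz / (fs / 2), type = "high")
  notes <- character()
  for (i in idx) {
    lab <- record$channels$label[i]
    x <- zero_phase(hp, record$samples[i, ], pad = fs)
    rect <- Mod(analytic_signal(x))
    z <- analytic_signal(rect - mean(rect))
    amp <- Mod(z)
    eps <- eps_rel * stats::median(amp)
    frac_low <- mean(amp < eps)
    if (frac_low > 0.01) {
      notes <- c(notes, sprintf(
        "warning: %s instantaneous amplitude below floor on %.1f%% of samples",
        lab, 100 * frac_low))
    }
    demod <- Re(z) / pmax(amp, eps)
    record$samples <- rbind(record$samples, rect, demod)
    nr <- nrow(record$samples)
    rownames(record$samples)[c(nr - 1L, nr)] <- paste0(lab, c("_rect", "_demod"))
    record$channels <- rbind(
      record$channels,
      data.frame(label = paste0(lab, c("_rect", "_demod")),
                 role = c("emg_rect", "emg_demod"),
                 units = c(record$channels$units[i], "a.u."))
    )
  }
  record <- add_history(record, sprintf(
    "preprocess_emg(highpass %g Hz order %d, Hilbert rectification + demodulation)",
    highpass_hz, order))
  for (nt in notes) record <- add_history(record, nt)
  record
}

#' Reject epochs containing high-amplitude EEG artefacts
#'
#' Removes epochs in which any EEG-role sample exceeds the amplitude
#' threshold (default 300 microvolt, the movement-artefact magnitude this
#' screen targets). Must be applied to epochs cut from data still in
#' physical units (before unit-variance normalisation).
#'
#' @param epochs An [epoch_set].
#' @param amplitude_threshold_uv Rejection threshold in microvolt.
#' @return List with `epochs` (surviving [epoch_set]) and `report`
#'   (data frame: epoch index, heel-strike time, peak EEG amplitude,
#'   rejected flag) plus the rejected fraction as attribute `fraction`.
#' @export
reject_epochs <- function(epochs, amplitude_threshold_uv = 300) {
  eeg_ch <- which(epochs$channels$role %in% c("eeg", "eeg_bipolar"))
  if (!length(eeg_ch)) stop("epoch set contains no EEG channels")
  L <- epochs$L
  peak <- vapply(seq_len(L), function(k) {
    max(abs(epochs$data[k, eeg_ch, , drop = FALSE]))
  }, numeric(1))
  rejected <- peak > amplitude_threshold_uv
  if (all(rejected)) {
    stop("all epochs exceed ", amplitude_threshold_uv,
         " uV; review the amplitude threshold")
  }
  report <- data.frame(
    epoch = seq_len(L),
    heel_strike_s = epochs$hs_times,
    peak_uv = peak,
    rejected = rejected
  )
  attr(report, "fraction") <- mean(rejected)
  list(epochs = subset_epochs(epochs, !rejected), report = report)
}
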