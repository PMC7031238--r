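#' Frequency bands of the band/window analysis
#'
#' @param low_beta_hi Upper edge of the lower beta band in Hz (default 20;
#'   set 21 to use the wider convention).
#' @return Data frame with columns `band`, `f_lo`, `f_hi` (closed
#'   intervals, Hz): theta 4-7, alpha 8-12, low_beta 13-20, high_beta
#'   21-30, gamma 31-45.
#' @export
band_table <- function(low_beta_hi = 20) {
  data.frame(
    band = c("theta", "alpha", "low_beta", "high_beta", "gamma"),
    f_lo = c(4, 8, 13, 21, 31),
    f_hi = c(7, 12, low_beta_hi, 30, 45)
  )
}

#' Heel-strike-aligned epoch set
#'
#' Trial x channel x time array cut around valid heel strikes of one foot,
#' window `[-0.8, +0.2)` s by default with heel strike at t = 0.
#'
#' @param record A [signal_record].
#' @param events An [event_series].
#' @param ref_foot Foot whose heel strikes define t = 0.
#' @param channels Channel labels to keep (default: all).
#' @param max_epochs Keep at most this many valid epochs, in temporal
#'   order (default 220).
#' @param window Epoch window in seconds relative to heel strike,
#'   half-open `[w1, w2)`.
#' @return An object of class `epoch_set`: list with `data` (L x channel x
#'   time array), `t` (time grid, s), `fs`, `channels` (metadata),
#'   `L`, `ref_foot`, `hs_times`.
#' @export
epoch_signals <- function(record, events, ref_foot = c("left", "right"),
                          channels = NULL, max_epochs = 220,
                          window = c(-0.8, 0.2)) {
  ref_foot <- match.arg(ref_foot)
  fs <- record$sample_rate_hz
  nwin <- round(diff(window) * fs)
  n_rec <- ncol(record$samples)
  foot <- events[[ref_foot]]
  hs <- foot$heel_strikes[foot$valid]
  start <- round(hs * fs) + round(window[1] * fs) + 1L
  ok <- start >= 1L & (start + nwin - 1L) <= n_rec
  hs <- hs[ok]; start <- start[ok]
  if (!length(hs)) stop("no heel strike with a complete epoch window inside the record")
  if (length(hs) > max_epochs) {
    hs <- hs[seq_len(max_epochs)]
    start <- start[seq_len(max_epochs)]
  }
  chan_idx <- if (is.null(channels)) {
    seq_len(nrow(record$channels))
  } else {
    channel_index(record, labels = channels)
  }
  L <- length(hs)
  data <- array(NA_real_, dim = c(L, length(chan_idx), nwin))
  for (k in seq_len(L)) {
    data[k, , ] <- record$samples[chan_idx, start[k]:(start[k] + nwin - 1L)]
  }
  structure(
    list(
      data = data,
      t = window[1] + (seq_len(nwin) - 1L) / fs,
      fs = fs,
      channels = record$channels[chan_idx, , drop = FALSE],
      L = L,
      ref_foot = ref_foot,
      hs_times = hs,
      window = window
    ),
    class = "epoch_set"
  )
}

#' Keep a subset of epochs
#'
#' @param epochs An [epoch_set].
#' @param keep Logical or integer index over trials.
#' @return The reduced [epoch_set].
#' @export
subset_epochs <- function(epochs, keep) {
  epochs$data <- epochs$data[keep, , , drop = FALSE]
  epochs$hs_times <- epochs$hs_times[keep]
  epochs$L <- dim(epochs$data)[1]
  epochs
}

#' @export
print.epoch_set <- function(x, ...) {
  cat(sprintf(
    "<epoch_set> %d trials x %d channels x %d samples, window [%g, %g) s, ref foot %s\n",
    x$L, dim(x$data)[2], dim(x$data)[3], x$window[1], x$window[2], x$ref_foot))
  invisible(x)
}

#' Short-time Fourier transform of an epoch set channel
#'
#' Per trial, Hann-windowed DFTs at window positions fully contained in
#' the epoch, onsets on the hop grid (default 375-ms window, 25-ms hop: 26
#' positions in a 1-s epoch). The time stamp of each bin is the window
#' centre; windows whose support would cross the epoch edges are not
#' computed (no padding). The frequency grid is set by the window length
#' (1/0.375 s = 2.667 Hz) with no zero-padding.
#'
#' @param epochs An [epoch_set].
#' @param channel Channel label to transform.
#' @param window_s Analysis window length in seconds (default 0.375).
#' @param hop_s Hop between window onsets in seconds (default 0.025).
#' @param fmax Highest frequency (Hz) to retain (default `Inf` = up to
#'   Nyquist).
#' @return An object of class `spectrogram`: list with `coef` (complex
#'   L x frequency x time array), `freq` (Hz), `time` (bin centres, s),
#'   `L`, `fs`, `window` descriptor.
#' @export
stft <- function(epochs, channel, window_s = 0.375, hop_s = 0.025,
                 fmax = Inf) {
  ci <- which(epochs$channels$label == channel)
  if (length(ci) != 1L) stop("channel not present in epoch set: ", channel)
  fs <- epochs$fs
  nwin <- round(window_s * fs)
  hop <- round(hop_s * fs)
  nsamp <- dim(epochs$data)[3]
  if (nwin > nsamp) stop("analysis window longer than epoch")
  nbins <- floor((nsamp - nwin) / hop) + 1L
  onsets <- (seq_len(nbins) - 1L) * hop
  win <- signal::hanning(nwin)
  freq <- (0:(nwin %/% 2)) * fs / nwin
  fkeep <- which(freq <= fmax)
  time <- epochs$t[1] + (onsets + (nwin - 1) / 2) / fs
  L <- epochs$L

  # one big mvfft over all (trial, bin) segments
  segs <- matrix(0, nrow = nwin, ncol = L * nbins)
  col <- 0L
  for (k in seq_len(L)) {
    x <- epochs$data[k, ci, ]
    for (j in seq_len(nbins)) {
      col <- col + 1L
      segs[, col] <- x[(onsets[j] + 1L):(onsets[j] + nwin)] * win
    }
  }
  F <- stats::mvfft(segs)[fkeep, , drop = FALSE]
  coef <- array(NA_complex_, dim = c(L, length(fkeep), nbins))
  col <- 0L
  for (k in seq_len(L)) {
    for (j in seq_len(nbins)) {
      col <- col + 1L
      coef[k, , j] <- F[, col]
    }
  }
  structure(
    list(coef = coef, freq = freq[fkeep], time = time, L = L, fs = fs,
         window = sprintf("hann %g ms, hop %g ms", 1000 * window_s, 1000 * hop_s),
         channel = channel),
    class = "spectrogram"
  )
}

# constructor for a frequency x time measure map
tf_map <- function(values, freq, time, measure, L, mask = NULL) {
  stopifnot(nrow(values) == length(freq), ncol(values) == length(time))
  structure(
    list(values = values, freq = freq, time = time, measure = measure,
         L = L, mask = mask),
    class = "tf_map"
  )
}

#' @export
print.tf_map <- function(x, ...) {
  cat(sprintf("<tf_map> %s: %d freq x %d time bins (L = %d)\n",
              x$measure, length(x$freq), length(x$time), x$L))
  invisible(x)
}

#' Event-related spectral power
#'
#' `percent` mode (EEG): per trial and frequency the power is expressed as
#' percentage change from its mean over the epoch's time bins,
#' `100 * (P(t,f) - mean_t P) / mean_t P`, computed in single-trial data
#' and then averaged over trials; tonic differences are subtracted away so
#' the map shows phasic modulation. `log` mode (EMG): natural log of the
#' across-trial mean power.
#'
#' @param spec A [stft()] spectrogram.
#' @param mode `"percent"` or `"log"`.
#' @return A `tf_map` with measure `eeg_power_pct` or `emg_power_log`.
#' @export
event_related_power <- function(spec, mode = c("percent", "log")) {
  mode <- match.arg(mode)
  P <- Mod(spec$coef)^2                      # L x F x T
  if (mode == "percent") {
    m <- rowMeans(P, dims = 2)               # L x F, mean over time
    if (any(m == 0)) stop("zero mean power at some frequency; degenerate input")
    pct <- 100 * (sweep(P, c(1, 2), m, "-") / replicate(dim(P)[3], m))
    tf_map(colMeans(pct, dims = 1), spec$freq, spec$time,
           "eeg_power_pct", spec$L)
  } else {
    mp <- colMeans(P, dims = 1)
    if (any(mp == 0)) stop("zero mean power at some bin; degenerate input")
    tf_map(log(mp), spec$freq, spec$time, "emg_power_log", spec$L)
  }
}

#' Inter-trial coherence
#'
#' `ITC(t,f) = |sum_k X_k|^2 / (L * sum_k |X_k|^2)` over trials k
#' (amplitude-weighted estimator): 1 when all trials carry identical
#' phase-locked coefficients, ~1/L in expectation for independent trials.
#' Quantifies locking of the signal's time-frequency content to heel
#' strike.
#'
#' @param spec A [stft()] spectrogram with `L >= 2`.
#' @param phase_only Use the phase-only variant (each coefficient
#'   normalised to unit modulus before summation). Default `FALSE`.
#' @return A `tf_map` (measure `itc`), values in \[0, 1\]. Bins with zero
#'   total power are set to 0 and flagged in `mask`.
#' @export
intertrial_coherence <- function(spec, phase_only = FALSE) {
  if (spec$L < 2L) stop("inter-trial coherence needs L >= 2 trials")
  X <- spec$coef
  if (phase_only) {
    m <- Mod(X)
    X <- ifelse(m > 0, X / m, 0 + 0i)
  }
  num <- Mod(colSums(X, dims = 1))^2
  den <- spec$L * colSums(Mod(X)^2, dims = 1)
  zero <- den == 0
  itc <- ifelse(zero, 0, num / pmax(den, .Machine$double.xmin))
  tf_map(itc, spec$freq, spec$time, "itc", spec$L,
         mask = if (any(zero)) zero else NULL)
}

#' Corticomuscular coherence
#'
#' Magnitude-squared coherence across trials per time-frequency bin:
#' `C(t,f) = |sum_k X_k Y_k*|^2 / (sum_k |X_k|^2 * sum_k |Y_k|^2)`.
#' Pairing convention: each tibialis anterior EMG with the contralateral
#' sensorimotor derivation (left TA with C4-F4, right TA with C3-F3).
#'
#' @param spec_eeg,spec_emg Spectrograms with identical grids and trial
#'   counts (EEG bipolar derivation; demodulated EMG).
#' @return A `tf_map` (measure `coherence_raw`), values in \[0, 1\].
#' @export
corticomuscular_coherence <- function(spec_eeg, spec_emg) {
  if (spec_eeg$L != spec_emg$L ||
      !isTRUE(all.equal(spec_eeg$freq, spec_emg$freq)) ||
      !isTRUE(all.equal(spec_eeg$time, spec_emg$time))) {
    stop("spectrogram grids or trial counts do not match")
  }
  X <- spec_eeg$coef; Y <- spec_emg$coef
  Sxy <- colSums(X * Conj(Y), dims = 1)
  Sxx <- colSums(Mod(X)^2, dims = 1)
  Syy <- colSums(Mod(Y)^2, dims = 1)
  den <- Sxx * Syy
  C <- ifelse(den == 0, 0, Mod(Sxy)^2 / pmax(den, .Machine$double.xmin))
  C <- pmin(C, 1)
  tf_map(C, spec_eeg$freq, spec_eeg$time, "coherence_raw", spec_eeg$L)
}

#' z-transform of coherence via its parametric null distribution
#'
#' For magnitude-squared coherence estimated from `L` independent
#' segments the null survival function is `p = (1 - C)^(L - 1)`; the
#' p-value is mapped through the standard normal quantile,
#' `z = qnorm(1 - p)`, so large coherence gives large positive z and under
#' independence z has expectation 0 and standard deviation 1. Computed in
#' log space for numerical safety; `C = 1` maps to the cap.
#'
#' @param C A `tf_map` of raw coherence (or ITC) values in \[0, 1\].
#' @param L Number of trials (default taken from the map).
#' @param cap Symmetric |z| cap (default 8.2, near the double-precision
#'   quantile limit).
#' @return A `tf_map` with measure `<measure>_z`.
#' @export
coherence_to_z <- function(C, L = C$L, cap = 8.2) {
  if (is.null(L) || L < 2) stop("parametric z-transform needs L >= 2")
  v <- C$values
  stopifnot(all(v >= 0 & v <= 1))
  logp <- (L - 1) * log1p(-v)            # log p; -Inf at C = 1
  z <- stats::qnorm(logp, lower.tail = FALSE, log.p = TRUE)
  z <- pmin(pmax(z, -cap), cap)
  tf_map(z, C$freq, C$time, paste0(sub("_raw$", "", C$measure), "_z"), L,
         mask = C$mask)
}

#' Parametric significance threshold for a coherence map
#'
#' The (1 - alpha) confidence limit of the null coherence distribution is
#' `C_thr = 1 - alpha^(1/(L-1))`; values below it are set to exactly zero
#' and recorded in the mask. The threshold decreases with the number of
#' trials.
#'
#' @param C A `tf_map` of raw coherence values.
#' @param L Number of trials (default from map).
#' @param alpha Significance level in (0, 1) (default 0.05: the 95%
#'   confidence limit).
#' @return The masked `tf_map`.
#' @export
threshold_map <- function(C, L = C$L, alpha = 0.05) {
  if (!(alpha > 0 && alpha < 1)) stop("alpha must lie in (0, 1)")
  if (is.null(L) || L < 2) stop("threshold needs L >= 2")
  thr <- coherence_threshold(L, alpha)
  mask <- C$values < thr
  C$values[mask] <- 0
  C$mask <- mask
  attr(C, "threshold") <- thr
  C
}

#' Null coherence confidence limit
#'
#' @param L Number of trials.
#' @param alpha Significance level.
#' @return `1 - alpha^(1/(L-1))`.
#' @export
coherence_threshold <- function(L, alpha = 0.05) {
  -expm1(log(alpha) / (L - 1))
}

#' Average a time-frequency map over a band and analysis window
#'
#' Mean of map values over time bins whose centres fall in the closed
#' window and frequency bins whose centres fall in the closed band
#' interval. The default window is the double-support phase, 0-125 ms
#' after heel strike.
#'
#' @param map A `tf_map`.
#' @param band Band name from `bands` or a numeric `c(f_lo, f_hi)`.
#' @param window Analysis window in seconds (closed interval).
#' @param bands Band definition table (default [band_table()]).
#' @return One-row data frame: `measure`, `band`, `window_lo_s`,
#'   `window_hi_s`, `value`, `L`, `n_bins`.
#' @export
band_window_average <- function(map, band, window = c(0, 0.125),
                                bands = band_table()) {
  if (is.character(band)) {
    row <- bands[bands$band == band, ]
    if (nrow(row) != 1L) stop("unknown band: ", band)
    f_lo <- row$f_lo; f_hi <- row$f_hi
    band_name <- band
  } else {
    stopifnot(length(band) == 2)
    f_lo <- band[1]; f_hi <- band[2]
    band_name <- sprintf("%g-%g Hz", f_lo, f_hi)
  }
  fi <- which(map$freq >= f_lo & map$freq <= f_hi)
  ti <- which(map$time >= window[1] & map$time <= window[2])
  if (!length(fi) || !length(ti)) {
    stop(sprintf(
      "empty band/window selection (band %g-%g Hz over grid [%g, %g]; window [%g, %g] s over grid [%g, %g])",
      f_lo, f_hi, min(map$freq), max(map$freq),
      window[1], window[2], min(map$time), max(map$time)))
  }
  data.frame(
    measure = map$measure, band = band_name,
    window_lo_s = window[1], window_hi_s = window[2],
    value = mean(map$values[fi, ti]),
    L = map$L %||% NA_integer_,
    n_bins = length(fi) * length(ti)
  )
}

#' Write a time-frequency map as long-format TSV
#'
#' Columns: `frequency_hz`, `time_s`, `value`, `measure`, `L`.
#'
#' @param map A `tf_map`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_tf_map <- function(map, path) {
  d <- expand.grid(frequency_hz = map$freq, time_s = map$time)
  d$value <- as.vector(map$values)
  d$measure <- map$measure
  d$L <- map$L %||% NA_integer_
  utils::write.table(d, path, sep = "\t", row.names = FALSE, quote = FALSE)
  invisible(path)
}
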