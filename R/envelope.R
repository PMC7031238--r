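#' Event-related EMG envelope
#'
#' Per trial the rectified EMG is smoothed with a zero-phase 2nd-order
#' low-pass (45 Hz default), averaged over trials, and expressed as a
#' percentage of the peak amplitude within the gait cycle (the maximum of
#' the trial-averaged envelope over the epoch grid, which spans close to
#' one full stride), so the profile maximum is 100%.
#'
#' @param epochs An [epoch_set] containing the rectified EMG channel.
#' @param channel Label of the rectified EMG channel (role `emg_rect`);
#'   default: the single `emg_rect` channel present.
#' @param lowpass_hz Smoothing cut-off in Hz (default 45).
#' @return An object of class `envelope_profile`: list with `time` (s),
#'   `amplitude_pct`, `muscle`, `L`.
#' @export
emg_envelope <- function(epochs, channel = NULL, lowpass_hz = 45) {
  if (is.null(channel)) {
    cand <- epochs$channels$label[epochs$channels$role == "emg_rect"]
    if (length(cand) != 1L) {
      stop("specify `channel`: found ", length(cand), " emg_rect channels")
    }
    channel <- cand
  }
  ci <- which(epochs$channels$label == channel)
  if (length(ci) != 1L) stop("channel not present in epoch set: ", channel)
  fs <- epochs$fs
  lp <- signal::butter(2, lowpass_hz / (fs / 2), type = "low")
  L <- epochs$L
  sm <- matrix(NA_real_, nrow = L, ncol = dim(epochs$data)[3])
  for (k in seq_len(L)) {
    sm[k, ] <- zero_phase(lp, epochs$data[k, ci, ], pad = round(0.2 * fs))
  }
  avg <- colMeans(sm)
  peak <- max(avg)
  if (peak <= 0) stop("zero peak amplitude; cannot normalize envelope")
  structure(
    list(time = epochs$t, amplitude_pct = 100 * avg / peak,
         muscle = channel, L = L),
    class = "envelope_profile"
  )
}

#' @export
print.envelope_profile <- function(x, ...) {
  cat(sprintf("<envelope_profile> %s, %d samples, L = %d, peak at t = %+.3f s\n",
              x$muscle, length(x$time), x$L, x$time[which.max(x$amplitude_pct)]))
  invisible(x)
}

#' Mean envelope amplitude in a named analysis window
#'
#' Windows relative to heel strike: `foot_lift` = \[-0.4, -0.25\] s (early
#' swing, when the dorsiflexors lift the foot) and `foot_drop` =
#' \[0.04, 0.08\] s (controlled lowering after heel strike); closed
#' intervals.
#'
#' @param profile An [emg_envelope()] profile.
#' @param window `"foot_lift"`, `"foot_drop"`, or numeric `c(lo, hi)` in
#'   seconds.
#' @return Mean amplitude (% of cycle peak) over the window.
#' @export
window_amplitude <- function(profile, window) {
  if (is.character(window)) {
    window <- switch(window,
      foot_lift = c(-0.4, -0.25),
      foot_drop = c(0.04, 0.08),
      stop("unknown window name: ", window)
    )
  }
  stopifnot(length(window) == 2)
  if (window[1] < min(profile$time) || window[2] > max(profile$time)) {
    stop(sprintf("window [%g, %g] s outside profile grid [%g, %g] s",
                 window[1], window[2], min(profile$time), max(profile$time)))
  }
  idx <- profile$time >= window[1] & profile$time <= window[2]
  mean(profile$amplitude_pct[idx])
}

#' Correlate per-record EMG amplitude with corticomuscular coherence
#'
#' Pearson correlation (Spearman optional) between the per-record envelope
#' amplitude in a window and the per-record band-averaged coherence
#' z-score, with a two-sided p-value.
#'
#' @param amplitudes Numeric vector of per-record envelope amplitudes.
#' @param cmc Numeric vector of per-record coherence summaries (same
#'   order).
#' @param method `"pearson"` (default) or `"spearman"`.
#' @return List: `estimate`, `p.value`, `n`, `method`.
#' @export
correlate_envelope_cmc <- function(amplitudes, cmc,
                                   method = c("pearson", "spearman")) {
  method <- match.arg(method)
  stopifnot(length(amplitudes) == length(cmc))
  if (length(amplitudes) < 3L) stop("need at least 3 paired records")
  if (stats::sd(amplitudes) == 0 || stats::sd(cmc) == 0) {
    stop("zero variance in one of the variables; correlation undefined")
  }
  ct <- stats::cor.test(amplitudes, cmc, method = method, exact = FALSE)
  list(estimate = unname(ct$estimate), p.value = ct$p.value,
       n = length(amplitudes), method = method)
}
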