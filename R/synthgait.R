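#' @keywords internal
eeg_1020_labels <- c(
  "Fp1", "Fp2", "F7", "F3", "Fz", "F4", "F8", "T3", "C3", "Cz", "C4", "T4",
  "T5", "P3", "Pz", "P4", "T6", "O1", "O2"
)

# 10-channel montage used for the walking recordings.
default_eeg_channels <- c("P3", "P4", "C3", "Cz", "C4", "F7", "F3", "Fz", "F4", "F8")

# Group presets: temporal gait parameters (means over valid cycles of a
# steady walk), relative strength of the early-swing TA burst (fraction of
# the heel-strike peak), and a multiplier on cortex-muscle coupling.
# Young values are the reference; the older and parkinsonian presets carry
# a shorter swing phase, a stronger foot-lift burst and reduced low-beta
# coupling.
# footlift_amp values are calibrated so the mean envelope amplitude in
# the foot-lift window (as % of the cycle peak) lands near the group
# means reported for healthy young (~48%), older (~67%) and parkinsonian
# (~62%) walkers.
synth_group_presets <- list(
  young = list(stride = 1.10, stride_sd = 0.020, stance = 0.690,
               footlift_amp = 0.71, coupling_mult = 1.00),
  old   = list(stride = 1.09, stride_sd = 0.019, stance = 0.700,
               footlift_amp = 1.05, coupling_mult = 0.65),
  pd    = list(stride = 1.06, stride_sd = 0.021, stance = 0.675,
               footlift_amp = 0.96, coupling_mult = 0.65)
)

#' Configuration of a synthetic gait record
#'
#' Defines the ground-truth structure of a simulated walking recording:
#' gait timing (stride mean/SD and phase durations), a two-burst tibialis
#' anterior EMG envelope, band-limited cortex-muscle coupling restricted to
#' a phase window around heel strike, 1/f EEG background, and optional
#' gait-locked high-amplitude artefacts.
#'
#' Phase-consistency: with equal per-foot stance times and alternating
#' steps, the per-step double-support duration is structurally
#' `stance - stride/2`; `double_support_s` and `swing_s` are therefore
#' derived from `stride_mean_s` and `stance_s` unless supplied, and
#' supplied values must be consistent within 5 ms.
#'
#' @param group_label One of `"young"`, `"old"`, `"pd"`; selects preset
#'   gait timing, envelope and coupling parameters that can be overridden
#'   individually.
#' @param duration_s Record duration in seconds.
#' @param sample_rate_hz Sampling rate (default 2000 Hz).
#' @param stride_mean_s,stride_sd_s Stride-time mean and SD in seconds.
#' @param stance_s Stance-phase duration (heel strike to same-foot
#'   toe-off) at the mean stride; jitters proportionally with stride.
#' @param swing_s,double_support_s Optional; derived from stride and
#'   stance when `NULL` (see Details).
#' @param coupling Named numeric vector of coupling strengths in \[0, 1\]
#'   per frequency band of [band_table()] (default `c(low_beta = 0.4)`
#'   scaled by the group multiplier). Strength 0 makes EEG and EMG
#'   independent.
#' @param coupling_window_s Phase window relative to heel strike in which
#'   the shared band-limited drive is active (default the double-support
#'   window `c(0, 0.125)`).
#' @param emg_bursts Data frame with columns `center_s`, `width_s`, `amp`
#'   describing Gaussian envelope bursts relative to each heel strike;
#'   default: early-swing burst at -0.33 s plus the double peak at 0 and
#'   +0.060 s.
#' @param emg_sigma_uv EMG broadband noise scale (microvolt).
#' @param eeg_sigma_uv EEG 1/f background scale (microvolt).
#' @param eeg_exponent Power-spectral exponent of the EEG background
#'   (default 1: pink).
#' @param eeg_drive_uv Amplitude (microvolt) with which the shared drive
#'   is projected additively onto the sensorimotor EEG channel.
#' @param emg_mod_depth Depth with which the shared drive
#'   amplitude-modulates the EMG carrier at unit coupling strength
#'   (default 0.8). Modulating the envelope rather than adding to the raw
#'   EMG mirrors how common corticospinal input expresses itself in
#'   surface EMG (motor-unit firing modulation) and survives the
#'   rectification/demodulation analysis path.
#' @param artefact_amplitude_uv Peak amplitude of gait-locked EEG
#'   artefact pulses (default 400).
#' @param artefact_rate Fraction of gait cycles contaminated (default 0).
#' @param eeg_channels EEG montage labels (10-20 system).
#' @param seed Integer RNG seed; identical seed + config give bit-identical
#'   records.
#' @return An object of class `synth_config`.
#' @export
synth_config <- function(group_label = c("young", "old", "pd"),
                         duration_s = 300,
                         sample_rate_hz = 2000,
                         stride_mean_s = NULL,
                         stride_sd_s = NULL,
                         stance_s = NULL,
                         swing_s = NULL,
                         double_support_s = NULL,
                         coupling = NULL,
                         coupling_window_s = c(0, 0.125),
                         emg_bursts = NULL,
                         emg_sigma_uv = 60,
                         eeg_sigma_uv = 20,
                         eeg_exponent = 1,
                         eeg_drive_uv = 10,
                         emg_mod_depth = 0.8,
                         artefact_amplitude_uv = 400,
                         artefact_rate = 0,
                         eeg_channels = default_eeg_channels,
                         seed = 1L) {
  group_label <- match.arg(group_label)
  preset <- synth_group_presets[[group_label]]
  stride_mean_s <- stride_mean_s %||% preset$stride
  stride_sd_s <- stride_sd_s %||% preset$stride_sd
  stance_s <- stance_s %||% preset$stance
  swing_s <- swing_s %||% (stride_mean_s - stance_s)
  double_support_s <- double_support_s %||% (stance_s - stride_mean_s / 2)
  coupling <- coupling %||% c(low_beta = 0.4 * preset$coupling_mult)
  emg_bursts <- emg_bursts %||% data.frame(
    center_s = c(-0.33, 0.000, 0.060),
    width_s = c(0.040, 0.012, 0.012),
    amp = c(preset$footlift_amp, 1, 1)
  )

  stopifnot(
    duration_s > 0, sample_rate_hz > 0,
    stride_mean_s > 0, stride_sd_s >= 0,
    stance_s > 0, swing_s > 0, double_support_s > 0,
    all(coupling >= 0), all(coupling <= 1),
    length(coupling_window_s) == 2, diff(coupling_window_s) > 0,
    all(emg_bursts$width_s > 0), all(emg_bursts$amp >= 0),
    emg_sigma_uv > 0, eeg_sigma_uv > 0,
    artefact_amplitude_uv >= 0, artefact_rate >= 0, artefact_rate <= 1
  )
  if (abs(stance_s + swing_s - stride_mean_s) > 0.005) {
    stop("inconsistent phase durations: stance_s + swing_s must equal stride_mean_s")
  }
  if (abs(double_support_s - (stance_s - stride_mean_s / 2)) > 0.005) {
    stop("inconsistent phase durations: double_support_s must equal stance_s - stride_mean_s/2")
  }
  if (double_support_s >= stance_s) stop("double_support_s must be < stance_s")
  unknown <- setdiff(eeg_channels, eeg_1020_labels)
  if (length(unknown)) {
    stop("unknown EEG channel label(s): ", paste(unknown, collapse = ", "))
  }
  bands <- band_table()
  bad_band <- setdiff(names(coupling), bands$band)
  if (length(bad_band)) {
    stop("unknown coupling band(s): ", paste(bad_band, collapse = ", "))
  }

  structure(
    list(
      group_label = group_label, duration_s = duration_s,
      sample_rate_hz = sample_rate_hz,
      stride_mean_s = stride_mean_s, stride_sd_s = stride_sd_s,
      stance_s = stance_s, swing_s = swing_s,
      double_support_s = double_support_s,
      step_s = stance_s - double_support_s,
      coupling = coupling, coupling_window_s = coupling_window_s,
      emg_bursts = emg_bursts,
      emg_sigma_uv = emg_sigma_uv, eeg_sigma_uv = eeg_sigma_uv,
      eeg_exponent = eeg_exponent,
      eeg_drive_uv = eeg_drive_uv, emg_mod_depth = emg_mod_depth,
      artefact_amplitude_uv = artefact_amplitude_uv,
      artefact_rate = artefact_rate,
      eeg_channels = eeg_channels,
      seed = as.integer(seed),
      seed_supplied = !missing(seed)
    ),
    class = "synth_config"
  )
}

#' Generate a gait-event timeline with the configured stride statistics
#'
#' Left-foot stride intervals are drawn i.i.d. normal (truncated at 30% of
#' the mean); all phase landmarks of a cycle (contralateral heel strike at
#' one step time, toe-offs at stance time) scale proportionally with that
#' cycle's stride, preserving the phase-fraction structure under jitter.
#'
#' @param config A [synth_config].
#' @param seed RNG seed; defaults to `config$seed`. Pass `NULL` to draw
#'   from the current RNG state.
#' @return An [event_series].
#' @export
generate_gait_timeline <- function(config, seed = config$seed) {
  if (!is.null(seed)) set.seed(seed)
  fs <- config$sample_rate_hz
  t0 <- 0.5
  margin <- 0.1
  if (config$duration_s < t0 + 2 * config$stride_mean_s + margin) {
    stop("duration_s too short for two full gait cycles")
  }
  n_max <- ceiling((config$duration_s - t0) / (0.7 * config$stride_mean_s)) + 2L
  strides <- stats::rnorm(n_max, config$stride_mean_s, config$stride_sd_s)
  strides <- pmax(strides, 0.3 * config$stride_mean_s)
  lhs_all <- t0 + c(0, cumsum(strides))
  n_cyc <- max(which(lhs_all + strides[pmin(seq_along(lhs_all), n_max)] <
                       config$duration_s - margin)) - 1L
  if (n_cyc < 2L) stop("duration_s too short for two full gait cycles")
  lhs <- lhs_all[seq_len(n_cyc + 1L)]
  scale <- strides[seq_len(n_cyc)] / config$stride_mean_s
  rhs <- lhs[seq_len(n_cyc)] + config$step_s * scale
  lto <- lhs[seq_len(n_cyc)] + config$stance_s * scale
  rto <- rhs + config$stance_s * scale
  keep <- rto < config$duration_s - margin
  event_series(
    left = list(heel_strikes = lhs, toe_offs = lto),
    right = list(heel_strikes = rhs[keep], toe_offs = rto[keep])
  )
}

# raised-cosine gate: 1 inside [hs + w1 + ramp, hs + w2 - ramp] for every
# valid heel strike, cosine ramps of `ramp` seconds at the edges.
coupling_gate <- function(t, hs_times, window, ramp = 0.025) {
  g <- numeric(length(t))
  n <- length(t)
  fs <- 1 / (t[2] - t[1])
  w1 <- window[1]; w2 <- window[2]
  ramp <- min(ramp, diff(window) / 2)
  for (hs in hs_times) {
    lo <- hs + w1; hi <- hs + w2
    idx <- idx_window(n, fs, lo, hi)
    idx <- idx[t[idx] >= lo & t[idx] < hi]
    if (!length(idx)) next
    u <- t[idx] - lo
    gi <- rep(1, length(idx))
    gi[u < ramp] <- 0.5 * (1 - cos(pi * u[u < ramp] / ramp))
    v <- hi - lo - u
    gi[v < ramp] <- pmin(gi[v < ramp], 0.5 * (1 - cos(pi * v[v < ramp] / ramp)))
    g[idx] <- pmax(g[idx], gi)
  }
  g
}

# unit-variance Gaussian process band-limited to [f_lo, f_hi] Hz
bandlimited_drive <- function(n, fs, f_lo, f_hi) {
  b <- signal::butter(4, c(f_lo, f_hi) / (fs / 2), type = "pass")
  x <- zero_phase(b, stats::rnorm(n), pad = fs)
  x / stats::sd(x)
}

# shared drives per side, one per coupled band; list(left = list(band = ...))
make_drives <- function(config, n) {
  fs <- config$sample_rate_hz
  bands <- band_table()
  out <- list()
  for (side in c("left", "right")) {
    out[[side]] <- lapply(stats::setNames(names(config$coupling), names(config$coupling)),
      function(bn) {
        row <- bands[bands$band == bn, ]
        bandlimited_drive(n, fs, row$f_lo, row$f_hi)
      })
  }
  out
}

#' Generate one tibialis anterior EMG channel
#'
#' Broadband Gaussian noise amplitude-modulated by (a) a cycle-locked
#' envelope (Gaussian bursts at the configured times relative to each heel
#' strike of the given foot, on a small tonic baseline) and (b) the shared
#' band-limited drive, scaled by the coupling strength and the modulation
#' depth and gated to the coupling window by a raised-cosine taper. The
#' drive thereby enters the EMG envelope, where the
#' rectification/demodulation analysis recovers it as corticomuscular
#' coherence. With coupling 0 the output is independent of the drive.
#'
#' @param timeline An [event_series].
#' @param config A [synth_config].
#' @param drives Named list (band -> drive series) as produced inside
#'   [generate_record()]; pass `NULL` for an uncoupled channel.
#' @param foot `"left"` or `"right"`: which foot's heel strikes the
#'   envelope and coupling gate lock to.
#' @param seed RNG seed (`NULL`: use current RNG state).
#' @return Numeric vector (microvolt) of `duration_s * sample_rate_hz`
#'   samples.
#' @export
generate_emg <- function(timeline, config, drives = NULL,
                         foot = c("left", "right"), seed = NULL) {
  foot <- match.arg(foot)
  if (!is.null(seed)) set.seed(seed)
  fs <- config$sample_rate_hz
  n <- round(config$duration_s * fs)
  t <- (seq_len(n) - 1L) / fs
  hs <- timeline[[foot]]$heel_strikes

  env <- rep(0.08, n)  # tonic baseline
  for (k in seq_len(nrow(config$emg_bursts))) {
    b <- config$emg_bursts[k, ]
    for (h in hs) {
      c0 <- h + b$center_s
      idx <- idx_window(n, fs, c0 - 4 * b$width_s, c0 + 4 * b$width_s)
      if (length(idx)) {
        env[idx] <- env[idx] + b$amp * exp(-(t[idx] - c0)^2 / (2 * b$width_s^2))
      }
    }
  }
  mod <- rep(1, n)
  if (!is.null(drives) && length(config$coupling)) {
    gate <- coupling_gate(t, hs, config$coupling_window_s)
    for (bn in names(config$coupling)) {
      mod <- mod + config$coupling[[bn]] * config$emg_mod_depth *
        drives[[bn]] * gate
    }
    mod <- pmax(mod, 0.05)  # keep the modulated envelope positive
  }
  config$emg_sigma_uv * env * mod * stats::rnorm(n)
}

#' Generate the multichannel EEG
#'
#' Each channel is unit-structure 1/f (pink) noise scaled to
#' `eeg_sigma_uv`. The shared band-limited drives are projected onto the
#' sensorimotor channels with crossed pairing: the drive shared with the
#' left-TA EMG onto C4 (right hemisphere), the right-TA drive onto C3, each
#' gated to the coupling window after the corresponding foot's heel
#' strikes. Optional gait-locked artefact pulses exceeding
#' `artefact_amplitude_uv` are added on a random fraction of cycles.
#'
#' @param timeline An [event_series].
#' @param config A [synth_config].
#' @param drives List `list(left = <band list>, right = <band list>)`;
#'   `NULL` for drive-free channels.
#' @param seed RNG seed (`NULL`: use current RNG state).
#' @return List with `samples` (channel x time matrix, microvolt, rows
#'   named by `config$eeg_channels`) and `artefact_cycles` (times of
#'   contaminated heel strikes).
#' @export
generate_eeg <- function(timeline, config, drives = NULL, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  fs <- config$sample_rate_hz
  n <- round(config$duration_s * fs)
  t <- (seq_len(n) - 1L) / fs
  chans <- config$eeg_channels
  unknown <- setdiff(chans, eeg_1020_labels)
  if (length(unknown)) {
    stop("unknown EEG channel label(s): ", paste(unknown, collapse = ", "))
  }
  m <- matrix(0, nrow = length(chans), ncol = n, dimnames = list(chans, NULL))
  for (i in seq_along(chans)) {
    m[i, ] <- config$eeg_sigma_uv * pink_noise(n, config$eeg_exponent)
  }
  if (!is.null(drives) && length(config$coupling)) {
    # crossed projection: left TA <-> C4, right TA <-> C3
    proj <- c(left = "C4", right = "C3")
    for (side in c("left", "right")) {
      target <- proj[[side]]
      if (!target %in% chans) next
      gate <- coupling_gate(t, timeline[[side]]$heel_strikes,
                            config$coupling_window_s)
      for (bn in names(config$coupling)) {
        m[target, ] <- m[target, ] +
          config$eeg_drive_uv * drives[[side]][[bn]] * gate
      }
    }
  }
  art_times <- numeric(0)
  if (config$artefact_rate > 0 && config$artefact_amplitude_uv > 0) {
    hs <- timeline$left$heel_strikes
    contaminated <- which(stats::runif(length(hs)) < config$artefact_rate)
    art_times <- hs[contaminated]
    for (h in art_times) {
      idx <- idx_window(n, fs, h - 0.08, h + 0.08)
      pulse <- config$artefact_amplitude_uv * 1.1 *
        exp(-(t[idx] - h)^2 / (2 * 0.02^2))
      m[, idx] <- sweep(m[, idx, drop = FALSE], 2, pulse, "+")
    }
  }
  list(samples = m, artefact_cycles = art_times)
}

# 0/1 contact pulses with linear 5-ms edges centred on the contact events
footswitch_channel <- function(t, on_times, off_times, rise_s = 0.005) {
  x <- numeric(length(t))
  n <- length(t)
  fs <- 1 / (t[2] - t[1])
  for (k in seq_along(on_times)) {
    idx <- idx_window(n, fs, on_times[k] - rise_s, off_times[k] + rise_s)
    if (!length(idx)) next
    x[idx] <- pmax(x[idx], ramp_up(t[idx], on_times[k], rise_s) *
                     (1 - ramp_up(t[idx], off_times[k], rise_s)))
  }
  x
}

#' Assemble a complete synthetic gait record with ground truth
#'
#' Builds the full montage: the configured EEG channels, bilateral TA EMG
#' (`TA_left`, `TA_right`), and four footswitch channels (`left_heel`,
#' `left_toe`, `right_heel`, `right_toe`) carrying 0/1 contact pulses with
#' 5-ms edges, the heel-contact onset and the toe-contact offset centred on
#' the true heel-strike and toe-off times. The ground truth carries the
#' injected event times, coupling parameters and artefact cycles.
#'
#' @param config A [synth_config].
#' @param path Optional path: when given the record is written via
#'   [write_record()] and the ground truth as `<path>.truth.json`.
#' @return List with elements `record` ([signal_record]) and `truth`
#'   (list: `event_series`, `coupling`, `coupling_window_s`,
#'   `artefact_cycles`, `config`).
#' @export
generate_record <- function(config, path = NULL) {
  stopifnot(inherits(config, "synth_config"))
  set.seed(config$seed)
  fs <- config$sample_rate_hz
  n <- round(config$duration_s * fs)
  t <- (seq_len(n) - 1L) / fs

  timeline <- generate_gait_timeline(config, seed = NULL)
  drives <- make_drives(config, n)
  emg_l <- generate_emg(timeline, config, drives$left, foot = "left")
  emg_r <- generate_emg(timeline, config, drives$right, foot = "right")
  eeg <- generate_eeg(timeline, config, drives)

  fsw <- rbind(
    left_heel = footswitch_channel(
      t, timeline$left$heel_strikes,
      timeline$left$heel_strikes + 0.55 * config$stance_s),
    left_toe = footswitch_channel(
      t, timeline$left$heel_strikes[seq_along(timeline$left$toe_offs)] +
        0.2 * config$stance_s,
      timeline$left$toe_offs),
    right_heel = footswitch_channel(
      t, timeline$right$heel_strikes,
      timeline$right$heel_strikes + 0.55 * config$stance_s),
    right_toe = footswitch_channel(
      t, timeline$right$heel_strikes[seq_along(timeline$right$toe_offs)] +
        0.2 * config$stance_s,
      timeline$right$toe_offs)
  )

  samples <- rbind(eeg$samples, TA_left = emg_l, TA_right = emg_r, fsw)
  channels <- data.frame(
    label = c(config$eeg_channels, "TA_left", "TA_right",
              "left_heel", "left_toe", "right_heel", "right_toe"),
    role = c(rep("eeg", length(config$eeg_channels)), rep("emg", 2),
             rep("footswitch", 4)),
    units = c(rep("uV", length(config$eeg_channels) + 2), rep("binary", 4))
  )
  record <- signal_record(samples, fs, channels,
                          history = sprintf("synthetic record (group=%s, seed=%d)",
                                            config$group_label, config$seed))
  truth <- list(
    event_series = timeline,
    coupling = config$coupling,
    coupling_window_s = config$coupling_window_s,
    artefact_cycles = eeg$artefact_cycles,
    config = config
  )
  if (!is.null(path)) {
    write_record(record, path)
    jsonlite::write_json(
      list(
        left_heel_strikes = timeline$left$heel_strikes,
        left_toe_offs = timeline$left$toe_offs,
        right_heel_strikes = timeline$right$heel_strikes,
        right_toe_offs = timeline$right$toe_offs,
        coupling = as.list(config$coupling),
        coupling_window_s = config$coupling_window_s,
        artefact_cycles = eeg$artefact_cycles
      ),
      paste0(path, ".truth.json"), auto_unbox = TRUE, digits = NA
    )
  }
  list(record = record, truth = truth)
}
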