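#' Benjamini-Hochberg step-up adjustment
#'
#' Classic step-up false-discovery-rate control: with `m` p-values sorted
#' ascending, `p_adj(i) = min_{j >= i} min(1, m * p(j) / j)`. Implemented
#' directly so that `stats::p.adjust(method = "BH")` remains an
#' independent cross-check.
#'
#' @param p Numeric vector of p-values in \[0, 1\].
#' @return Adjusted p-values in the original order.
#' @export
bh_adjust <- function(p) {
  if (any(!is.finite(p)) || any(p < 0 | p > 1)) {
    stop("p-values must lie in [0, 1]")
  }
  m <- length(p)
  o <- order(p, decreasing = TRUE)          # largest first
  adj <- pmin(1, m / (m:1) * p[o])          # m * p_(i) / rank_(i)
  adj <- cummin(adj)                        # enforce step-up monotonicity
  adj[order(o)]
}

#' Cohen's d_s between two groups
#'
#' Standardised mean difference with the pooled SD on `n_a + n_b - 2`
#' degrees of freedom. Note that effect sizes from small samples are
#' noisy and tend to be inflated.
#'
#' @param group_a,group_b Numeric vectors with at least 2 values each.
#' @return The effect size (positive when `group_a` has the larger mean).
#' @export
cohens_ds <- function(group_a, group_b) {
  na <- length(group_a); nb <- length(group_b)
  if (na < 2L || nb < 2L) stop("each group needs at least 2 values")
  sp2 <- ((na - 1) * stats::var(group_a) + (nb - 1) * stats::var(group_b)) /
    (na + nb - 2)
  if (sp2 == 0) stop("zero pooled SD; effect size undefined")
  (mean(group_a) - mean(group_b)) / sqrt(sp2)
}

# contralateral sensorimotor pairing: TA of one side with the bipolar
# derivation over the opposite hemisphere
contralateral_pair <- function(side) {
  switch(side,
    left = list(eeg = "C4-F4", emg = "TA_left"),
    right = list(eeg = "C3-F3", emg = "TA_right"),
    stop("side must be 'left' or 'right'")
  )
}

#' Full spectral and envelope analysis of one record
#'
#' Runs the complete per-record chain: event detection (unless supplied),
#' validity screen, amplitude-based epoch rejection on the raw EEG,
#' conditioning (unit variance, 0.5-70 Hz band-pass, common average
#' reference, sensorimotor bipolar derivations, EMG rectification and
#' demodulation), heel-strike-locked epoching per side, STFT, the five
#' spectral measures (EEG % power, log EMG power, EEG and EMG inter-trial
#' coherence z, corticomuscular coherence z), band/window summaries, and
#' the EMG envelope with foot-lift/foot-drop amplitudes.
#'
#' Per side, coherence and EMG inter-trial coherence use the demodulated
#' EMG while EMG power and the envelope use the rectified EMG
#' (demodulation removes amplitude information by construction).
#'
#' @param record A [signal_record] in physical units.
#' @param events Optional [event_series]; detected from the footswitch
#'   channels when `NULL`.
#' @param sides Which feet to analyse (`"left"` pairs the left TA with
#'   C4-F4 epoched on left heel strikes, and conversely).
#' @param max_epochs Epoch-count ceiling per side (default 220).
#' @param amplitude_threshold_uv EEG artefact rejection threshold.
#' @param min_heel_strikes Validity threshold for [validate_record()].
#' @param bands Band table (default [band_table()]).
#' @param window Band-summary analysis window (default double support,
#'   `c(0, 0.125)` s).
#' @param fmax Highest frequency retained in the spectrograms (Hz).
#' @param keep_maps Keep the full time-frequency maps in the output.
#' @return List of class `record_analysis`: `summaries` (tidy band/window
#'   table incl. envelope rows), `gait` (temporal gait parameters),
#'   `validity`, `rejection` (per-side reports), `maps` (optional),
#'   `envelopes`, `L` (per side).
#' @export
analyze_record <- function(record, events = NULL,
                           sides = c("left", "right"),
                           max_epochs = 220,
                           amplitude_threshold_uv = 300,
                           min_heel_strikes = 100,
                           bands = band_table(),
                           window = c(0, 0.125),
                           fmax = 100,
                           keep_maps = FALSE) {
  if (is.null(events)) events <- detect_events(record)
  validity <- validate_record(events, min_heel_strikes)
  gait <- compute_gait_parameters(events)

  eeg_labels <- record$channels$label[record$channels$role == "eeg"]

  # amplitude screen on raw epochs, per side: epochs whose raw EEG exceeds
  # the threshold are removed before counting towards max_epochs
  rejection <- list()
  valid_hs <- list()
  for (side in sides) {
    ep_raw <- epoch_signals(record, events, ref_foot = side,
                            channels = eeg_labels, max_epochs = .Machine$integer.max)
    rej <- reject_epochs(ep_raw, amplitude_threshold_uv)
    rejection[[side]] <- rej$report
    valid_hs[[side]] <- rej$epochs$hs_times
  }

  cond <- record
  cond <- normalize_variance(cond)
  cond <- filter_eeg(cond)
  cond <- rereference_car(cond)
  cond <- bipolar_derive(cond)
  cond <- preprocess_emg(cond)

  summaries <- NULL
  maps <- list()
  envelopes <- list()
  L_side <- integer()
  for (side in sides) {
    pairing <- contralateral_pair(side)
    ev <- events
    ev[[side]]$valid <- ev[[side]]$valid &
      (ev[[side]]$heel_strikes %in% valid_hs[[side]])
    chans <- c(pairing$eeg, paste0(pairing$emg, c("_rect", "_demod")))
    ep <- epoch_signals(cond, ev, ref_foot = side, channels = chans,
                        max_epochs = max_epochs)
    L_side[side] <- ep$L
    spec_eeg <- stft(ep, pairing$eeg, fmax = fmax)
    spec_rect <- stft(ep, paste0(pairing$emg, "_rect"), fmax = fmax)
    spec_demod <- stft(ep, paste0(pairing$emg, "_demod"), fmax = fmax)

    side_maps <- list(
      eeg_power_pct = event_related_power(spec_eeg, "percent"),
      emg_power_log = event_related_power(spec_rect, "log"),
      itc_eeg_z = coherence_to_z(intertrial_coherence(spec_eeg)),
      itc_emg_z = coherence_to_z(intertrial_coherence(spec_demod)),
      cmc_raw = corticomuscular_coherence(spec_eeg, spec_demod)
    )
    side_maps$cmc_z <- coherence_to_z(side_maps$cmc_raw)

    for (mname in c("eeg_power_pct", "emg_power_log", "itc_eeg_z",
                    "itc_emg_z", "cmc_z")) {
      for (b in bands$band) {
        row <- band_window_average(side_maps[[mname]], b, window, bands)
        row$measure <- mname
        row$side <- side
        summaries <- rbind(summaries, row)
      }
    }

    prof <- emg_envelope(ep, paste0(pairing$emg, "_rect"))
    envelopes[[side]] <- prof
    for (w in c("foot_lift", "foot_drop")) {
      summaries <- rbind(summaries, data.frame(
        measure = "emg_envelope_pct", band = w,
        window_lo_s = if (w == "foot_lift") -0.4 else 0.04,
        window_hi_s = if (w == "foot_lift") -0.25 else 0.08,
        value = window_amplitude(prof, w), L = prof$L,
        n_bins = NA_integer_, side = side
      ))
    }
    if (keep_maps) maps[[side]] <- side_maps
  }
  rownames(summaries) <- NULL
  structure(
    list(summaries = summaries, gait = gait, validity = validity,
         rejection = rejection, maps = if (keep_maps) maps,
         envelopes = envelopes, L = L_side),
    class = "record_analysis"
  )
}

#' Run the pipeline over a cohort and assemble group-level tables
#'
#' Accepts a list of [synth_config] objects (records are generated) and/or
#' lists with elements `record` (a [signal_record]), optional `events`,
#' `id`, `group`, `condition`. Each record passes the full
#' [analyze_record()] chain; invalid records (fewer valid heel strikes
#' than `min_heel_strikes` on either foot) are skipped with a logged
#' reason. The tidy outcome table holds one row per record, condition,
#' side, measure and band; the 5-measure x 5-band spectral grid is
#' additionally screened for group differences with Welch's test
#' (two-sample t for 2 groups, Welch one-way for 3), Benjamini-Hochberg
#' adjusted across the 25 cells. This screen is a self-contained check;
#' the exported table is intended for external mixed-model software when
#' records are repeated within participants.
#'
#' @param cohort List of inputs (see above).
#' @param seed Integer seed controlling record generation for
#'   `synth_config` entries without their own seed.
#' @param min_heel_strikes Validity threshold (default 100; lower for
#'   short simulated records).
#' @param ... Passed on to [analyze_record()].
#' @return List of class `pipeline_result`: `outcomes`, `gait`, `screen`,
#'   `log` (per-record status), `provenance`.
#' @export
run_pipeline <- function(cohort, seed = 1L, min_heel_strikes = 100, ...) {
  if (!length(cohort)) stop("empty input list")
  outcomes <- NULL
  gait <- NULL
  log <- NULL
  for (i in seq_along(cohort)) {
    item <- cohort[[i]]
    if (inherits(item, "synth_config")) {
      cfg <- item
      if (!isTRUE(cfg$seed_supplied)) {
        cfg$seed <- as.integer((seed + 7919 * i) %% .Machine$integer.max)
      }
      rec <- generate_record(cfg)$record
      events <- NULL
      id <- names(cohort)[i] %||% sprintf("rec%03d", i)
      if (is.null(names(cohort)) || names(cohort)[i] == "") id <- sprintf("rec%03d", i)
      group <- cfg$group_label
      condition <- "simulated"
    } else {
      rec <- item$record
      events <- item$events %||% NULL
      id <- item$id %||% sprintf("rec%03d", i)
      group <- item$group %||% NA_character_
      condition <- item$condition %||% NA_character_
    }
    status <- tryCatch({
      res <- analyze_record(rec, events = events,
                            min_heel_strikes = min_heel_strikes, ...)
      if (!res$validity$valid) {
        stop(sprintf("record invalid: %d/%d valid heel strikes (min %d)",
                     res$validity$counts[["left"]], res$validity$counts[["right"]],
                     min_heel_strikes))
      }
      s <- res$summaries
      s$record_id <- id; s$group <- group; s$condition <- condition
      outcomes <- rbind(outcomes, s)
      g <- res$gait
      g$record_id <- id; g$group <- group; g$condition <- condition
      gait <- rbind(gait, g)
      "analysed"
    }, error = function(e) paste("excluded:", conditionMessage(e)))
    log <- rbind(log, data.frame(record_id = id, group = group,
                                 condition = condition, status = status))
  }
  if (is.null(outcomes)) stop("no record could be analysed; see log")

  screen <- group_screen(outcomes)
  structure(
    list(
      outcomes = outcomes, gait = gait, screen = screen, log = log,
      provenance = list(
        package = "gaitcmc",
        version = as.character(utils::packageVersion("gaitcmc")),
        seed = seed,
        n_input = length(cohort),
        n_analysed = sum(log$status == "analysed"),
        n_excluded = sum(log$status != "analysed")
      )
    ),
    class = "pipeline_result"
  )
}

# Welch screen over the spectral measure x band grid with BH adjustment
group_screen <- function(outcomes) {
  spectral <- outcomes[outcomes$measure != "emg_envelope_pct", ]
  groups <- unique(spectral$group)
  cells <- unique(spectral[, c("measure", "band")])
  if (length(groups) < 2L || !nrow(cells)) return(NULL)
  out <- NULL
  for (k in seq_len(nrow(cells))) {
    cell <- spectral[spectral$measure == cells$measure[k] &
                       spectral$band == cells$band[k], ]
    # one value per record: average over sides (and conditions)
    per_rec <- stats::aggregate(value ~ record_id + group, cell, mean)
    p <- tryCatch({
      if (length(groups) == 2L) {
        stats::t.test(value ~ group, per_rec)$p.value
      } else {
        stats::oneway.test(value ~ group, per_rec, var.equal = FALSE)$p.value
      }
    }, error = function(e) NA_real_)
    out <- rbind(out, data.frame(measure = cells$measure[k],
                                 band = cells$band[k], p = p))
  }
  ok <- is.finite(out$p)
  out$p_adj <- NA_real_
  out$p_adj[ok] <- bh_adjust(out$p[ok])
  out
}

#' @export
print.pipeline_result <- function(x, ...) {
  cat(sprintf("<pipeline_result> %d/%d records analysed (%d excluded)\n",
              x$provenance$n_analysed, x$provenance$n_input,
              x$provenance$n_excluded))
  if (!is.null(x$screen)) {
    sig <- x$screen[!is.na(x$screen$p_adj) & x$screen$p_adj < 0.05, ]
    cat(sprintf("  group screen: %d/%d cells with adjusted p < 0.05\n",
                nrow(sig), nrow(x$screen)))
  }
  invisible(x)
}
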