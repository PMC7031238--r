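#' Per-foot gait event series
#'
#' Heel-strike and toe-off times (seconds) for the left and right foot,
#' each with a per-event validity flag (used e.g. to exclude turning
#' sections or artefact-contaminated cycles). Within each foot the event
#' lists are strictly increasing and between consecutive heel strikes of a
#' foot lies exactly one toe-off of that foot.
#'
#' @param left,right Lists with numeric elements `heel_strikes`, `toe_offs`
#'   and optional logical `valid` (per heel strike; defaults to all `TRUE`).
#' @param detected Logical flag: `FALSE` when the series is degenerate
#'   (e.g. no threshold crossings found).
#' @return An object of class `event_series`.
#' @export
event_series <- function(left, right, detected = TRUE) {
  fix <- function(f) {
    f$heel_strikes <- as.numeric(f$heel_strikes)
    f$toe_offs <- as.numeric(f$toe_offs)
    if (is.unsorted(f$heel_strikes, strictly = TRUE) ||
        is.unsorted(f$toe_offs, strictly = TRUE)) {
      stop("event times must be strictly increasing within each foot")
    }
    f$valid <- f$valid %||% rep(TRUE, length(f$heel_strikes))
    stopifnot(length(f$valid) == length(f$heel_strikes))
    f
  }
  structure(list(left = fix(left), right = fix(right), detected = detected),
            class = "event_series")
}

#' @export
print.event_series <- function(x, ...) {
  cat(sprintf(
    "<event_series> left: %d HS / %d TO (%d valid); right: %d HS / %d TO (%d valid)%s\n",
    length(x$left$heel_strikes), length(x$left$toe_offs), sum(x$left$valid),
    length(x$right$heel_strikes), length(x$right$toe_offs), sum(x$right$valid),
    if (x$detected) "" else " [no events detected]"
  ))
  invisible(x)
}

#' Detect heel-strike and toe-off events from footswitch channels
#'
#' Heel strike is the upward crossing of the heel-switch channel through a
#' threshold set as a fraction of the per-channel range; toe-off is the
#' downward crossing of the toe-switch channel. Crossing times are refined
#' by linear interpolation between samples, and crossings closer than the
#' debounce interval are merged (first kept). Detection is therefore
#' invariant to amplitude scaling of the switch signals.
#'
#' @param record A [signal_record] containing four channels with role
#'   `footswitch` labelled `left_heel`, `left_toe`, `right_heel`,
#'   `right_toe`.
#' @param threshold Crossing threshold as a fraction of each channel's
#'   range (default 0.5).
#' @param debounce_ms Minimum separation between successive crossings of
#'   the same channel; closer crossings are merged (default 50 ms).
#' @return An [event_series]. If a channel shows no usable crossings the
#'   series is returned empty with `detected = FALSE`.
#' @export
detect_events <- function(record, threshold = 0.5, debounce_ms = 50) {
  need <- c("left_heel", "left_toe", "right_heel", "right_toe")
  have <- record$channels$label[record$channels$role == "footswitch"]
  miss <- setdiff(need, have)
  if (length(miss)) {
    stop("missing footswitch channel role(s): ", paste(miss, collapse = ", "))
  }
  fs <- record$sample_rate_hz

  crossings <- function(x, up) {
    rng <- range(x)
    if (diff(rng) <= 0) return(numeric(0))
    thr <- rng[1] + threshold * diff(rng)
    n <- length(x)
    below <- x < thr
    if (up) {
      i <- which(below[-n] & !below[-1])
    } else {
      i <- which(!below[-n] & below[-1])
    }
    if (!length(i)) return(numeric(0))
    frac <- (thr - x[i]) / (x[i + 1L] - x[i])
    t <- (i - 1L + frac) / fs
    # debounce: drop crossings within debounce_ms of the previous kept one
    keep <- c(TRUE, diff(t) > debounce_ms / 1000)
    while (!all(keep)) {
      t <- t[keep]
      keep <- c(TRUE, diff(t) > debounce_ms / 1000)
    }
    t
  }

  lhs <- crossings(get_channel(record, "left_heel"), up = TRUE)
  lto <- crossings(get_channel(record, "left_toe"), up = FALSE)
  rhs <- crossings(get_channel(record, "right_heel"), up = TRUE)
  rto <- crossings(get_channel(record, "right_toe"), up = FALSE)

  if (!length(lhs) && !length(rhs)) {
    warning("no footswitch threshold crossings found; returning empty event series")
    return(event_series(
      left = list(heel_strikes = numeric(0), toe_offs = numeric(0)),
      right = list(heel_strikes = numeric(0), toe_offs = numeric(0)),
      detected = FALSE
    ))
  }
  event_series(
    left = list(heel_strikes = lhs, toe_offs = lto),
    right = list(heel_strikes = rhs, toe_offs = rto)
  )
}

#' Validity screen on heel-strike counts
#'
#' A record is flagged invalid when either foot carries fewer valid heel
#' strikes than `min_heel_strikes` (default 100, the exclusion rule applied
#' to the walking recordings this pipeline targets).
#'
#' @param events An [event_series].
#' @param min_heel_strikes Minimum number of valid heel strikes per foot.
#' @return A list with `valid` (logical), per-foot `counts`, and the
#'   threshold used.
#' @export
validate_record <- function(events, min_heel_strikes = 100) {
  counts <- c(
    left = sum(events$left$valid),
    right = sum(events$right$valid)
  )
  list(
    valid = events$detected && all(counts >= min_heel_strikes),
    counts = counts,
    min_heel_strikes = min_heel_strikes
  )
}

#' Mark events inside given time intervals as invalid
#'
#' Heel strikes falling in any `[start, end]` interval (e.g. turning
#' sections of an overground walk) are flagged invalid; cycles anchored on
#' them are excluded from parameter and epoch computation.
#'
#' @param events An [event_series].
#' @param intervals Two-column matrix or data.frame of `start`, `end`
#'   times in seconds.
#' @return The updated [event_series].
#' @export
mask_intervals <- function(events, intervals) {
  intervals <- as.matrix(intervals)
  stopifnot(ncol(intervals) == 2)
  for (foot in c("left", "right")) {
    hs <- events[[foot]]$heel_strikes
    bad <- rep(FALSE, length(hs))
    for (k in seq_len(nrow(intervals))) {
      bad <- bad | (hs >= intervals[k, 1] & hs <= intervals[k, 2])
    }
    events[[foot]]$valid <- events[[foot]]$valid & !bad
  }
  events
}

# per-foot cycle table: one row per heel strike with the phase landmarks
# needed downstream; errors if the one-toe-off-per-cycle invariant fails.
foot_cycles <- function(events, foot) {
  this <- events[[foot]]
  other <- events[[if (foot == "left") "right" else "left"]]
  hs <- this$heel_strikes
  n <- length(hs)
  if (n < 2L) return(NULL)
  out <- data.frame(
    hs = hs[-n], next_hs = hs[-1],
    to = NA_real_, contra_hs = NA_real_,
    valid = this$valid[-n] & this$valid[-1]
  )
  for (i in seq_len(n - 1L)) {
    to_in <- this$toe_offs[this$toe_offs > out$hs[i] & this$toe_offs < out$next_hs[i]]
    if (length(to_in) != 1L) {
      stop(sprintf(
        "event interleaving violated: %d toe-offs between %s heel strikes at %.3f s and %.3f s",
        length(to_in), foot, out$hs[i], out$next_hs[i]
      ))
    }
    out$to[i] <- to_in
    c_in <- other$heel_strikes[other$heel_strikes > out$hs[i] &
                                 other$heel_strikes < out$next_hs[i]]
    out$contra_hs[i] <- if (length(c_in)) c_in[1] else NA_real_
  }
  out
}

#' Temporal gait parameters from an event series
#'
#' Definitions, per same-foot gait cycle: stride time = interval between
#' successive heel strikes of one foot; step time = heel strike to the next
#' contralateral heel strike; stance = heel strike to the same foot's
#' toe-off; swing (single support) = toe-off to the next same-foot heel
#' strike; double support = contralateral heel strike to the same foot's
#' toe-off, computed per step (two steps per stride) and averaged.
#' Variability = SD across valid cycles. Means are pooled over feet by
#' default.
#'
#' @param events An [event_series] with at least 2 valid heel strikes per
#'   foot.
#' @param walking_speed_kmh Optional walking speed metadata, passed
#'   through.
#' @param pool_feet Pool cycles of both feet (default) or report the mean
#'   of per-foot means.
#' @return A one-row `data.frame` of class `gait_parameters`.
#' @export
compute_gait_parameters <- function(events, walking_speed_kmh = NA_real_,
                                    pool_feet = TRUE) {
  cyc <- rbind(foot_cycles(events, "left"), foot_cycles(events, "right"))
  if (is.null(cyc) || sum(cyc$valid) < 1L) {
    stop("need at least 2 valid heel strikes per foot to compute gait parameters")
  }
  cyc <- cyc[cyc$valid, , drop = FALSE]
  stride <- cyc$next_hs - cyc$hs
  stance <- cyc$to - cyc$hs
  swing <- cyc$next_hs - cyc$to
  step <- cyc$contra_hs - cyc$hs              # this foot HS -> contra HS
  dsupp <- cyc$to - cyc$contra_hs             # contra HS -> this foot TO
  out <- data.frame(
    walking_speed_kmh = walking_speed_kmh,
    stride_time_s = mean(stride),
    stride_time_sd_s = stats::sd(stride),
    step_time_s = mean(step, na.rm = TRUE),
    step_time_sd_s = stats::sd(step[!is.na(step)]),
    stance_s = mean(stance),
    swing_single_support_s = mean(swing),
    double_support_s = mean(dsupp, na.rm = TRUE),
    n_cycles = nrow(cyc)
  )
  class(out) <- c("gait_parameters", class(out))
  out
}

#' Export an event series as tidy TSV
#'
#' Columns: `foot`, `event_type` (`heel_strike`/`toe_off`), `time_s`,
#' `valid`.
#'
#' @param events An [event_series].
#' @param path Output TSV path.
#' @return `path`, invisibly.
#' @export
write_events <- function(events, path) {
  rows <- do.call(rbind, lapply(c("left", "right"), function(foot) {
    f <- events[[foot]]
    rbind(
      data.frame(foot = foot, event_type = "heel_strike",
                 time_s = f$heel_strikes, valid = f$valid),
      if (length(f$toe_offs)) {
        data.frame(foot = foot, event_type = "toe_off",
                   time_s = f$toe_offs, valid = TRUE)
      }
    )
  }))
  utils::write.table(rows, path, sep = "\t", row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Read an event series written by [write_events()]
#'
#' @param path TSV path.
#' @return An [event_series].
#' @export
read_events <- function(path) {
  d <- utils::read.table(path, header = TRUE, sep = "\t")
  pick <- function(foot) {
    hs <- d[d$foot == foot & d$event_type == "heel_strike", ]
    list(
      heel_strikes = hs$time_s,
      toe_offs = d$time_s[d$foot == foot & d$event_type == "toe_off"],
      valid = as.logical(hs$valid)
    )
  }
  event_series(left = pick("left"), right = pick("right"))
}
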