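make_epochs <- function(fun, L, fs = 2000, dur = 1) {
  n <- round(dur * fs)
  t <- -0.8 + (seq_len(n) - 1) / fs
  data <- array(NA_real_, dim = c(L, 1, n))
  for (k in seq_len(L)) data[k, 1, ] <- fun(t, k)
  toy_epochs(data, fs, t, "x", "eeg")
}

test_that("epoching honours the window, the epoch cap and validity flags", {
  gr <- generate_record(synth_config("young", duration_s = 300, seed = 44))
  ev <- gr$truth$event_series
  ep <- epoch_signals(gr$record, ev, "left", channels = "C3")
  expect_equal(ep$L, 220)            # more strides than the cap
  expect_equal(dim(ep$data)[3], 2000)
  expect_equal(ep$t[1], -0.8)
  # heel strike maps to t = 0 within half a sample
  expect_lt(abs(ep$t[which.min(abs(ep$t))]), 0.5 / 2000)

  # a heel strike too close to the record start is dropped
  ev2 <- event_series(
    left = list(heel_strikes = c(0.5, 2, 3.1), toe_offs = c(1.19, 2.69)),
    right = list(heel_strikes = c(1.05, 2.55), toe_offs = c(1.74, 3.24))
  )
  short <- signal_record(matrix(rnorm(2000 * 4), 1), 2000,
                         data.frame(label = "C3", role = "eeg", units = "uV"))
  ep2 <- epoch_signals(short, ev2, "left")
  expect_equal(ep2$L, 2L)            # the 0.5-s strike lacks its pre-window
  expect_equal(ep2$hs_times, c(2, 3.1))

  # fewer valid strides than the cap: L is the actual count (the first
  # heel strike at 0.5 s lacks its pre-window, leaving 149 of 150)
  ev3 <- ev
  ev3$left$valid[151:length(ev3$left$valid)] <- FALSE
  ep3 <- epoch_signals(gr$record, ev3, "left", channels = "C3")
  expect_equal(ep3$L, 149L)
})

test_that("the STFT grid has 26 fully-contained windows and a 2.667 Hz frequency step", {
  ep <- make_epochs(function(t, k) rnorm(length(t)), L = 2)
  sp <- stft(ep, "x")
  expect_equal(dim(sp$coef), c(2, length(sp$freq), 26))
  expect_equal(diff(sp$freq)[1], 2000 / 750)
  expect_equal(diff(sp$time), rep(0.025, 25), tolerance = 1e-12)
  # all window supports (first to last covered sample) lie inside the epoch
  half <- (750 - 1) / 2 / 2000
  expect_gte(min(sp$time) - half, -0.8 - 1e-9)
  expect_lte(max(sp$time) + half, 0.2 + 1e-9)
})

test_that("a 16 Hz sinusoid concentrates at the 16 Hz bin with the Hann-predicted power", {
  ep <- make_epochs(function(t, k) sin(2 * pi * 16 * t), L = 1)
  sp <- stft(ep, "x", fmax = 100)
  i16 <- which.min(abs(sp$freq - 16))
  expect_equal(sp$freq[i16], 16)
  mag <- Mod(sp$coef[1, , 13])
  expect_equal(which.max(mag), i16)
  # analytic value: half the window sum for a unit sinusoid on the grid
  pred <- sum(signal::hanning(750)) / 2
  expect_equal(mag[i16]^2, pred^2, tolerance = 0.05)
  # zero signal gives all-zero coefficients
  sp0 <- stft(make_epochs(function(t, k) 0 * t, L = 1), "x")
  expect_equal(max(Mod(sp0$coef)), 0)
})

test_that("percent-change power is zero-mean per frequency and matches the oracle", {
  set.seed(10)
  X <- random_coef(4, 3, 5)
  sp <- toy_spectrogram(X)
  m <- event_related_power(sp, "percent")
  expect_equal(m$values, oracle_percent_power(X), tolerance = 1e-12)
  # per-trial normalization forces zero time-mean, which survives averaging
  expect_equal(rowMeans(m$values), rep(0, 3), tolerance = 1e-9)

  # time-constant power maps to exactly zero
  Xc <- array(rep(complex(modulus = 2, argument = 0.3), 2 * 2 * 4),
              dim = c(2, 2, 4))
  expect_equal(max(abs(event_related_power(toy_spectrogram(Xc), "percent")$values)), 0)

  # power 2c in one half, c in the other: +/- 33.3% around the mean
  Xh <- array(complex(modulus = rep(c(sqrt(2), 1), each = 2), argument = 0),
              dim = c(1, 1, 4))
  expect_equal(as.vector(event_related_power(toy_spectrogram(Xh), "percent")$values),
               c(100 / 3, 100 / 3, -100 / 3, -100 / 3), tolerance = 1e-9)

  # log mode: natural log of across-trial mean power
  lg <- event_related_power(sp, "log")
  expect_equal(lg$values, log(colMeans(Mod(X)^2, dims = 1)), tolerance = 1e-12)
})

test_that("inter-trial coherence matches the loop oracle and its boundary values", {
  set.seed(11)
  X <- random_coef(5, 4, 3)
  itc <- intertrial_coherence(toy_spectrogram(X))
  expect_equal(itc$values, oracle_itc(X), tolerance = 1e-12)
  expect_true(all(itc$values >= 0 & itc$values <= 1))

  # identical trials: perfect locking
  Xi <- array(rep(X[1, , ], each = 5), dim = dim(X))
  expect_equal(intertrial_coherence(toy_spectrogram(Xi))$values,
               matrix(1, 4, 3), tolerance = 1e-12)

  # independent random-phase trials: expectation 1/L over many bins
  L <- 20
  Xr <- random_coef(L, 60, 40)
  expect_equal(mean(intertrial_coherence(toy_spectrogram(Xr))$values), 1 / L,
               tolerance = 0.1)
  expect_error(intertrial_coherence(toy_spectrogram(random_coef(1, 2, 2))),
               "L >= 2")
})

test_that("coherence matches the loop oracle, is 1 for identical inputs and scale invariant", {
  set.seed(12)
  X <- random_coef(3, 4, 2)
  Y <- random_coef(3, 4, 2)
  C <- corticomuscular_coherence(toy_spectrogram(X), toy_spectrogram(Y))
  expect_equal(C$values, oracle_coherence(X, Y), tolerance = 1e-12)
  expect_true(all(C$values >= 0 & C$values <= 1))
  # Y = X gives coherence exactly 1
  C1 <- corticomuscular_coherence(toy_spectrogram(X), toy_spectrogram(X))
  expect_equal(C1$values, matrix(1, 4, 2), tolerance = 1e-12)
  # invariant to global rescaling of either signal
  C2 <- corticomuscular_coherence(toy_spectrogram(3.7 * X),
                                  toy_spectrogram(0.2 * Y))
  expect_equal(C2$values, C$values, tolerance = 1e-12)
  # independent signals: expectation ~ 1/L
  L <- 25
  Cn <- corticomuscular_coherence(toy_spectrogram(random_coef(L, 50, 40)),
                                  toy_spectrogram(random_coef(L, 50, 40)))
  expect_equal(mean(Cn$values), 1 / L, tolerance = 0.1)
  expect_error(corticomuscular_coherence(toy_spectrogram(X),
                                         toy_spectrogram(random_coef(4, 4, 2))),
               "match")
})

test_that("the parametric z-transform matches its closed form and caps the extremes", {
  # C = 0.5, L = 11: p = 0.5^10, z = qnorm(1 - p), evaluated independently
  m <- toy_map(matrix(0.5, 1, 1), 1, 1, L = 11)
  p <- (1 - 0.5)^10
  expect_equal(as.vector(coherence_to_z(m)$values), qnorm(1 - p),
               tolerance = 1e-9)
  expect_equal(p, 9.765625e-4)
  # C = 0: p = 1, z floored at the cap
  z0 <- coherence_to_z(toy_map(matrix(0, 1, 1), 1, 1, L = 50))
  expect_equal(as.vector(z0$values), -8.2)
  # C = 1 maps to the finite cap
  z1 <- coherence_to_z(toy_map(matrix(1, 1, 1), 1, 1, L = 50))
  expect_equal(as.vector(z1$values), 8.2)
  expect_error(coherence_to_z(toy_map(matrix(0.5, 1, 1), 1, 1, L = 1)),
               "L >= 2")
})

test_that("confidence masking uses the closed-form threshold and respects its limits", {
  expect_equal(coherence_threshold(220, 0.05), 1 - 0.05^(1 / 219),
               tolerance = 1e-12)
  expect_equal(coherence_threshold(220, 0.05), 0.01359, tolerance = 1e-3)
  # threshold decreases with trial count
  Ls <- c(10, 50, 100, 220)
  expect_true(all(diff(coherence_threshold(Ls)) < 0))
  # alpha -> 1 lets everything survive
  set.seed(13)
  v <- matrix(runif(20, 0.001, 0.999), 4, 5)
  m <- toy_map(v, 1:4, 1:5, L = 30)
  out <- threshold_map(m, alpha = 1 - 1e-12)
  expect_equal(out$values, v, tolerance = 1e-6)
  # masked values are exactly zero and recorded
  out2 <- threshold_map(m, alpha = 0.05)
  expect_true(all(out2$values[out2$mask] == 0))
  expect_equal(out2$mask, v < coherence_threshold(30, 0.05))
  expect_error(threshold_map(m, alpha = 1.2), "alpha")
})

test_that("band and window averaging selects bins by closed-interval centre membership", {
  freq <- (0:40) * 2000 / 750
  time <- seq(0, 0.125, by = 0.025)
  vals <- outer(freq, seq_along(time), function(f, t) f + t)
  m <- toy_map(vals, freq, time, L = 10)
  # low beta on the 2.667 Hz grid: bins 13.33, 16.00, 18.67
  sel <- band_window_average(m, "low_beta", window = c(0, 0.125))
  expect_equal(sel$n_bins, 3 * 6)
  fi <- which(freq >= 13 & freq <= 20)
  expect_equal(freq[fi], c(13.33333, 16, 18.66667), tolerance = 1e-4)
  expect_equal(sel$value, mean(vals[fi, ]))
  # constant map averages to the constant
  mc <- toy_map(matrix(4.2, 41, 6), freq, time, L = 5)
  expect_equal(band_window_average(mc, "gamma")$value, 4.2)
  # empty selections are refused with grid information
  expect_error(band_window_average(m, c(300, 310)), "empty")
})
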