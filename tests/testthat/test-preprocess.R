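# small record builders ------------------------------------------------------

eeg_record <- function(mat, fs = 2000, labels = NULL, roles = "eeg") {
  labels <- labels %||% paste0("ch", seq_len(nrow(mat)))
  signal_record(mat, fs, data.frame(
    label = labels,
    role = rep(roles, length.out = nrow(mat)),
    units = "uV"
  ))
}

test_that("variance normalization yields unit SD and is scale invariant", {
  set.seed(1)
  x <- rbind(2 * rnorm(5000), 0.5 * rnorm(5000))
  rec <- eeg_record(x)
  out <- normalize_variance(rec, roles = "eeg")
  expect_equal(apply(out$samples, 1, sd), c(ch1 = 1, ch2 = 1), tolerance = 1e-12)
  rec7 <- rec; rec7$samples <- 7 * rec7$samples
  out7 <- normalize_variance(rec7, roles = "eeg")
  expect_equal(out$samples, out7$samples, tolerance = 1e-12)
  # divisors are the channel SDs
  expect_equal(out$samples[1, ], x[1, ] / sd(x[1, ]), tolerance = 1e-12)
})

test_that("zero-variance channels are refused by name", {
  rec <- eeg_record(rbind(rnorm(100), rep(3, 100)), labels = c("C3", "flat"))
  expect_error(normalize_variance(rec), "flat")
})

test_that("EEG band-pass keeps the passband and removes slow drift", {
  fs <- 500
  t <- seq(0, 120 - 1 / fs, by = 1 / fs)
  rec <- eeg_record(rbind(sin(2 * pi * 10 * t), sin(2 * pi * 0.05 * t)), fs = fs)
  out <- filter_eeg(rec)
  mid <- seq(20 * fs, 100 * fs)
  expect_equal(sd(out$samples[1, mid]) / sd(rec$samples[1, mid]), 1,
               tolerance = 0.01)
  expect_lt(sd(out$samples[2, mid]) / sd(rec$samples[2, mid]), 0.10)
  expect_error(filter_eeg(eeg_record(matrix(rnorm(100), 1), fs = 120)),
               "sampling rate")
})

test_that("filtered white-noise spectrum follows the squared transfer magnitude", {
  fs <- 2000
  set.seed(4)
  x <- rnorm(fs * 60)
  rec <- eeg_record(matrix(x, 1), fs = fs)
  y <- filter_eeg(rec)$samples[1, ]
  sp_in <- spec.pgram(ts(x, frequency = fs), spans = c(51, 51), plot = FALSE,
                      taper = 0)
  sp_out <- spec.pgram(ts(y, frequency = fs), spans = c(51, 51), plot = FALSE,
                       taper = 0)
  # analytic double-pass magnitude response of the 2nd-order Butterworth
  h <- signal::freqz(signal::butter(2, c(0.5, 70) / (fs / 2), "pass"),
                     Fs = fs, n = 4096)
  Hmag4 <- Mod(h$h)^4  # forward-backward application squares |H|^2
  pick <- c(5, 10, 20, 40, 60)
  emp <- approx(sp_in$freq, sp_out$spec / sp_in$spec, xout = pick)$y
  ana <- approx(h$f, Hmag4, xout = pick)$y
  expect_equal(emp, ana, tolerance = 0.1)
  # strong attenuation well above the band
  expect_lt(approx(sp_in$freq, sp_out$spec / sp_in$spec, xout = 200)$y, 0.05)
})

test_that("zero-phase filtering keeps a symmetric pulse symmetric", {
  fs <- 2000
  n <- 8000
  t <- (seq_len(n) - 1) / fs
  pulse <- exp(-(t - 2)^2 / (2 * 0.05^2))
  out <- filter_eeg(eeg_record(matrix(pulse, 1), fs = fs))$samples[1, ]
  ctr <- which.max(out)
  expect_equal(ctr, which.max(pulse))
  k <- 300
  expect_equal(out[(ctr - k):(ctr - 1)], rev(out[(ctr + 1):(ctr + k)]),
               tolerance = 1e-6)
})

test_that("common average reference zeroes the cross-channel mean and removes common mode", {
  set.seed(2)
  base <- matrix(rnorm(4 * 1000), 4)
  common <- sin(2 * pi * 7 * (1:1000) / 2000)
  rec <- eeg_record(sweep(base, 2, common, "+"))
  rec$samples <- rbind(rec$samples, aux = 1:1000)
  rec$channels <- rbind(rec$channels,
                        data.frame(label = "aux", role = "emg", units = "uV"))
  out <- rereference_car(rec)
  eeg <- out$samples[1:4, ]
  expect_equal(max(abs(colMeans(eeg))), 0, tolerance = 1e-12)
  car_base <- sweep(base, 2, colMeans(base))
  expect_equal(eeg, car_base, tolerance = 1e-12, ignore_attr = TRUE)
  # non-EEG channels untouched
  expect_equal(out$samples["aux", ], rec$samples["aux", ], tolerance = 0)
})

test_that("bipolar derivation is the plain channel difference and cancels far fields", {
  s <- sin(2 * pi * 11 * (1:4000) / 2000)
  far <- cos(2 * pi * 3 * (1:4000) / 2000)
  rec <- eeg_record(rbind(s + far, far, s + far, far),
                    labels = c("C3", "F3", "C4", "F4"))
  out <- bipolar_derive(rec)
  expect_equal(nrow(out$samples) - nrow(rec$samples), 2L)
  expect_equal(get_channel(out, "C3-F3"), s, tolerance = 1e-12,
               ignore_attr = TRUE)
  expect_equal(get_channel(out, "C4-F4"), s, tolerance = 1e-12,
               ignore_attr = TRUE)
  expect_error(bipolar_derive(rec, data.frame(anode = "Cz", cathode = "F3")),
               "Cz")
})

test_that("CAR then bipolar equals bipolar alone on the pair difference", {
  set.seed(3)
  rec <- eeg_record(matrix(rnorm(4 * 2000), 4),
                    labels = c("C3", "F3", "C4", "F4"))
  d1 <- get_channel(bipolar_derive(rereference_car(rec)), "C3-F3")
  d2 <- get_channel(bipolar_derive(rec), "C3-F3")
  expect_equal(d1, d2, tolerance = 1e-12)
})

test_that("EMG rectification gives a flat envelope for a pure sinusoid", {
  fs <- 2000
  t <- seq(0, 10 - 1 / fs, by = 1 / fs)
  rec <- eeg_record(matrix(sin(2 * pi * 40 * t), 1), fs = fs,
                    labels = "TA_left", roles = "emg")
  out <- preprocess_emg(rec)
  rect <- get_channel(out, "TA_left_rect")
  mid <- seq(2 * fs, 8 * fs)
  expect_equal(mean(rect[mid]), 1, tolerance = 0.02)
  expect_lt(sd(rect[mid]), 0.02)
})

test_that("demodulation flattens periodic amplitude modulation and preserves phase", {
  # a 60 Hz carrier with slow periodic AM: the rectified envelope carries
  # the modulation, the demodulated signal has it removed (unit
  # instantaneous amplitude) with the modulation phase intact
  fs <- 2000
  t <- seq(0, 20 - 1 / fs, by = 1 / fs)
  am <- (1 + 0.8 * sin(2 * pi * 0.9 * t)) * sin(2 * pi * 60 * t)
  rec <- eeg_record(matrix(am, 1), fs = fs, labels = "TA_left", roles = "emg")
  out <- preprocess_emg(rec)
  mid <- seq(2 * fs, 18 * fs)
  rect <- get_channel(out, "TA_left_rect")
  expect_gt(cor(rect[mid], 1 + 0.8 * sin(2 * pi * 0.9 * t[mid])), 0.999)
  demod <- get_channel(out, "TA_left_demod")
  amp <- Mod(analytic_signal(demod))
  expect_equal(mean(abs(amp[mid] - 1)), 0, tolerance = 0.02)
  expect_lt(max(abs(demod)), 1 + 1e-6)
  # phase sequence preserved: demodulation divides the analytic signal of
  # the mean-subtracted envelope by its modulus, leaving the argument
  # unchanged
  z <- analytic_signal(rect - mean(rect))
  expect_equal(Arg(analytic_signal(demod))[mid], Arg(z)[mid], tolerance = 0.05)
})

test_that("demodulation is idempotent up to floor effects", {
  fs <- 2000
  t <- seq(0, 10 - 1 / fs, by = 1 / fs)
  x <- (1 + 0.6 * sin(2 * pi * 1.1 * t)) * sin(2 * pi * 55 * t)
  demod_once <- function(v) {
    z <- analytic_signal(v - mean(v))
    Re(z) / pmax(Mod(z), 1e-8 * median(Mod(z)))
  }
  d1 <- demod_once(Mod(analytic_signal(x)))
  d2 <- demod_once(d1)
  mid <- seq(fs, 9 * fs)
  expect_gt(cor(d1[mid], d2[mid]), 0.99)
})

test_that("amplitude rejection removes exactly the contaminated epochs", {
  set.seed(8)
  L <- 30
  data <- array(rnorm(L * 2 * 400, sd = 20), dim = c(L, 2, 400))
  bad <- sort(sample(L, 10))
  for (k in bad) data[k, 1, 200] <- 400
  ep <- toy_epochs(data, fs = 2000, t = seq(-0.1, 0.0995, by = 5e-4),
                   labels = c("C3", "C4"), roles = c("eeg", "eeg"))
  out <- reject_epochs(ep, 300)
  expect_equal(which(out$report$rejected), bad)
  expect_equal(out$epochs$L, L - 10)
  # infinite threshold is the identity
  all_in <- reject_epochs(ep, Inf)
  expect_equal(all_in$epochs$L, L)
  # all-rejected input is an error advising threshold review
  expect_error(reject_epochs(ep, 1e-9), "threshold")
})
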