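# Deterministic double-burst EMG envelope builders shared by the envelope
# and acceptance tests.

burst_profile <- function(t, centers = c(-0.33, 0, 0.06),
                          widths = c(0.04, 0.012, 0.012),
                          amps = c(0.5, 1, 1)) {
  out <- rep(0.05, length(t))
  for (i in seq_along(centers)) {
    out <- out + amps[i] * exp(-(t - centers[i])^2 / (2 * widths[i]^2))
  }
  out
}

burst_epochs <- function(L = 8, fs = 2000, noise_sd = 0, seed = 1, ...) {
  set.seed(seed)
  n <- fs
  t <- -0.8 + (seq_len(n) - 1) / fs
  data <- array(NA_real_, dim = c(L, 1, n))
  for (k in seq_len(L)) {
    data[k, 1, ] <- burst_profile(t, ...) + rnorm(n, sd = noise_sd)
  }
  list(epochs = toy_epochs(data, fs, t, "TA_left_rect", "emg_rect"), t = t)
}
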