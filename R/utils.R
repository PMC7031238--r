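#' Analytic signal via the FFT half-spectrum construction
#'
#' Returns the complex analytic signal `x + i * H(x)` where `H` is the
#' Hilbert transform. The modulus of the result is the instantaneous
#' (Hilbert) amplitude, the argument the instantaneous phase.
#'
#' @param x Real numeric vector.
#' @return Complex vector of the same length.
#' @examples
#' z <- analytic_signal(cos(2 * pi * 5 * seq(0, 1, by = 1e-3)))
#' summary(Mod(z[100:900]))  # ~1: constant envelope of a pure sinusoid
#' @export
analytic_signal <- function(x) {
  stopifnot(is.numeric(x), length(x) > 1L)
  n <- length(x)
  X <- stats::fft(x)
  h <- numeric(n)
  if (n %% 2L == 0L) {
    h[1L] <- 1
    h[n / 2L + 1L] <- 1
    h[2:(n / 2L)] <- 2
  } else {
    h[1L] <- 1
    h[2:((n + 1L) / 2L)] <- 2
  }
  stats::fft(X * h, inverse = TRUE) / n
}

# 1/f^exponent power-spectrum noise, unit variance, by spectral shaping of
# white Gaussian noise. exponent refers to the power spectrum (amplitude
# scales as f^(-exponent/2)).
pink_noise <- function(n, exponent = 1) {
  stopifnot(n > 3L)
  w <- stats::rnorm(n)
  W <- stats::fft(w)
  f <- c(1, seq_len(n - 1))           # guard DC; relative frequencies
  f <- pmin(f, n - f + 1)             # fold to two-sided spectrum
  amp <- f^(-exponent / 2)
  amp[1] <- 0                         # remove DC
  x <- Re(stats::fft(W * amp, inverse = TRUE) / n)
  x / stats::sd(x)
}

# Linear ramp from 0 to 1 centred on `center` with total rise time
# `rise_s`; evaluated on time grid t. Used for footswitch contact edges.
ramp_up <- function(t, center, rise_s) {
  pmin(1, pmax(0, (t - center) / rise_s + 0.5))
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# Zero-phase (forward-backward) filtering with odd-reflection edge
# padding, which suppresses the start/end transients of a plain
# forward-backward pass. `pad` is the number of padded samples per edge.
zero_phase <- function(filt, x, pad = min(length(x) - 1L, 2000L)) {
  n <- length(x)
  pad <- max(1L, min(as.integer(pad), n - 1L))
  xp <- c(2 * x[1] - x[(pad + 1L):2L],
          x,
          2 * x[n] - x[(n - 1L):(n - pad)])
  y <- signal::filtfilt(filt, xp)
  y[(pad + 1L):(pad + n)]
}

# sample indices of the time interval [lo, hi] on a uniform grid
# t = (0:(n-1))/fs, clamped to the record
idx_window <- function(n, fs, lo, hi) {
  i1 <- max(1L, as.integer(floor(lo * fs)) + 1L)
  i2 <- min(n, as.integer(ceiling(hi * fs)) + 1L)
  if (i1 > i2) integer(0) else i1:i2
}
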