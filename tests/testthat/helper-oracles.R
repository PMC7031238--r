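# Independent brute-force oracles and toy-object constructors used across
# the spectral and statistics tests. The oracles evaluate the defining
# sums with explicit loops and share no code with the package
# implementations.

# spectrogram object from a given complex coefficient array (L x F x T)
toy_spectrogram <- function(coef, freq = NULL, time = NULL) {
  d <- dim(coef)
  structure(
    list(
      coef = coef,
      freq = freq %||% seq_len(d[2]),
      time = time %||% seq_len(d[3]),
      L = d[1], fs = NA_real_, window = "toy", channel = "toy"
    ),
    class = "spectrogram"
  )
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# loop-based magnitude-squared coherence across trials
oracle_coherence <- function(X, Y) {
  d <- dim(X)
  C <- matrix(NA_real_, d[2], d[3])
  for (f in seq_len(d[2])) {
    for (t in seq_len(d[3])) {
      sxy <- 0 + 0i; sxx <- 0; syy <- 0
      for (k in seq_len(d[1])) {
        sxy <- sxy + X[k, f, t] * Conj(Y[k, f, t])
        sxx <- sxx + Mod(X[k, f, t])^2
        syy <- syy + Mod(Y[k, f, t])^2
      }
      C[f, t] <- Mod(sxy)^2 / (sxx * syy)
    }
  }
  C
}

# loop-based inter-trial coherence
oracle_itc <- function(X) {
  d <- dim(X)
  out <- matrix(NA_real_, d[2], d[3])
  for (f in seq_len(d[2])) {
    for (t in seq_len(d[3])) {
      s <- 0 + 0i; pw <- 0
      for (k in seq_len(d[1])) {
        s <- s + X[k, f, t]
        pw <- pw + Mod(X[k, f, t])^2
      }
      out[f, t] <- Mod(s)^2 / (d[1] * pw)
    }
  }
  out
}

# loop-based single-trial percent-change power, averaged over trials
oracle_percent_power <- function(X) {
  d <- dim(X)
  P <- Mod(X)^2
  acc <- matrix(0, d[2], d[3])
  for (k in seq_len(d[1])) {
    for (f in seq_len(d[2])) {
      m <- mean(P[k, f, ])
      acc[f, ] <- acc[f, ] + 100 * (P[k, f, ] - m) / m
    }
  }
  acc / d[1]
}

# literal textbook step-up Benjamini-Hochberg rule
oracle_bh <- function(p) {
  m <- length(p)
  o <- order(p)
  sorted <- p[o]
  adj <- numeric(m)
  for (i in seq_len(m)) {
    adj[i] <- min(1, min(sorted[i:m] * m / (i:m)))
  }
  out <- numeric(m)
  out[o] <- adj
  out
}

# random complex Gaussian coefficient array
random_coef <- function(L, F, T) {
  array(complex(real = stats::rnorm(L * F * T),
                imaginary = stats::rnorm(L * F * T)),
        dim = c(L, F, T))
}

# tf_map built directly from a value matrix
toy_map <- function(values, freq, time, measure = "toy", L = NA_integer_) {
  structure(
    list(values = values, freq = freq, time = time, measure = measure,
         L = L, mask = NULL),
    class = "tf_map"
  )
}

# epoch_set built directly from a trial x channel x time array
toy_epochs <- function(data, fs, t, labels, roles) {
  structure(
    list(
      data = data, t = t, fs = fs,
      channels = data.frame(label = labels, role = roles,
                            units = rep("a.u.", length(labels))),
      L = dim(data)[1], ref_foot = "left",
      hs_times = seq_len(dim(data)[1]),
      window = range(t)
    ),
    class = "epoch_set"
  )
}
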