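# Small configurations shared across test files.  Durations are kept short
# so generation stays in the millisecond range; the full-scale run lives in
# test-acceptance.R.

small_stimulus <- function(duration_s = 20) stimulus_config(duration_s = duration_s)

small_cohort <- function(n_subjects = 3, noise_sd = 0, duration_s = 20, ...) {
  cohort_config(n_subjects = n_subjects, noise_sd = noise_sd,
                stimulus = small_stimulus(duration_s), ...)
}

# Raw periodogram: power at the discrete Fourier frequencies of the
# zero-padded, demeaned signal.  Used as an independent spectral oracle.
periodogram_peak_hz <- function(x, fs, nfft = 2^14) {
  x <- x - mean(x)
  xp <- c(x, rep(0, max(0, nfft - length(x))))
  p <- Mod(fft(xp))^2
  k <- 2:(floor(nfft / 2))
  (k[which.max(p[k])] - 1) * fs / nfft
}

# Naive time-domain lagged convolution, independent of the package's
# vectorized implementation.
naive_lagged_convolve <- function(s, k, lags) {
  n <- length(s)
  out <- numeric(n)
  for (t in seq_len(n)) {
    acc <- 0
    for (j in seq_along(lags)) {
      src <- t - lags[j]
      if (src >= 1 && src <= n) acc <- acc + k[j] * s[src]
    }
    out[t] <- acc
  }
  out
}

# Brute-force ridge solution via explicit matrix inversion on a naively
# constructed lag matrix.
naive_ridge <- function(s, r, lags, lambda) {
  n <- length(s)
  S <- matrix(0, n, length(lags))
  for (j in seq_along(lags)) {
    for (t in seq_len(n)) {
      src <- t - lags[j]
      if (src >= 1 && src <= n) S[t, j] <- s[src]
    }
  }
  solve(t(S) %*% S + lambda * diag(length(lags))) %*% (t(S) %*% r)
}

# trf_set filled from ground-truth kernels plus optional additive noise.
kernel_trf_set <- function(channels = c("C3", "CP3", "CPz"),
                           conditions = c(-4, -2, -0.5, 0.5, 2, 4),
                           n_subjects = 3, kp = kernel_params(),
                           noise_sd = 0, seed = 42) {
  sp <- lag_spec()
  arr <- array(0, c(length(sp$lag_ms), length(channels),
                    length(conditions), n_subjects))
  set.seed(seed)
  for (s in seq_len(n_subjects)) for (ci in seq_along(conditions)) {
    k <- as.numeric(ground_truth_kernel(kp, conditions[ci], sp))
    for (e in seq_along(channels)) {
      arr[, e, ci, s] <- k + if (noise_sd > 0)
        rnorm(length(k), 0, noise_sd) else 0
    }
  }
  trf_set(arr, sp$lag_ms, channels, conditions, seq_len(n_subjects))
}
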