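fs <- 120

test_that("band-pass filter is linear, flat in-band and zero-phase", {
  spec <- filter_spec()
  n <- 1200
  expect_equal(bandpass_filter(rep(0, n), fs, spec), rep(0, n))
  # 5 Hz unit sine: amplitude within 5%, no lag at the cross-correlation peak
  t <- (0:(n - 1)) / fs
  x <- sin(2 * pi * 5 * t)
  y <- bandpass_filter(x, fs, spec)
  mid <- 300:900
  expect_lt(abs(max(abs(y[mid])) - 1), 0.05)
  lags <- -5:5
  xc <- vapply(lags, function(l) {
    cor(x[mid], y[mid + l])
  }, numeric(1))
  expect_equal(lags[which.max(xc)], 0)
  expect_gt(max(xc), 0.999)
})

test_that("DC is attenuated by at least 40 dB", {
  spec <- filter_spec()
  taps <- design_bandpass_fir(spec, fs)
  # designed response evaluated at 0 Hz
  expect_lt(20 * log10(abs(sum(taps))), -40)
  # end-to-end: adding an offset leaves the output essentially unchanged
  t <- (0:1199) / fs
  x <- sin(2 * pi * 5 * t)
  d <- bandpass_filter(x + 1, fs, spec) - bandpass_filter(x, fs, spec)
  expect_lt(max(abs(d[300:900])), 0.01)
})

test_that("designed taps are symmetric with passband ripple below 0.05", {
  taps <- design_bandpass_fir(filter_spec(), fs)
  expect_length(taps, 398)
  expect_equal(taps, rev(taps), tolerance = 1e-12)
  freqs <- seq(2, 9, by = 0.1)
  H <- vapply(freqs, function(f) {
    w <- 2 * pi * f / fs
    Mod(sum(taps * exp(-1i * w * (seq_along(taps) - 1))))
  }, numeric(1))
  expect_lt(max(abs(H - 1)), 0.05)
})

test_that("filter input validation catches short signals and bad cutoffs", {
  expect_error(bandpass_filter(rnorm(100), fs, filter_spec()),
               class = "trfspeech_data_error")
  expect_error(design_bandpass_fir(filter_spec(high_hz = 70), fs),
               class = "trfspeech_config_error")
  expect_error(filter_spec(low_hz = 10, high_hz = 1),
               class = "trfspeech_config_error")
})

test_that("resampling preserves DC, length and band-limited content", {
  expect_equal(resample_signal(rep(2.5, 1000), 480, 120),
               rep(2.5, 250), tolerance = 1e-6)
  n <- 4800
  y <- resample_signal(rnorm(n), 4800, 120)
  expect_lte(abs(length(y) - n / 40), 1)
  # 10 Hz sine through 4800 -> 120 Hz matches the analytic 120 Hz sine
  t_in <- (0:(4800 * 2 - 1)) / 4800
  x <- sin(2 * pi * 10 * t_in)
  y <- resample_signal(x, 4800, 120)
  t_out <- (seq_along(y) - 1) / 120
  ref <- sin(2 * pi * 10 * t_out)
  mid <- 20:(length(y) - 20)
  expect_gte(cor(y[mid], ref[mid]), 0.999)
  expect_error(resample_signal(rnorm(100), 120, 4800),
               class = "trfspeech_config_error")
  expect_error(resample_signal(rnorm(1000), 100, 30),
               class = "trfspeech_config_error")
})

test_that("envelope extraction compresses, resamples then band-passes", {
  expect_error(extract_envelope(numeric(0), 4800),
               class = "trfspeech_data_error")
  z <- extract_envelope(rep(0, 48000), 4800)
  expect_equal(z$samples, rep(0, 1200), tolerance = 1e-12)
  expect_equal(z$fs_hz, 120)
  # constant-amplitude tone: rectified-compressed mean is removed by the
  # 1 Hz high-pass edge
  t <- (0:(4800 * 10 - 1)) / 4800
  tone <- sin(2 * pi * 220 * t)
  pre_mean <- mean(abs(tone)^0.6)
  env <- extract_envelope(tone, 4800)
  expect_lt(sqrt(mean(env$samples[200:1000]^2)), 0.05 * pre_mean)
  # 4 Hz amplitude modulation survives as the dominant envelope component
  am <- (1 + 0.8 * sin(2 * pi * 4 * t)) * sin(2 * pi * 220 * t)
  env_am <- extract_envelope(am, 4800)
  expect_lt(abs(periodogram_peak_hz(env_am$samples[100:1100], 120) - 4), 0.5)
})

test_that("envelope pipeline order is fixed: compress, resample, then filter", {
  set.seed(8)
  t <- (0:(4800 * 5 - 1)) / 4800
  x <- (1 + 0.5 * sin(2 * pi * 3 * t)) * sin(2 * pi * 300 * t) + rnorm(length(t), 0, 0.01)
  spec <- filter_spec()
  got <- extract_envelope(x, 4800, spec)$samples
  manual <- bandpass_filter(resample_signal(abs(x)^0.6, 4800, 120), 120, spec)
  expect_equal(got, manual, tolerance = 1e-12)
  # the reversed order (filter at audio rate first) is genuinely different
  alt <- resample_signal(bandpass_filter(abs(x)^0.6, 4800, spec), 4800, 120)
  expect_gt(max(abs(alt - got)), 1e-3)
})

test_that("artifact hook is identity by default and enforces its contract", {
  co <- cohort_config(stimulus = small_stimulus(5))
  env <- generate_envelope(co$stimulus, seed = 1)
  eeg <- synthesize_eeg(env, co$kernel, co, 0, seed = 1)
  expect_identical(remove_artifacts(eeg, "none"), eeg)
  bad_hook <- function(x) new_rec <- structure(
    list(samples = x$samples[, 1:2], fs_hz = x$fs_hz,
         channels = x$channels[1:2], condition = x$condition),
    class = "eeg_recording")
  expect_error(remove_artifacts(eeg, bad_hook), class = "trfspeech_data_error")
  good_hook <- function(x) { x$samples <- x$samples * 1; x }
  expect_equal(remove_artifacts(eeg, good_hook), eeg)
  expect_error(remove_artifacts(eeg, "ica"), class = "trfspeech_config_error")
})

test_that("preprocessing is deterministic and length-preserving", {
  co <- cohort_config(stimulus = small_stimulus(10))
  env <- generate_envelope(co$stimulus, seed = 2)
  eeg <- synthesize_eeg(env, co$kernel, co, 0, seed = 2)
  p1 <- preprocess_recording(eeg)
  p2 <- preprocess_recording(eeg)
  expect_identical(p1, p2)
  expect_identical(dim(p1$samples), dim(eeg$samples))
  expect_identical(p1$channels, eeg$channels)
})
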