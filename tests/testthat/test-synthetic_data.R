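test_that("stimulus and cohort configs validate their inputs", {
  expect_error(stimulus_config(duration_s = 0), class = "trfspeech_config_error")
  expect_error(stimulus_config(syllable_rate_hz = -1),
               class = "trfspeech_config_error")
  expect_error(cohort_config(n_subjects = 1), class = "trfspeech_config_error")
  expect_error(cohort_config(delta_snr_grid_db = c(0, -1)),
               class = "trfspeech_config_error")
  expect_error(cohort_config(noise_sd = -0.1), class = "trfspeech_config_error")
  expect_error(kernel_params(n1_amplitude = 0.5),
               class = "trfspeech_config_error")
  expect_error(kernel_params(n1_width_ms = 0), class = "trfspeech_config_error")
  expect_error(kernel_params(topography = c(C3 = 1.2)),
               class = "trfspeech_config_error")
})

test_that("envelope generation is deterministic, nonnegative and gap-structured", {
  cfg <- small_stimulus(30)
  e1 <- generate_envelope(cfg, seed = 11)
  e2 <- generate_envelope(cfg, seed = 11)
  expect_identical(e1$samples, e2$samples)
  e3 <- generate_envelope(cfg, seed = 12)
  expect_false(identical(e1$samples, e3$samples))
  expect_true(all(e1$samples >= 0))
  expect_equal(length(e1$samples), 30 * 120)
  expect_true(any(e1$samples == 0))       # silent gaps present
  expect_true(any(e1$samples > 0.3))      # sentence bursts present
})

test_that("sentence segments peak spectrally at the syllable rate", {
  env <- generate_envelope(small_stimulus(60), seed = 5)
  x <- env$samples
  active <- x > 0
  runs <- rle(active)
  ends <- cumsum(runs$lengths)
  starts <- ends - runs$lengths + 1
  sent <- which(runs$values & runs$lengths > 120)  # sentences > 1 s
  expect_gt(length(sent), 10)
  peaks <- vapply(sent, function(i) {
    periodogram_peak_hz(x[starts[i]:ends[i]], env$fs_hz)
  }, numeric(1))
  expect_true(all(abs(peaks - 3.8) <= 0.5))
})

test_that("ground-truth kernel follows the stated parametric form", {
  sp <- lag_spec()
  # no modulation: identical kernel at all delta SNRs
  kp0 <- kernel_params(amp_slope_per_db = 0, lat_slope_ms_per_db = 0)
  expect_equal(as.numeric(ground_truth_kernel(kp0, -4, sp)),
               as.numeric(ground_truth_kernel(kp0, 4, sp)))
  # default: larger and earlier N1 at higher SNR
  kp <- kernel_params()
  k_hi <- ground_truth_kernel(kp, 4, sp)
  k_lo <- ground_truth_kernel(kp, -4, sp)
  expect_gt(abs(min(k_hi)), abs(min(k_lo)))
  expect_lt(sp$lag_ms[which.min(k_hi)], sp$lag_ms[which.min(k_lo)])
  # single-Gaussian identity: minimum -1 at the (on-grid) N1 latency
  kp1 <- kernel_params(n1_latency_ms = 100, n1_amplitude = -1,
                       p2_amplitude = 1e-12, p2_latency_ms = 300)
  k1 <- ground_truth_kernel(kp1, 0, sp)
  expect_equal(min(k1), -1, tolerance = 1e-9)
  expect_equal(sp$lag_ms[which.min(k1)], 100)
  # causal support only
  expect_true(all(k1[sp$lag_ms < 0] == 0))
  expect_true(all(k1[sp$lag_ms > 400] == 0))
  # amplitude floor at zero when the SNR scale would go negative
  kfloor <- ground_truth_kernel(kernel_params(amp_slope_per_db = 0.25), -4, sp)
  expect_true(all(kfloor == 0))
})

test_that("synthesized EEG equals the direct convolution oracle when noiseless", {
  sp <- lag_spec()
  topo <- c(C3 = 1, CP3 = 0)
  kp <- kernel_params(topography = topo)
  co <- cohort_config(n_channels = 2, noise_sd = 0, kernel = kp,
                      stimulus = small_stimulus(5))
  env <- generate_envelope(co$stimulus, seed = 3)
  eeg <- synthesize_eeg(env, kp, co, delta_snr_db = 0, seed = 1)
  k <- as.numeric(ground_truth_kernel(kp, 0, sp))
  oracle <- naive_lagged_convolve(env$samples, k, sp$lags)
  expect_equal(unname(eeg$samples[, "C3"]), oracle, tolerance = 1e-12)
  expect_equal(unname(eeg$samples[, "CP3"]), rep(0, length(oracle)))
})

test_that("noiseless round trip recovers the generating kernel and N1 latency", {
  sp <- lag_spec()
  kp <- kernel_params()
  co <- cohort_config(noise_sd = 0, stimulus = small_stimulus(40))
  env <- generate_envelope(co$stimulus, seed = 7)
  eeg <- synthesize_eeg(env, kp, co, 0, seed = 1)
  est <- estimate_trf(env, eeg$samples[, "C3"], sp, lambda = 1e-8)
  k <- as.numeric(ground_truth_kernel(kp, 0, sp))
  sel <- sp$lag_ms >= 0 & sp$lag_ms <= 400
  expect_gte(cor(est$coef[sel, 1], k[sel]), 0.99)
  pk <- detect_peak(est$coef[, 1], sp$lag_ms, "negative", c(75, 175))
  true_lat <- sp$lag_ms[which.min(k)]
  expect_lte(abs(pk$latency_ms - true_lat), 1000 / 120 + 1e-9)
})

test_that("per-condition N1 amplitude increases strictly with SNR when noiseless", {
  sp <- lag_spec()
  kp <- kernel_params()       # amp_slope_per_db > 0
  co <- cohort_config(noise_sd = 0, stimulus = small_stimulus(30))
  grid <- co$delta_snr_grid_db
  amps <- vapply(seq_along(grid), function(ci) {
    env <- generate_envelope(co$stimulus, seed = 100 + ci)
    eeg <- synthesize_eeg(env, kp, co, grid[ci], seed = ci)
    est <- estimate_trf(env, eeg$samples[, "C3"], sp, lambda = 1e-8)
    detect_peak(est$coef[, 1], sp$lag_ms, "negative", c(75, 175))$amplitude
  }, numeric(1))
  expect_equal(cor(grid, amps, method = "spearman"), 1)
})

test_that("behavioral simulation matches the logistic psychometric model", {
  # at threshold the long-run score is 50%
  b0 <- simulate_behavior(-7, 1.462, 0, n_sentences = 20000,
                          words_per_sentence = 5, seed = 1)
  expect_lt(abs(b0$intelligibility_pct - 50), 1)
  # large-N score approaches 100 * f(+2) computed independently
  f2 <- 100 / (1 + exp(-2 / 1.462))
  b2 <- simulate_behavior(-7, 1.462, 2, n_sentences = 20000,
                          words_per_sentence = 5, seed = 2)
  expect_lt(abs(b2$intelligibility_pct - f2), 1)
  # default scoring unit: 20 sentences x 5 words = 100 words
  b <- simulate_behavior(-7, 1.462, c(-4, 4), seed = 3)
  expect_equal(b$n_sentences * b$words_per_sentence, c(100, 100))
  expect_equal(b$intelligibility_pct, b$n_correct / 100 * 100)
  expect_error(simulate_behavior(-7, 0, 0), class = "trfspeech_config_error")
})

test_that("mean simulated scores track the psychometric curve over many seeds", {
  grid <- c(-4, -2, -0.5, 0.5, 2, 4)
  n_rep <- 200
  scores <- sapply(seq_len(n_rep), function(i) {
    simulate_behavior(-7, 1.462, grid, seed = 1000 + i)$intelligibility_pct
  })
  p <- 1 / (1 + exp(-grid / 1.462))
  se <- 100 * sqrt(p * (1 - p) / (100 * n_rep))
  expect_true(all(abs(rowMeans(scores) - 100 * p) <= 4 * se + 1e-9))
})

test_that("cohort generation is deterministic and hits the threshold distribution", {
  co <- small_cohort(n_subjects = 2, duration_s = 5)
  c1 <- generate_cohort(co)
  c2 <- generate_cohort(co)
  expect_identical(c1, c2)
  expect_length(c1$subjects, 2)
  expect_length(c1$subjects[[1]]$conditions, 6)
  expect_equal(ncol(c1$subjects[[1]]$conditions[[1]]$eeg$samples), 32)
  # thresholds are drawn Normal(-7, 0.9); check the sampler at large n
  srt <- trfspeech:::cohort_srt50(cohort_config(n_subjects = 500))
  expect_lt(abs(mean(srt) - (-7.0)), 0.2)
  expect_lt(abs(sd(srt) - 0.9), 0.15)
  expect_equal(vapply(c1$subjects, `[[`, 0, "srt50_db"),
               trfspeech:::cohort_srt50(co))
})
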