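sp <- lag_spec()
lag_ms <- sp$lag_ms
step <- 1000 / 120

gauss_trf <- function(mu, amp, width = 15) amp * exp(-(lag_ms - mu)^2 / (2 * width^2))

test_that("peak detection finds the first correctly-signed extremum", {
  # single negative Gaussian at 100 ms
  x <- gauss_trf(100, -2)
  pk <- detect_peak(x, lag_ms, "negative", c(75, 175))
  expect_true(pk$found)
  expect_lte(abs(pk$latency_ms - 100), step)
  expect_equal(pk$amplitude, 2, tolerance = 1e-6)
  # flat TRF: fallback amplitude 0, latency at the window maximum
  flat <- detect_peak(rep(0, length(lag_ms)), lag_ms, "negative", c(75, 175))
  expect_false(flat$found)
  expect_equal(flat$amplitude, 0)
  expect_equal(flat$latency_ms, 175)
  # two minima at 90 and 150 ms: the first is returned
  two <- gauss_trf(90, -1, 10) + gauss_trf(150, -2, 10)
  pk2 <- detect_peak(two, lag_ms, "negative", c(75, 175))
  expect_lte(abs(pk2$latency_ms - 90), step)
  # positive-polarity search ignores negative-valued extrema
  pos <- detect_peak(gauss_trf(200, -1), lag_ms, "positive", c(175, 300))
  expect_false(pos$found)
  expect_equal(pos$latency_ms, 300)
  # plateaus are attributed to the first plateau sample
  xp <- c(5, 3, 3, 3, 4, 5, 6)
  pkp <- detect_peak(xp - 10, seq(0, by = step, length.out = 7), "negative",
                     c(0, 50))
  expect_equal(pkp$latency_ms, step)   # index 2, the first "3"
  expect_error(detect_peak(x, lag_ms, "negative", c(-300, 175)),
               class = "trfspeech_config_error")
})

test_that("peak latency is scale-invariant while amplitude scales linearly", {
  x <- gauss_trf(110, -1.3) + gauss_trf(210, 0.8)
  for (c_scale in c(0.1, 1, 7.5)) {
    pk <- detect_peak(c_scale * x, lag_ms, "negative", c(75, 175))
    ref <- detect_peak(x, lag_ms, "negative", c(75, 175))
    expect_equal(pk$latency_ms, ref$latency_ms)
    expect_equal(pk$amplitude, c_scale * ref$amplitude, tolerance = 1e-12)
  }
})

test_that("windowed RMS matches hand-computed values and is homogeneous", {
  x <- rep(0.5, length(lag_ms))
  expect_equal(windowed_rms(x, lag_ms, 83, 133), 0.5)
  # window holding exactly the samples {3, 4}
  x2 <- numeric(length(lag_ms))
  x2[lag_ms == 100] <- 3
  x2[lag_ms == 100 + step] <- 4
  expect_equal(windowed_rms(x2, lag_ms, 100, 100 + step), sqrt((9 + 16) / 2))
  x3 <- gauss_trf(110, -1)
  expect_equal(windowed_rms(3 * x3, lag_ms, 75, 175),
               3 * windowed_rms(x3, lag_ms, 75, 175))
  expect_error(windowed_rms(x, lag_ms, 600, 700),
               class = "trfspeech_config_error")
})

test_that("window optimization finds the informative latency region", {
  # SNR-dependent signal confined to 80-130 ms, white noise elsewhere
  conds <- c(-4, -2, -0.5, 0.5, 2, 4)
  n_subj <- 6
  arr <- array(0, c(length(lag_ms), 1, length(conds), n_subj))
  set.seed(99)
  for (s in seq_len(n_subj)) for (ci in seq_along(conds)) {
    x <- rnorm(length(lag_ms), 0, 0.2)
    sig <- lag_ms >= 80 & lag_ms <= 130
    x[sig] <- x[sig] + (1 + 0.15 * conds[ci]) * 1.5
    arr[, 1, ci, s] <- x
  }
  tset <- trf_set(arr, lag_ms, "C3", conds, seq_len(n_subj))
  w <- optimize_rms_windows(tset, "C3")
  expect_gte(w$rho, 0.9)
  expect_lt(w$lower_ms, 130)
  expect_gt(w$upper_ms, 108 - 1e-9)     # overlap with the signal region
  expect_lte(w$lower_ms, 100)
  # the evaluated grid honors the bound ranges
  g <- attr(w, "grid")
  expect_true(all(g$lower_ms <= 100 & g$lower_ms >= 0))
  expect_true(all(g$upper_ms >= 108 & g$upper_ms <= 200))
})

test_that("criterion ties are broken by the narrowest window, smallest lower bound", {
  conds <- c(-2, 0, 2)
  arr <- array(0, c(length(lag_ms), 1, length(conds), 2))
  for (ci in seq_along(conds)) arr[, 1, ci, ] <- 1 + 0.1 * conds[ci]
  tset <- trf_set(arr, lag_ms, "Cz", conds, 1:2)
  # constant-over-lag TRFs: every window yields the same RMS, so all tie
  # and the single narrowest admissible window (100 -> 108.3 ms) wins
  w <- optimize_rms_windows(tset, "Cz")
  expect_equal(w$lower_ms, 100)
  expect_equal(w$upper_ms, 13 * step)
  expect_equal(w$rho, 1)
})

test_that("window criterion is invariant to monotone feature transforms", {
  tset <- kernel_trf_set(noise_sd = 0.05)
  w1 <- optimize_rms_windows(tset, "C3")
  cube <- tset
  cube$coef <- cube$coef    # rank-based criterion: scaling cannot change it
  cube$coef[] <- cube$coef * 10
  w2 <- optimize_rms_windows(cube, "C3")
  expect_equal(w1$lower_ms, w2$lower_ms)
  expect_equal(w1$upper_ms, w2$upper_ms)
  expect_equal(w1$rho, w2$rho)
})

test_that("degenerate all-constant feature sets are rejected", {
  arr <- array(1, c(length(lag_ms), 1, 3, 2))
  tset <- trf_set(arr, lag_ms, "C3", c(-1, 0, 1), 1:2)
  expect_error(optimize_rms_windows(tset, "C3"),
               class = "trfspeech_config_error")
})

test_that("feature table enumerates subject x condition x electrode", {
  # one subject, six conditions, 32 electrodes -> 192 rows
  kp <- kernel_params()
  tset1 <- kernel_trf_set(channels = montage_32(), n_subjects = 1,
                          noise_sd = 0.02)
  ft1 <- extract_feature_table(tset1)
  expect_equal(nrow(ft1), 192)
  # small grid
  tset2 <- kernel_trf_set(channels = c("C3", "CP3", "CPz"),
                          conditions = c(-2, 2), n_subjects = 2)
  ft2 <- extract_feature_table(tset2)
  expect_equal(nrow(ft2), 12)
  expect_true(all(c("n1_amp", "n1_lat_ms", "p2_amp", "p2_lat_ms", "rms")
                  %in% names(ft2)))
  # all-zero TRFs: rms 0 and fallback peaks everywhere
  arr0 <- array(0, c(length(lag_ms), 2, 3, 2))
  t0 <- trf_set(arr0, lag_ms, c("C3", "Cz"), c(-1, 0, 1), 1:2)
  ft0 <- extract_feature_table(t0)
  expect_true(all(ft0$rms == 0))
  expect_true(all(ft0$n1_amp == 0))
  expect_true(all(ft0$n1_lat_ms == 175))
  expect_true(all(ft0$p2_lat_ms == 300))
})

test_that("RMS_sum adds exactly the configured electrode subset", {
  ft <- data.frame(subject = rep(1, 4), condition = rep(0, 4),
                   electrode = c("C3", "CP3", "CPz", "Fz"),
                   rms = c(0.1, 0.1, 0.1, 9))
  rs <- compute_rms_sum(ft)
  expect_equal(rs$rms_sum, 0.3)
  expect_error(compute_rms_sum(ft, character(0)),
               class = "trfspeech_data_error")
  expect_error(compute_rms_sum(ft, c("C3", "POz")),
               class = "trfspeech_data_error")
  # default subset on a full montage picks exactly three addends
  tset <- kernel_trf_set(channels = montage_32(), n_subjects = 1,
                         conditions = c(-2, 2))
  ftm <- extract_feature_table(tset)
  rsm <- compute_rms_sum(ftm)
  one <- ftm[ftm$condition == 2 & ftm$electrode %in% c("C3", "CP3", "CPz"), ]
  expect_equal(rsm$rms_sum[rsm$condition == 2], sum(one$rms))
})
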