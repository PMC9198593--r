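#' Stimulus configuration for the synthetic matrix-sentence experiment
#'
#' Describes one condition's stimulus stream: concatenated five-word matrix
#' sentences whose envelope is modulated at the matrix-test syllable rate,
#' separated by silent gaps, presented at a fixed speech level.
#'
#' @param duration_s Total stimulus duration per condition in seconds
#'   (default 540 s, i.e. about 9 min of presentation).
#' @param syllable_rate_hz Syllable modulation rate in Hz (default 3.8, the
#'   mean matrix-test syllable rate).
#' @param gap_mean_s Nominal mean inter-sentence silence in seconds.
#' @param gap_range_s Range of the uniform gap draw (default 0.9--1.8 s).
#' @param speech_level_db Nominal presentation level in dB SPL (metadata
#'   only; default 60).
#' @param fs_hz Pipeline sampling rate the envelope is generated at
#'   (default 120 Hz).
#' @param audio_fs_hz Audio sampling rate used when real waveforms are
#'   supplied (metadata in synthetic mode).
#' @return A `stimulus_config` list.
#' @export
stimulus_config <- function(duration_s = 540, syllable_rate_hz = 3.8,
                            gap_mean_s = 1.4, gap_range_s = c(0.9, 1.8),
                            speech_level_db = 60, fs_hz = 120,
                            audio_fs_hz = 44100) {
  if (!is_number(duration_s) || duration_s <= 0)
    stop_config("duration_s must be a positive number")
  if (!is_number(syllable_rate_hz) || syllable_rate_hz <= 0)
    stop_config("syllable_rate_hz must be positive")
  if (length(gap_range_s) != 2L || gap_range_s[1] > gap_range_s[2] ||
      gap_range_s[1] < 0)
    stop_config("gap_range_s must be an increasing nonnegative pair")
  if (!is_number(fs_hz) || fs_hz <= 0)
    stop_config("fs_hz must be positive")
  structure(list(duration_s = duration_s, syllable_rate_hz = syllable_rate_hz,
                 gap_mean_s = gap_mean_s, gap_range_s = gap_range_s,
                 speech_level_db = speech_level_db, fs_hz = fs_hz,
                 audio_fs_hz = audio_fs_hz),
            class = "stimulus_config")
}

#' Ground-truth TRF kernel parameters
#'
#' Parametrizes the simulated cortical impulse response as a sum of a
#' negative (N1-like) and a positive (P2-like) Gaussian deflection, plus a
#' linear dependence of amplitude and latency on the SNR of the stimulus
#' relative to the behavioral threshold (delta SNR).  Higher SNR gives
#' larger amplitudes and shorter latencies, matching the morphology changes
#' seen in speech-in-noise evoked responses.
#'
#' @param n1_latency_ms,n1_amplitude Position (ms) and size of the negative
#'   peak at delta SNR = 0; `n1_amplitude` must be negative.
#' @param p2_latency_ms,p2_amplitude Position and size of the positive peak;
#'   `p2_amplitude` must be positive.
#' @param n1_width_ms,p2_width_ms Gaussian widths (standard deviations, ms).
#' @param amp_slope_per_db Fractional amplitude change per dB delta SNR; the
#'   common scale `1 + amp_slope_per_db * delta_snr` is floored at 0.
#' @param lat_slope_ms_per_db Latency decrease per dB delta SNR (ms/dB).
#' @param topography Named per-electrode gain map in `[0, 1]`; see
#'   [default_topography()].
#' @return A `kernel_params` list.
#' @export
kernel_params <- function(n1_latency_ms = 110, n1_amplitude = -1,
                          p2_latency_ms = 210, p2_amplitude = 0.6,
                          n1_width_ms = 22, p2_width_ms = 32,
                          amp_slope_per_db = 0.08, lat_slope_ms_per_db = 3,
                          topography = default_topography()) {
  if (!is_number(n1_amplitude) || n1_amplitude >= 0)
    stop_config("n1_amplitude must be negative")
  if (!is_number(p2_amplitude) || p2_amplitude <= 0)
    stop_config("p2_amplitude must be positive")
  if (n1_width_ms <= 0 || p2_width_ms <= 0)
    stop_config("kernel widths must be positive")
  if (any(topography < 0 | topography > 1))
    stop_config("topography gains must lie in [0, 1]")
  if (is.null(names(topography)))
    stop_config("topography must be a named (electrode-labelled) vector")
  structure(list(n1_latency_ms = n1_latency_ms, n1_amplitude = n1_amplitude,
                 p2_latency_ms = p2_latency_ms, p2_amplitude = p2_amplitude,
                 n1_width_ms = n1_width_ms, p2_width_ms = p2_width_ms,
                 amp_slope_per_db = amp_slope_per_db,
                 lat_slope_ms_per_db = lat_slope_ms_per_db,
                 topography = topography),
            class = "kernel_params")
}

#' Cohort configuration for the synthetic study
#'
#' Study-level parameters: cohort size, distribution of behavioral speech
#' reception thresholds, the delta-SNR condition grid, EEG channel count and
#' background-noise level, and the psychometric slope of the simulated
#' listeners.
#'
#' @param n_subjects Number of subjects (default 18).
#' @param srt_mean_db,srt_sd_db Mean and SD (dB SNR) of the behavioral 50%
#'   speech reception threshold across subjects (defaults -7.0 and 0.9).
#' @param delta_snr_grid_db Strictly increasing grid of SNRs relative to the
#'   individual threshold (default -4, -2, -0.5, +0.5, +2, +4 dB).
#' @param n_channels Number of EEG channels (default 32).
#' @param slope_s_db Logistic psychometric slope parameter `s` in dB
#'   (default 1.462, giving expected word scores of about 6, 20, 40, 60, 80
#'   and 93% over the default grid).
#' @param noise_sd Amplitude of the additive EEG background noise relative
#'   to the unit-amplitude response kernel (default 1, i.e. roughly -10 dB
#'   response-to-background ratio, typical for cortical evoked activity).
#' @param noise_kind `"pink"` (1/f amplitude spectrum, default) or
#'   `"white"`.
#' @param n_sentences,words_per_sentence Behavioral scoring unit counts
#'   (defaults 20 sentences of 5 words, i.e. 100 words per condition).
#' @param seed Master seed; all per-subject/per-condition seeds derive from
#'   it deterministically.
#' @param stimulus A [stimulus_config()].
#' @param kernel A [kernel_params()]; its topography must name
#'   `n_channels` electrodes.
#' @return A `cohort_config` list.
#' @export
cohort_config <- function(n_subjects = 18, srt_mean_db = -7.0, srt_sd_db = 0.9,
                          delta_snr_grid_db = c(-4, -2, -0.5, 0.5, 2, 4),
                          n_channels = 32, slope_s_db = 1.462,
                          noise_sd = 1, noise_kind = c("pink", "white"),
                          n_sentences = 20, words_per_sentence = 5,
                          seed = 1L,
                          stimulus = stimulus_config(),
                          kernel = kernel_params()) {
  noise_kind <- match.arg(noise_kind)
  if (!is_number(n_subjects) || n_subjects < 2)
    stop_config("n_subjects must be at least 2")
  if (is.unsorted(delta_snr_grid_db, strictly = TRUE))
    stop_config("delta_snr_grid_db must be strictly increasing")
  if (!is_number(noise_sd) || noise_sd < 0)
    stop_config("noise_sd must be nonnegative")
  if (!is_number(slope_s_db) || slope_s_db <= 0)
    stop_config("slope_s_db must be positive")
  if (length(kernel$topography) < n_channels)
    stop_config("kernel topography names fewer electrodes than n_channels")
  topo <- kernel$topography[seq_len(n_channels)]
  kernel$topography <- topo
  structure(list(n_subjects = as.integer(n_subjects),
                 srt_mean_db = srt_mean_db, srt_sd_db = srt_sd_db,
                 delta_snr_grid_db = delta_snr_grid_db,
                 n_channels = as.integer(n_channels),
                 slope_s_db = slope_s_db, noise_sd = noise_sd,
                 noise_kind = noise_kind,
                 n_sentences = as.integer(n_sentences),
                 words_per_sentence = as.integer(words_per_sentence),
                 seed = as.integer(seed),
                 stimulus = stimulus, kernel = kernel),
            class = "cohort_config")
}

new_envelope <- function(samples, fs_hz, condition = NA_real_) {
  structure(list(samples = as.numeric(samples), fs_hz = fs_hz,
                 condition = condition),
            class = "trf_envelope")
}

#' @export
print.trf_envelope <- function(x, ...) {
  cat(sprintf("<trf_envelope> %d samples at %g Hz (%.1f s)\n",
              length(x$samples), x$fs_hz, length(x$samples) / x$fs_hz))
  invisible(x)
}

new_eeg_recording <- function(samples, fs_hz, channels, condition = NA_real_) {
  samples <- as.matrix(samples)
  if (ncol(samples) != length(channels))
    stop_data("channel label count (", length(channels),
              ") does not match data columns (", ncol(samples), ")")
  colnames(samples) <- channels
  structure(list(samples = samples, fs_hz = fs_hz,
                 channels = channels, condition = condition),
            class = "eeg_recording")
}

#' @export
print.eeg_recording <- function(x, ...) {
  cat(sprintf("<eeg_recording> %d channels x %d samples at %g Hz\n",
              length(x$channels), nrow(x$samples), x$fs_hz))
  invisible(x)
}

#' Generate a synthetic speech envelope
#'
#' Builds a nonnegative envelope at the pipeline rate consisting of
#' sentence-shaped bursts -- raised-cosine syllable modulation at the
#' configured syllable rate with mild per-sentence level jitter -- separated
#' by silent gaps drawn uniformly from the configured gap range.  The
#' dominant modulation energy therefore sits at the syllable rate, inside
#' the 1--10 Hz analysis band.
#'
#' @param cfg A [stimulus_config()].
#' @param seed Integer seed; the output is reproducible for a fixed seed.
#' @return A `trf_envelope` (samples, `fs_hz`).
#' @export
#' @examples
#' env <- generate_envelope(stimulus_config(duration_s = 10), seed = 1)
#' range(env$samples)
generate_envelope <- function(cfg, seed = 1L) {
  if (!inherits(cfg, "stimulus_config")) stop_config("cfg must be a stimulus_config")
  fs <- cfg$fs_hz
  n <- round(cfg$duration_s * fs)
  if (n < 1) stop_config("duration too short for one sample")
  with_seed(seed, {
    env <- numeric(n)
    # Alternate gap / sentence segments until the stream is full.  A matrix
    # sentence has five words; we draw 8-10 syllables so sentences last
    # roughly 2.1-2.6 s at the default 3.8 Hz rate.
    t_cur <- round(runif(1, 0, cfg$gap_range_s[2]) * fs)
    while (t_cur < n) {
      n_syll <- sample(8:10, 1)
      dur <- n_syll / cfg$syllable_rate_hz
      len <- round(dur * fs)
      idx <- t_cur + seq_len(len)
      idx <- idx[idx <= n]
      if (length(idx)) {
        tt <- (seq_along(idx) - 1) / fs
        level <- runif(1, 0.7, 1.0)
        env[idx] <- level * 0.5 * (1 - cos(2 * pi * cfg$syllable_rate_hz * tt))
      }
      gap <- runif(1, cfg$gap_range_s[1], cfg$gap_range_s[2])
      t_cur <- t_cur + len + round(gap * fs)
    }
    new_envelope(env, fs)
  })
}

#' Evaluate the ground-truth TRF kernel at one delta SNR
#'
#' The simulated impulse response is the sum of the two Gaussian
#' deflections defined by [kernel_params()], with both amplitudes scaled by
#' `max(0, 1 + amp_slope_per_db * delta_snr_db)` and both latencies shifted
#' by `-lat_slope_ms_per_db * delta_snr_db`.  The kernel is zero outside
#' the 0--400 ms causal support.
#'
#' @param kp A [kernel_params()].
#' @param delta_snr_db SNR relative to the behavioral threshold, in dB.
#' @param spec A [lag_spec()] giving the lag grid to evaluate on.
#' @return Numeric vector of kernel values with attribute `lag_ms`.
#' @export
ground_truth_kernel <- function(kp, delta_snr_db = 0, spec = lag_spec()) {
  if (!inherits(kp, "kernel_params")) stop_config("kp must be kernel_params")
  if (!is_number(delta_snr_db)) stop_config("delta_snr_db must be a number")
  lag_ms <- spec$lag_ms
  scale <- max(0, 1 + kp$amp_slope_per_db * delta_snr_db)
  shift <- -kp$lat_slope_ms_per_db * delta_snr_db
  g <- function(mu, w) exp(-((lag_ms - mu)^2) / (2 * w^2))
  k <- scale * (kp$n1_amplitude * g(kp$n1_latency_ms + shift, kp$n1_width_ms) +
                kp$p2_amplitude * g(kp$p2_latency_ms + shift, kp$p2_width_ms))
  k[lag_ms < 0 | lag_ms > 400] <- 0
  attr(k, "lag_ms") <- lag_ms
  k
}

# 1/f ("pink") noise via spectral shaping of white Gaussian noise,
# normalized to unit standard deviation.
pink_noise <- function(n) {
  w <- rnorm(n)
  W <- fft(w)
  f <- c(1, seq_len(n - 1))        # avoid the DC singularity
  f <- pmin(f, n - f + 1)          # mirrored frequency index
  amp <- 1 / sqrt(f)
  amp[1] <- 0                      # zero-mean
  x <- Re(fft(W * amp, inverse = TRUE)) / n
  x / sd(x)
}

#' Synthesize a multichannel EEG recording from an envelope
#'
#' Each channel is `topography[ch] * (envelope convolved with the
#' ground-truth kernel) + noise_sd * noise`, with noise drawn independently
#' per channel as pink (1/f) or white Gaussian noise.  The convolution uses
#' the same lag bookkeeping as TRF estimation, so a noiseless recording is
#' exactly reproduced by [predict_response()] with the true kernel.
#'
#' @param env A `trf_envelope` at the pipeline rate.
#' @param kp A [kernel_params()].
#' @param cohort A [cohort_config()] (supplies channel count, noise level
#'   and kind).
#' @param delta_snr_db Condition delta SNR in dB.
#' @param seed Integer seed for the noise draw.
#' @param spec Lag grid for the kernel; default [lag_spec()].
#' @return An `eeg_recording` with the montage labels of the topography.
#' @export
synthesize_eeg <- function(env, kp, cohort, delta_snr_db = 0, seed = 1L,
                           spec = lag_spec()) {
  if (!inherits(env, "trf_envelope")) stop_config("env must be a trf_envelope")
  if (env$fs_hz != spec$fs_hz)
    stop_config("envelope rate does not match the lag grid rate")
  topo <- kp$topography
  if (length(topo) != cohort$n_channels)
    stop_data("topography names ", length(topo),
              " electrodes but n_channels is ", cohort$n_channels)
  k <- ground_truth_kernel(kp, delta_snr_db, spec)
  clean <- lagged_convolve(env$samples, as.numeric(k), spec$lags)
  n <- length(clean)
  noise_fun <- if (cohort$noise_kind == "pink") pink_noise else function(n) rnorm(n)
  dat <- with_seed(seed, {
    m <- matrix(0, n, cohort$n_channels)
    for (ch in seq_len(cohort$n_channels)) {
      m[, ch] <- topo[ch] * clean +
        if (cohort$noise_sd > 0) cohort$noise_sd * noise_fun(n) else 0
    }
    m
  })
  new_eeg_recording(dat, env$fs_hz, names(topo), condition = delta_snr_db)
}

#' Logistic psychometric function
#'
#' Word-recognition probability
#' `f(SNR) = 1 / (1 + exp(-(SNR - SRT50) / s))`, so that `f(SRT50) = 0.5`
#' and `s` controls the slope of the intelligibility transition.
#'
#' @param snr_db Stimulus SNR in dB.
#' @param srt50_db 50% speech reception threshold in dB SNR.
#' @param slope_s_db Slope parameter `s` in dB (> 0).
#' @return Recognition probability in `[0, 1]`.
#' @export
#' @examples
#' psychometric_function(-7, srt50_db = -7, slope_s_db = 1.462)  # 0.5
psychometric_function <- function(snr_db, srt50_db, slope_s_db) {
  if (any(slope_s_db <= 0)) stop_config("slope_s_db must be positive")
  1 / (1 + exp(-(snr_db - srt50_db) / slope_s_db))
}

#' Simulate a behavioral word-recognition score
#'
#' Draws the number of correctly repeated words for one condition as a
#' binomial sample with success probability given by the logistic
#' psychometric function evaluated at `srt50_db + delta_snr_db`, over
#' `n_sentences * words_per_sentence` words.
#'
#' @param srt50_db Subject's behavioral threshold (dB SNR).
#' @param slope_s_db Psychometric slope (dB, > 0).
#' @param delta_snr_db Condition SNR(s) relative to the threshold; may be a
#'   vector.
#' @param n_sentences,words_per_sentence Scoring units (defaults 20 and 5,
#'   i.e. 100 words per condition).
#' @param seed Integer seed.
#' @return Data frame with one row per condition: `delta_snr_db`,
#'   `n_sentences`, `words_per_sentence`, `n_correct`,
#'   `intelligibility_pct`.
#' @export
simulate_behavior <- function(srt50_db, slope_s_db, delta_snr_db,
                              n_sentences = 20, words_per_sentence = 5,
                              seed = 1L) {
  if (slope_s_db <= 0) stop_config("slope_s_db must be positive")
  if (n_sentences < 1 || words_per_sentence < 1)
    stop_config("sentence and word counts must be positive integers")
  n_words <- round(n_sentences) * round(words_per_sentence)
  p <- psychometric_function(srt50_db + delta_snr_db, srt50_db, slope_s_db)
  n_correct <- with_seed(seed, rbinom(length(p), n_words, p))
  data.frame(delta_snr_db = delta_snr_db,
             n_sentences = round(n_sentences),
             words_per_sentence = round(words_per_sentence),
             n_correct = n_correct,
             intelligibility_pct = 100 * n_correct / n_words)
}

# One subject's full record (threshold, envelopes, EEG, behavior).  Shared
# by generate_cohort() and the streaming pipeline driver.
generate_subject_data <- function(cohort, subject, srt50_db) {
  conds <- cohort$delta_snr_grid_db
  beh <- simulate_behavior(srt50_db, cohort$slope_s_db, conds,
                           cohort$n_sentences, cohort$words_per_sentence,
                           seed = derive_seed(cohort$seed, subject, 0L, 3L))
  conditions <- vector("list", length(conds))
  for (ci in seq_along(conds)) {
    env <- generate_envelope(cohort$stimulus,
                             seed = derive_seed(cohort$seed, subject, ci, 1L))
    env$condition <- conds[ci]
    eeg <- synthesize_eeg(env, cohort$kernel, cohort, conds[ci],
                          seed = derive_seed(cohort$seed, subject, ci, 2L))
    conditions[[ci]] <- list(delta_snr_db = conds[ci], envelope = env,
                             eeg = eeg)
  }
  list(id = subject, srt50_db = srt50_db, behavior = beh,
       conditions = conditions)
}

# Subject thresholds for a cohort config, without generating signals.
cohort_srt50 <- function(cohort) {
  with_seed(derive_seed(cohort$seed, 0L, 0L, 0L),
            rnorm(cohort$n_subjects, cohort$srt_mean_db, cohort$srt_sd_db))
}

#' Generate a full synthetic cohort
#'
#' Draws each subject's behavioral threshold from
#' `Normal(srt_mean_db, srt_sd_db)`, then generates per-condition stimuli,
#' EEG and behavioral scores with seeds derived deterministically from the
#' master seed, so the same configuration always yields an identical
#' dataset.
#'
#' @param cohort A [cohort_config()].
#' @return A `trf_cohort`: list with `config` and `subjects`, each subject
#'   holding `srt50_db`, a behavior data frame, and per-condition
#'   envelope/EEG pairs.
#' @export
generate_cohort <- function(cohort) {
  if (!inherits(cohort, "cohort_config"))
    stop_config("cohort must be a cohort_config")
  srt <- cohort_srt50(cohort)
  subjects <- lapply(seq_len(cohort$n_subjects), function(s) {
    generate_subject_data(cohort, s, srt[s])
  })
  structure(list(config = cohort, subjects = subjects), class = "trf_cohort")
}

#' @export
print.trf_cohort <- function(x, ...) {
  cat(sprintf("<trf_cohort> %d subjects x %d conditions x %d channels\n",
              length(x$subjects), length(x$config$delta_snr_grid_db),
              x$config$n_channels))
  invisible(x)
}

#' Behavioral table of a cohort
#'
#' @param cohort A `trf_cohort`.
#' @return Data frame: `subject`, `srt50_db`, `delta_snr_db`,
#'   `intelligibility_pct`.
#' @export
cohort_behavior <- function(cohort) {
  do.call(rbind, lapply(cohort$subjects, function(s) {
    cbind(subject = s$id, srt50_db = s$srt50_db, s$behavior)
  }))
}
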