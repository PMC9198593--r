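#' Band-pass filter specification
#'
#' Parameters of the Hamming windowed-sinc FIR band-pass applied to both
#' the EEG and the stimulus envelope: 1--10 Hz, order 397, applied
#' non-causally (zero phase) by compensating the filter's linear-phase
#' group delay.  Band edges are the -6 dB cutoff frequencies of the
#' windowed-sinc design.
#'
#' @param low_hz,high_hz Cutoff frequencies in Hz (defaults 1 and 10).
#' @param order FIR filter order (number of taps minus one; default 397).
#' @param window Taper name; only `"hamming"` is implemented.
#' @param zero_phase Logical; compensate the group delay (default TRUE).
#' @return A `filter_spec` list.
#' @export
filter_spec <- function(low_hz = 1, high_hz = 10, order = 397,
                        window = "hamming", zero_phase = TRUE) {
  if (!is_number(low_hz) || !is_number(high_hz) || low_hz <= 0 ||
      low_hz >= high_hz)
    stop_config("need 0 < low_hz < high_hz")
  if (!is_number(order) || order < 2)
    stop_config("order must be a positive integer >= 2")
  if (!identical(window, "hamming"))
    stop_config("only the Hamming window is supported")
  structure(list(low_hz = low_hz, high_hz = high_hz, order = as.integer(order),
                 window = window, zero_phase = isTRUE(zero_phase)),
            class = "filter_spec")
}

#' Design the windowed-sinc band-pass taps
#'
#' @param spec A [filter_spec()].
#' @param fs_hz Sampling rate in Hz; cutoffs must be below Nyquist.
#' @return Numeric vector of `order + 1` symmetric taps.
#' @export
design_bandpass_fir <- function(spec, fs_hz) {
  if (spec$high_hz >= fs_hz / 2)
    stop_config("high cutoff (", spec$high_hz, " Hz) must be below Nyquist (",
                fs_hz / 2, " Hz)")
  w <- c(spec$low_hz, spec$high_hz) / (fs_hz / 2)
  as.numeric(signal::fir1(spec$order, w, type = "pass",
                          window = signal::hamming(spec$order + 1)))
}

# Apply a linear-phase FIR with exact delay compensation via the frequency
# domain.  The signal is zero-padded on both sides, circular convolution is
# avoided by padding the FFT length past n + taps, and the (possibly
# fractional, order/2 samples) group delay is removed by a conjugate-
# symmetric phase ramp, so the output is zero phase and length-preserving.
fir_zero_phase <- function(x, taps) {
  n <- length(x)
  m <- length(taps)
  pad <- m
  nfft <- nextn(n + 2L * pad, c(2, 3, 5))
  xp <- c(rep(0, pad), x, rep(0, nfft - n - pad))
  H <- fft(c(taps, rep(0, nfft - m)))
  d <- (m - 1) / 2
  k <- 0:(nfft - 1)
  wsig <- 2 * pi * (((k + nfft / 2) %% nfft) - nfft / 2) / nfft  # signed freq
  D <- exp(1i * wsig * d)
  y <- Re(fft(fft(xp) * H * D, inverse = TRUE)) / nfft
  y[(pad + 1):(pad + n)]
}

#' Zero-phase FIR band-pass filtering
#'
#' Applies the designed windowed-sinc filter in a single pass and removes
#' its group delay (order/2 samples) exactly, so passband components keep
#' their amplitude and phase.  The signal is zero-padded at both ends
#' before filtering and trimmed afterwards, preserving length.
#'
#' @param x Numeric signal (or matrix with signals in columns).
#' @param fs_hz Sampling rate in Hz.
#' @param spec A [filter_spec()].
#' @return Filtered signal, same length/shape as `x`.
#' @export
#' @examples
#' fs <- 120; t <- seq(0, 5, by = 1 / fs)
#' y <- bandpass_filter(sin(2 * pi * 5 * t), fs, filter_spec())
bandpass_filter <- function(x, fs_hz, spec = filter_spec()) {
  taps <- design_bandpass_fir(spec, fs_hz)
  if (is.matrix(x)) {
    if (nrow(x) <= spec$order)
      stop_data("signal length (", nrow(x), ") must exceed filter order (",
                spec$order, ")")
    return(apply(x, 2, fir_zero_phase, taps = taps))
  }
  if (length(x) <= spec$order)
    stop_data("signal length (", length(x), ") must exceed filter order (",
              spec$order, ")")
  fir_zero_phase(x, taps)
}

#' Down-sample a signal with anti-alias filtering
#'
#' Low-pass filters at 0.4 times the output rate with a zero-phase
#' windowed-sinc FIR (edges padded by replication so constant signals pass
#' unchanged) and then keeps every `fs_in/fs_out`-th sample.  Only integer
#' decimation factors are supported; upsampling is rejected.
#'
#' @param x Numeric signal.
#' @param fs_in_hz,fs_out_hz Input and output sampling rates; `fs_in_hz`
#'   must be an integer multiple of `fs_out_hz`.
#' @return The resampled signal, length `ceiling(length(x) / factor)`.
#' @export
resample_signal <- function(x, fs_in_hz, fs_out_hz) {
  if (fs_out_hz > fs_in_hz)
    stop_config("upsampling (", fs_in_hz, " -> ", fs_out_hz,
                " Hz) is not supported")
  if (fs_in_hz == fs_out_hz) return(x)
  factor <- fs_in_hz / fs_out_hz
  if (abs(factor - round(factor)) > 1e-9)
    stop_config("fs_in_hz must be an integer multiple of fs_out_hz")
  factor <- round(factor)
  order <- max(64L, 10L * factor)
  if (length(x) <= order)
    stop_data("signal too short (", length(x), " samples) to resample")
  w <- min(0.8 / factor, 0.99)          # cutoff at 0.4 * fs_out
  taps <- as.numeric(signal::fir1(order, w, type = "low",
                                  window = signal::hamming(order + 1)))
  taps <- taps / sum(taps)              # exact unity gain at DC
  # replicate-pad edges so DC is preserved exactly at the boundaries
  pad <- length(taps)
  xp <- c(rep(x[1], pad), x, rep(x[length(x)], pad))
  y <- fir_zero_phase(xp, taps)[(pad + 1):(pad + length(x))]
  y[seq(1, length(y), by = factor)]
}

#' Extract a compressed, band-limited speech envelope from audio
#'
#' Rectifies the waveform, applies power-law compression with exponent
#' 0.6, down-samples to the pipeline rate, and band-pass filters with the
#' same specification used for the EEG -- in that order.
#'
#' @param audio Numeric waveform.
#' @param audio_fs_hz Audio sampling rate (integer multiple of `fs_out_hz`).
#' @param spec A [filter_spec()].
#' @param fs_out_hz Pipeline rate (default 120 Hz).
#' @param compression_exponent Power-law exponent (default 0.6).
#' @return A `trf_envelope` at `fs_out_hz`.
#' @export
extract_envelope <- function(audio, audio_fs_hz, spec = filter_spec(),
                             fs_out_hz = 120, compression_exponent = 0.6) {
  if (!length(audio)) stop_data("empty audio waveform")
  if (any(!is.finite(audio))) stop_data("audio contains non-finite samples")
  compressed <- abs(audio)^compression_exponent
  down <- resample_signal(compressed, audio_fs_hz, fs_out_hz)
  filtered <- bandpass_filter(down, fs_out_hz, spec)
  new_envelope(filtered, fs_out_hz)
}

#' Artifact-removal hook
#'
#' Placeholder for artifact rejection (e.g. ICA-based eye-blink removal on
#' real recordings).  The default method `"none"` returns the recording
#' unchanged; a user-supplied function may be passed as `method` and must
#' return a recording with identical shape, labels and sampling rate.
#'
#' @param eeg An `eeg_recording`.
#' @param method `"none"` or a function `eeg_recording -> eeg_recording`.
#' @return An `eeg_recording`.
#' @export
remove_artifacts <- function(eeg, method = "none") {
  if (!inherits(eeg, "eeg_recording")) stop_config("eeg must be an eeg_recording")
  if (identical(method, "none")) return(eeg)
  if (is.function(method)) {
    out <- method(eeg)
    if (!inherits(out, "eeg_recording") ||
        !identical(dim(out$samples), dim(eeg$samples)) ||
        !identical(out$channels, eeg$channels) ||
        !identical(out$fs_hz, eeg$fs_hz))
      stop_data("artifact hook must preserve shape, labels and sampling rate")
    return(out)
  }
  stop_config("unknown artifact-removal method")
}

#' Preprocess an EEG recording for TRF estimation
#'
#' Down-samples to the pipeline rate if needed, applies the artifact hook,
#' and band-pass filters every channel with the zero-phase FIR.
#'
#' @param eeg An `eeg_recording`.
#' @param spec A [filter_spec()].
#' @param fs_out_hz Pipeline rate (default 120 Hz).
#' @param artifact_method Passed to [remove_artifacts()].
#' @return A filtered `eeg_recording` at `fs_out_hz`.
#' @export
preprocess_recording <- function(eeg, spec = filter_spec(), fs_out_hz = 120,
                                 artifact_method = "none") {
  if (eeg$fs_hz != fs_out_hz) {
    dat <- apply(eeg$samples, 2, resample_signal,
                 fs_in_hz = eeg$fs_hz, fs_out_hz = fs_out_hz)
    eeg <- new_eeg_recording(dat, fs_out_hz, eeg$channels, eeg$condition)
  }
  eeg <- remove_artifacts(eeg, artifact_method)
  filt <- bandpass_filter(eeg$samples, fs_out_hz, spec)
  new_eeg_recording(filt, fs_out_hz, eeg$channels, eeg$condition)
}
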