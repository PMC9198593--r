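#' Lag grid specification for TRF estimation
#'
#' Defines the lag window of the encoding model.  At the default pipeline
#' rate of 120 Hz the grid runs from -200 ms to 500 ms in steps of
#' 1000/120 = 8.33 ms, i.e. 85 lags.  Positive lags mean the stimulus
#' precedes the EEG sample (the causal response); the negative lags act as
#' a sanity floor.
#'
#' @param lag_min_ms,lag_max_ms Lag window bounds in ms (defaults -200 and
#'   500).
#' @param fs_hz Sampling rate (default 120 Hz).
#' @return A `lag_spec` with integer sample lags (`lags`) and their
#'   latencies in ms (`lag_ms`).
#' @export
#' @examples
#' length(lag_spec()$lags)  # 85
lag_spec <- function(lag_min_ms = -200, lag_max_ms = 500, fs_hz = 120) {
  if (lag_min_ms >= lag_max_ms) stop_config("lag_min_ms must be below lag_max_ms")
  lags <- seq.int(round(lag_min_ms * fs_hz / 1000),
                  round(lag_max_ms * fs_hz / 1000))
  structure(list(lag_min_ms = lag_min_ms, lag_max_ms = lag_max_ms,
                 fs_hz = fs_hz, lags = lags, lag_ms = lags * 1000 / fs_hz),
            class = "lag_spec")
}

# r(t) = sum_j k[j] * s(t - lags[j]) with zero-padded boundaries; shared by
# the synthetic generator, the lag-matrix builder and predict_response so
# all three use one boundary convention.
lagged_convolve <- function(s, k, lags) {
  n <- length(s)
  out <- numeric(n)
  for (j in seq_along(lags)) {
    tau <- lags[j]
    if (k[j] == 0) next
    if (tau >= 0) {
      idx <- seq_len(n - tau)
      out[idx + tau] <- out[idx + tau] + k[j] * s[idx]
    } else {
      idx <- seq_len(n + tau)
      out[idx] <- out[idx] + k[j] * s[idx - tau]
    }
  }
  out
}

#' Build the lagged stimulus design matrix
#'
#' Column `j` holds the envelope delayed by lag `tau_j`:
#' `S[t, j] = s(t - tau_j)`, with out-of-range samples zero-filled.  The
#' row count equals the envelope length.
#'
#' @param env A `trf_envelope` or numeric vector at the grid rate.
#' @param spec A [lag_spec()].
#' @return Matrix of size `length(env) x length(spec$lags)` with `lag_ms`
#'   column names.
#' @export
build_lag_matrix <- function(env, spec = lag_spec()) {
  s <- if (inherits(env, "trf_envelope")) {
    if (env$fs_hz != spec$fs_hz)
      stop_config("envelope rate (", env$fs_hz,
                  ") does not match lag grid rate (", spec$fs_hz, ")")
    env$samples
  } else {
    as.numeric(env)
  }
  n <- length(s)
  if (n <= diff(range(spec$lags)))
    stop_data("envelope (", n, " samples) shorter than the lag span")
  S <- matrix(0, n, length(spec$lags))
  for (j in seq_along(spec$lags)) {
    tau <- spec$lags[j]
    if (tau >= 0) {
      S[(tau + 1):n, j] <- s[seq_len(n - tau)]
    } else {
      S[seq_len(n + tau), j] <- s[(1 - tau):n]
    }
  }
  colnames(S) <- sprintf("%.6g", spec$lag_ms)
  S
}

#' Estimate a temporal response function by regularized regression
#'
#' Solves the ridge-regularized normal equations
#' `TRF = (S'S + lambda I)^{-1} S' r`, where `S` is the lagged envelope
#' design matrix, and reports the residual sum of squares of the fit.  The
#' default regularization is `lambda = 2^15`, held constant across
#' electrodes and conditions so TRF amplitudes stay comparable.  No
#' intercept is included: both signals are band-passed and hence zero
#' mean.
#'
#' @param env A `trf_envelope` or numeric vector.
#' @param response Numeric vector (one electrode) or matrix with
#'   electrodes in columns, same length as the envelope.
#' @param spec A [lag_spec()].
#' @param lambda Ridge parameter (>= 0; default `2^15`).
#' @param channels Optional electrode labels for a matrix response.
#' @param condition,subject Optional metadata tags.
#' @return A `trf_estimate`: `coef` (lags x electrodes), `lag_ms`,
#'   `lambda`, `cost` (residual sum of squares per electrode), `fs_hz`,
#'   `channels`, plus the metadata tags.
#' @export
#' @examples
#' sp <- lag_spec(0, 1000 / 120, fs_hz = 120)  # lags {0, 1 sample}
#' estimate_trf(c(1, 0, 0, 0), c(0, 2, 0, 0), sp, lambda = 0)$coef
estimate_trf <- function(env, response, spec = lag_spec(), lambda = 2^15,
                         channels = NULL, condition = NA, subject = NA) {
  if (!is_number(lambda) || lambda < 0) stop_config("lambda must be >= 0")
  R <- if (is.matrix(response)) response else matrix(response, ncol = 1)
  if (is.null(channels))
    channels <- colnames(R) %||% paste0("ch", seq_len(ncol(R)))
  S <- build_lag_matrix(env, spec)
  if (nrow(S) != nrow(R))
    stop_data("envelope (", nrow(S), ") and response (", nrow(R),
              ") lengths differ")
  A <- crossprod(S)
  diag(A) <- diag(A) + lambda
  B <- crossprod(S, R)
  W <- tryCatch(solve(A, B), error = function(e) {
    stop_fit("normal equations are numerically singular (lambda = ",
             lambda, "); increase lambda")
  })
  cost <- colSums((R - S %*% W)^2)
  structure(list(coef = W, lag_ms = spec$lag_ms, lags = spec$lags,
                 lambda = lambda, cost = as.numeric(cost),
                 fs_hz = spec$fs_hz, channels = channels,
                 condition = condition, subject = subject),
            class = "trf_estimate")
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' @export
print.trf_estimate <- function(x, ...) {
  cat(sprintf("<trf_estimate> %d lags (%g..%g ms) x %d electrode(s), lambda = %g\n",
              length(x$lag_ms), min(x$lag_ms), max(x$lag_ms),
              ncol(x$coef), x$lambda))
  invisible(x)
}

#' Predict the EEG response from a TRF and an envelope
#'
#' Computes the linear convolution `r_hat(t) = sum_tau TRF(tau) s(t - tau)`
#' with the same zero-padded boundary convention as [build_lag_matrix()].
#'
#' @param trf A `trf_estimate`.
#' @param env A `trf_envelope` or numeric vector at the TRF's rate.
#' @return Matrix (samples x electrodes) of predicted responses; a vector
#'   for a single electrode.
#' @export
predict_response <- function(trf, env) {
  s <- if (inherits(env, "trf_envelope")) {
    if (env$fs_hz != trf$fs_hz)
      stop_config("envelope and TRF sampling rates differ")
    env$samples
  } else {
    as.numeric(env)
  }
  out <- vapply(seq_len(ncol(trf$coef)), function(ch) {
    lagged_convolve(s, trf$coef[, ch], trf$lags)
  }, numeric(length(s)))
  if (ncol(trf$coef) == 1L) as.numeric(out) else out
}

#' Pearson correlation between predicted and measured response
#'
#' @param predicted,measured Equal-length numeric vectors (length >= 3,
#'   non-constant).
#' @return Correlation coefficient in `[-1, 1]`.
#' @export
prediction_correlation <- function(predicted, measured) {
  if (length(predicted) != length(measured))
    stop_data("predicted and measured lengths differ")
  if (length(predicted) < 3) stop_data("need at least 3 samples")
  if (sd(predicted) == 0 || sd(measured) == 0)
    stop_data("correlation undefined for constant input")
  cor(predicted, measured)
}
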