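#' Collect estimated TRFs into a subjects x conditions x electrodes set
#'
#' Container used by feature extraction and window optimization: a 4-way
#' array of coefficients indexed by lag, electrode, condition and subject.
#'
#' @param coef Array `[n_lags, n_electrodes, n_conditions, n_subjects]`.
#' @param lag_ms Lag latencies in ms (length `n_lags`).
#' @param channels Electrode labels.
#' @param conditions Condition values (delta SNR in dB, ascending).
#' @param subjects Subject identifiers.
#' @param lambda Ridge parameter used for estimation.
#' @return A `trf_set`.
#' @export
trf_set <- function(coef, lag_ms, channels, conditions, subjects,
                    lambda = NA_real_) {
  coef <- as.array(coef)
  if (length(dim(coef)) != 4L)
    stop_config("coef must be a 4-way array [lag, electrode, condition, subject]")
  d <- dim(coef)
  if (d[1] != length(lag_ms) || d[2] != length(channels) ||
      d[3] != length(conditions) || d[4] != length(subjects))
    stop_config("coef dimensions do not match the supplied labels")
  dimnames(coef) <- list(NULL, channels, NULL, NULL)
  structure(list(coef = coef, lag_ms = lag_ms, channels = channels,
                 conditions = conditions, subjects = subjects,
                 lambda = lambda),
            class = "trf_set")
}

#' @export
print.trf_set <- function(x, ...) {
  cat(sprintf("<trf_set> %d subjects x %d conditions x %d electrodes x %d lags\n",
              length(x$subjects), length(x$conditions), length(x$channels),
              length(x$lag_ms)))
  invisible(x)
}

#' Detect the first N1- or P2-like peak of a TRF
#'
#' Scans the TRF in ascending latency and returns the first local extremum
#' of the requested polarity inside the search window.  A local minimum
#' (maximum) is a sample where the discrete first derivative changes sign
#' from negative to positive (positive to negative); plateaus take the
#' first sample of the plateau.  The extremum must have the correct sign
#' of the TRF value (negative for N1, positive for P2); wrong-signed
#' extrema are skipped.  If no peak is found, `found = FALSE`, amplitude is
#' 0 and latency is set to the window's upper bound.
#'
#' @param x Numeric TRF coefficients, or a `trf_estimate` (with `channel`
#'   selecting the electrode).
#' @param lag_ms Latency grid in ms (ignored when `x` is a
#'   `trf_estimate`).
#' @param polarity `"negative"` (N1) or `"positive"` (P2).
#' @param window_ms Search window, e.g. `c(75, 175)` for N1 and
#'   `c(175, 300)` for P2.
#' @param channel Electrode label or index when `x` is a `trf_estimate`.
#' @return List with `amplitude` (absolute magnitude, >= 0), `latency_ms`
#'   and `found`.
#' @export
detect_peak <- function(x, lag_ms = NULL,
                        polarity = c("negative", "positive"),
                        window_ms, channel = 1L) {
  polarity <- match.arg(polarity)
  if (inherits(x, "trf_estimate")) {
    lag_ms <- x$lag_ms
    x <- x$coef[, channel]
  }
  x <- as.numeric(x)
  if (length(x) != length(lag_ms)) stop_config("x and lag_ms lengths differ")
  if (window_ms[1] < min(lag_ms) || window_ms[2] > max(lag_ms))
    stop_config("search window lies outside the lag span")
  cand <- local_extrema(x, polarity)
  ok <- cand[lag_ms[cand] >= window_ms[1] & lag_ms[cand] <= window_ms[2]]
  ok <- if (polarity == "negative") ok[x[ok] < 0] else ok[x[ok] > 0]
  if (!length(ok))
    return(list(amplitude = 0, latency_ms = window_ms[2], found = FALSE))
  i <- ok[1]
  list(amplitude = abs(x[i]), latency_ms = lag_ms[i], found = TRUE)
}

# Indices of local minima ("negative") or maxima ("positive"): derivative
# sign changes, with zero-derivative runs (plateaus) attributed to the
# first plateau sample.  Indices are returned in ascending order.
local_extrema <- function(x, polarity) {
  d <- sign(diff(x))
  r <- rle(d)
  ends <- cumsum(r$lengths)
  want_before <- if (polarity == "negative") -1 else 1
  out <- integer(0)
  for (i in seq_along(r$values)) {
    if (r$values[i] != want_before) next
    # next nonzero-signed run after (skipping at most one plateau run)
    j <- i + 1L
    while (j <= length(r$values) && r$values[j] == 0) j <- j + 1L
    if (j > length(r$values)) next
    if (r$values[j] == -want_before) out <- c(out, ends[i] + 1L)
  }
  out
}

#' Windowed root-mean-square of a TRF
#'
#' RMS of the coefficients whose latency lies in `[lower_ms, upper_ms]`
#' (inclusive rectangular window).
#'
#' @param x Numeric TRF coefficients or a `trf_estimate`.
#' @param lag_ms Latency grid (ignored for a `trf_estimate`).
#' @param lower_ms,upper_ms Window bounds in ms.
#' @param channel Electrode selector for a `trf_estimate`.
#' @return Nonnegative RMS value.
#' @export
windowed_rms <- function(x, lag_ms = NULL, lower_ms, upper_ms, channel = 1L) {
  if (inherits(x, "trf_estimate")) {
    lag_ms <- x$lag_ms
    x <- x$coef[, channel]
  }
  sel <- lag_ms >= lower_ms & lag_ms <= upper_ms
  if (!any(sel)) stop_config("RMS window contains no lag samples")
  sqrt(mean(x[sel]^2))
}

#' Optimize the RMS latency window for one electrode
#'
#' Exhaustive grid search over all lag-grid windows with lower bound in
#' `lower_range_ms` and upper bound in `upper_range_ms`.  The criterion is
#' the mean over subjects of each subject's Spearman correlation between
#' delta SNR and the windowed RMS (rank-based per subject; the pooled-rank
#' variant is available via `pooled = TRUE`).  Ties are broken by the
#' narrowest window, then the smallest lower bound.
#'
#' @param tset A [trf_set()].
#' @param electrode Electrode label.
#' @param lower_range_ms,upper_range_ms Bound ranges in ms (defaults
#'   `c(0, 100)` and `c(108, 200)`).
#' @param pooled If TRUE, rank all subject-condition pairs jointly instead
#'   of averaging per-subject correlations.
#' @return List with `electrode`, `lower_ms`, `upper_ms` and the achieved
#'   criterion `rho`; the evaluated grid is attached as attribute `grid`.
#' @export
optimize_rms_windows <- function(tset, electrode,
                                 lower_range_ms = c(0, 100),
                                 upper_range_ms = c(108, 200),
                                 pooled = FALSE) {
  if (length(tset$conditions) < 2)
    stop_config("need at least 2 conditions per subject")
  e <- match(electrode, tset$channels)
  if (is.na(e)) stop_data("electrode ", electrode, " not in the TRF set")
  lag_ms <- tset$lag_ms
  lowers <- which(lag_ms >= lower_range_ms[1] & lag_ms <= lower_range_ms[2])
  uppers <- which(lag_ms >= upper_range_ms[1] & lag_ms <= upper_range_ms[2])
  if (!length(lowers) || !length(uppers))
    stop_config("window bound ranges contain no lag samples")
  x <- tset$coef[, e, , , drop = TRUE]           # lag x cond x subj
  dim(x) <- c(length(lag_ms), length(tset$conditions), length(tset$subjects))
  csum <- apply(x^2, c(2, 3), cumsum)            # cumulative over lags
  grid <- expand.grid(l = lowers, u = uppers)
  grid$width <- grid$u - grid$l
  grid <- grid[order(grid$width, lag_ms[grid$l]), ]
  snr <- tset$conditions
  best <- NULL
  best_rho <- -Inf
  varied <- FALSE
  rhos <- numeric(nrow(grid))
  for (i in seq_len(nrow(grid))) {
    l <- grid$l[i]; u <- grid$u[i]
    ss <- csum[u, , ] - if (l > 1) csum[l - 1, , ] else 0
    rms <- matrix(sqrt(ss / (u - l + 1)), nrow = length(snr))  # cond x subj
    if (!varied && any(apply(rms, 2, sd) > 0)) varied <- TRUE
    rho <- if (pooled) {
      spearman_safe(rep(snr, times = ncol(rms)), as.numeric(rms))
    } else {
      mean(apply(rms, 2, function(v) spearman_safe(snr, v)))
    }
    rhos[i] <- rho
    if (is.finite(rho) && rho > best_rho) {
      best_rho <- rho
      best <- c(l, u)
    }
  }
  if (!varied || !is.finite(best_rho))
    stop_config("degenerate criterion: windowed RMS is constant everywhere")
  out <- list(electrode = electrode, lower_ms = lag_ms[best[1]],
              upper_ms = lag_ms[best[2]], rho = best_rho)
  attr(out, "grid") <- data.frame(lower_ms = lag_ms[grid$l],
                                  upper_ms = lag_ms[grid$u], rho = rhos)
  out
}

# Spearman correlation with the constant-vector convention rho = 0.
spearman_safe <- function(a, b) {
  if (sd(b) == 0 || sd(a) == 0) return(0)
  cor(a, b, method = "spearman")
}

#' Optimize RMS windows for every electrode
#'
#' @inheritParams optimize_rms_windows
#' @return Data frame with one row per electrode: `electrode`, `lower_ms`,
#'   `upper_ms`, `rho`.
#' @export
optimize_all_windows <- function(tset, lower_range_ms = c(0, 100),
                                 upper_range_ms = c(108, 200),
                                 pooled = FALSE) {
  rows <- lapply(tset$channels, function(el) {
    w <- optimize_rms_windows(tset, el, lower_range_ms, upper_range_ms, pooled)
    data.frame(electrode = el, lower_ms = w$lower_ms, upper_ms = w$upper_ms,
               rho = w$rho)
  })
  do.call(rbind, rows)
}

#' Extract the five TRF features for every subject, condition and electrode
#'
#' Applies N1 detection (negative peak, default window 75--175 ms), P2
#' detection (positive peak, default 175--300 ms) and the windowed RMS to
#' every TRF in the set.
#'
#' @param tset A [trf_set()].
#' @param windows Data frame `electrode, lower_ms, upper_ms` (as returned
#'   by [optimize_all_windows()]).  If NULL, a fixed N1-centred window of
#'   83.3--133.3 ms is used for every electrode.
#' @param n1_window_ms,p2_window_ms Peak search windows in ms.
#' @return Data frame with one row per (subject, condition, electrode):
#'   `n1_amp`, `n1_lat_ms`, `n1_found`, `p2_amp`, `p2_lat_ms`, `p2_found`,
#'   `rms`, `window_lower_ms`, `window_upper_ms`.
#' @export
extract_feature_table <- function(tset, windows = NULL,
                                  n1_window_ms = c(75, 175),
                                  p2_window_ms = c(175, 300)) {
  if (is.null(windows)) {
    step <- 1000 / 120
    windows <- data.frame(electrode = tset$channels,
                          lower_ms = 10 * step, upper_ms = 16 * step)
  }
  miss <- setdiff(tset$channels, windows$electrode)
  if (length(miss))
    stop_data("windows missing for electrode(s): ", paste(miss, collapse = ", "))
  lag_ms <- tset$lag_ms
  nS <- length(tset$subjects); nC <- length(tset$conditions)
  nE <- length(tset$channels)
  rows <- vector("list", nS * nC * nE)
  r <- 0L
  for (si in seq_len(nS)) for (ci in seq_len(nC)) for (ei in seq_len(nE)) {
    x <- tset$coef[, ei, ci, si]
    w <- windows[match(tset$channels[ei], windows$electrode), ]
    n1 <- detect_peak(x, lag_ms, "negative", n1_window_ms)
    p2 <- detect_peak(x, lag_ms, "positive", p2_window_ms)
    r <- r + 1L
    rows[[r]] <- data.frame(
      subject = tset$subjects[si], condition = tset$conditions[ci],
      electrode = tset$channels[ei],
      n1_amp = n1$amplitude, n1_lat_ms = n1$latency_ms, n1_found = n1$found,
      p2_amp = p2$amplitude, p2_lat_ms = p2$latency_ms, p2_found = p2$found,
      rms = windowed_rms(x, lag_ms, w$lower_ms, w$upper_ms),
      window_lower_ms = w$lower_ms, window_upper_ms = w$upper_ms)
  }
  do.call(rbind, rows)
}

#' Sum the windowed RMS over a fixed electrode subset
#'
#' Computes `RMS_sum`, the per-(subject, condition) arithmetic sum of the
#' windowed RMS values of the configured electrodes (default C3, CP3 and
#' CPz, the left central/centro-parietal sites carrying the strongest
#' speech-tracking response).
#'
#' @param features Feature table from [extract_feature_table()].
#' @param electrodes Electrode labels to sum (default
#'   `c("C3", "CP3", "CPz")`).
#' @return Data frame `subject`, `condition`, `rms_sum`.
#' @export
compute_rms_sum <- function(features, electrodes = c("C3", "CP3", "CPz")) {
  if (!length(electrodes)) stop_data("electrode set must not be empty")
  miss <- setdiff(electrodes, unique(features$electrode))
  if (length(miss))
    stop_data("electrode(s) not present in the feature table: ",
              paste(miss, collapse = ", "))
  sub <- features[features$electrode %in% electrodes, ]
  agg <- stats::aggregate(rms ~ subject + condition, data = sub, FUN = sum)
  names(agg)[names(agg) == "rms"] <- "rms_sum"
  agg[order(agg$subject, agg$condition), ]
}
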