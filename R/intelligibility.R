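#' Fit the logistic psychometric function to word scores
#'
#' Nonlinear least squares fit of
#' `100 / (1 + exp(-(SNR - SRT50) / s))` to intelligibility scores in
#' percent, with deterministic multi-start initialization (threshold
#' started at the SNR whose score is nearest 50%, slope started at 1.5 dB
#' and a small fixed ladder of alternatives).
#'
#' @param snr_db SNR values in dB (at least 3 distinct).
#' @param intelligibility_pct Observed scores in percent.
#' @return A `psychometric_fit`: `srt50_db`, `slope_s_db`, `rmse_pct`,
#'   `n`.
#' @export
fit_psychometric <- function(snr_db, intelligibility_pct) {
  if (length(unique(snr_db)) < 3)
    stop_data("need at least 3 distinct SNRs")
  if (length(snr_db) != length(intelligibility_pct))
    stop_data("snr and score lengths differ")
  df <- data.frame(snr = snr_db, y = intelligibility_pct)
  srt0 <- snr_db[which.min(abs(intelligibility_pct - 50))]
  starts <- expand.grid(srt = c(srt0, srt0 - 1, srt0 + 1),
                        s = c(1.5, 0.5, 3))
  fit <- NULL
  for (i in seq_len(nrow(starts))) {
    fit <- tryCatch(
      minpack.lm::nlsLM(y ~ 100 / (1 + exp(-(snr - srt) / s)), data = df,
                        start = list(srt = starts$srt[i], s = starts$s[i]),
                        lower = c(-Inf, 1e-4),
                        control = minpack.lm::nls.lm.control(maxiter = 200)),
      error = function(e) NULL)
    if (!is.null(fit) && coef(fit)[["s"]] > 0) break
    fit <- NULL
  }
  if (is.null(fit)) stop_fit("psychometric fit did not converge")
  cf <- coef(fit)
  structure(list(srt50_db = unname(cf[["srt"]]),
                 slope_s_db = unname(cf[["s"]]),
                 rmse_pct = sqrt(mean(resid(fit)^2)),
                 n = length(snr_db)),
            class = "psychometric_fit")
}

#' Fit the exponential intelligibility-vs-RMS_sum model
#'
#' Single-parameter nonlinear least squares fit of
#' `Intelligibility = 100 * (1 - exp(-b * RMS_sum)) %` across pooled
#' (RMS_sum, score) pairs.  The curve starts at 0% for RMS_sum = 0 and
#' saturates at 100%.  The 95% confidence interval for `b` comes from the
#' linearized (Jacobian) standard error with normal quantiles, and the
#' 50%-intelligibility threshold `RMS_50 = ln(2) / b` is populated via
#' [rms50_from_b()].
#'
#' @param rms_sum Nonnegative RMS_sum values.
#' @param intelligibility_pct Scores in percent.
#' @return An `exponential_fit`: `b`, `b_ci_low`, `b_ci_high`, `rms50`,
#'   `rmse_pct`, `n`.
#' @export
fit_exponential <- function(rms_sum, intelligibility_pct) {
  if (length(rms_sum) != length(intelligibility_pct))
    stop_data("rms_sum and score lengths differ")
  if (length(rms_sum) < 3) stop_data("need at least 3 pairs")
  if (any(rms_sum < 0)) stop_data("rms_sum must be nonnegative")
  if (all(intelligibility_pct <= 0))
    stop_fit("all intelligibility scores are zero; exponential fit undefined")
  df <- data.frame(x = rms_sum, y = intelligibility_pct)
  pos <- df$x > 0
  b0 <- stats::median(-log(pmax(1e-6, 1 - pmin(df$y[pos], 99) / 100)) / df$x[pos])
  if (!is.finite(b0) || b0 <= 0) b0 <- 1
  fit <- tryCatch(
    minpack.lm::nlsLM(y ~ 100 * (1 - exp(-b * x)), data = df,
                      start = list(b = b0), lower = 1e-8,
                      control = minpack.lm::nls.lm.control(maxiter = 200)),
    error = function(e) stop_fit("exponential fit did not converge: ",
                                 conditionMessage(e)))
  b <- unname(coef(fit)[["b"]])
  se <- tryCatch(summary(fit)$coefficients["b", "Std. Error"],
                 error = function(e) NA_real_)
  ci <- b + c(-1, 1) * qnorm(0.975) * se
  structure(list(b = b, b_ci_low = ci[1], b_ci_high = ci[2],
                 rms50 = rms50_from_b(b),
                 rmse_pct = sqrt(mean(resid(fit)^2)),
                 n = length(rms_sum)),
            class = "exponential_fit")
}

#' Threshold RMS_sum at 50% intelligibility
#'
#' Solves `100 * (1 - exp(-b * x)) = 50` for `x`, giving
#' `RMS_50 = ln(2) / b`.
#'
#' @param b Positive rate parameter of the exponential model.
#' @return The RMS_sum value mapped to 50% intelligibility.
#' @export
#' @examples
#' rms50_from_b(2.415)  # about 0.287
rms50_from_b <- function(b) {
  if (!is_number(b) || b <= 0) stop_config("b must be a positive number")
  log(2) / b
}

#' Predict individual SRT50 by leave-one-out threshold crossing
#'
#' For each subject, the exponential model is fitted to all other
#' subjects' (RMS_sum, intelligibility) pairs to obtain that subject's
#' held-out threshold `RMS_50`.  The subject's conditions are then scanned
#' in ascending delta SNR, and the first condition whose RMS_sum reaches
#' the threshold (`>=`) is the predicted SRT50, expressed as a delta SNR.
#' Because the condition grid is defined relative to the measured
#' behavioral threshold, the prediction deviation equals the predicted
#' delta SNR itself.
#'
#' @param data Data frame with columns `subject`, `delta_snr_db`,
#'   `rms_sum`, `intelligibility_pct`.
#' @return Data frame per subject: `subject`, `rms50_loo`,
#'   `predicted_srt_delta_db`, `crossed`, `deviation_db` (NA when the
#'   threshold is never crossed).
#' @export
predict_srt_loo <- function(data) {
  need <- c("subject", "delta_snr_db", "rms_sum", "intelligibility_pct")
  miss <- setdiff(need, names(data))
  if (length(miss)) stop_data("missing column(s): ", paste(miss, collapse = ", "))
  subjects <- unique(data$subject)
  if (length(subjects) < 2) stop_data("need at least 2 subjects")
  rows <- lapply(subjects, function(s) {
    train <- data[data$subject != s, ]
    thr <- fit_exponential(train$rms_sum, train$intelligibility_pct)$rms50
    test <- data[data$subject == s, ]
    test <- test[order(test$delta_snr_db), ]
    hit <- which(test$rms_sum >= thr)
    if (length(hit)) {
      pred <- test$delta_snr_db[hit[1]]
      data.frame(subject = s, rms50_loo = thr,
                 predicted_srt_delta_db = pred, crossed = TRUE,
                 deviation_db = pred)
    } else {
      data.frame(subject = s, rms50_loo = thr,
                 predicted_srt_delta_db = NA_real_, crossed = FALSE,
                 deviation_db = NA_real_)
    }
  })
  do.call(rbind, rows)
}

#' Summarize leave-one-out SRT predictions
#'
#' @param results Data frame from [predict_srt_loo()].
#' @param pairs Optional data frame with `rms_sum` and
#'   `intelligibility_pct` columns; if given, their pooled Spearman
#'   correlation is reported.
#' @return List: `n_total`, `n_crossed`, `mean_abs_deviation_db`,
#'   `min_deviation_db`, `max_deviation_db`, `n_within_1db`,
#'   `n_within_2db`, and `rho_rms_intelligibility` when `pairs` is given.
#' @export
evaluate_predictions <- function(results, pairs = NULL) {
  crossed <- results[results$crossed %in% TRUE, ]
  if (!nrow(crossed)) stop_data("no subject crossed the threshold")
  dev <- crossed$deviation_db
  out <- list(n_total = nrow(results), n_crossed = nrow(crossed),
              mean_abs_deviation_db = mean(abs(dev)),
              min_deviation_db = min(dev), max_deviation_db = max(dev),
              n_within_1db = sum(abs(dev) <= 1),
              n_within_2db = sum(abs(dev) <= 2))
  if (!is.null(pairs)) {
    out$rho_rms_intelligibility <-
      cor(pairs$rms_sum, pairs$intelligibility_pct, method = "spearman")
  }
  out
}
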