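#' Pipeline configuration
#'
#' Aggregates every analysis constant in one place: sampling and filtering
#' (120 Hz pipeline rate, 1--10 Hz order-397 band-pass), the lag grid
#' (-200..500 ms), the ridge parameter (2^15), the N1/P2 peak search
#' windows (75--175 and 175--300 ms), the RMS window-bound grids (0--100
#' and 108--200 ms), the RMS_sum electrode subset (C3, CP3, CPz) and the
#' synthetic cohort configuration.
#'
#' @param cohort A [cohort_config()].
#' @param filter A [filter_spec()].
#' @param lags A [lag_spec()].
#' @param lambda Ridge regularization (default `2^15`).
#' @param n1_window_ms,p2_window_ms Peak search windows.
#' @param rms_lower_range_ms,rms_upper_range_ms RMS window-bound grids.
#' @param rms_electrodes Electrode subset summed into RMS_sum.
#' @param artifact_method Passed to [remove_artifacts()].
#' @param bandpass Apply the band-pass to EEG and envelope (default TRUE).
#' @return A `pipeline_config` list.
#' @export
pipeline_config <- function(cohort = cohort_config(),
                            filter = filter_spec(),
                            lags = lag_spec(),
                            lambda = 2^15,
                            n1_window_ms = c(75, 175),
                            p2_window_ms = c(175, 300),
                            rms_lower_range_ms = c(0, 100),
                            rms_upper_range_ms = c(108, 200),
                            rms_electrodes = c("C3", "CP3", "CPz"),
                            artifact_method = "none",
                            bandpass = TRUE) {
  structure(list(cohort = cohort, filter = filter, lags = lags,
                 lambda = lambda, n1_window_ms = n1_window_ms,
                 p2_window_ms = p2_window_ms,
                 rms_lower_range_ms = rms_lower_range_ms,
                 rms_upper_range_ms = rms_upper_range_ms,
                 rms_electrodes = rms_electrodes,
                 artifact_method = artifact_method,
                 bandpass = isTRUE(bandpass)),
            class = "pipeline_config")
}

#' Run the full analysis pipeline
#'
#' Simulates (or loads) the cohort, preprocesses EEG and envelopes,
#' estimates one TRF per electrode, condition and subject, optimizes the
#' RMS windows, extracts the five morphology features, computes
#' electrode-wise monotonicity and group statistics, fits the behavioral
#' psychometric and the exponential intelligibility models, and predicts
#' each subject's SRT50 by leave-one-out threshold crossing.  Each
#' subject's raw EEG is discarded after TRF estimation, so memory stays
#' bounded.  With fixed seeds the run is fully reproducible.
#'
#' @param config A [pipeline_config()].
#' @param dataset Optional cohort from [generate_cohort()] or
#'   [read_dataset()]; when NULL (default) the synthetic cohort defined by
#'   `config$cohort` is generated on the fly.
#' @param verbose Log stage parameters and row counts to stderr.
#' @return A `trf_report`: `windows`, `features`, `stat_maps`, `rms_sum`,
#'   `behavioral_fit`, `exponential_fit`, `predictions`, `summary`,
#'   `mean_rho_rms_sum`, `n_trfs`, `config`.
#' @export
run_pipeline <- function(config = pipeline_config(), dataset = NULL,
                         verbose = TRUE) {
  log_ <- if (verbose) msg else function(...) invisible(NULL)
  cohort <- config$cohort
  spec <- config$lags
  if (is.null(dataset)) {
    srt <- cohort_srt50(cohort)
    n_subj <- cohort$n_subjects
    conds <- cohort$delta_snr_grid_db
    channels <- names(cohort$kernel$topography)
    get_subject <- function(s) generate_subject_data(cohort, s, srt[s])
  } else {
    n_subj <- length(dataset$subjects)
    conds <- vapply(dataset$subjects[[1]]$conditions, `[[`, 0, "delta_snr_db")
    channels <- dataset$subjects[[1]]$conditions[[1]]$eeg$channels
    get_subject <- function(s) dataset$subjects[[s]]
  }
  log_("simulate", n_subj, " subjects x ", length(conds), " conditions x ",
       length(channels), " channels")
  log_("trf", "lags ", spec$lag_min_ms, "..", spec$lag_max_ms, " ms (",
       length(spec$lags), " lags), lambda = ", config$lambda,
       if (config$bandpass) paste0("; band-pass ", config$filter$low_hz, "-",
                                   config$filter$high_hz, " Hz order ",
                                   config$filter$order) else "; no filtering")
  coef_arr <- array(0, c(length(spec$lag_ms), length(channels),
                         length(conds), n_subj))
  behavior <- vector("list", n_subj)
  for (s in seq_len(n_subj)) {
    sub <- get_subject(s)
    for (ci in seq_along(conds)) {
      cond <- sub$conditions[[ci]]
      env <- cond$envelope
      eeg <- cond$eeg
      if (config$bandpass) {
        eeg <- preprocess_recording(eeg, config$filter, spec$fs_hz,
                                    config$artifact_method)
        env <- new_envelope(bandpass_filter(env$samples, spec$fs_hz,
                                            config$filter),
                            spec$fs_hz, env$condition)
      } else {
        eeg <- remove_artifacts(eeg, config$artifact_method)
      }
      trf <- estimate_trf(env, eeg$samples, spec, config$lambda,
                          channels = eeg$channels,
                          condition = conds[ci], subject = sub$id)
      coef_arr[, , ci, s] <- trf$coef
    }
    behavior[[s]] <- data.frame(subject = sub$id,
                                delta_snr_db = sub$behavior$delta_snr_db,
                                intelligibility_pct =
                                  sub$behavior$intelligibility_pct)
  }
  behavior <- do.call(rbind, behavior)
  tset <- trf_set(coef_arr, spec$lag_ms, channels, conds, seq_len(n_subj),
                  config$lambda)
  n_trfs <- length(channels) * length(conds) * n_subj
  log_("trf", n_trfs, " TRFs estimated")

  windows <- optimize_all_windows(tset, config$rms_lower_range_ms,
                                  config$rms_upper_range_ms)
  log_("features", "RMS windows optimized for ", nrow(windows), " electrodes")
  features <- extract_feature_table(tset, windows, config$n1_window_ms,
                                    config$p2_window_ms)
  log_("features", nrow(features), " feature rows")

  if (length(conds) >= 3) {
    stat_maps <- list(rms = electrode_stat_map(features, "rms"),
                      n1_amp = electrode_stat_map(features, "n1_amp"),
                      n1_lat_ms = electrode_stat_map(features, "n1_lat_ms"))
    log_("stats", "electrode maps computed for rms, n1_amp, n1_lat_ms")
  } else {
    stat_maps <- NULL
    log_("stats", "skipped: monotonicity statistics need >= 3 conditions")
  }

  rms_sum <- compute_rms_sum(features, config$rms_electrodes)
  names(rms_sum)[names(rms_sum) == "condition"] <- "delta_snr_db"
  rms_sum <- merge(rms_sum, behavior, by = c("subject", "delta_snr_db"))
  rms_mat <- matrix(NA_real_, n_subj, length(conds))
  for (i in seq_len(nrow(rms_sum))) {
    rms_mat[rms_sum$subject[i], match(rms_sum$delta_snr_db[i], conds)] <-
      rms_sum$rms_sum[i]
  }
  mono <- if (length(conds) >= 3) {
    suppressWarnings(spearman_monotonicity(rms_mat, conds))
  } else {
    list(mean_rho = NA_real_)
  }

  behavioral_fit <- if (length(conds) >= 3) {
    fit_psychometric(behavior$delta_snr_db, behavior$intelligibility_pct)
  } else {
    NULL                      # sigmoid fit needs at least 3 distinct SNRs
  }
  ref <- 100 * psychometric_function(behavior$delta_snr_db, 0,
                                     cohort$slope_s_db %||% 1.462)
  reference_rmse <- sqrt(mean((behavior$intelligibility_pct - ref)^2))
  exponential_fit <- fit_exponential(rms_sum$rms_sum,
                                     rms_sum$intelligibility_pct)
  log_("predict", "RMS_50 = ", signif(exponential_fit$rms50, 4),
       " (b = ", signif(exponential_fit$b, 4), ")")
  if ((n_subj - 1) * length(conds) >= 3) {
    predictions <- predict_srt_loo(rms_sum)
    summary <- evaluate_predictions(predictions, rms_sum)
    log_("predict", summary$n_crossed, "/", summary$n_total,
         " subjects crossed; mean |deviation| = ",
         signif(summary$mean_abs_deviation_db, 3), " dB")
  } else {
    predictions <- NULL       # leave-one-out needs >= 3 training pairs
    summary <- NULL
    log_("predict", "skipped: too few subject-condition pairs for LOO")
  }

  structure(list(windows = windows, features = features,
                 stat_maps = stat_maps, rms_sum = rms_sum,
                 behavioral_fit = behavioral_fit,
                 reference_rmse_pct = reference_rmse,
                 exponential_fit = exponential_fit,
                 predictions = predictions, summary = summary,
                 mean_rho_rms_sum = mono$mean_rho,
                 n_trfs = n_trfs, config = config),
            class = "trf_report")
}

#' @export
print.trf_report <- function(x, ...) {
  cat("<trf_report>\n")
  cat(sprintf("  TRFs estimated:        %d\n", x$n_trfs))
  cat(sprintf("  mean rho (RMS_sum):    %.3f\n", x$mean_rho_rms_sum))
  cat(sprintf("  RMS_50 / b:            %.4g / %.4g\n",
              x$exponential_fit$rms50, x$exponential_fit$b))
  cat(sprintf("  mean |SRT50 deviation|: %.2f dB (%d/%d within 2 dB)\n",
              x$summary$mean_abs_deviation_db, x$summary$n_within_2db,
              x$summary$n_total))
  invisible(x)
}

#' Write a report bundle to disk
#'
#' CSV tables (`features.csv`, `windows.csv`, `stat_map_<feature>.csv`,
#' `rms_sum.csv`, `predictions.csv`) and a JSON summary (`summary.json`)
#' holding fits and prediction statistics.
#'
#' @param report A `trf_report`.
#' @param path Output directory.
#' @return `path`, invisibly.
#' @export
write_report <- function(report, path) {
  dir.create(path, recursive = TRUE, showWarnings = FALSE)
  write.csv(report$features, file.path(path, "features.csv"), row.names = FALSE)
  write.csv(report$windows, file.path(path, "windows.csv"), row.names = FALSE)
  for (nm in names(report$stat_maps)) {
    write.csv(report$stat_maps[[nm]],
              file.path(path, paste0("stat_map_", nm, ".csv")),
              row.names = FALSE)
  }
  write.csv(report$rms_sum, file.path(path, "rms_sum.csv"), row.names = FALSE)
  if (!is.null(report$predictions))
    write.csv(report$predictions, file.path(path, "predictions.csv"),
              row.names = FALSE)
  jsonlite::write_json(
    list(n_trfs = report$n_trfs,
         mean_rho_rms_sum = report$mean_rho_rms_sum,
         behavioral_fit = unclass(report$behavioral_fit),
         reference_rmse_pct = report$reference_rmse_pct,
         exponential_fit = unclass(report$exponential_fit),
         summary = report$summary),
    file.path(path, "summary.json"), auto_unbox = TRUE, digits = NA)
  invisible(path)
}
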