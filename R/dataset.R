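#' Write a synthetic cohort to disk
#'
#' One directory per subject holding, per condition, the envelope and the
#' EEG as plain-text numeric tables with a JSON sidecar (sampling rate,
#' channel labels, delta SNR); behavioral scores as a single CSV; cohort
#' metadata (thresholds, configuration summary) as JSON.  Values are
#' written with 17 significant digits so the round trip is lossless.
#'
#' @param cohort A `trf_cohort` from [generate_cohort()].
#' @param path Output directory (created if missing).
#' @return `path`, invisibly.
#' @export
write_dataset <- function(cohort, path) {
  dir.create(path, recursive = TRUE, showWarnings = FALSE)
  fmt <- function(x) format(x, digits = 17, scientific = TRUE, trim = TRUE)
  for (s in cohort$subjects) {
    sdir <- file.path(path, sprintf("subject_%02d", s$id))
    dir.create(sdir, showWarnings = FALSE)
    for (ci in seq_along(s$conditions)) {
      cond <- s$conditions[[ci]]
      tag <- sprintf("cond%02d", ci)
      writeLines(fmt(cond$envelope$samples),
                 file.path(sdir, paste0("envelope_", tag, ".txt")))
      eeg_file <- file.path(sdir, paste0("eeg_", tag, ".csv"))
      write.table(matrix(fmt(cond$eeg$samples), nrow(cond$eeg$samples)),
                  eeg_file, sep = ",", row.names = FALSE, col.names = FALSE,
                  quote = FALSE)
      jsonlite::write_json(
        list(delta_snr_db = cond$delta_snr_db, fs_hz = cond$eeg$fs_hz,
             channels = cond$eeg$channels,
             envelope_fs_hz = cond$envelope$fs_hz),
        file.path(sdir, paste0("meta_", tag, ".json")), auto_unbox = TRUE)
    }
  }
  write.csv(cohort_behavior(cohort), file.path(path, "behavior.csv"),
            row.names = FALSE)
  jsonlite::write_json(
    list(n_subjects = cohort$config$n_subjects,
         delta_snr_grid_db = cohort$config$delta_snr_grid_db,
         n_channels = cohort$config$n_channels,
         seed = cohort$config$seed,
         srt50_db = vapply(cohort$subjects, `[[`, 0, "srt50_db")),
    file.path(path, "cohort.json"), auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' Read a cohort written by [write_dataset()]
#'
#' @param path Dataset directory.
#' @return A `trf_cohort`-like list with `subjects` (each holding
#'   `srt50_db`, `behavior` and per-condition envelope/EEG pairs) and
#'   `meta` from the cohort sidecar.
#' @export
read_dataset <- function(path) {
  if (!dir.exists(path)) stop_data("dataset directory not found: ", path)
  beh_file <- file.path(path, "behavior.csv")
  if (!file.exists(beh_file))
    stop_data("missing behavior table: ", beh_file)
  meta_file <- file.path(path, "cohort.json")
  if (!file.exists(meta_file))
    stop_data("missing cohort metadata: ", meta_file)
  meta <- jsonlite::read_json(meta_file, simplifyVector = TRUE)
  behavior <- read.csv(beh_file)
  sdirs <- sort(list.dirs(path, recursive = FALSE))
  subjects <- lapply(sdirs, function(sdir) {
    id <- as.integer(sub(".*subject_", "", sdir))
    metas <- sort(list.files(sdir, pattern = "^meta_cond[0-9]+\\.json$"))
    conditions <- lapply(metas, function(mf) {
      tag <- sub("^meta_(cond[0-9]+)\\.json$", "\\1", mf)
      cm <- jsonlite::read_json(file.path(sdir, mf), simplifyVector = TRUE)
      env <- new_envelope(
        as.numeric(readLines(file.path(sdir, paste0("envelope_", tag, ".txt")))),
        cm$envelope_fs_hz, cm$delta_snr_db)
      eeg_m <- as.matrix(read.csv(file.path(sdir, paste0("eeg_", tag, ".csv")),
                                  header = FALSE))
      eeg <- new_eeg_recording(unname(eeg_m), cm$fs_hz, cm$channels,
                               cm$delta_snr_db)
      list(delta_snr_db = cm$delta_snr_db, envelope = env, eeg = eeg)
    })
    beh <- behavior[behavior$subject == id, ]
    list(id = id, srt50_db = beh$srt50_db[1],
         behavior = beh[, setdiff(names(beh), c("subject", "srt50_db"))],
         conditions = conditions)
  })
  structure(list(meta = meta, subjects = subjects), class = "trf_cohort")
}
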