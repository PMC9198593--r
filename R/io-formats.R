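# Minimal readers for the field's container formats.  No EDF/BrainVision/WAV
# reader ships with the installed stack, so the small subsets needed here
# (uncompressed PCM WAV, EDF continuous recordings, BrainVision multiplexed
# binary) are parsed directly.

#' Read an uncompressed WAV file
#'
#' Supports PCM 16-bit and IEEE float 32-bit mono or multichannel files.
#' Samples are returned as doubles in `[-1, 1]` (PCM scaled by 2^15).
#'
#' @param path Path to a `.wav` file.
#' @return List with `samples` (matrix, channels in columns) and `fs_hz`.
#' @export
read_wav <- function(path) {
  if (!file.exists(path)) stop_data("WAV file not found: ", path)
  con <- file(path, "rb")
  on.exit(close(con))
  riff <- readChar(con, 4, useBytes = TRUE)
  if (!identical(riff, "RIFF")) stop_data(path, ": not a RIFF/WAV file")
  invisible(readBin(con, "integer", 1, 4, endian = "little"))
  wave <- readChar(con, 4, useBytes = TRUE)
  if (!identical(wave, "WAVE")) stop_data(path, ": not a WAVE file")
  fmt <- NULL
  repeat {
    id <- readChar(con, 4, useBytes = TRUE)
    if (!nchar(id)) stop_data(path, ": no data chunk found")
    size <- readBin(con, "integer", 1, 4, endian = "little")
    if (identical(id, "fmt ")) {
      raw <- readBin(con, "raw", size)
      fmt <- list(
        audio_format = readBin(raw[1:2], "integer", 1, 2, endian = "little"),
        n_channels = readBin(raw[3:4], "integer", 1, 2, endian = "little"),
        fs = readBin(raw[5:8], "integer", 1, 4, endian = "little"),
        bits = readBin(raw[15:16], "integer", 1, 2, endian = "little"))
    } else if (identical(id, "data")) {
      if (is.null(fmt)) stop_data(path, ": data chunk before fmt chunk")
      if (fmt$audio_format == 1L && fmt$bits == 16L) {
        x <- readBin(con, "integer", size / 2, 2, signed = TRUE,
                     endian = "little") / 2^15
      } else if (fmt$audio_format == 3L && fmt$bits == 32L) {
        x <- readBin(con, "double", size / 4, 4, endian = "little")
      } else {
        stop_data(path, ": unsupported WAV encoding (format ",
                  fmt$audio_format, ", ", fmt$bits, " bits)")
      }
      m <- matrix(x, ncol = fmt$n_channels, byrow = TRUE)
      return(list(samples = m, fs_hz = fmt$fs))
    } else {
      invisible(readBin(con, "raw", size + size %% 2))
    }
  }
}

# PCM16 WAV writer (used by tests and for exporting synthetic stimuli).
write_wav <- function(samples, fs_hz, path) {
  m <- as.matrix(samples)
  inter <- as.integer(round(pmax(-1, pmin(1, t(m))) * (2^15 - 1)))
  data_size <- length(inter) * 2L
  con <- file(path, "wb")
  on.exit(close(con))
  writeChar("RIFF", con, eos = NULL)
  writeBin(as.integer(36L + data_size), con, 4, endian = "little")
  writeChar("WAVEfmt ", con, eos = NULL)
  writeBin(16L, con, 4, endian = "little")
  writeBin(c(1L, ncol(m)), con, 2, endian = "little")
  writeBin(as.integer(fs_hz), con, 4, endian = "little")
  writeBin(as.integer(fs_hz * ncol(m) * 2), con, 4, endian = "little")
  writeBin(c(as.integer(ncol(m) * 2), 16L), con, 2, endian = "little")
  writeChar("data", con, eos = NULL)
  writeBin(data_size, con, 4, endian = "little")
  writeBin(inter, con, 2, endian = "little")
  invisible(path)
}

#' Read a continuous EDF recording
#'
#' Parses the European Data Format header (ASCII, 256 bytes plus 256 per
#' signal) and the 16-bit data records, applying each signal's
#' physical/digital calibration.  Annotation channels are not supported.
#'
#' @param path Path to an `.edf` file.
#' @return An `eeg_recording` (all signals must share one sampling rate).
#' @export
read_edf <- function(path) {
  if (!file.exists(path)) stop_data("EDF file not found: ", path)
  con <- file(path, "rb")
  on.exit(close(con))
  hdr <- readChar(con, 256, useBytes = TRUE)
  fld <- function(s, from, len) trimws(substr(s, from, from + len - 1))
  n_records <- as.integer(fld(hdr, 237, 8))
  record_dur <- as.numeric(fld(hdr, 245, 8))
  ns <- as.integer(fld(hdr, 253, 4))
  if (is.na(ns) || ns < 1) stop_data(path, ": malformed EDF header (ns)")
  sig_hdr <- readChar(con, 256 * ns, useBytes = TRUE)
  grab <- function(offset, width) {
    vapply(seq_len(ns), function(i) {
      trimws(substr(sig_hdr, offset * ns + (i - 1) * width + 1,
                    offset * ns + i * width))
    }, character(1))
  }
  labels <- grab(0, 16)
  # offsets within the signal header block, in bytes per field group
  pos <- 16 * ns
  read_field <- function(width) {
    out <- vapply(seq_len(ns), function(i) {
      substr(sig_hdr, pos + (i - 1) * width + 1, pos + i * width)
    }, character(1))
    pos <<- pos + width * ns
    trimws(out)
  }
  invisible(read_field(80))                 # transducer
  invisible(read_field(8))                  # physical dimension
  phys_min <- as.numeric(read_field(8))
  phys_max <- as.numeric(read_field(8))
  dig_min <- as.numeric(read_field(8))
  dig_max <- as.numeric(read_field(8))
  invisible(read_field(80))                 # prefiltering
  n_samp <- as.integer(read_field(8))
  if (length(unique(n_samp)) != 1L)
    stop_data(path, ": signals with differing rates are not supported")
  fs <- n_samp[1] / record_dur
  gain <- (phys_max - phys_min) / (dig_max - dig_min)
  offset <- phys_min - gain * dig_min
  total <- n_records * ns * n_samp[1]
  raw <- readBin(con, "integer", total, 2, signed = TRUE, endian = "little")
  if (length(raw) != total) stop_data(path, ": truncated EDF data")
  dat <- matrix(0, n_records * n_samp[1], ns)
  for (r in seq_len(n_records)) {
    block <- matrix(raw[((r - 1) * ns * n_samp[1] + 1):(r * ns * n_samp[1])],
                    nrow = n_samp[1])
    rows <- ((r - 1) * n_samp[1] + 1):(r * n_samp[1])
    dat[rows, ] <- sweep(sweep(block, 2, gain, "*"), 2, offset, "+")
  }
  new_eeg_recording(dat, fs, labels)
}

# Fixed-width EDF writer for round-trip tests and synthetic exports.
write_edf <- function(eeg, path) {
  m <- eeg$samples
  ns <- ncol(m)
  n_samp <- nrow(m)
  pad <- function(x, w) formatC(as.character(x), width = w, flag = "-")
  phys_min <- apply(m, 2, min); phys_max <- apply(m, 2, max)
  span <- pmax(phys_max - phys_min, 1e-6)
  phys_max <- phys_min + span
  dig_min <- rep(-32768, ns); dig_max <- rep(32767, ns)
  gain <- span / (dig_max - dig_min)
  digital <- round(sweep(sweep(m, 2, phys_min, "-"), 2, gain, "/") + dig_min)
  con <- file(path, "wb")
  on.exit(close(con))
  hdr <- paste0(pad("0", 8), pad("synthetic", 80), pad("synthetic", 80),
                pad("01.01.26", 8), pad("00.00.00", 8),
                pad(256 * (ns + 1), 8), pad("", 44),
                pad(1, 8), pad(n_samp / eeg$fs_hz, 8), pad(ns, 4))
  writeChar(hdr, con, eos = NULL)
  field <- function(vals, w) writeChar(paste0(vapply(vals, pad, "", w = w),
                                              collapse = ""), con, eos = NULL)
  field(eeg$channels, 16)
  field(rep("", ns), 80)
  field(rep("uV", ns), 8)
  field(formatC(phys_min, format = "g", digits = 6), 8)
  field(formatC(phys_max, format = "g", digits = 6), 8)
  field(dig_min, 8)
  field(dig_max, 8)
  field(rep("", ns), 80)
  field(rep(n_samp, ns), 8)
  field(rep("", ns), 32)
  writeBin(as.integer(digital), con, 2, endian = "little")
  invisible(path)
}

#' Read a BrainVision recording
#'
#' Parses the `.vhdr` INI header and the associated binary data file.
#' Supports multiplexed IEEE float 32 and signed 16-bit integer formats.
#'
#' @param vhdr_path Path to the `.vhdr` header file.
#' @return An `eeg_recording`.
#' @export
read_brainvision <- function(vhdr_path) {
  if (!file.exists(vhdr_path)) stop_data("header not found: ", vhdr_path)
  lines <- readLines(vhdr_path, warn = FALSE)
  get_val <- function(key) {
    ln <- grep(paste0("^", key, "="), lines, value = TRUE)
    if (!length(ln)) stop_data(vhdr_path, ": missing field ", key)
    sub("^[^=]*=", "", ln[1])
  }
  data_file <- get_val("DataFile")
  n_ch <- as.integer(get_val("NumberOfChannels"))
  interval_us <- as.numeric(get_val("SamplingInterval"))
  fs <- 1e6 / interval_us
  fmt <- get_val("BinaryFormat")
  orient <- tryCatch(get_val("DataOrientation"),
                     error = function(e) "MULTIPLEXED")
  if (toupper(orient) != "MULTIPLEXED")
    stop_data(vhdr_path, ": only multiplexed orientation is supported")
  ch_lines <- grep("^Ch[0-9]+=", lines, value = TRUE)
  labels <- vapply(strsplit(sub("^[^=]*=", "", ch_lines), ","), `[`, "", 1)
  if (length(labels) != n_ch)
    stop_data(vhdr_path, ": channel list does not match NumberOfChannels")
  resolutions <- vapply(strsplit(sub("^[^=]*=", "", ch_lines), ","),
                        function(p) {
                          r <- suppressWarnings(as.numeric(p[3]))
                          if (is.na(r)) 1 else r
                        }, numeric(1))
  data_path <- file.path(dirname(vhdr_path), data_file)
  if (!file.exists(data_path)) stop_data("data file not found: ", data_path)
  sz <- file.info(data_path)$size
  con <- file(data_path, "rb")
  on.exit(close(con))
  if (toupper(fmt) == "IEEE_FLOAT_32") {
    x <- readBin(con, "double", sz / 4, 4, endian = "little")
  } else if (toupper(fmt) == "INT_16") {
    x <- readBin(con, "integer", sz / 2, 2, signed = TRUE, endian = "little")
  } else {
    stop_data(vhdr_path, ": unsupported BinaryFormat ", fmt)
  }
  m <- matrix(x, ncol = n_ch, byrow = TRUE)
  m <- sweep(m, 2, resolutions, "*")
  new_eeg_recording(m, fs, labels)
}
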