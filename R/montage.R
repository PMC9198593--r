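#' Default 32-channel 10-20 montage
#'
#' Electrode labels of the 32-channel montage used throughout the package.
#' The set covers the standard 10-20 positions plus the centro-parietal row
#' (CP3/CPz/CP4) that carries the strongest speech-tracking response.
#'
#' @return Character vector of 32 electrode labels.
#' @export
#' @examples
#' montage_32()
montage_32 <- function() {
  c("Fp1", "Fp2", "F7", "F3", "Fz", "F4", "F8",
    "FT7", "FC3", "FCz", "FC4", "FT8",
    "T7", "C3", "Cz", "C4", "T8",
    "TP7", "CP3", "CPz", "CP4", "TP8",
    "P7", "P3", "Pz", "P4", "P8",
    "O1", "Oz", "O2", "M1", "M2")
}

#' Default scalp topography of the simulated speech-tracking response
#'
#' Per-electrode gain map in `[0, 1]` applied to the envelope-convolved
#' kernel when synthesizing EEG.  Gains peak over the left central and
#' centro-parietal region (C3, CP3, CPz) where auditory N1-like responses
#' to speech are largest, and fall off toward frontal polar, occipital and
#' mastoid sites.
#'
#' @param channels Electrode labels; defaults to [montage_32()].
#' @return Named numeric vector of gains in `[0, 1]`.
#' @export
default_topography <- function(channels = montage_32()) {
  gains <- c(
    Fp1 = 0.10, Fp2 = 0.10, F7 = 0.15, F3 = 0.30, Fz = 0.25, F4 = 0.15, F8 = 0.10,
    FT7 = 0.20, FC3 = 0.70, FCz = 0.60, FC4 = 0.40, FT8 = 0.10,
    T7 = 0.30, C3 = 1.00, Cz = 0.80, C4 = 0.50, T8 = 0.20,
    TP7 = 0.40, CP3 = 1.00, CPz = 0.90, CP4 = 0.60, TP8 = 0.20,
    P7 = 0.20, P3 = 0.60, Pz = 0.50, P4 = 0.30, P8 = 0.15,
    O1 = 0.10, Oz = 0.10, O2 = 0.10, M1 = 0.05, M2 = 0.05)
  missing <- setdiff(channels, names(gains))
  if (length(missing)) {
    extra <- rep(0.1, length(missing))
    names(extra) <- missing
    gains <- c(gains, extra)
  }
  gains[channels]
}
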