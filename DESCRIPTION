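Package: trfspeech
Title: Temporal Response Functions and EEG-Based Prediction of Speech
    Intelligibility in Noise
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Estimates temporal response functions (TRFs) between speech
    envelopes and continuous EEG using regularized (ridge) linear
    regression, extracts auditory-evoked-potential-like morphology
    features (N1/P2 amplitude and latency, windowed RMS) per electrode
    and signal-to-noise-ratio condition, and predicts an individual's
    50% speech reception threshold (SRT50) from the summed windowed RMS
    via an exponential intelligibility model with leave-one-out
    threshold calibration.  Ships a synthetic cohort generator that
    emulates matrix-sentence speech-in-noise experiments (envelope
    bursts at the matrix-test syllable rate, kernel-convolved
    multichannel EEG with 1/f background noise, binomially sampled word
    scores from a logistic psychometric function) so the full analysis
    is testable without access to recordings.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    signal,
    minpack.lm,
    jsonlite,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
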