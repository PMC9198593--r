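---
title: "Predicting speech reception thresholds from TRF morphology"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Predicting speech reception thresholds from TRF morphology}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

## The encoding model

Continuous speech evokes cortical activity that tracks the slow amplitude
modulations (the envelope) of the acoustic signal. The package models the
EEG at each electrode as the linear convolution of the stimulus envelope
$s(t)$ with an unknown impulse response, the temporal response function
(TRF):

$$\hat r(t) = \sum_\tau \mathrm{TRF}(\tau)\, s(t - \tau),$$

with lags $\tau$ from $-200$ to $500$ ms in steps of $1000/120 \approx
8.33$ ms (85 lags). Minimizing the squared prediction error
$J = \sum_t [r(t) - \hat r(t)]^2$ with an $L_2$ penalty gives the ridge
solution

$$\mathrm{TRF} = (S^\top S + \lambda I)^{-1} S^\top r,$$

where the columns of $S$ are time-lagged copies of the envelope
(zero-padded at the boundaries) and $\lambda$ is held fixed at $2^{15}$
for every electrode, condition and subject. Holding $\lambda$ constant
matters: ridge shrinkage scales the coefficients, and the analysis
compares TRF *amplitudes* across SNR conditions, which is only meaningful
under one shrinkage convention. For the same reason envelopes are not
renormalized per condition. The model has no intercept because both
signals are band-passed (1–10 Hz) and therefore zero-mean.

Assumptions worth stating: linearity and time invariance of the
envelope-to-EEG mapping within a condition; stationarity of the
background EEG; and a response that is fully driven by the *clean-speech*
envelope. The last point settles an ambiguity in how the regressor should
be computed when speech is embedded in noise: the package uses the clean
envelope (the noise is stationary and carries no sentence structure), and
the generator follows the same reading.

## Signal conditioning

Both the EEG and the envelope pass through the same band-pass: a Hamming
windowed-sinc FIR of order 397 with $-6$ dB edges at 1 and 10 Hz,
covering the delta and theta bands and the matrix-test syllable rate of
3.8 Hz. The filter is applied non-causally ("zero phase"). An odd-order
linear-phase FIR has a group delay of $397/2 = 198.5$ samples — a
*fractional* delay — so instead of shifting by a rounded sample count,
the filter is applied in the frequency domain and its delay removed
exactly with a conjugate-symmetric phase ramp. Passband components then
keep amplitude (ripple below 5% between 2 and 9 Hz) and phase; DC is
attenuated by more than 40 dB. Signals are zero-padded on both ends before
filtering and trimmed afterwards, which preserves length without
wrap-around artifacts. Edge distortion is confined to roughly half the
filter length (~1.7 s) at each end — negligible against 9 minutes of
data per condition.

Envelope extraction from audio follows a fixed order of operations:
full-wave rectification, power-law compression with exponent 0.6
(approximating cochlear compression), down-sampling to the 120 Hz
pipeline rate (anti-alias low-pass with replicate-padded edges so DC
passes exactly, then decimation), and finally the shared band-pass.
Artifact removal is a pluggable hook (`remove_artifacts`), identity by
default: synthetic recordings contain no eye blinks, and on real data any
ICA-based cleaner satisfying the shape/label/rate contract can be slotted
in.

## Feature extraction

Each TRF yields five features. N1$_\mathrm{TRF}$ is the *first* local
minimum between 75 and 175 ms, found by a sign change of the discrete
first derivative (negative to positive); P2$_\mathrm{TRF}$ is the first
local maximum between 175 and 300 ms. Extrema of the wrong sign (a
"minimum" with positive TRF value, say) are skipped, since the features
are meant to capture genuine N1/P2-like deflections. Plateaus of zero
derivative are attributed to their first sample, which keeps detection
deterministic at the 8.33 ms lag resolution without interpolation. When
no peak exists the amplitude is 0 and the latency is the window's upper
bound (for P2, 300 ms), a fallback that penalizes degraded conditions in
the expected direction.

The fifth feature is the RMS of the TRF within a per-electrode latency
window. The window bounds are grid-searched exhaustively — lower bound
over 0–100 ms, upper over 108–200 ms, both at lag resolution, endpoints
inclusive — maximizing the mean over subjects of each subject's Spearman
$\rho$ between $\Delta$SNR and the windowed RMS. Averaging per-subject
$\rho$ (rather than pooling ranks across subjects) matches how the
monotonicity statistics are computed elsewhere; the pooled variant
remains available via `pooled = TRUE`. Exact criterion ties are broken
toward the narrowest window and then the smallest lower bound, making the
argmax unique and reproducible. The optimized windows concentrate around
the N1 latency, and the RMS of C3, CP3 and CPz — the left
central/centro-parietal sites where the speech-tracking response is
largest — are summed into `RMS_sum`. The electrode subset is a
configuration default, not re-derived per dataset, so that `RMS_sum` has
one fixed definition across studies.

## Statistics

Monotonicity of any feature with SNR is quantified per electrode as the
mean over subjects of Spearman's $\rho$ (midranks for ties). A subject
with a constant feature vector contributes $\rho = 0$ with a warning
rather than dropping out, keeping electrode maps total. Differences
between $\Delta$SNR conditions are tested per electrode with the
Kruskal–Wallis test (tie-corrected; a fully tied sample returns $H = 0$,
$p = 1$, the limiting value) and followed up with Dunn's z tests on the
pooled midranks, Bonferroni-multiplied by the 15 condition pairs and
clipped at 1. Two-sided p-values are used even where a direction is
expected, matching generic post-hoc reporting.

## From RMS_sum to a threshold prediction

Behavior is summarized by the logistic psychometric function
$f(\mathrm{SNR}) = 1/(1 + e^{-(\mathrm{SNR} - \mathrm{SRT}_{50})/s})$.
The EEG feature is linked to intelligibility through
$I = 100\,(1 - e^{-b\,\mathrm{RMS_{sum}}})\%$ — zero at zero tracking,
saturating at 100% — fitted by nonlinear least squares with a single
parameter $b$, whose 95% CI comes from the linearized standard error.
The 50% point is analytic: $\mathrm{RMS}_{50} = \ln 2 / b$.

Prediction is leave-one-out: $b$ (hence $\mathrm{RMS}_{50}$) is fitted
without the evaluated subject, and the subject's conditions are scanned
in ascending $\Delta$SNR for the first `RMS_sum` $\geq$
$\mathrm{RMS}_{50}$. The crossing is evaluated on the discrete condition
grid (no interpolation), so predictions land on grid values and the
deviation from the behavioral threshold — which sits at $\Delta$SNR = 0
by construction — is read off directly. "Exceeds" is implemented as
$\geq$ to make the boundary case deterministic; an interpolating variant
was considered and rejected because the discrete rule is what the grid
design supports.

## The synthetic cohort

The generator reproduces the statistical structure the analysis relies
on, at the study's dimensions: 18 subjects, thresholds drawn from
$\mathcal N(-7.0, 0.9^2)$ dB, six conditions at $\Delta$SNR
$\in \{-4, -2, -0.5, +0.5, +2, +4\}$ dB, 32 electrodes, 9 minutes of
stimulus per condition at 120 Hz, and word scores that are binomial over
20 sentences × 5 words with success probability $f$ at slope
$s = 1.462$ dB (giving the familiar ~6/20/40/60/80/93% ladder across the
grid).

Stimuli are sentence-shaped envelope bursts: 8–10 raised-cosine syllable
cycles at 3.8 Hz with mild per-sentence level jitter, separated by
silences drawn uniformly from 0.9–1.8 s (mean 1.35 s, slightly below the
published mean interval of 1.4 s with the same range — the uniform draw
is kept for simplicity). The EEG is the envelope convolved with a
ground-truth kernel — a negative Gaussian at 110 ms and a positive one at
210 ms, widths 22 and 32 ms — plus independent pink (1/f) background
noise per channel. SNR dependence lives on the kernel, not the stimulus:
amplitudes scale by $1 + 0.08 \cdot \Delta$SNR (floored at 0, since a
negative-gain response is physiologically meaningless) and latencies
shift by $-3$ ms/dB, emulating the reported morphology changes. A scalp
gain map peaking at C3/CP3/CPz provides the topography. The default
noise SD of 1 against a unit-amplitude kernel puts the single-trial
response about 10 dB below the background, typical for cortical evoked
activity. One master seed drives everything; per-subject and
per-condition streams are derived by a fixed integer mix, so a cohort is
a pure function of its configuration.

What the generator does *not* emulate — and what passing tests therefore
do not establish about real recordings: volume conduction and correlated
noise across electrodes, eye-blink and movement artifacts, non-stationary
attention and vigilance drifts, phoneme-level acoustic structure, and
between-subject variability in kernel shape or topography. With 9 minutes
of data and independent noise, the estimation problem is considerably
easier than in vivo: monotonicity correlations saturate near 1 and all 18
synthetic subjects are predicted within ±0.5 dB, whereas real cohorts
show $\rho \approx 0.8$ and a ~1 dB mean deviation. The synthetic results
validate the machinery, not the effect size.

## Numerical choices and problem sizes

Degenerate inputs are handled explicitly: zero envelopes make the
$\lambda = 0$ normal equations singular (a classed fit error suggests
increasing $\lambda$); constant signals are rejected where a correlation
is undefined; configurations below the minimum data sizes (fewer than 3
conditions for monotonicity and the psychometric fit, fewer than 3
training pairs for leave-one-out) skip those stages with a logged note
instead of failing the whole run.

The test suite fixes its own problem sizes: unit tests use 5–60 s
stimuli so they run in milliseconds; the ridge estimator is checked
against brute-force matrix inversion on random instances of up to 30
samples and 5 lags; the Kruskal–Wallis null calibration uses 2,000
simulated electrode datasets; parameter recovery uses 200 cohorts of 18
subjects; and the end-to-end checks run the full default scale (18 × 6 ×
32, 9 min/condition), which completes in about two minutes on one CPU.

## Known limitations

The $\lambda$ search the original analysis alluded to is not
implemented — $\lambda$ is a configuration input, fixed at $2^{15}$.
Backward (stimulus-reconstruction) models, cross-validated
regularization, spatial cluster statistics, re-referencing and full ICA
are out of scope. The EDF/BrainVision/WAV readers cover the common
continuous-recording subsets of those formats (no annotations, no
segmented files). Real-data performance depends on artifact quality and
electrode impedance in ways the synthetic cohort cannot probe.
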