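---
title: "Audio-based assessment of pMDI inhaler user technique: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Audio-based assessment of pMDI inhaler user technique: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(flotone)
```

## The problem

Pressurised metered dose inhalers (pMDIs) only deliver their full dose
when the patient presses the canister *during* a slow, deep inhalation.
The two critical user-technique errors are poor actuation coordination
(releasing the dose outside the breath) and inhaling too fast (peak
inspiratory flow rate, PIFR, above 90 L/min). Both are hard to judge by
eye. With a Flo-Tone training mouthpiece attached, the inhalation itself
becomes audible: the mouthpiece reed emits a harmonic tone (fundamental
around 540 Hz, varying roughly 520--570 Hz across devices) once
inspiratory flow reaches about 30--60 L/min, and the tone gets louder as
flow increases. `flotone` turns a plain mono recording of inhaler use
into (i) a timed sequence of sound events, (ii) an estimated inspiratory
flow profile with PIFR and inhaled volume, and (iii) dichotomous
critical-error findings.

## Stage 1: frame-by-frame sound-event classification

Recordings are band-pass filtered 140--22,000 Hz (4th-order Butterworth
applied forward and backward, so the filter is zero-phase; the filter
family is our choice -- only the band is prescribed by the method) and
cut into 40 ms frames with a 20 ms step, each frame mean-subtracted.
Thirty features per frame form the default registry: 12 MFCCs (26
triangular mel filters over 0--fs/2, log floor `1e-10`, DCT-II, c0
excluded so the cepstral features are gain-invariant), 10 LPC
coefficients (autocorrelation method, Levinson--Durbin, convention
`A(z) = 1 + sum a_i z^-i`), RMS energy, zero-crossing rate,
high-frequency power above 15 kHz from an analytic Morlet continuous
wavelet transform (12 voices/octave), the harmonic feature (peak of the
lag-0-normalised autocorrelation over lags corresponding to 500--600 Hz),
spectral entropy, time-domain skewness and kurtosis (non-excess,
`m4/m2^2`), and spectral centroid. The exact identity of the original
method's 30 features is not public; this registry covers the 29 named
feature families and completes the set with the spectral centroid, and it
is configurable so any other list can be substituted.

Classification is quadratic discriminant analysis: each class
(1 noise, 2 exhalation, 3 inhalation, 4 actuation) is a Gaussian with its
own mean, covariance and prior (class frame frequency in training). The
covariance gets a ridge `lambda * trace(Sigma)/d * I` (`lambda = 1e-6`)
so collinear features never break the Cholesky factorisation. Scores are
evaluated in the log domain; this is a correctness contract, not an
approximation -- the labels equal the direct density argmax wherever the
densities do not underflow, and the test suite checks this against
brute-force enumeration and against an independent QDA implementation.

Testing a recording runs four steps:

1. **Noise estimation.** The noise-class mean and covariance are
   re-estimated from the frames in the lowest 40% of RMS energy of *this*
   recording (backgrounds differ between clinics). Trained priors are
   kept -- the method only states that noise is re-estimated, and
   re-weighting priors per recording would let a noisy recording silence
   the event classes. Recordings shorter than 13 frames skip this step.
2. **Model adaptation.** Reeds differ across devices, so the inhalation
   mean moves to the unweighted average of the trained mean and the
   centroid of frames that a nearest-mean (Euclidean) pass labels as
   inhalation. Applied once; applying it again would halve the remaining
   gap again (documented non-idempotence).
3. **QDA classification** of every frame, ties to the lowest class id.
4. **Event formation.** An order-5 median filter smooths the label
   sequence (edges replicated), then maximal same-class runs become
   events. Inhalation and exhalation events need at least 5 frames
   (100 ms); actuations are kept at any length, since real actuations can
   be only a few frames long.

## Feature selection

Sequential forward selection greedily adds the feature that maximises the
weighted event-level measure
`J = 0.2 (S_A + P_A) + 0.2 (S_I + P_I) + 0.1 (S_E + P_E)` of the full
pipeline on validation recordings (S, P = sensitivity and positive
predictive value in percent). We score J at the event level rather than
the frame level because its constituent quantities are event metrics;
selection stops when the best improvement is below 0.01 points, and the
full trajectory is recorded so the selection curve can be inspected. The
default 11-feature working subset (`selected_feature_names()`) spans
loudness, harmonicity, spectral shape and high-frequency transient
content; energy and HF power are included because an actuation burst and
background noise share a flat spectrum and differ chiefly in level and
bandwidth.

## Stage 2: flow estimation from the reed sound

Inhalation audio is decimated by 4 (anti-aliased), band-passed
200--5000 Hz and framed at 50/25 ms. The reed fundamental is estimated
once per segment by autocorrelation restricted to 520--570 Hz with
parabolic peak interpolation; if the normalised peak is below 0.2 the
segment is flagged as having no reed sound. Per frame we compute the RMS
energy E and Welch-PSD band powers `P_f0` (fundamental +/- 30 Hz) and
`P_f0f1` (adding the first harmonic band); higher harmonics are excluded
so broadband actuation energy cannot leak in. Flow is mapped through a
power law, `ln f = gamma ln Phi + delta`, with the fitted default
`gamma = 0.3183`, `delta = 7.5061` on `Phi = P_f0f1` (flow in L/min).
The logarithm is natural: with base-10 these coefficients imply
physically absurd flows (far above 10^5 L/min) for plausible band powers,
while natural logs give 40--200 L/min.

PIFR is the model applied at the frame of maximum `P_f0` -- that frame is
robust to actuations, unlike the maximum-energy frame. The flow profile
applies the model to every frame, zeroing frames whose `P_f0f1` is below
1% of the segment maximum (and below an absolute `1e-12` floor), because
a log-domain model extrapolates wildly on silence. Volume is the
trapezoidal integral of the profile divided by 60 (L/min to L/s).
Estimation accuracy is reported as `100 (1 - |est - ref| / ref)`, floored
at 0 -- read literally, the printed formula would score a zero estimate
at 99%, so we interpret it as percentage relative error subtracted
from 100.

Numerical choices the method description leaves open, fixed here: Welch
segments of 256 samples with 50% overlap and Hanning taper (47 Hz
resolution at 12 kHz); band integration widened by one bin on each side
of +/- 30 Hz so a tone's Hanning main lobe is captured (otherwise a
bin-centred tone loses a third of its power and band power would not
approximate A^2/2); flow frames left unwindowed because Welch applies its
own taper and windowing twice biases band power roughly 35% low.

## Stage 3: technique findings and agreement

Coordination is good when at least one detected actuation *starts* inside
a detected inhalation event (onset and end inclusive, so an actuation
that split the breath into two runs still counts); the method never
formalises this computationally, so the rule follows the device
checklist -- generate the tone, then actuate -- and a midpoint variant is
available. "Too fast" is strictly `PIFR > 90` L/min. Event-level
sensitivity/PPV use one-to-one greedy overlap matching; Cohen's kappa
(`(p_o - p_e)/(1 - p_e)`, marginal-product expectation) and Bland--Altman
bias and limits of agreement quantify rater agreement; cohort summaries
report the percentage of subjects with at least one flagged recording per
phase.

## The synthetic-data generator

Real patient recordings are not public, so the generator is the package's
test bed. It emulates:

* **Inhalation**: tone at `f0` and `2 f0` (75/25 power split,
  configurable) whose total band power inverts the default power law for
  the programmed flow, gated on flow >= 45 L/min (the midpoint of the
  30--60 L/min reed-onset range), plus 300--2500 Hz turbulence with RMS
  proportional to the tone scale (factor 0.3). Profiles are trapezoids
  (0.25 s rise, 0.3 s fall) by default.
* **Actuation**: a white-noise burst (RMS 0.025, raised-cosine ramps) --
  the same spectral surrogate the method itself uses for actuations. In
  good-technique scenarios it fires 0.1 s after the reed-onset crossing,
  matching the checklist ordering and keeping the max-`P_f0` frame on the
  clean plateau; in poor-technique scenarios it fires 0.5 s before the
  breath.
* **Exhalation**: low-pass (< 1 kHz) noise under a half-sine envelope.
* **Background**: white noise at a controlled SNR measured over the full
  clean mixture (default 20 dB).

Corpora draw PIFR stratified over the four clinical ranges (&lt;60,
60--120, 120--180, 180--240 L/min), with the lowest range bounded below
by the reed threshold so every inhalation is acoustically observable --
the device's design premise. Each recording carries a label track (the
actuation entry may overlap the inhalation entry; per-frame labels
resolve the overlap with a later-event-wins midpoint rule) and the exact
programmed flow, so volume ground truth is exact.

What the generator does *not* emulate -- and what passing tests therefore
do not demonstrate about clinical data: room reverberation, non-white
clinical background noise, reed-pitch drift within a breath, actuation
plume decay structure, patient movement, or lips-off-mouthpiece
recordings. Event-detection scores on this corpus are an artifact-level
analogue of the published patient-data figures, not a reproduction.

## Problem sizes used in the checks

The end-to-end checks train on a 12-recording corpus and score a
40-recording corpus at 20 dB SNR (event sensitivity/PPV and median PIFR
round-trip accuracy), and the SNR robustness sweep runs 6 validation
inhalations across -10..25 dB in 5 dB steps against models fitted on 8
design inhalations. These sizes give stable metrics on the synthetic
conditions while keeping the full suite fast.

## Known limitations

* Exhalation detection inherits the method's weakness: exhalations are
  quiet, low-frequency and easily confused with noise; the weighted
  measure down-weights them accordingly.
* Volume is integrated only over acoustically observable flow; the
  sub-threshold tails of a breath contribute no tone, so volume is
  biased slightly low at low PIFR.
* The 30-feature and 11-feature registries are documented stand-ins for
  the original (non-public) lists; both are configurable.
* Flow estimation assumes exactly one Flo-Tone reed; recordings without
  the mouthpiece yield a "no reed sound" flag rather than a flow.

## A minimal end-to-end run

```{r, eval = FALSE}
corpus <- make_corpus(12, master_seed = 101)
prep <- function(rec) {
  fm <- frame_signal(bandpass(rec$sig, 140, 22000), 0.04, 0.02)
  list(features = extract_features(fm),
       labels = labels_to_frames(rec$labels, fm))
}
tr <- lapply(corpus$recordings, prep)
sel <- selected_feature_names()
X <- do.call(rbind, lapply(tr, function(r)
  subset_features(r$features, sel)$values))
fmx <- structure(list(values = X, names = sel,
                      frame_times = seq_len(nrow(X))),
                 class = "feature_matrix")
models <- train_event_models(fmx, unlist(lapply(tr, `[[`, "labels")))

rec <- synth_recording(synth_scenario(pifr = 150, seed = 42))
assess_recording(rec$sig, models)
```
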