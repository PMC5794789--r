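# flotone

Audio-based, objective assessment of how patients use a pressurised
metered dose inhaler (pMDI). Many patients make one of two critical
user-technique errors — releasing the dose outside the breath (poor
actuation coordination) or inhaling too fast (peak inspiratory flow rate,
PIFR, above 90 L/min) — and neither is reliable to judge by ear or
checklist. With a Flo-Tone training mouthpiece on the inhaler, the
inhalation produces a harmonic reed tone (fundamental ≈ 540 Hz) whose
power grows with flow, which makes both errors measurable from a plain
mono audio recording.

The package is aimed at respiratory digital-health researchers and
provides the full pipeline:

* **Sound-event classification.** 40 ms frames (20 ms step, band-passed
  140–22,000 Hz) are described by 30 audio features (12 MFCCs, 10 LPC
  coefficients, energy, zero-crossing rate, CWT high-frequency power,
  the 500–600 Hz harmonic feature, spectral entropy, skewness, kurtosis,
  centroid) and classified as noise / exhalation / inhalation / actuation
  by quadratic discriminant analysis,

  ω\* = argmax_ω  N(x; μ_ω, Σ_ω) · P(ω),

  evaluated in the log domain, after per-recording noise estimation
  (noise model refit on the lowest-40%-energy frames) and inhalation
  model adaptation (mean averaged with the recording's nearest-mean
  inhalation centroid). An order-5 median filter and a 5-frame (100 ms)
  minimum-duration rule turn frame labels into events.
* **Feature selection.** Sequential forward selection under the weighted
  event measure J = 0.2(S^A+P^A) + 0.2(S^I+P^I) + 0.1(S^E+P^E).
* **Flow estimation.** From the detected inhalation audio (decimated to
  12 kHz, band-passed 200–5000 Hz, 50/25 ms frames), the reed
  fundamental is found by autocorrelation (520–570 Hz) and the Welch-PSD
  band power of the fundamental plus first harmonic drives the fitted
  power law ln f̂ = 0.3183 · ln P_f0f1 + 7.5061 (f̂ in L/min). PIFR is
  the flow at the max-P_f0 frame; volume is the trapezoidal integral of
  the per-frame flow profile.
* **Technique findings.** Actuation-onset-inside-inhalation coordination
  rule, strict PIFR > 90 L/min speed rule, event-level
  sensitivity/PPV, Cohen's kappa and Bland–Altman agreement, cohort
  prevalence summaries.
* **Synthetic data.** A seeded generator of labelled recordings with
  known flow profiles (reed tone + turbulence, white actuation bursts,
  low-pass exhalations, background noise at controlled SNR), so every
  stage is testable without patient data.

## Worked example

Train a classifier on a synthetic corpus and assess a new recording whose
programmed truth is PIFR 150 L/min, 4.31 L, good coordination:

```r
library(flotone)

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
classify_recording(rec$sig, models)$events
#>   class start_s end_s n_frames
#> 1     2    0.78  2.02       61
#> 2     3    2.64  2.78        6
#> 3     4    2.76  2.94        8
#> 4     3    2.92  4.54       80

assess_recording(rec$sig, models)
#> <technique_report> synthetic-42
#>   events: 4 | PIFR: 159.1 L/min | volume: 4.28 L
#>   poor coordination: FALSE | too fast (>90 L/min): TRUE
```

Reading the output: the recording contains an exhalation (class 2,
0.78–2.02 s), then an inhalation (class 3) split in two by the actuation
(class 4) fired inside it — good coordination. The estimated PIFR of
159.1 L/min (truth: 150) exceeds 90 L/min, so the "inhaling too fast"
critical error is correctly flagged; the estimated inhaled volume is
4.28 L against a programmed 4.31 L.

A thin command-line wrapper with `synth`, `train`, `classify`, `assess`
and `kappa` subcommands is installed at `inst/cli/flotone`.

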