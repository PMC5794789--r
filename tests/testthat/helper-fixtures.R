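# Shared fixtures: deterministic audio snippets and a lazily-built
# classifier corpus reused across test files.

tone_signal <- function(freq, fs = 48000, dur = 1, amp = 1) {
  audio_signal(amp * sin(2 * pi * freq * (0:(fs * dur - 1)) / fs), fs)
}

white_noise_signal <- function(fs = 48000, dur = 1, sd = 1, seed = 1) {
  set.seed(seed)
  audio_signal(rnorm(fs * dur, 0, sd), fs)
}

# band-pass + frame + features + frame labels for one synthetic recording
prep_recording <- function(rec, registry = default_registry()) {
  bp <- bandpass(rec$sig, 140, 22000)
  fm <- frame_signal(bp, 0.04, 0.02)
  list(features = extract_features(fm, registry),
       labels = labels_to_frames(rec$labels, fm),
       energy = rms_energy(fm))
}

train_models_on <- function(prepped, feature_names = selected_feature_names()) {
  X <- do.call(rbind, lapply(prepped, function(r)
    subset_features(r$features, feature_names)$values))
  labs <- unlist(lapply(prepped, `[[`, "labels"))
  fmx <- structure(list(values = X, names = feature_names,
                        frame_times = seq_len(nrow(X))),
                   class = "feature_matrix")
  train_event_models(fmx, labs)
}

# corpus + trained models built once per test run (classification tests
# and the end-to-end acceptance checks share them)
.fixture_env <- new.env(parent = emptyenv())

get_trained_models <- function() {
  if (is.null(.fixture_env$models)) {
    train_c <- make_corpus(12, master_seed = 101)
    prepped <- lapply(train_c$recordings, prep_recording)
    .fixture_env$models <- train_models_on(prepped)
  }
  .fixture_env$models
}

# score predictions against truth labels; truth events use the same
# minimum-duration convention as the detector
score_corpus <- function(corpus, models) {
  agg <- flotone:::new_metric_accumulator()
  for (rec in corpus$recordings) {
    out <- classify_recording(rec$sig, models)
    fm <- frame_signal(bandpass(rec$sig, 140, 22000), 0.04, 0.02)
    truth_lab <- labels_to_frames(rec$labels, fm)
    truth_ev <- form_events(truth_lab, min_frames = 5L)
    agg <- flotone:::accumulate_event_metrics(agg, out$events, truth_ev,
                                              out$labels, truth_lab)
  }
  flotone:::finalize_event_metrics(agg)
}

# small clean inhalation set for flow-model fitting and SNR sweeps
make_inhalation_set <- function(pifrs, f0 = 540, seed0 = 300) {
  lapply(seq_along(pifrs), function(i) {
    prof <- flow_profile(pifrs[i], 2.0)
    inh <- synth_inhalation(prof, f0 = f0, fs = 48000, seed = seed0 + i)
    list(sig = inh$sig, pifr = pifrs[i], volume = prof$volume)
  })
}

fit_feature_models <- function(design_set) {
  phim <- t(vapply(design_set, function(r) {
    ff <- extract_flow_features(r$sig)
    i <- which.max(ff$P_f0)
    c(E = ff$E[i], P_f0 = ff$P_f0[i], P_f0f1 = ff$P_f0f1[i])
  }, numeric(3)))
  pifrs <- vapply(design_set, `[[`, 0, "pifr")
  list(E = fit_flow_model(phim[, "E"], pifrs, "power", feature = "E"),
       P_f0 = fit_flow_model(phim[, "P_f0"], pifrs, "power",
                             feature = "P_f0"),
       P_f0f1 = fit_flow_model(phim[, "P_f0f1"], pifrs, "power",
                               feature = "P_f0f1"))
}
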