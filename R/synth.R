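# Seeded synthetic pMDI + Flo-Tone recording generator.
#
# Emulates the four sound classes: a harmonic reed tone (fundamental plus
# first harmonic, power tied to instantaneous flow by the inverse of the
# fitted power law) gated on a reed-onset flow threshold, with
# flow-proportional turbulence; white-noise actuation bursts; low-pass
# exhalation noise; and white background noise at a controlled SNR. Every
# generated recording carries its label track and exact programmed flow
# profile, so both classification and flow estimation can be scored
# against known truth.

#' Programmed inspiratory flow profile
#'
#' Trapezoid (linear rise to the peak, plateau, linear fall; default) or
#' half-sine, sampled on a dense grid.
#'
#' @param pifr peak inspiratory flow rate in L/min.
#' @param duration_s inhalation duration in seconds.
#' @param shape `"trapezoid"` or `"halfsine"`.
#' @param rise_s,fall_s trapezoid ramp durations (s).
#' @param dt sampling interval of the returned profile (s).
#' @return list with `times` (s, starting at 0), `flows` (L/min),
#'   `pifr`, `volume` (L, trapezoidal integral of the profile).
#' @export
flow_profile <- function(pifr, duration_s, shape = c("trapezoid",
                                                     "halfsine"),
                         rise_s = 0.25, fall_s = 0.3, dt = 0.001) {
  shape <- match.arg(shape)
  t <- seq(0, duration_s, by = dt)
  f <- if (shape == "halfsine") {
    pifr * sin(pi * t / duration_s)
  } else {
    rise_s <- min(rise_s, duration_s / 3)
    fall_s <- min(fall_s, duration_s / 3)
    pmin(pifr,
         pmin(pifr * t / rise_s,
              pifr * (duration_s - t) / fall_s))
  }
  f <- pmax(0, f)
  list(times = t, flows = f, pifr = pifr,
       volume = pracma::trapz(t, f / 60))
}

# band power demanded by the power law at a given flow (L/min):
# inverse of ln f = gamma ln P + delta
flow_to_band_power <- function(flow, model = default_flow_model()) {
  g <- model$coef[["gamma"]]; d <- model$coef[["delta"]]
  ifelse(flow > 0, exp((log(pmax(flow, 1e-6)) - d) / g), 0)
}

#' Synthesise a Flo-Tone inhalation
#'
#' Harmonic tone at `f0` and `2*f0` (75/25 power split) whose total band
#' power follows the power law's inverse for the programmed flow,
#' present only while the flow is at or above the reed-onset threshold,
#' plus flow-proportional band-limited turbulence. Deterministic for a
#' fixed seed.
#'
#' @param profile a [flow_profile()] result.
#' @param f0 reed fundamental in Hz.
#' @param fs sample rate in Hz.
#' @param seed RNG seed.
#' @param reed_threshold flow (L/min) at which the reed starts sounding.
#' @param harmonic_split fraction of harmonic power at the fundamental.
#' @param turb_gain turbulence RMS as a fraction of the tone RMS scale.
#' @return list with `sig` ([audio_signal]), `profile` (the programmed
#'   truth), `f0`.
#' @export
synth_inhalation <- function(profile, f0 = 540, fs = 48000, seed = 1L,
                             reed_threshold = 45, harmonic_split = 0.75,
                             turb_gain = 0.3) {
  set.seed(seed)
  n <- round(max(profile$times) * fs) + 1L
  t <- (seq_len(n) - 1L) / fs
  f_t <- stats::approx(profile$times, profile$flows, xout = t,
                       rule = 2)$y
  P <- flow_to_band_power(f_t)             # total tone band power target
  gate <- f_t >= reed_threshold
  a0 <- sqrt(2 * harmonic_split * P) * gate
  a1 <- sqrt(2 * (1 - harmonic_split) * P) * gate
  ph0 <- stats::runif(1, 0, 2 * pi)
  ph1 <- stats::runif(1, 0, 2 * pi)
  tone <- a0 * sin(2 * pi * f0 * t + ph0) +
    a1 * sin(2 * pi * 2 * f0 * t + ph1)
  # breath turbulence: band-limited noise scaled with the (ungated) flow
  turb <- stats::rnorm(n)
  bf <- signal::butter(4, c(300, 2500) / (fs / 2), type = "pass")
  turb <- signal::filtfilt(bf, turb)
  turb <- turb / max(stats::sd(turb), 1e-12)
  turb <- turb * turb_gain * sqrt(2 * P)
  list(sig = audio_signal(tone + turb, fs, "synthetic-inhalation"),
       profile = profile, f0 = f0)
}

#' Synthesise an actuation burst
#'
#' White Gaussian noise (the spectral surrogate for the broadband plume
#' hiss of a pMDI actuation) with raised-cosine on/offset ramps.
#'
#' @param duration_s burst duration, 0.05-0.5 s.
#' @param fs sample rate in Hz.
#' @param seed RNG seed.
#' @param amplitude RMS amplitude of the burst body.
#' @param ramp_s raised-cosine ramp duration (s).
#' @return an [audio_signal].
#' @export
synth_actuation <- function(duration_s = 0.2, fs = 48000, seed = 1L,
                            amplitude = 0.025, ramp_s = 0.01) {
  if (duration_s < 0.05 || duration_s > 0.5) {
    stop("actuation duration must be 0.05-0.5 s")
  }
  set.seed(seed)
  n <- round(duration_s * fs)
  x <- stats::rnorm(n, 0, amplitude)
  nr <- min(round(ramp_s * fs), n %/% 2)
  if (nr > 0L) {
    ramp <- 0.5 - 0.5 * cos(pi * seq_len(nr) / nr)
    x[seq_len(nr)] <- x[seq_len(nr)] * ramp
    x[(n - nr + 1L):n] <- x[(n - nr + 1L):n] * rev(ramp)
  }
  audio_signal(x, fs, "synthetic-actuation")
}

#' Synthesise an exhalation
#'
#' Low-pass (< 1 kHz) filtered noise under a slow half-sine amplitude
#' envelope.
#'
#' @param duration_s exhalation duration in seconds.
#' @param fs sample rate in Hz.
#' @param seed RNG seed.
#' @param amplitude peak RMS amplitude.
#' @return an [audio_signal].
#' @export
synth_exhalation <- function(duration_s = 1.2, fs = 48000, seed = 1L,
                             amplitude = 0.04) {
  set.seed(seed)
  n <- round(duration_s * fs)
  x <- stats::rnorm(n)
  bf <- signal::butter(4, 900 / (fs / 2), type = "low")
  x <- signal::filtfilt(bf, x)
  x <- x / max(stats::sd(x), 1e-12)
  env <- sin(pi * seq_len(n) / n)
  audio_signal(x * env * amplitude, fs, "synthetic-exhalation")
}

#' Scenario for one synthetic recording
#'
#' Default schedule (good technique): background, exhalation, pause,
#' inhalation with an actuation early in the breath, tail. With
#' `coordination = "poor"` the actuation fires 0.5 s before the
#' inhalation begins.
#'
#' @param pifr peak inspiratory flow rate (L/min), 20-240.
#' @param snr_db background-noise SNR in dB (signal power measured over
#'   the full clean mixture).
#' @param seed RNG seed.
#' @param f0 reed fundamental in Hz (520-570).
#' @param fs sample rate in Hz.
#' @param reed_threshold reed-onset flow (L/min), 30-60.
#' @param coordination `"good"` or `"poor"`.
#' @param inhale_duration_s inhalation length (s).
#' @param actuation_offset_s actuation onset relative to the reed-onset
#'   time (the moment the flow first reaches `reed_threshold`); good
#'   technique releases the dose after the tone starts.
#' @return a list of class `synth_scenario`.
#' @export
synth_scenario <- function(pifr = 90, snr_db = 20, seed = 1L, f0 = 540,
                           fs = 48000, reed_threshold = 45,
                           coordination = c("good", "poor"),
                           inhale_duration_s = 2.0,
                           actuation_offset_s = 0.1) {
  coordination <- match.arg(coordination)
  stopifnot(f0 >= 520, f0 <= 570, reed_threshold >= 30,
            reed_threshold <= 60, pifr >= 20, pifr <= 240)
  exhale_start <- 0.8
  exhale_dur <- 1.2
  inhale_start <- 2.6
  act_dur <- 0.15
  rise_s <- min(0.25, inhale_duration_s / 3)
  t_reed <- rise_s * min(1, reed_threshold / pifr)
  act_start <- if (coordination == "good")
    inhale_start + t_reed + actuation_offset_s else inhale_start - 0.5
  structure(list(
    fs = fs, f0 = f0, reed_threshold = reed_threshold, snr_db = snr_db,
    seed = as.integer(seed), pifr = pifr, coordination = coordination,
    exhale_start = exhale_start, exhale_dur = exhale_dur,
    inhale_start = inhale_start, inhale_dur = inhale_duration_s,
    act_start = act_start, act_dur = act_dur,
    total_s = inhale_start + inhale_duration_s + 0.6
  ), class = "synth_scenario")
}

#' Synthesise a full labelled recording
#'
#' Mixes exhalation, inhalation and actuation components on a timeline,
#' adds white background noise at the scenario's SNR, and returns the
#' audio together with its label track and the programmed flow truth.
#'
#' @param scenario a [synth_scenario()].
#' @return list with `sig` ([audio_signal]), `labels` ([label_track]),
#'   `truth` (list: `pifr`, `volume`, `flow_times`, `flows`, `f0`),
#'   `scenario`.
#' @export
synth_recording <- function(scenario) {
  stopifnot(inherits(scenario, "synth_scenario"))
  sc <- scenario
  if (sc$act_start < 0) stop("invalid schedule: actuation before t = 0")
  fs <- sc$fs
  n <- round(sc$total_s * fs)
  x <- numeric(n)
  place <- function(x, seg, at_s) {
    i0 <- round(at_s * fs) + 1L
    i1 <- min(n, i0 + length(seg) - 1L)
    x[i0:i1] <- x[i0:i1] + seg[seq_len(i1 - i0 + 1L)]
    x
  }
  exh <- synth_exhalation(sc$exhale_dur, fs, seed = sc$seed * 11L + 1L)
  x <- place(x, exh$samples, sc$exhale_start)
  prof <- flow_profile(sc$pifr, sc$inhale_dur)
  inh <- synth_inhalation(prof, f0 = sc$f0, fs = fs,
                          seed = sc$seed * 11L + 2L,
                          reed_threshold = sc$reed_threshold)
  x <- place(x, inh$sig$samples, sc$inhale_start)
  act <- synth_actuation(sc$act_dur, fs, seed = sc$seed * 11L + 3L)
  x <- place(x, act$samples, sc$act_start)
  # background noise at the requested SNR over the full mixture support
  p_sig <- mean(x^2)
  set.seed(sc$seed * 11L + 4L)
  noise <- stats::rnorm(n, 0, sqrt(p_sig / 10^(sc$snr_db / 10)))
  sig <- audio_signal(x + noise, fs,
                      sprintf("synthetic-%d", sc$seed))
  labels <- label_track(data.frame(
    start_s = c(sc$exhale_start, sc$inhale_start, sc$act_start),
    end_s = c(sc$exhale_start + sc$exhale_dur,
              sc$inhale_start + sc$inhale_dur,
              sc$act_start + sc$act_dur),
    class = c(CLASS_EXHALATION, CLASS_INHALATION, CLASS_ACTUATION)))
  truth <- list(pifr = prof$pifr, volume = prof$volume,
                flow_times = prof$times + sc$inhale_start,
                flows = prof$flows, f0 = sc$f0)
  list(sig = sig, labels = labels, truth = truth, scenario = sc)
}

#' Generate a reproducible corpus of synthetic recordings
#'
#' Draws PIFRs stratified over the four clinical flow ranges (the lowest
#' bounded below by the reed threshold so every inhalation is
#' acoustically observable), a per-device reed fundamental in 520-570
#' Hz, and a per-recording seed, all derived from `master_seed`. With a
#' directory, writes `rec_<i>.wav`, `rec_<i>_labels.csv` and
#' `rec_<i>_truth.json` per recording plus `manifest.csv`; otherwise the
#' recordings are returned in memory.
#'
#' @param n_recordings number of recordings (>= 1).
#' @param master_seed corpus seed.
#' @param dir output directory (created); `NULL` for in-memory.
#' @param snr_db background SNR in dB.
#' @param prop_poor_coordination fraction of recordings generated with
#'   the actuation before the inhalation.
#' @param reed_threshold reed-onset flow in L/min.
#' @return list with `recordings` (list as from [synth_recording()];
#'   `NULL` entries when written to disk) and `manifest` (data.frame).
#' @export
make_corpus <- function(n_recordings, master_seed = 1L, dir = NULL,
                        snr_db = 20, prop_poor_coordination = 0,
                        reed_threshold = 45) {
  stopifnot(n_recordings >= 1L)
  set.seed(master_seed)
  ranges <- list(c(reed_threshold, 60), c(60, 120), c(120, 180),
                 c(180, 240))
  strata <- rep(seq_along(ranges), length.out = n_recordings)
  pifrs <- vapply(strata, function(s)
    stats::runif(1, ranges[[s]][1L], ranges[[s]][2L]), numeric(1))
  f0s <- stats::runif(n_recordings, 520, 570)
  seeds <- sample.int(2^20, n_recordings)
  poor <- seq_len(n_recordings) <= round(prop_poor_coordination *
                                           n_recordings)
  recs <- vector("list", n_recordings)
  manifest <- data.frame(id = sprintf("rec_%03d", seq_len(n_recordings)),
                         pifr = pifrs, f0 = f0s, seed = seeds,
                         snr_db = snr_db,
                         coordination = ifelse(poor, "poor", "good"),
                         volume = NA_real_)
  if (!is.null(dir)) dir.create(dir, showWarnings = FALSE,
                                recursive = TRUE)
  for (i in seq_len(n_recordings)) {
    sc <- synth_scenario(pifr = pifrs[i], snr_db = snr_db,
                         seed = seeds[i], f0 = f0s[i],
                         reed_threshold = reed_threshold,
                         coordination = ifelse(poor[i], "poor", "good"))
    rec <- synth_recording(sc)
    manifest$volume[i] <- rec$truth$volume
    if (is.null(dir)) {
      recs[[i]] <- rec
    } else {
      base <- file.path(dir, manifest$id[i])
      write_wav(rec$sig, paste0(base, ".wav"))
      write_labels(rec$labels, paste0(base, "_labels.csv"))
      jsonlite::write_json(rec$truth, paste0(base, "_truth.json"),
                           digits = NA, auto_unbox = TRUE)
    }
  }
  if (!is.null(dir)) {
    utils::write.csv(manifest, file.path(dir, "manifest.csv"),
                     row.names = FALSE)
  }
  list(recordings = recs, manifest = manifest)
}
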