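# Acoustic estimation of inspiratory flow from the Flo-Tone reed sound.
#
# The reed emits a harmonic tone (fundamental ~520-570 Hz) whose power
# grows with inspiratory flow. Per 50 ms frame, three features are
# extracted: RMS energy E, band power at the fundamental (P_f0) and the
# total power of the fundamental plus first harmonic (P_f0f1). Flow is
# mapped from a feature by a linear or power-law model; the fitted
# power-law default is ln(f) = 0.3183 ln(P_f0f1) + 7.5061 (flow in
# L/min). PIFR is the flow at the max-P_f0 frame, volume the trapezoidal
# integral of the flow profile.

#' Pre-process audio for flow estimation
#'
#' Decimates by 4 (anti-aliased), band-pass filters 200-5000 Hz and cuts
#' Hanning-windowed 50 ms frames with a 25 ms step (DC removed). At the
#' nominal 48 kHz input this yields 12 kHz frames of 600 samples. Sample
#' rates not divisible by 4 are first resampled to the nearest multiple.
#'
#' @param sig an [audio_signal].
#' @param band band-pass edges in Hz.
#' @param frame_len_s,step_s framing parameters (s).
#' @return a `frame_matrix` at `fs/4`.
#' @export
preprocess_flow <- function(sig, band = c(200, 5000),
                            frame_len_s = 0.05, step_s = 0.025) {
  bp <- flow_preprocess_signal(sig, band, frame_len_s)
  frame_signal(bp, frame_len_s, step_s, remove_dc = TRUE,
               window = "hanning")
}

# decimate by 4 (anti-aliased) and band-pass; shared by framing and pitch
flow_preprocess_signal <- function(sig, band = c(200, 5000),
                                   frame_len_s = 0.05) {
  stopifnot(inherits(sig, "audio_signal"))
  if (length(sig$samples) < frame_len_s * sig$fs) {
    stop("signal shorter than one flow-analysis frame")
  }
  fs <- sig$fs
  x <- sig$samples
  if (fs %% 4 != 0) {
    fs_new <- round(fs / 4) * 4
    x <- signal::resample(x, fs_new, fs)
    fs <- fs_new
  }
  y <- signal::decimate(x, 4L)
  dec <- audio_signal(y, fs / 4, sig$source_id)
  hi <- min(band[2L], 0.45 * dec$fs)
  bandpass(dec, band[1L], hi)
}

#' Estimate the reed fundamental frequency
#'
#' Autocorrelation pitch estimate restricted to the Flo-Tone range
#' (520-570 Hz by default) with parabolic sub-sample interpolation of
#' the peak lag. When the normalised autocorrelation peak is below
#' `min_peak` no reed sound is assumed present.
#'
#' @param sig an [audio_signal] of (candidate) inhalation audio, at
#'   least 100 ms long.
#' @param f_range searched fundamental range in Hz.
#' @param min_peak detection threshold on the normalised autocorrelation.
#' @return list with `f0` (Hz, `NA` when undetected), `peak` (normalised
#'   autocorrelation value) and `reed_detected` (logical).
#' @export
estimate_f0 <- function(sig, f_range = c(520, 570), min_peak = 0.2) {
  stopifnot(inherits(sig, "audio_signal"))
  x <- sig$samples
  fs <- sig$fs
  if (length(x) < 0.1 * fs) stop("segment shorter than 100 ms")
  x <- x - mean(x)
  nfft <- stats::nextn(2L * length(x), 2L)
  R <- Re(stats::fft(Mod(stats::fft(c(x, numeric(nfft - length(x)))))^2,
                     inverse = TRUE)) / nfft
  r0 <- R[1L]
  if (r0 <= 0) return(list(f0 = NA_real_, peak = 0, reed_detected = FALSE))
  lag_lo <- max(2L, floor(fs / f_range[2L]))
  lag_hi <- ceiling(fs / f_range[1L])
  rs <- R[(lag_lo:lag_hi) + 1L] / r0
  i <- which.max(rs)
  peak <- rs[i]
  if (peak < min_peak) {
    return(list(f0 = NA_real_, peak = peak, reed_detected = FALSE))
  }
  lag <- lag_lo + i - 1L
  # parabolic interpolation over the three lags around the peak
  ym <- R[lag] / r0; y0 <- R[lag + 1L] / r0; yp <- R[lag + 2L] / r0
  denom <- ym - 2 * y0 + yp
  shift <- if (abs(denom) > 1e-12) 0.5 * (ym - yp) / denom else 0
  shift <- max(min(shift, 0.5), -0.5)
  list(f0 = fs / (lag + shift), peak = peak, reed_detected = TRUE)
}

#' Welch power spectral density estimate
#'
#' Averaged modified periodogram with Hanning-windowed segments (default
#' 256 samples, 50% overlap), one-sided density normalisation so that
#' `sum(psd) * fs/nseg` equals the signal power.
#'
#' @param x numeric vector.
#' @param fs sample rate in Hz.
#' @param nseg segment length (reduced to the largest power of two that
#'   fits when `x` is shorter).
#' @param overlap fractional segment overlap.
#' @return list with `freq` (Hz) and `psd` (power per Hz).
#' @export
welch_psd <- function(x, fs, nseg = 256L, overlap = 0.5) {
  n <- length(x)
  if (n < nseg) nseg <- max(8L, 2^floor(log2(n)))
  w <- hanning_window(nseg)
  U <- sum(w^2)
  step <- max(1L, round(nseg * (1 - overlap)))
  starts <- seq(1L, n - nseg + 1L, by = step)
  acc <- numeric(nseg)
  for (s in starts) {
    acc <- acc + Mod(stats::fft(x[s:(s + nseg - 1L)] * w))^2
  }
  P <- acc / length(starts)
  half <- nseg %/% 2 + 1L
  psd <- P[seq_len(half)] / (fs * U)
  if (half > 2L) psd[2:(half - 1L)] <- 2 * psd[2:(half - 1L)]
  list(freq = (seq_len(half) - 1L) * fs / nseg, psd = psd)
}

# integrate a PSD over [f_center - half, f_center + half], widened by one
# bin on each side to capture Hanning main-lobe leakage
band_power <- function(pw, f_center, half = 30) {
  df <- pw$freq[2L] - pw$freq[1L]
  sel <- pw$freq >= f_center - half - df & pw$freq <= f_center + half + df
  sum(pw$psd[sel]) * df
}

#' Harmonic band powers of one frame
#'
#' Welch-PSD band power integrated over `f0 +/- 30 Hz` (`P_f0`) and the
#' same plus the first harmonic band `2 f0 +/- 30 Hz` (`P_f0f1`). Higher
#' harmonics are deliberately excluded so that broadband actuation energy
#' does not leak into the flow feature.
#'
#' @param frame numeric vector (one analysis frame).
#' @param fs sample rate in Hz.
#' @param f0 fundamental frequency in Hz.
#' @param half half-width of each integration band (Hz).
#' @param nseg Welch segment length.
#' @return named numeric vector `c(P_f0 = , P_f0f1 = )`.
#' @export
harmonic_powers <- function(frame, fs, f0, half = 30, nseg = 256L) {
  pw <- welch_psd(as.numeric(frame), fs, nseg = nseg)
  p0 <- band_power(pw, f0, half)
  p1 <- band_power(pw, 2 * f0, half)
  c(P_f0 = p0, P_f0f1 = p0 + p1)
}

#' Extract the per-frame flow features of an inhalation segment
#'
#' Runs [preprocess_flow()], estimates the reed fundamental from the
#' decimated band-passed audio, and computes E, P_f0 and P_f0f1 for
#' every frame. When no reed sound is detected the nominal mid-range
#' fundamental (`fallback_f0`) is used for the band positions and the
#' result is flagged.
#'
#' @param sig an [audio_signal] of inhalation audio.
#' @param f0 known fundamental in Hz; estimated when `NULL`.
#' @param fallback_f0 fundamental assumed when detection fails (Hz).
#' @return an object of class `flow_features`: `E`, `P_f0`, `P_f0f1`
#'   (per frame), `f0`, `reed_detected`, `frame_times` (s).
#' @export
extract_flow_features <- function(sig, f0 = NULL, fallback_f0 = 545) {
  bp <- flow_preprocess_signal(sig)
  # frames are left unwindowed here: the Welch estimator inside
  # harmonic_powers applies its own Hanning taper, and windowing twice
  # would bias the band powers (and hence the flow) low
  fm <- frame_signal(bp, 0.05, 0.025, remove_dc = TRUE, window = "none")
  reed <- TRUE
  if (is.null(f0)) {
    est <- estimate_f0(bp, min_peak = 0.2)
    reed <- est$reed_detected
    f0 <- if (reed) est$f0 else fallback_f0
  }
  E <- rms_energy(fm)
  hp <- t(apply(fm$frames, 1L, harmonic_powers, fs = fm$fs, f0 = f0))
  structure(list(E = E, P_f0 = hp[, "P_f0"], P_f0f1 = hp[, "P_f0f1"],
                 f0 = f0, reed_detected = reed,
                 frame_times = fm$start_times + fm$frame_len_s / 2),
            class = "flow_features")
}

#' Fit a feature-to-flow regression model
#'
#' Linear: `f = alpha * phi + beta`. Power law: ordinary least squares of
#' `ln f` on `ln phi` (natural logarithms), i.e.
#' `ln f = gamma * ln phi + delta`.
#'
#' @param phi feature values (strictly positive for the power model).
#' @param flow reference flows in L/min.
#' @param kind `"power"` or `"linear"`.
#' @param feature name of the feature the model maps (metadata).
#' @return an object of class `flow_model`: `kind`, `feature`, `coef`
#'   (`c(alpha, beta)` or `c(gamma, delta)`), `r2`.
#' @export
fit_flow_model <- function(phi, flow, kind = c("power", "linear"),
                           feature = "P_f0f1") {
  kind <- match.arg(kind)
  ok <- is.finite(phi) & is.finite(flow)
  phi <- phi[ok]; flow <- flow[ok]
  if (length(phi) < 3L) stop("at least 3 points required")
  if (kind == "power") {
    if (any(phi <= 0) || any(flow <= 0)) {
      stop("power-law fit requires strictly positive phi and flow")
    }
    fit <- stats::lm(log(flow) ~ log(phi))
    y <- log(flow)
    coefs <- c(gamma = unname(coef(fit)[2L]), delta = unname(coef(fit)[1L]))
  } else {
    fit <- stats::lm(flow ~ phi)
    y <- flow
    coefs <- c(alpha = unname(coef(fit)[2L]), beta = unname(coef(fit)[1L]))
  }
  ss_tot <- sum((y - mean(y))^2)
  r2 <- if (ss_tot > 0) 1 - sum(stats::residuals(fit)^2) / ss_tot else 1
  structure(list(kind = kind, feature = feature, coef = coefs, r2 = r2),
            class = "flow_model")
}

#' The default fitted power-law flow model
#'
#' `ln(f) = 0.3183 * ln(P_f0f1) + 7.5061` with flow in L/min; the model
#' fitted on the healthy-participant design recordings.
#'
#' @return a `flow_model`.
#' @export
default_flow_model <- function() {
  structure(list(kind = "power", feature = "P_f0f1",
                 coef = c(gamma = 0.3183, delta = 7.5061), r2 = NA_real_),
            class = "flow_model")
}

#' @export
print.flow_model <- function(x, ...) {
  cat(sprintf("<flow_model> %s on %s: %s = %.4f, %s = %.4f (R2 = %s)\n",
              x$kind, x$feature, names(x$coef)[1L], x$coef[1L],
              names(x$coef)[2L], x$coef[2L],
              ifelse(is.na(x$r2), "NA", sprintf("%.3f", x$r2))))
  invisible(x)
}

#' Map feature values to flow through a fitted model
#' @param model a `flow_model`.
#' @param phi feature values.
#' @return flows in L/min (0 where a power model gets `phi <= 0`).
#' @export
predict_flow <- function(model, phi) {
  stopifnot(inherits(model, "flow_model"))
  if (model$kind == "power") {
    out <- numeric(length(phi))
    pos <- is.finite(phi) & phi > 0
    out[pos] <- exp(model$coef[["gamma"]] * log(phi[pos]) +
                    model$coef[["delta"]])
    out
  } else {
    pmax(0, model$coef[["alpha"]] * phi + model$coef[["beta"]])
  }
}

#' Estimate the peak inspiratory flow rate
#'
#' The frame with maximum fundamental power (`P_f0`) is selected -- it is
#' robust to actuation sounds, unlike the maximum-energy frame -- and the
#' flow model is applied to that frame's value of the model's feature.
#'
#' @param features a `flow_features` object.
#' @param model a `flow_model` (default: [default_flow_model()]).
#' @return list with `pifr` (L/min, `NA` when no reed sound was found)
#'   and `measurable` (logical).
#' @export
estimate_pifr <- function(features, model = default_flow_model()) {
  stopifnot(inherits(features, "flow_features"))
  if (!features$reed_detected || all(features$P_f0 <= 0)) {
    return(list(pifr = NA_real_, measurable = FALSE))
  }
  i <- which.max(features$P_f0)
  phi <- features[[model$feature]][i]
  list(pifr = predict_flow(model, phi), measurable = TRUE)
}

#' Estimate the inhalation flow profile
#'
#' Applies the flow model to every frame. Frames whose `P_f0f1` is below
#' 1% of the segment maximum are set to 0 L/min: below that floor the
#' band power is background noise and a log-domain model would
#' extrapolate wildly.
#'
#' @inheritParams estimate_pifr
#' @param noise_floor_frac fraction of the maximum `P_f0f1` below which
#'   frames are zeroed.
#' @return an object of class `flow_profile`: `times` (s), `flows`
#'   (L/min), `pifr` (flow at the max-`P_f0` frame), `volume` (L).
#' @export
estimate_flow_profile <- function(features, model = default_flow_model(),
                                  noise_floor_frac = 0.01) {
  stopifnot(inherits(features, "flow_features"))
  phi <- features[[model$feature]]
  flows <- predict_flow(model, phi)
  mx <- max(features$P_f0f1)
  if (mx > 0) flows[features$P_f0f1 < noise_floor_frac * mx] <- 0
  flows[features$P_f0f1 < 1e-12] <- 0  # absolute silence floor
  pifr <- if (all(features$P_f0 <= 0)) 0 else
    flows[which.max(features$P_f0)]
  prof <- structure(list(times = features$frame_times, flows = flows,
                         pifr = pifr, volume = NA_real_),
                    class = "flow_profile")
  prof$volume <- estimate_volume(prof)
  prof
}

#' Inhaled volume from a flow profile
#'
#' Trapezoidal integration of the flow profile, converting L/min to L/s.
#'
#' @param profile a `flow_profile` (needs at least 2 frames).
#' @return volume in litres.
#' @export
estimate_volume <- function(profile) {
  stopifnot(inherits(profile, "flow_profile"))
  if (length(profile$times) < 2L) stop("at least 2 frames required")
  pracma::trapz(profile$times, profile$flows / 60)
}

#' Percentage estimation accuracy
#'
#' `100 * (1 - |estimate - reference| / reference)`, floored at 0 so an
#' estimate more than 100% off scores 0 rather than going negative.
#'
#' @param est estimate (same units as `ref`).
#' @param ref strictly positive reference value.
#' @return accuracy in percent.
#' @export
flow_accuracy <- function(est, ref) {
  if (any(ref <= 0)) stop("reference must be positive")
  pmax(0, 100 * (1 - abs(est - ref) / ref))
}

#' Add white Gaussian noise at a target SNR
#'
#' Noise power is scaled so that `10*log10(P_signal / P_noise)` equals
#' `snr_db`, with signal power measured over the full signal support.
#'
#' @param sig a non-silent [audio_signal].
#' @param snr_db target signal-to-noise ratio in dB.
#' @param seed RNG seed for reproducible noise.
#' @return the noisy [audio_signal].
#' @export
add_noise_snr <- function(sig, snr_db, seed = NULL) {
  stopifnot(inherits(sig, "audio_signal"))
  p_sig <- mean(sig$samples^2)
  if (p_sig <= 0) stop("cannot set an SNR against a silent signal")
  if (!is.null(seed)) set.seed(seed)
  p_noise <- p_sig / 10^(snr_db / 10)
  noise <- stats::rnorm(length(sig$samples), 0, sqrt(p_noise))
  audio_signal(sig$samples + noise, sig$fs, sig$source_id)
}

#' SNR robustness sweep of the flow estimators
#'
#' For every SNR in `snr_grid` and every feature in `features`, adds
#' seeded white noise to each inhalation recording, re-runs the flow
#' pipeline and scores PIFR and volume accuracy against the programmed
#' ground truth.
#'
#' @param recordings list of inhalations, each a list with `sig`
#'   ([audio_signal]), `pifr` and `volume` (ground truth), and optionally
#'   `f0`.
#' @param models named list of `flow_model`s, one per feature (names
#'   from `features`).
#' @param snr_grid SNR levels in dB.
#' @param features which flow features to sweep.
#' @param seed master seed; each (recording, SNR) pair derives its own.
#' @return data.frame with columns `snr_db`, `feature`, `metric`
#'   (`"pifr"`/`"volume"`), `mean`, `se`.
#' @export
snr_sweep <- function(recordings, models, snr_grid = seq(-10, 25, by = 5),
                      features = c("E", "P_f0", "P_f0f1"), seed = 1L) {
  if (length(snr_grid) == 0L) {
    return(data.frame(snr_db = numeric(0), feature = character(0),
                      metric = character(0), mean = numeric(0),
                      se = numeric(0)))
  }
  rows <- list()
  for (snr in snr_grid) {
    acc <- list()
    for (i in seq_along(recordings)) {
      rec <- recordings[[i]]
      noisy <- add_noise_snr(rec$sig, snr,
                             seed = (seed * 1000L + i * 37L + round(snr)) %%
                               .Machine$integer.max)
      ff <- extract_flow_features(noisy)
      for (feat in features) {
        model <- models[[feat]]
        est_p <- estimate_pifr_feature(ff, model)
        prof <- estimate_flow_profile(ff, model)
        acc[[length(acc) + 1L]] <- data.frame(
          feature = feat,
          pifr = flow_accuracy(est_p, rec$pifr),
          volume = flow_accuracy(prof$volume, rec$volume))
      }
    }
    accd <- do.call(rbind, acc)
    for (feat in features) {
      sub <- accd[accd$feature == feat, ]
      for (metric in c("pifr", "volume")) {
        v <- sub[[metric]]
        rows[[length(rows) + 1L]] <- data.frame(
          snr_db = snr, feature = feat, metric = metric,
          mean = mean(v), se = stats::sd(v) / sqrt(length(v)))
      }
    }
  }
  do.call(rbind, rows)
}

# PIFR with an arbitrary feature model, always measurable (fallback f0 is
# used upstream); used by the sweep where low-SNR reed detection may fail
estimate_pifr_feature <- function(ff, model) {
  i <- which.max(ff$P_f0)
  predict_flow(model, ff[[model$feature]][i])
}

#' Bland-Altman agreement statistics
#'
#' Mean bias `mean(est - ref)` and 95% limits of agreement
#' `bias +/- 1.96 * sd(est - ref)`.
#'
#' @param est,ref paired measurements (equal length, n >= 2).
#' @return list with `bias`, `sd`, `loa` (lower, upper).
#' @export
bland_altman_stats <- function(est, ref) {
  if (length(est) != length(ref)) stop("paired samples required")
  if (length(est) < 2L) stop("need at least 2 pairs")
  d <- est - ref
  bias <- mean(d)
  s <- stats::sd(d)
  list(bias = bias, sd = s, loa = c(bias - 1.96 * s, bias + 1.96 * s))
}
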