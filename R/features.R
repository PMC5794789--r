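# Per-frame audio features for sound-event classification.
#
# The classifier uses 30 features per 40 ms frame: 12 MFCCs, 10 LPC
# coefficients, RMS energy, zero-crossing rate, continuous-wavelet
# high-frequency power (> 15 kHz), the Flo-Tone harmonic feature
# (autocorrelation peak in 500-600 Hz), spectral entropy, skewness,
# kurtosis and spectral centroid. Extractors accept a whole frame_matrix
# and are vectorised over frames where the arithmetic allows it.

LOG_FLOOR <- 1e-10

# one-sided power spectrum of every frame: n_frames x (nfft/2 + 1)
frame_power_spectra <- function(fr, nfft = NULL) {
  l <- ncol(fr)
  if (is.null(nfft)) nfft <- 2^ceiling(log2(l))
  X <- stats::mvfft(rbind(t(fr), matrix(0, nfft - l, nrow(fr))))
  P <- Mod(X[seq_len(nfft %/% 2 + 1L), , drop = FALSE])^2
  t(P)
}

#' Mel-frequency cepstral coefficients
#'
#' MFCCs 1-12 (the 0th, overall-gain coefficient is excluded) from a
#' 26-band triangular mel filterbank spanning 0 to `fs/2`, log-compressed
#' with floor `1e-10`, followed by a DCT-II. Because c0 is dropped the
#' coefficients are invariant to frame gain.
#'
#' @param frames a `frame_matrix`, or a numeric matrix of frames in rows.
#' @param fs sample rate in Hz (taken from `frames` when available).
#' @param n_coef number of cepstral coefficients kept (default 12).
#' @param n_mel number of mel filters (default 26).
#' @return numeric matrix, `n_frames x n_coef`.
#' @export
mfcc <- function(frames, fs = NULL, n_coef = 12L, n_mel = 26L) {
  fr <- frames_as_matrix(frames); fs <- frames_fs(frames, fs)
  if (ncol(fr) < 64L) stop("frame length must be at least 64 samples")
  P <- frame_power_spectra(fr)
  fb <- mel_filterbank(n_mel, ncol(P), fs)
  E <- log(pmax(P %*% t(fb), LOG_FLOOR))
  D <- dct2_matrix(n_mel)[, seq(2L, n_coef + 1L), drop = FALSE]
  C <- E %*% D
  colnames(C) <- paste0("mfcc", seq_len(n_coef))
  C
}

hz_to_mel <- function(f) 2595 * log10(1 + f / 700)
mel_to_hz <- function(m) 700 * (10^(m / 2595) - 1)

mel_filterbank <- function(n_mel, n_bins, fs) {
  # triangular filters with peaks equally spaced on the mel scale
  edges <- mel_to_hz(seq(0, hz_to_mel(fs / 2), length.out = n_mel + 2L))
  freqs <- seq(0, fs / 2, length.out = n_bins)
  fb <- matrix(0, n_mel, n_bins)
  for (m in seq_len(n_mel)) {
    lo <- edges[m]; ce <- edges[m + 1L]; hi <- edges[m + 2L]
    up <- (freqs - lo) / (ce - lo)
    dn <- (hi - freqs) / (hi - ce)
    fb[m, ] <- pmax(0, pmin(up, dn))
  }
  fb
}

dct2_matrix <- function(n) {
  # orthonormal DCT-II basis, columns are basis vectors
  k <- 0:(n - 1L)
  D <- outer(k, k, function(i, j) cos(pi * (2 * i + 1) * j / (2 * n)))
  D <- D * sqrt(2 / n)
  D[, 1L] <- D[, 1L] / sqrt(2)
  D
}

#' Linear predictive coding coefficients
#'
#' Autocorrelation-method LPC via Levinson-Durbin. The convention is the
#' prediction polynomial `A(z) = 1 + sum(a_i z^-i)`, so a frame generated
#' by `x[n] = 0.9 x[n-1] + e[n]` yields `a1` close to -0.9. Degenerate
#' (constant or all-zero) frames fall back to a zero vector.
#'
#' @inheritParams mfcc
#' @param order predictor order (default 10).
#' @return numeric matrix, `n_frames x order`, columns `lpc1..lpc<order>`.
#' @export
lpc_coeffs <- function(frames, order = 10L) {
  fr <- frames_as_matrix(frames)
  n <- nrow(fr); l <- ncol(fr)
  r <- matrix(0, n, order + 1L)
  for (k in 0:order) {
    r[, k + 1L] <- rowSums(fr[, seq_len(l - k), drop = FALSE] *
                           fr[, seq_len(l - k) + k, drop = FALSE])
  }
  A <- matrix(0, n, order)
  degen <- r[, 1L] <= l * 1e-24
  if (any(degen)) warning("constant/zero frames: LPC fallback a = 0")
  for (i in which(!degen)) A[i, ] <- levinson_durbin(r[i, ], order)
  colnames(A) <- paste0("lpc", seq_len(order))
  A
}

# r is autocorrelation r[1] = lag 0; returns a_1..a_p of A(z)=1+sum a_i z^-i
levinson_durbin <- function(r, p) {
  a <- numeric(p)
  e <- r[1L]
  for (i in seq_len(p)) {
    acc <- r[i + 1L]
    if (i > 1L) acc <- acc + sum(a[seq_len(i - 1L)] * r[i:2])
    if (e <= 0) break
    k <- -acc / e
    if (i > 1L) {
      a[seq_len(i - 1L)] <- a[seq_len(i - 1L)] + k * a[(i - 1L):1L]
    }
    a[i] <- k
    e <- e * (1 - k^2)
  }
  a
}

#' Zero-crossing rate
#'
#' Fraction of adjacent-sample pairs whose signs differ; ranges 0-1 and a
#' full-scale alternating sequence gives exactly 1.
#'
#' @inheritParams mfcc
#' @return numeric vector, one value per frame.
#' @export
zcr <- function(frames) {
  fr <- frames_as_matrix(frames)
  s <- sign(fr)
  s[s == 0] <- 1
  rowSums(abs(s[, -1L, drop = FALSE] - s[, -ncol(fr), drop = FALSE])) /
    (2 * (ncol(fr) - 1L))
}

#' Root-mean-square frame energy
#' @inheritParams mfcc
#' @return numeric vector of RMS amplitudes, one per frame.
#' @export
rms_energy <- function(frames) {
  fr <- frames_as_matrix(frames)
  sqrt(rowMeans(fr^2))
}

#' High-frequency power via the continuous wavelet transform
#'
#' Mean squared magnitude of analytic Morlet CWT coefficients over the
#' scales whose centre frequency is at or above `cutoff` (default
#' 15 kHz), 12 voices per octave. Actuation bursts are broadband up to
#' the Nyquist frequency, so this feature separates them from reed tones
#' and breath noise. Returns 0 (with a warning) when `fs/2 < cutoff`.
#'
#' @inheritParams mfcc
#' @param cutoff lower edge of the analysed band in Hz.
#' @return numeric vector, one value per frame.
#' @export
hf_power_cwt <- function(frames, fs = NULL, cutoff = 15000) {
  fr <- frames_as_matrix(frames); fs <- frames_fs(frames, fs)
  n <- nrow(fr)
  if (fs / 2 < cutoff) {
    warning(sprintf("fs/2 = %g Hz is below the %g Hz cutoff; returning 0",
                    fs / 2, cutoff))
    return(numeric(n))
  }
  l <- ncol(fr)
  omega0 <- 6
  fmax <- fs / 2
  n_scales <- max(1L, ceiling(12 * log2(fmax / cutoff)))
  fc <- cutoff * 2^(seq(0, log2(fmax / cutoff), length.out = n_scales + 1L))
  scales <- omega0 * fs / (2 * pi * fc)   # samples
  w <- 2 * pi * (seq_len(l) - 1L) / l     # rad/sample, DFT grid
  X <- stats::mvfft(t(fr))
  acc <- numeric(n)
  for (s in scales) {
    psi <- numeric(l)
    pos <- w > 0 & w <= pi
    psi[pos] <- exp(-0.5 * (s * w[pos] - omega0)^2)  # analytic Morlet
    W <- stats::mvfft(X * psi, inverse = TRUE) / l
    acc <- acc + colMeans(Mod(W)^2)
  }
  acc / length(scales)
}

#' Flo-Tone harmonic feature
#'
#' Peak of the frame's lag-0-normalised autocorrelation over lags
#' corresponding to 500-600 Hz. A sustained reed tone gives values near
#' 1, broadband noise stays low; the normalisation makes the feature
#' amplitude-invariant. Negative peaks are floored at 0.
#'
#' @inheritParams mfcc
#' @param f_range searched fundamental range in Hz.
#' @return numeric vector in \[0, 1\], one value per frame.
#' @export
harmonic_feature <- function(frames, fs = NULL, f_range = c(500, 600)) {
  fr <- frames_as_matrix(frames); fs <- frames_fs(frames, fs)
  l <- ncol(fr)
  lag_lo <- max(1L, floor(fs / f_range[2L]))
  lag_hi <- ceiling(fs / f_range[1L])
  if (l <= lag_hi) stop("frame too short for the requested pitch range")
  nfft <- stats::nextn(2L * l, 2L)
  X <- stats::mvfft(rbind(t(fr), matrix(0, nfft - l, nrow(fr))))
  R <- Re(stats::mvfft(Mod(X)^2, inverse = TRUE)) / nfft
  r0 <- R[1L, ]
  peak <- apply(R[(lag_lo + 1L):(lag_hi + 1L), , drop = FALSE], 2L, max)
  out <- ifelse(r0 > 0, pmax(0, peak / r0), 0)
  pmin(out, 1)
}

#' Spectral entropy
#'
#' Shannon entropy (bits) of the frame's power spectrum normalised to a
#' probability mass; 0 for a silent frame by convention, near
#' `log2(n_bins)` for white noise.
#'
#' @inheritParams mfcc
#' @return numeric vector, one value per frame.
#' @export
spectral_entropy <- function(frames) {
  fr <- frames_as_matrix(frames)
  P <- frame_power_spectra(fr)
  tot <- rowSums(P)
  H <- numeric(nrow(P))
  ok <- tot > 0
  if (any(ok)) {
    p <- P[ok, , drop = FALSE] / tot[ok]
    plogp <- ifelse(p > 0, p * log2(p), 0)
    H[ok] <- -rowSums(plogp)
  }
  H
}

#' Time-domain sample skewness
#' @inheritParams mfcc
#' @return numeric vector; 0 for constant frames.
#' @export
skewness <- function(frames) {
  fr <- frames_as_matrix(frames)
  xc <- fr - rowMeans(fr)
  m2 <- rowMeans(xc^2)
  ifelse(m2 > 0, rowMeans(xc^3) / m2^1.5, 0)
}

#' Time-domain sample kurtosis (non-excess, Pearson convention)
#'
#' `m4 / m2^2`; approximately 3 for Gaussian frames. Constant frames
#' return 0.
#'
#' @inheritParams mfcc
#' @return numeric vector, one value per frame.
#' @export
kurtosis <- function(frames) {
  fr <- frames_as_matrix(frames)
  xc <- fr - rowMeans(fr)
  m2 <- rowMeans(xc^2)
  ifelse(m2 > 0, rowMeans(xc^4) / m2^2, 0)
}

#' Spectral centroid
#' @inheritParams mfcc
#' @return numeric vector in \[0, fs/2\] Hz; 0 for silent frames.
#' @export
spectral_centroid <- function(frames, fs = NULL) {
  fr <- frames_as_matrix(frames); fs <- frames_fs(frames, fs)
  P <- frame_power_spectra(fr)
  freqs <- seq(0, fs / 2, length.out = ncol(P))
  tot <- rowSums(P)
  ifelse(tot > 0, as.numeric(P %*% freqs) / tot, 0)
}

frames_as_matrix <- function(frames) {
  if (inherits(frames, "frame_matrix")) return(frames$frames)
  if (is.matrix(frames)) return(frames)
  matrix(as.numeric(frames), nrow = 1L)
}

frames_fs <- function(frames, fs) {
  if (inherits(frames, "frame_matrix")) return(frames$fs)
  if (is.null(fs)) stop("fs must be given when frames is a bare matrix")
  fs
}

#' Default 30-feature registry
#'
#' Ordered extractor list: `mfcc1..12`, `lpc1..10`, `rms`, `zcr`,
#' `hf_power`, `harmonic`, `entropy`, `skewness`, `kurtosis`, `centroid`.
#' The registry is a plain list so alternative feature sets can be
#' substituted; each entry provides the column names it emits and a
#' function of a `frame_matrix` returning a vector or matrix.
#'
#' @return a list of feature definitions (class `feature_registry`).
#' @export
default_registry <- function() {
  reg <- list(
    list(names = paste0("mfcc", 1:12), fun = function(fm) mfcc(fm)),
    list(names = paste0("lpc", 1:10), fun = function(fm) lpc_coeffs(fm)),
    list(names = "rms", fun = function(fm) rms_energy(fm)),
    list(names = "zcr", fun = function(fm) zcr(fm)),
    list(names = "hf_power", fun = function(fm) hf_power_cwt(fm)),
    list(names = "harmonic", fun = function(fm) harmonic_feature(fm)),
    list(names = "entropy", fun = function(fm) spectral_entropy(fm)),
    list(names = "skewness", fun = function(fm) skewness(fm)),
    list(names = "kurtosis", fun = function(fm) kurtosis(fm)),
    list(names = "centroid", fun = function(fm) spectral_centroid(fm))
  )
  structure(reg, class = "feature_registry")
}

#' Names of the 11-feature working subset
#'
#' A compact feature set spanning loudness (`rms`), harmonicity
#' (`harmonic`), spectral shape (`entropy`, `mfcc1..3`, `lpc1..2`),
#' waveform statistics (`skewness`, `kurtosis`) and high-frequency
#' transient content (`hf_power`). Used as the default classifier feature
#' set; any subset of the registry names may be supplied instead.
#'
#' @return character vector of 11 feature names.
#' @export
selected_feature_names <- function() {
  c("rms", "harmonic", "entropy", "skewness", "kurtosis", "hf_power",
    "mfcc1", "mfcc2", "mfcc3", "lpc1", "lpc2")
}

#' Extract a feature matrix from framed audio
#'
#' Runs every registry extractor and column-binds the results in registry
#' order. Non-finite values (possible on pathological frames) are
#' replaced by 0 with a warning so downstream classification never sees
#' NaN.
#'
#' @param frames a `frame_matrix`.
#' @param registry a feature registry from [default_registry()] (default).
#' @return an object of class `feature_matrix`: `values` (n_frames x
#'   n_features), `names`, `frame_times` (frame midpoints, s).
#' @export
extract_features <- function(frames, registry = default_registry()) {
  stopifnot(inherits(frames, "frame_matrix"))
  cols <- lapply(registry, function(def) {
    v <- def$fun(frames)
    m <- if (is.matrix(v)) v else matrix(v, ncol = 1L)
    if (ncol(m) != length(def$names)) {
      stop("extractor for ", def$names[1L], " returned wrong width")
    }
    m
  })
  values <- do.call(cbind, cols)
  colnames(values) <- unlist(lapply(registry, `[[`, "names"))
  if (anyNA(values) || any(!is.finite(values))) {
    warning("non-finite feature values replaced by 0")
    values[!is.finite(values)] <- 0
  }
  structure(list(values = values, names = colnames(values),
                 frame_times = frames$start_times + frames$frame_len_s / 2),
            class = "feature_matrix")
}

#' Subset the columns of a feature matrix by name
#' @param features a `feature_matrix`.
#' @param names feature names to keep, in the requested order.
#' @return a `feature_matrix` with the selected columns.
#' @export
subset_features <- function(features, names) {
  stopifnot(inherits(features, "feature_matrix"))
  missing <- setdiff(names, features$names)
  if (length(missing)) stop("unknown features: ",
                            paste(missing, collapse = ", "))
  structure(list(values = features$values[, names, drop = FALSE],
                 names = names, frame_times = features$frame_times),
            class = "feature_matrix")
}
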