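#' Zero-phase band-pass filter
#'
#' 4th-order Butterworth band-pass applied forward and backward
#' (`signal::filtfilt`), so the output has no group delay. The default
#' band (140-22,000 Hz) emphasises inhaler sound events and suppresses
#' mains hum and very-low-frequency rumble; the flow-estimation stage
#' uses 200-5000 Hz. When the upper edge is not representable at the
#' signal's sample rate it is clamped to `0.45 * fs` with a warning.
#'
#' @param sig an [audio_signal].
#' @param lo,hi band edges in Hz, `0 < lo < hi`.
#' @return the filtered [audio_signal].
#' @export
bandpass <- function(sig, lo = 140, hi = 22000) {
  stopifnot(inherits(sig, "audio_signal"))
  if (!(lo > 0 && lo < hi)) stop("band edges must satisfy 0 < lo < hi")
  nyq <- sig$fs / 2
  if (hi >= nyq) {
    hi <- 0.45 * sig$fs
    warning(sprintf("upper band edge clamped to %.0f Hz (0.45*fs)", hi))
    if (lo >= hi) stop("band collapsed after clamping; lower lo")
  }
  bf <- signal::butter(4, c(lo, hi) / nyq, type = "pass")
  y <- signal::filtfilt(bf, sig$samples)
  audio_signal(y, sig$fs, sig$source_id)
}

#' Slice a signal into overlapping frames
#'
#' Event classification uses 40 ms frames with a 20 ms step; flow
#' estimation uses 50 ms frames with a 25 ms step and a Hanning window.
#' The trailing partial frame is discarded, so
#' `n_frames = floor((n_samples - frame_len) / step) + 1`. DC removal
#' subtracts each frame's mean before any windowing.
#'
#' @param sig an [audio_signal].
#' @param frame_len_s frame duration in seconds (> `step_s`).
#' @param step_s hop between frame starts in seconds (> 0).
#' @param remove_dc subtract the per-frame mean.
#' @param window `"none"` or `"hanning"`.
#' @return an object of class `frame_matrix`: `frames` (n_frames x
#'   frame_len), `frame_len_s`, `step_s`, `fs`, `start_times` (s).
#' @export
frame_signal <- function(sig, frame_len_s = 0.04, step_s = 0.02,
                         remove_dc = TRUE, window = c("none", "hanning")) {
  stopifnot(inherits(sig, "audio_signal"))
  window <- match.arg(window)
  if (!(frame_len_s > step_s && step_s > 0)) {
    stop("need frame_len_s > step_s > 0")
  }
  l <- round(frame_len_s * sig$fs)
  h <- round(step_s * sig$fs)
  L <- length(sig$samples)
  if (L < l) stop("signal shorter than one frame")
  n <- (L - l) %/% h + 1L
  idx <- outer(seq_len(l) - 1L, (seq_len(n) - 1L) * h, "+") + 1L
  fr <- t(matrix(sig$samples[idx], nrow = l))
  if (remove_dc) fr <- fr - rowMeans(fr)
  if (window == "hanning") {
    fr <- sweep(fr, 2L, hanning_window(l), "*")
  }
  structure(list(frames = fr, frame_len_s = frame_len_s, step_s = step_s,
                 fs = sig$fs, start_times = (seq_len(n) - 1L) * h / sig$fs),
            class = "frame_matrix")
}

# symmetric Hanning window (matches signal::hanning)
hanning_window <- function(n) {
  if (n == 1L) return(1)
  0.5 - 0.5 * cos(2 * pi * (0:(n - 1L)) / (n - 1L))
}

#' Construct / validate a label track
#'
#' Timed sound-event labels with class ids 1 noise, 2 exhalation,
#' 3 inhalation, 4 actuation. Intervals are half-open `[start_s, end_s)`
#' in seconds. Exhalation and inhalation entries must not overlap each
#' other; an actuation entry may overlap an inhalation (the patient
#' actuates during the breath) and wins the per-frame label over the span
#' it covers.
#'
#' @param entries data.frame with columns `start_s`, `end_s`, `class`.
#' @return an object of class `label_track`.
#' @export
label_track <- function(entries) {
  entries <- as.data.frame(entries)
  need <- c("start_s", "end_s", "class")
  if (!all(need %in% names(entries))) {
    stop("label entries need columns start_s, end_s, class")
  }
  entries$class <- as.integer(entries$class)
  if (nrow(entries) > 0) {
    if (!all(entries$class %in% 1:4)) stop("unknown class id in labels")
    if (!all(entries$start_s < entries$end_s)) stop("need start_s < end_s")
    resp <- entries[entries$class %in% c(2L, 3L), , drop = FALSE]
    if (nrow(resp) > 1) {
      resp <- resp[order(resp$start_s), ]
      if (any(resp$end_s[-nrow(resp)] > resp$start_s[-1] + 1e-9)) {
        stop("exhalation/inhalation label entries overlap")
      }
    }
  }
  structure(list(entries = entries[order(entries$start_s), , drop = FALSE]),
            class = "label_track")
}

#' Read a label CSV (`start_s,end_s,class` with header)
#' @param path CSV path.
#' @return a [label_track].
#' @export
read_labels <- function(path) {
  df <- utils::read.csv(path)
  label_track(df)
}

#' Write a label track to CSV
#' @param track a [label_track] (or event data.frame with the same columns).
#' @param path output CSV path.
#' @export
write_labels <- function(track, path) {
  df <- if (inherits(track, "label_track")) track$entries else
    as.data.frame(track)[, c("start_s", "end_s", "class")]
  utils::write.csv(df, path, row.names = FALSE)
  invisible(path)
}

#' Assign a class label to every frame of a recording
#'
#' A frame takes the class of the label entry covering its midpoint;
#' frames covered by no entry are noise (class 1). When several entries
#' cover the midpoint (actuation inside inhalation, or a boundary tie at
#' exactly one entry's end and the next one's start), the later-starting
#' entry wins.
#'
#' @param track a [label_track].
#' @param frames a `frame_matrix`.
#' @return integer vector of class ids, one per frame.
#' @export
labels_to_frames <- function(track, frames) {
  stopifnot(inherits(track, "label_track"), inherits(frames, "frame_matrix"))
  mid <- frames$start_times + frames$frame_len_s / 2
  lab <- rep(CLASS_NOISE, length(mid))
  e <- track$entries
  if (nrow(e) > 0) {
    for (i in order(e$start_s)) {  # later-starting applied last -> wins
      sel <- mid >= e$start_s[i] & mid < e$end_s[i]
      lab[sel] <- e$class[i]
    }
  }
  lab
}
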