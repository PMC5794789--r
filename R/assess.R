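# Critical user-technique error detection and evaluation statistics.

#' Assess actuation coordination
#'
#' Coordination is good when at least one actuation event starts within
#' the span (onset inclusive, end inclusive) of an inhalation event --
#' the patient generates the reed sound before releasing the dose.
#' Missing actuation or inhalation events are flagged and count as poor
#' coordination. With `rule = "midpoint"` the actuation midpoint, rather
#' than its onset, must fall inside an inhalation.
#'
#' @param events event data.frame (`class`, `start_s`, `end_s`), as
#'   returned by [form_events()] or [classify_recording()].
#' @param rule `"onset"` (default) or `"midpoint"`.
#' @return list with `poor` (logical), `no_actuation`, `no_inhalation`.
#' @export
assess_coordination <- function(events, rule = c("onset", "midpoint")) {
  rule <- match.arg(rule)
  events <- as.data.frame(events)
  act <- events[events$class == CLASS_ACTUATION, , drop = FALSE]
  inh <- events[events$class == CLASS_INHALATION, , drop = FALSE]
  no_act <- nrow(act) == 0L
  no_inh <- nrow(inh) == 0L
  good <- FALSE
  if (!no_act && !no_inh) {
    ref <- if (rule == "onset") act$start_s else
      (act$start_s + act$end_s) / 2
    for (t in ref) {
      if (any(t >= inh$start_s & t <= inh$end_s)) { good <- TRUE; break }
    }
    # an actuation bridging two inhalation runs that it split also counts:
    # its onset coincides with the end of the first run (inclusive above)
  }
  list(poor = !good, no_actuation = no_act, no_inhalation = no_inh)
}

#' Assess inhalation speed
#'
#' The "inhaling too fast" critical error: strictly more than 90 L/min
#' peak inspiratory flow rate. Exactly 90 L/min is not an error.
#'
#' @param pifr peak inspiratory flow rate in L/min (NA allowed).
#' @param threshold error threshold in L/min.
#' @return logical: `TRUE` when too fast (`NA` when `pifr` is `NA`).
#' @export
assess_speed <- function(pifr, threshold = 90) {
  pifr > threshold
}

# ---- event-level metrics -------------------------------------------------

new_metric_accumulator <- function() {
  list(tp = numeric(4), fp = numeric(4), fn = numeric(4),
       frames_correct = 0, frames_total = 0)
}

# one-to-one greedy matching by largest temporal overlap, per class
match_events <- function(pred, truth) {
  tp <- fp <- fn <- numeric(4)
  for (w in 2:4) {
    p <- pred[pred$class == w, , drop = FALSE]
    t <- truth[truth$class == w, , drop = FALSE]
    np <- nrow(p); nt <- nrow(t)
    if (np == 0L || nt == 0L) {
      fp[w] <- fp[w] + np
      fn[w] <- fn[w] + nt
      next
    }
    ov <- outer(seq_len(np), seq_len(nt), Vectorize(function(i, j) {
      max(0, min(p$end_s[i], t$end_s[j]) - max(p$start_s[i], t$start_s[j]))
    }))
    used_p <- rep(FALSE, np); used_t <- rep(FALSE, nt)
    repeat {
      ov[used_p, ] <- -1; ov[, used_t] <- -1
      m <- which(ov == max(ov), arr.ind = TRUE)
      if (length(m) == 0L || max(ov) <= 0) break
      i <- m[1L, 1L]; j <- m[1L, 2L]
      used_p[i] <- TRUE; used_t[j] <- TRUE
      tp[w] <- tp[w] + 1
      if (all(used_p) || all(used_t)) break
    }
    fp[w] <- fp[w] + sum(!used_p)
    fn[w] <- fn[w] + sum(!used_t)
  }
  list(tp = tp, fp = fp, fn = fn)
}

accumulate_event_metrics <- function(acc, pred, truth,
                                     pred_frames = NULL,
                                     true_frames = NULL) {
  m <- match_events(as.data.frame(pred), as.data.frame(truth))
  acc$tp <- acc$tp + m$tp
  acc$fp <- acc$fp + m$fp
  acc$fn <- acc$fn + m$fn
  if (!is.null(pred_frames) && !is.null(true_frames)) {
    acc$frames_correct <- acc$frames_correct +
      sum(pred_frames == true_frames)
    acc$frames_total <- acc$frames_total + length(true_frames)
  }
  acc
}

finalize_event_metrics <- function(acc) {
  pct <- function(num, den) ifelse(den > 0, 100 * num / den, 100)
  sens <- pct(acc$tp, acc$tp + acc$fn)
  ppv <- pct(acc$tp, acc$tp + acc$fp)
  names(sens) <- names(ppv) <- CLASS_NAMES
  list(sensitivity = sens[2:4], ppv = ppv[2:4],
       frame_accuracy = if (acc$frames_total > 0)
         100 * acc$frames_correct / acc$frames_total else NA_real_)
}

#' Event-level sensitivity, PPV and frame accuracy
#'
#' A predicted event is a true positive when it temporally overlaps a
#' same-class labelled event; matching is one-to-one greedy by largest
#' overlap, so a second prediction on an already-matched labelled event
#' counts as a false positive. Sensitivity = TP/(TP+FN), PPV =
#' TP/(TP+FP), both in percent per class; frame accuracy is the percent
#' of frames (all four classes) labelled correctly.
#'
#' @param pred_events,true_events event data.frames (`class`, `start_s`,
#'   `end_s`). For several recordings, offset times so recordings do not
#'   overlap, or call once per recording and aggregate.
#' @param pred_frames,true_frames optional per-frame label vectors for
#'   the frame-accuracy figure.
#' @return list with `sensitivity` and `ppv` (named per class:
#'   exhalation/inhalation/actuation) and `frame_accuracy` (percent).
#' @export
event_metrics <- function(pred_events, true_events,
                          pred_frames = NULL, true_frames = NULL) {
  acc <- accumulate_event_metrics(new_metric_accumulator(),
                                  pred_events, true_events,
                                  pred_frames, true_frames)
  finalize_event_metrics(acc)
}

#' Cohen's kappa for two dichotomous raters
#'
#' `kappa = (p_o - p_e) / (1 - p_e)` with expected agreement from the
#' product of the marginals. When both raters are constant and identical
#' (`p_e = 1`, `p_o = 1`) kappa is defined as 1.
#'
#' @param a,b equal-length vectors of dichotomous ratings (logical,
#'   factor or any two-valued coding), length >= 2.
#' @return kappa in \[-1, 1\].
#' @export
cohens_kappa <- function(a, b) {
  if (length(a) != length(b)) stop("ratings must have equal length")
  if (length(a) < 2L) stop("need at least 2 paired ratings")
  lev <- sort(unique(c(as.character(a), as.character(b))))
  a <- factor(as.character(a), levels = lev)
  b <- factor(as.character(b), levels = lev)
  tab <- table(a, b)
  n <- sum(tab)
  p_o <- sum(diag(tab)) / n
  p_e <- sum(rowSums(tab) * colSums(tab)) / n^2
  if (abs(1 - p_e) < 1e-12) return(1)
  (p_o - p_e) / (1 - p_e)
}

#' Assess one recording's user technique
#'
#' Runs sound-event classification, extracts the detected inhalation
#' audio (span from the first to the last inhalation event, so an
#' actuation splitting the breath stays inside), estimates PIFR and
#' volume, and evaluates the two critical errors.
#'
#' @param sig an [audio_signal].
#' @param models a trained `class_model_set`.
#' @param flow_model a `flow_model` (default [default_flow_model()]).
#' @param ... passed to [classify_recording()].
#' @return an object of class `technique_report`: `source_id`, `events`,
#'   `pifr` (L/min), `volume` (L), `poor_coordination`, `too_fast`,
#'   `no_inhalation`, `no_actuation`.
#' @export
assess_recording <- function(sig, models,
                             flow_model = default_flow_model(), ...) {
  cls <- classify_recording(sig, models, ...)
  coord <- assess_coordination(cls$events)
  pifr <- NA_real_
  volume <- NA_real_
  inh <- cls$events[cls$events$class == CLASS_INHALATION, , drop = FALSE]
  if (nrow(inh) > 0L) {
    i0 <- max(1L, floor(min(inh$start_s) * sig$fs) + 1L)
    i1 <- min(length(sig$samples), ceiling(max(inh$end_s) * sig$fs))
    seg <- audio_signal(sig$samples[i0:i1], sig$fs, sig$source_id)
    ff <- tryCatch(extract_flow_features(seg), error = function(e) NULL)
    if (!is.null(ff)) {
      est <- estimate_pifr(ff, flow_model)
      if (est$measurable) {
        prof <- estimate_flow_profile(ff, flow_model)
        pifr <- est$pifr
        volume <- prof$volume
      }
    }
  }
  structure(list(source_id = sig$source_id, events = cls$events,
                 pifr = pifr, volume = volume,
                 poor_coordination = coord$poor,
                 too_fast = isTRUE(assess_speed(pifr)),
                 no_inhalation = coord$no_inhalation,
                 no_actuation = coord$no_actuation),
            class = "technique_report")
}

#' @export
print.technique_report <- function(x, ...) {
  cat(sprintf("<technique_report> %s\n", ifelse(is.na(x$source_id), "?",
                                                x$source_id)))
  cat(sprintf("  events: %d | PIFR: %s L/min | volume: %s L\n",
              nrow(x$events),
              ifelse(is.na(x$pifr), "unmeasurable", sprintf("%.1f", x$pifr)),
              ifelse(is.na(x$volume), "-", sprintf("%.2f", x$volume))))
  cat(sprintf("  poor coordination: %s | too fast (>90 L/min): %s\n",
              x$poor_coordination, x$too_fast))
  invisible(x)
}

#' Cohort prevalence of critical errors before/after tuition
#'
#' Percentage of subjects with at least one flagged recording, per error
#' and per phase.
#'
#' @param reports data.frame with columns `subject`, `phase` (e.g.
#'   "before"/"after"), `poor_coordination`, `too_fast` (logicals).
#' @return data.frame with columns `phase`, `error`, `percent`.
#' @export
cohort_summary <- function(reports) {
  reports <- as.data.frame(reports)
  if (nrow(reports) == 0L) {
    return(data.frame(phase = character(0), error = character(0),
                      percent = numeric(0)))
  }
  out <- list()
  for (ph in unique(reports$phase)) {
    sub <- reports[reports$phase == ph, ]
    for (err in c("poor_coordination", "too_fast")) {
      flagged <- tapply(sub[[err]], sub$subject,
                        function(v) any(v, na.rm = TRUE))
      out[[length(out) + 1L]] <- data.frame(
        phase = ph, error = err,
        percent = 100 * mean(flagged))
    }
  }
  do.call(rbind, out)
}
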