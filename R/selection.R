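# Sequential forward feature selection under the weighted event-level
# performance measure J.

#' Weighted event-classification performance measure
#'
#' `J = wA*(S_A + P_A) + wI*(S_I + P_I) + wE*(S_E + P_E)` with default
#' weights 0.2 (actuation), 0.2 (inhalation) and 0.1 (exhalation), where
#' S and P are event-level sensitivity and positive predictive value in
#' percent. Exhalation is down-weighted because it is the least reliable
#' class clinically. J ranges 0-100.
#'
#' @param s_a,p_a actuation sensitivity and PPV (percent, 0-100).
#' @param s_i,p_i inhalation sensitivity and PPV.
#' @param s_e,p_e exhalation sensitivity and PPV.
#' @param weights named numeric vector `c(a=, i=, e=)`.
#' @return J in percent.
#' @export
weighted_J <- function(s_a, p_a, s_i, p_i, s_e, p_e,
                       weights = c(a = 0.2, i = 0.2, e = 0.1)) {
  vals <- c(s_a, p_a, s_i, p_i, s_e, p_e)
  if (any(!is.finite(vals)) || any(vals < 0) || any(vals > 100)) {
    stop("sensitivities/PPVs must lie in [0, 100]")
  }
  weights[["a"]] * (s_a + p_a) + weights[["i"]] * (s_i + p_i) +
    weights[["e"]] * (s_e + p_e)
}

# J of a trained model evaluated on validation recordings.
# train/val: lists of list(features = feature_matrix over the full
# registry, labels = integer frame labels, energy = optional rms vector).
evaluate_feature_subset <- function(subset_names, train, val,
                                    lambda = 1e-6, smooth_order = 5L,
                                    min_frames = 5L, step_s = 0.02,
                                    frame_len_s = 0.04) {
  tr_feats <- do.call(rbind, lapply(train, function(r)
    subset_features(r$features, subset_names)$values))
  tr_labels <- unlist(lapply(train, `[[`, "labels"))
  fm <- structure(list(values = tr_feats, names = subset_names,
                       frame_times = seq_len(nrow(tr_feats))),
                  class = "feature_matrix")
  models <- train_event_models(fm, tr_labels, lambda = lambda)
  agg <- new_metric_accumulator()
  for (r in val) {
    feats <- subset_features(r$features, subset_names)
    energy <- if (!is.null(r$energy)) r$energy else
      if ("rms" %in% r$features$names) r$features$values[, "rms"] else NULL
    m <- estimate_noise(models, feats, energy = energy)
    m <- adapt_inhalation_model(m, feats)
    lab <- smooth_labels(classify_frames(m, feats), smooth_order)
    pred <- form_events(lab, step_s = step_s, frame_len_s = frame_len_s,
                        min_frames = min_frames)
    truth <- form_events(r$labels, step_s = step_s,
                         frame_len_s = frame_len_s, min_frames = min_frames)
    agg <- accumulate_event_metrics(agg, pred, truth, lab, r$labels)
  }
  met <- finalize_event_metrics(agg)
  weighted_J(met$sensitivity[["actuation"]], met$ppv[["actuation"]],
             met$sensitivity[["inhalation"]], met$ppv[["inhalation"]],
             met$sensitivity[["exhalation"]], met$ppv[["exhalation"]])
}

#' Sequential forward feature selection
#'
#' Greedy wrapper selection: at each step the candidate feature whose
#' addition maximises the weighted event-level measure J of the full
#' classification pipeline (noise estimation, adaptation, QDA, median
#' smoothing, event formation) on the validation recordings is added.
#' Selection stops when the best improvement falls below `min_gain`
#' J-points or the candidate pool is exhausted; the full J trajectory is
#' recorded so the selection curve can be plotted and its argmax taken.
#'
#' @param train,val lists of recordings, each a list with `features`
#'   (a `feature_matrix` over the candidate features), `labels` (integer
#'   frame labels) and optionally `energy` (per-frame RMS for the noise
#'   estimation rule; defaults to the `rms` column when present).
#' @param feature_names candidate pool; defaults to all columns of the
#'   first training recording.
#' @param min_gain stopping threshold in J percentage points.
#' @param lambda covariance ridge passed to the trainer.
#' @return an object of class `selection_result`: `selected` (ordered
#'   names), `J_trajectory` (J after each addition), `weights`.
#' @export
sequential_forward_selection <- function(train, val, feature_names = NULL,
                                         min_gain = 0.01, lambda = 1e-6) {
  stopifnot(length(train) >= 1L, length(val) >= 1L)
  if (is.null(feature_names)) feature_names <- train[[1L]]$features$names
  if (length(feature_names) < 1L) stop("empty candidate feature pool")
  val_classes <- unique(unlist(lapply(val, `[[`, "labels")))
  if (length(val_classes) < 2L) {
    stop("validation recordings contain a single class; cannot score J")
  }
  selected <- character(0)
  trajectory <- numeric(0)
  best_J <- -Inf
  pool <- feature_names
  while (length(pool) > 0L) {
    scores <- vapply(pool, function(f) {
      tryCatch(evaluate_feature_subset(c(selected, f), train, val,
                                       lambda = lambda),
               error = function(e) -Inf)
    }, numeric(1))
    i <- which.max(scores)
    if (!is.finite(scores[i])) break
    if (length(selected) > 0L && scores[i] - best_J < min_gain) break
    selected <- c(selected, pool[i])
    trajectory <- c(trajectory, scores[i])
    best_J <- scores[i]
    pool <- pool[-i]
  }
  structure(list(selected = selected, J_trajectory = trajectory,
                 weights = c(a = 0.2, i = 0.2, e = 0.1)),
            class = "selection_result")
}

#' @export
print.selection_result <- function(x, ...) {
  cat(sprintf("<selection_result> %d features, final J = %.2f%%\n",
              length(x$selected), tail(x$J_trajectory, 1)))
  cat("  ", paste(x$selected, collapse = " > "), "\n")
  invisible(x)
}
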