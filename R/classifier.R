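# Per-class Gaussian (QDA) sound-event classifier.
#
# Training estimates a mean vector, covariance matrix and prior for each
# of the four classes (noise/exhalation/inhalation/actuation). Testing a
# recording runs four steps: (1) per-recording noise estimation from the
# lowest-energy frames, (2) inhalation-model mean adaptation seeded by a
# nearest-mean classification, (3) frame-by-frame prior-weighted Gaussian
# density argmax in the log domain, (4) median smoothing and event
# formation with a minimum-duration rule.

#' Train the per-class Gaussian models
#'
#' Each class model is the sample mean and ridge-regularised sample
#' covariance of its labelled frames; priors are class frame frequencies.
#' The ridge `lambda * (trace(Sigma)/d) * I` guarantees positive-definite
#' covariances even with collinear features.
#'
#' @param features a `feature_matrix` of training frames (recordings may
#'   be concatenated).
#' @param frame_labels integer class ids (1-4), one per frame.
#' @param lambda covariance ridge factor (default `1e-6`).
#' @return an object of class `class_model_set`: `models` (per class:
#'   `class_id`, `mean`, `cov`, `prior`), `feature_names`, `lambda`.
#' @export
train_event_models <- function(features, frame_labels, lambda = 1e-6) {
  stopifnot(inherits(features, "feature_matrix"))
  X <- features$values
  d <- ncol(X)
  frame_labels <- as.integer(frame_labels)
  if (length(frame_labels) != nrow(X)) {
    stop("one label per frame required")
  }
  counts <- tabulate(frame_labels, nbins = 4L)
  short <- which(counts < d + 2L)
  if (length(short)) {
    stop("too few training frames (< d+2) for class(es): ",
         paste(CLASS_NAMES[short], collapse = ", "))
  }
  models <- lapply(1:4, function(w) {
    Xi <- X[frame_labels == w, , drop = FALSE]
    list(class_id = w,
         mean = colMeans(Xi),
         cov = ridge_cov(stats::cov(Xi), lambda),
         prior = counts[w] / sum(counts))
  })
  structure(list(models = models, feature_names = features$names,
                 lambda = lambda),
            class = "class_model_set")
}

ridge_cov <- function(S, lambda) {
  d <- ncol(S)
  tr <- sum(diag(S))
  if (tr <= 0) tr <- d  # fully degenerate class: fall back to identity scale
  S + lambda * (tr / d) * diag(d)
}

#' @export
print.class_model_set <- function(x, ...) {
  cat(sprintf("<class_model_set> d = %d features, priors = %s\n",
              length(x$feature_names),
              paste(sprintf("%s %.3f", CLASS_NAMES,
                            vapply(x$models, `[[`, 0, "prior")),
                    collapse = ", ")))
  invisible(x)
}

#' Per-recording background-noise estimation
#'
#' Clinical recordings differ in background noise, so the noise-class
#' model is re-estimated for every recording from the frames with the
#' lowest 40% of energy values; the other class models and all priors
#' stay as trained. Recordings with fewer than 13 frames are left
#' unchanged with a warning.
#'
#' @param models a `class_model_set`.
#' @param features the recording's `feature_matrix` (columns matching the
#'   model's `feature_names`).
#' @param energy per-frame energy used for the 40% rule; defaults to the
#'   `rms` feature column when present.
#' @return the adapted `class_model_set`.
#' @export
estimate_noise <- function(models, features, energy = NULL) {
  stopifnot(inherits(models, "class_model_set"),
            inherits(features, "feature_matrix"))
  X <- features$values
  n <- nrow(X)
  if (is.null(energy)) {
    if (!("rms" %in% features$names)) {
      stop("supply `energy` when the feature set has no rms column")
    }
    energy <- X[, "rms"]
  }
  if (n < 13L) {
    warning("recording too short for noise estimation (< 13 frames); ",
            "models unchanged")
    return(models)
  }
  k <- floor(0.4 * n)
  sel <- order(energy)[seq_len(k)]
  Xn <- X[sel, , drop = FALSE]
  models$models[[CLASS_NOISE]]$mean <- colMeans(Xn)
  models$models[[CLASS_NOISE]]$cov <- ridge_cov(stats::cov(Xn),
                                                models$lambda)
  models
}

#' Nearest-mean (Euclidean) frame classification
#'
#' Initial classification used to seed model adaptation: each frame is
#' assigned the class whose mean vector is nearest in Euclidean distance.
#' Ties go to the lowest class id.
#'
#' @inheritParams estimate_noise
#' @return integer vector of class ids, one per frame.
#' @export
initial_classify_euclidean <- function(models, features) {
  X <- align_features(models, features)
  D2 <- vapply(models$models, function(m) {
    rowSums(sweep(X, 2L, m$mean)^2)
  }, numeric(nrow(X)))
  if (!is.matrix(D2)) D2 <- matrix(D2, nrow = 1L)
  max.col(-D2, ties.method = "first")
}

#' Adapt the inhalation model to the current recording
#'
#' Flo-Tone reeds differ slightly across devices, so the inhalation mean
#' vector is moved to the unweighted average of the trained mean and the
#' centroid of the frames that a nearest-mean pass classifies as
#' inhalation. Covariances, priors and the other classes are untouched.
#' If no frame classifies as inhalation the models are returned unchanged
#' with a warning. The update is applied once per recording; reapplying
#' it halves the remaining gap again.
#'
#' @inheritParams estimate_noise
#' @return the adapted `class_model_set`.
#' @export
adapt_inhalation_model <- function(models, features) {
  X <- align_features(models, features)
  lab <- initial_classify_euclidean(models, features)
  sel <- lab == CLASS_INHALATION
  if (!any(sel)) {
    warning("no frames initially classified as inhalation; ",
            "adaptation skipped")
    return(models)
  }
  centroid <- colMeans(X[sel, , drop = FALSE])
  models$models[[CLASS_INHALATION]]$mean <-
    (models$models[[CLASS_INHALATION]]$mean + centroid) / 2
  models
}

#' QDA frame classification
#'
#' Assigns each frame the class maximising the prior-weighted Gaussian
#' density. Scores are computed in the log domain
#' (`log P(w) - log|Sigma_w|/2 - Mahalanobis/2`), which is identical to
#' the direct density argmax wherever the latter does not underflow.
#' Ties go to the lowest class id.
#'
#' @inheritParams estimate_noise
#' @return integer vector of class ids, one per frame.
#' @export
classify_frames <- function(models, features) {
  X <- align_features(models, features)
  S <- vapply(models$models, function(m) {
    R <- tryCatch(chol(m$cov),
                  error = function(e) stop("non-positive-definite ",
                                           "covariance for class ",
                                           CLASS_NAMES[m$class_id]))
    Z <- forwardsolve(t(R), t(X) - m$mean)
    maha <- colSums(Z^2)
    log(m$prior) - sum(log(diag(R))) - maha / 2
  }, numeric(nrow(X)))
  if (!is.matrix(S)) S <- matrix(S, nrow = 1L)
  max.col(S, ties.method = "first")
}

align_features <- function(models, features) {
  stopifnot(inherits(models, "class_model_set"),
            inherits(features, "feature_matrix"))
  if (!identical(features$names, models$feature_names)) {
    features <- subset_features(features, models$feature_names)
  }
  features$values
}

#' Median-filter a frame label sequence
#'
#' Sliding median of the class ids (default order 5) with replicated
#' edges; suppresses isolated misclassified frames. The median of an odd
#' window of class ids is always a class present in the window.
#'
#' @param labels integer class ids.
#' @param order odd window length.
#' @return smoothed integer label vector of the same length.
#' @export
smooth_labels <- function(labels, order = 5L) {
  if (order %% 2L != 1L) stop("median filter order must be odd")
  n <- length(labels)
  if (n == 0L || order == 1L) return(labels)
  half <- (order - 1L) %/% 2L
  padded <- c(rep(labels[1L], half), labels, rep(labels[n], half))
  vapply(seq_len(n), function(i) {
    as.integer(stats::median(padded[i:(i + order - 1L)]))
  }, integer(1))
}

#' Concatenate labelled frames into sound events
#'
#' Maximal runs of the same class become events. Inhalation and
#' exhalation runs shorter than `min_frames` (default 5 frames = 100 ms
#' at a 20 ms step) are discarded as false positives; actuation runs are
#' kept at any length because true actuations can be very short. Event
#' times span the first frame's start to the last frame's end.
#'
#' @param labels integer class ids per frame.
#' @param step_s frame step in seconds.
#' @param frame_len_s frame duration in seconds.
#' @param min_frames minimum run length for inhalation/exhalation events.
#' @param t0 time of the first frame's start (s).
#' @return data.frame with columns `class`, `start_s`, `end_s`, `n_frames`.
#' @export
form_events <- function(labels, step_s = 0.02, frame_len_s = 0.04,
                        min_frames = 5L, t0 = 0) {
  r <- rle(as.integer(labels))
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1L
  keep <- r$values %in% c(CLASS_EXHALATION, CLASS_INHALATION,
                          CLASS_ACTUATION) &
    (r$values == CLASS_ACTUATION | r$lengths >= min_frames)
  data.frame(class = r$values[keep],
             start_s = t0 + (starts[keep] - 1L) * step_s,
             end_s = t0 + (ends[keep] - 1L) * step_s + frame_len_s,
             n_frames = r$lengths[keep])
}

#' Classify a full recording into sound events
#'
#' Runs the complete testing pipeline: band-pass filtering, framing with
#' DC removal, feature extraction, per-recording noise estimation,
#' inhalation-model adaptation, QDA classification, median smoothing and
#' event formation. Deterministic for a fixed input.
#'
#' @param sig an [audio_signal].
#' @param models a trained `class_model_set`.
#' @param registry feature registry covering the model's features.
#' @param band classification band-pass edges in Hz.
#' @param frame_len_s,step_s framing parameters (s).
#' @param smooth_order median filter order.
#' @param min_frames minimum event duration rule (frames).
#' @return list with `labels` (per-frame class ids), `frame_times`
#'   (frame start times, s), `events` (data.frame as in [form_events()])
#'   and `features` (the recording's `feature_matrix`).
#' @export
classify_recording <- function(sig, models, registry = default_registry(),
                               band = c(140, 22000), frame_len_s = 0.04,
                               step_s = 0.02, smooth_order = 5L,
                               min_frames = 5L) {
  stopifnot(inherits(sig, "audio_signal"),
            inherits(models, "class_model_set"))
  bp <- bandpass(sig, band[1L], band[2L])
  fm <- frame_signal(bp, frame_len_s, step_s, remove_dc = TRUE)
  feats <- extract_features(fm, registry)
  energy <- rms_energy(fm)
  m <- estimate_noise(models, subset_features(feats, models$feature_names),
                      energy = energy)
  m <- adapt_inhalation_model(m, feats)
  lab <- classify_frames(m, feats)
  lab <- smooth_labels(lab, smooth_order)
  events <- form_events(lab, step_s = step_s, frame_len_s = frame_len_s,
                        min_frames = min_frames)
  list(labels = lab, frame_times = fm$start_times, events = events,
       features = feats)
}

#' Serialise a model set to JSON
#' @param models a `class_model_set`.
#' @param path output path.
#' @export
save_models <- function(models, path) {
  stopifnot(inherits(models, "class_model_set"))
  doc <- list(feature_names = models$feature_names,
              lambda = models$lambda,
              models = lapply(models$models, function(m) {
                list(class_id = m$class_id, mean = m$mean,
                     cov = m$cov, prior = m$prior)
              }))
  jsonlite::write_json(doc, path, digits = NA, auto_unbox = TRUE)
  invisible(path)
}

#' Load a model set from JSON
#' @param path path written by [save_models()].
#' @return a `class_model_set`.
#' @export
load_models <- function(path) {
  doc <- jsonlite::read_json(path, simplifyVector = FALSE)
  feature_names <- unlist(doc$feature_names)
  d <- length(feature_names)
  models <- lapply(doc$models, function(m) {
    covm <- t(vapply(m$cov, function(row) unlist(row), numeric(d)))
    list(class_id = as.integer(m$class_id),
         mean = stats::setNames(unlist(m$mean), feature_names),
         cov = covm,
         prior = as.numeric(m$prior))
  })
  structure(list(models = models, feature_names = feature_names,
                 lambda = as.numeric(doc$lambda)),
            class = "class_model_set")
}
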