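make_feature_matrix <- function(X) {
  structure(list(values = X, names = colnames(X),
                 frame_times = seq_len(nrow(X))),
            class = "feature_matrix")
}

gaussian_training_set <- function(n = 500, d = 2, seed = 1) {
  set.seed(seed)
  means <- matrix(c(0, 0, 5, 0, 0, 5, 5, 5), 4, d, byrow = TRUE)
  X <- do.call(rbind, lapply(1:4, function(w)
    sweep(matrix(rnorm(n * d), n, d), 2, means[w, ], "+")))
  colnames(X) <- paste0("f", seq_len(d))
  list(fm = make_feature_matrix(X), labels = rep(1:4, each = n),
       means = means)
}

test_that("training recovers class means, priors and PD covariances", {
  ts <- gaussian_training_set()
  m <- train_event_models(ts$fm, ts$labels)
  for (w in 1:4) {
    expect_lt(max(abs(m$models[[w]]$mean - ts$means[w, ])), 0.1)
    expect_silent(chol(m$models[[w]]$cov))
  }
  # priors from frame frequencies
  labs <- rep(1:4, times = c(100, 300, 100, 500))
  set.seed(2)
  X <- matrix(rnorm(1000 * 2), 1000, 2) + labs
  colnames(X) <- c("f1", "f2")
  m2 <- train_event_models(make_feature_matrix(X), labs)
  expect_equal(vapply(m2$models, `[[`, 0, "prior"),
               c(0.1, 0.3, 0.1, 0.5))
  # duplicated (singular) feature still yields a PD covariance
  Xd <- cbind(f1 = rnorm(400), f2 = 0)
  Xd[, 2] <- Xd[, 1]
  colnames(Xd) <- c("f1", "f2")
  m3 <- train_event_models(make_feature_matrix(Xd), rep(1:4, each = 100))
  for (w in 1:4) expect_silent(chol(m3$models[[w]]$cov))
  # class with too few frames is named in the error
  expect_error(train_event_models(ts$fm, c(rep(1, 3),
                                           rep(2:4, length.out = 1997))),
               "noise")
})

test_that("noise estimation uses exactly the lowest 40% energy frames", {
  ts <- gaussian_training_set(n = 50, seed = 3)
  m <- train_event_models(ts$fm, ts$labels)
  # strictly increasing energies over 20 frames -> frames 1-8 selected
  set.seed(4)
  X <- matrix(rnorm(40), 20, 2)
  colnames(X) <- c("f1", "f2")
  fm <- make_feature_matrix(X)
  m2 <- estimate_noise(m, fm, energy = 1:20)
  expect_equal(m2$models[[1]]$mean, colMeans(X[1:8, ]))
  # other classes and all priors untouched
  for (w in 2:4) expect_equal(m2$models[[w]], m$models[[w]])
  expect_equal(vapply(m2$models, `[[`, 0, "prior"),
               vapply(m$models, `[[`, 0, "prior"))
  # too-short recording: unchanged with a warning
  expect_warning(m3 <- estimate_noise(m, make_feature_matrix(X[1:10, ]),
                                      energy = 1:10),
                 "13 frames")
  expect_equal(m3, m)
})

test_that("noise adaptation on pure background matches the full-frame mean", {
  ts <- gaussian_training_set(seed = 5)
  m <- train_event_models(ts$fm, ts$labels)
  set.seed(6)
  n <- 500
  Xn <- matrix(rnorm(n * 2, mean = 0.5), n, 2)  # stationary background
  colnames(Xn) <- c("f1", "f2")
  # energy independent of the features (stationary backgrounds vary in
  # level, not content), so the lowest-40% subset is an unbiased sample
  energy <- runif(n)
  m2 <- estimate_noise(m, make_feature_matrix(Xn), energy = energy)
  tol <- 2.5 / sqrt(0.4 * n)  # ~2.5 SD of the subset mean
  expect_lt(max(abs(m2$models[[1]]$mean - colMeans(Xn))), tol)
})

test_that("nearest-mean classification matches brute force with low-id ties", {
  ts <- gaussian_training_set(seed = 7)
  m <- train_event_models(ts$fm, ts$labels)
  # d = 1 intuition via a 1-column model set
  X1 <- matrix(c(12), 1, 1, dimnames = list(NULL, "f1"))
  m1 <- m
  for (w in 1:4) {
    m1$models[[w]]$mean <- c(f1 = c(0, 10, 20, 30)[w])
    m1$models[[w]]$cov <- matrix(1, 1, 1)
  }
  m1$feature_names <- "f1"
  expect_equal(initial_classify_euclidean(m1, make_feature_matrix(X1)), 2L)
  # exact tie between classes 2 (mean 10) and 3 (mean 20) at x = 15
  expect_equal(initial_classify_euclidean(
    m1, make_feature_matrix(matrix(15, 1, 1,
                                   dimnames = list(NULL, "f1")))), 2L)
  # brute-force oracle on random frames
  set.seed(8)
  X <- matrix(rnorm(400, 2, 4), 200, 2)
  colnames(X) <- c("f1", "f2")
  D2 <- vapply(m$models, function(mm) colSums((t(X) - mm$mean)^2),
               numeric(200))
  expect_equal(initial_classify_euclidean(m, make_feature_matrix(X)),
               max.col(-D2, ties.method = "first"))
})

test_that("inhalation adaptation averages the trained and observed means", {
  ts <- gaussian_training_set(seed = 9)
  m <- train_event_models(ts$fm, ts$labels)
  mu3 <- m$models[[3]]$mean
  delta <- c(0.4, -0.3)
  # frames tightly clustered at mu3 + delta classify as inhalation
  X <- sweep(matrix(rnorm(400, 0, 0.05), 200, 2), 2, mu3 + delta, "+")
  colnames(X) <- c("f1", "f2")
  fm <- make_feature_matrix(X)
  m2 <- adapt_inhalation_model(m, fm)
  expect_equal(m2$models[[3]]$mean, mu3 + delta / 2, tolerance = 0.02)
  expect_equal(m2$models[[3]]$cov, m$models[[3]]$cov)
  expect_equal(m2$models[[2]], m$models[[2]])
  # adaptation moves the mean strictly toward the recording centroid
  cen <- colMeans(X)
  expect_lt(sqrt(sum((m2$models[[3]]$mean - cen)^2)),
            sqrt(sum((mu3 - cen)^2)))
  # second application halves the remaining gap again (non-idempotent)
  m3 <- adapt_inhalation_model(m2, fm)
  gap2 <- m2$models[[3]]$mean - colMeans(X[
    initial_classify_euclidean(m2, fm) == 3, , drop = FALSE])
  expect_equal(m3$models[[3]]$mean, m2$models[[3]]$mean - gap2 / 2,
               tolerance = 1e-10)
  # no inhalation-like frames: unchanged with warning
  Xfar <- sweep(matrix(rnorm(100, 0, 0.01), 50, 2), 2,
                m$models[[1]]$mean, "+")
  colnames(Xfar) <- c("f1", "f2")
  expect_warning(m4 <- adapt_inhalation_model(m, make_feature_matrix(Xfar)),
                 "skipped")
  expect_equal(m4, m)
})

test_that("QDA equals brute-force density argmax and its LDA limit", {
  # equal priors + shared spherical covariance -> nearest mean
  ts <- gaussian_training_set(seed = 10)
  m <- train_event_models(ts$fm, ts$labels)
  for (w in 1:4) {
    m$models[[w]]$cov <- diag(2)
    m$models[[w]]$prior <- 0.25
  }
  set.seed(11)
  X <- matrix(rnorm(600, 2, 4), 300, 2)
  colnames(X) <- c("f1", "f2")
  fm <- make_feature_matrix(X)
  expect_equal(classify_frames(m, fm), initial_classify_euclidean(m, fm))
  # d = 1, N(0,1) vs N(0,9): at x = 0 the tighter class wins
  m1 <- m
  m1$feature_names <- "f1"
  for (w in 1:4) {
    m1$models[[w]]$mean <- c(f1 = 0)
    m1$models[[w]]$cov <- matrix(c(1, 9, 1e6, 1e6)[w], 1, 1)
    m1$models[[w]]$prior <- 0.25
  }
  X0 <- matrix(0, 1, 1, dimnames = list(NULL, "f1"))
  expect_equal(classify_frames(m1, make_feature_matrix(X0)), 1L)
  # brute-force oracle, d = 3, unequal covariances and priors
  set.seed(12)
  d <- 3
  m3 <- list(models = lapply(1:4, function(w) {
    A <- matrix(rnorm(d * d), d)
    list(class_id = w, mean = setNames(rnorm(d, w), paste0("f", 1:d)),
         cov = crossprod(A) + diag(d) * 0.5, prior = c(0.4, 0.3, 0.2, 0.1)[w])
  }), feature_names = paste0("f", 1:d), lambda = 1e-6)
  class(m3) <- "class_model_set"
  Xr <- matrix(rnorm(200 * d, 1, 2), 200, d)
  colnames(Xr) <- paste0("f", 1:d)
  dens <- vapply(m3$models, function(mm) {
    vapply(seq_len(nrow(Xr)), function(i) {
      xc <- Xr[i, ] - mm$mean
      (2 * pi)^(-d / 2) * det(mm$cov)^(-0.5) *
        exp(-0.5 * xc %*% solve(mm$cov, xc)) * mm$prior
    }, numeric(1))
  }, numeric(nrow(Xr)))
  expect_equal(classify_frames(m3, make_feature_matrix(Xr)),
               max.col(dens, ties.method = "first"))
})

test_that("QDA agrees with MASS::qda on separable training data", {
  ts <- gaussian_training_set(n = 300, seed = 13)
  m <- train_event_models(ts$fm, ts$labels, lambda = 0)
  fit <- MASS::qda(ts$fm$values, factor(ts$labels))
  set.seed(14)
  Xn <- matrix(rnorm(800, 2.5, 3), 400, 2)
  colnames(Xn) <- c("f1", "f2")
  ref <- as.integer(predict(fit, Xn)$class)
  expect_equal(classify_frames(m, make_feature_matrix(Xn)), ref)
})

test_that("median smoothing removes islands without inventing classes", {
  expect_equal(smooth_labels(c(3, 3, 4, 3, 3), 5), rep(3L, 5))
  expect_equal(smooth_labels(rep(2L, 10), 5), rep(2L, 10))
  # a 3-frame run survives an order-5 median at its centre
  x <- c(1, 1, 1, 4, 4, 4, 1, 1, 1)
  expect_equal(smooth_labels(x, 5)[5], 4L)
  expect_error(smooth_labels(1:5, 4), "odd")
  set.seed(15)
  for (i in 1:20) {
    lab <- sample(1:4, 60, replace = TRUE)
    sm <- smooth_labels(lab, 5)
    padded <- c(rep(lab[1], 2), lab, rep(lab[60], 2))
    for (j in seq_along(sm)) {
      expect_true(sm[j] %in% padded[j:(j + 4)])
    }
  }
})

test_that("event formation enforces the 5-frame rule except for actuation", {
  lab4 <- c(rep(1, 5), rep(3, 4), rep(1, 5))
  expect_equal(nrow(form_events(lab4)), 0L)
  lab5 <- c(rep(1, 5), rep(3, 5), rep(1, 5))
  ev <- form_events(lab5)
  expect_equal(nrow(ev), 1L)
  expect_equal(ev$class, 3L)
  expect_equal(ev$end_s - ev$start_s, 4 * 0.02 + 0.04)
  act <- c(rep(1, 5), rep(4, 2), rep(1, 5))
  eva <- form_events(act)
  expect_equal(nrow(eva), 1L)
  expect_equal(eva$class, 4L)
})

test_that("classify_recording finds the programmed event sequence", {
  models <- get_trained_models()
  sc <- synth_scenario(pifr = 200, snr_db = 20, seed = 77)
  rec <- synth_recording(sc)
  out <- classify_recording(rec$sig, models)
  fm <- frame_signal(bandpass(rec$sig, 140, 22000), 0.04, 0.02)
  truth <- form_events(labels_to_frames(rec$labels, fm), min_frames = 5L)
  # one matching predicted event per truth event, onset within 3 steps
  for (i in seq_len(nrow(truth))) {
    same <- out$events[out$events$class == truth$class[i], , drop = FALSE]
    expect_gt(nrow(same), 0)
    onset_err <- min(abs(same$start_s - truth$start_s[i]))
    expect_lte(onset_err, 3 * 0.02 + 1e-9)
  }
  # detected classes cover exhalation, inhalation and actuation
  expect_setequal(unique(out$events$class), c(2L, 3L, 4L))
  # determinism
  out2 <- classify_recording(rec$sig, models)
  expect_identical(out$labels, out2$labels)
  # pure background noise yields no events
  noise_only <- audio_signal(rnorm(48000 * 3, 0, 0.002), 48000)
  out3 <- classify_recording(noise_only, models)
  expect_equal(nrow(out3$events), 0L)
})

test_that("model sets survive a JSON round trip", {
  ts <- gaussian_training_set(n = 100, seed = 16)
  m <- train_event_models(ts$fm, ts$labels)
  path <- withr::local_tempfile(fileext = ".json")
  save_models(m, path)
  m2 <- load_models(path)
  expect_equal(m2$feature_names, m$feature_names)
  set.seed(17)
  X <- matrix(rnorm(100, 2, 3), 50, 2)
  colnames(X) <- c("f1", "f2")
  expect_identical(classify_frames(m, make_feature_matrix(X)),
                   classify_frames(m2, make_feature_matrix(X)))
})
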