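test_that("flow pre-processing decimates to fs/4 with 50/25 ms frames", {
  fm <- preprocess_flow(tone_signal(1000, dur = 1))
  expect_equal(fm$fs, 12000)
  expect_equal(ncol(fm$frames), 600L)
  # 1 kHz tone preserved within 10% (window-corrected RMS)
  win_rms <- sqrt(mean(hanning_window(600)^2))
  expect_equal(mean(sqrt(rowMeans(fm$frames^2))) / win_rms, sqrt(0.5),
               tolerance = 0.1)
  # 5.9 kHz tone killed by anti-aliasing + band edge
  fm59 <- preprocess_flow(tone_signal(5900, dur = 1))
  expect_lt(mean(sqrt(rowMeans(fm59$frames^2))), 0.1 * sqrt(0.5))
  expect_error(preprocess_flow(audio_signal(rnorm(100), 48000)),
               "shorter")
})

test_that("reed fundamental is estimated to within 2 Hz", {
  expect_equal(estimate_f0(tone_signal(540))$f0, 540, tolerance = 2 / 540)
  expect_equal(estimate_f0(tone_signal(555))$f0, 555, tolerance = 2 / 555)
  est <- estimate_f0(white_noise_signal(seed = 40))
  expect_false(est$reed_detected)
  expect_true(is.na(est$f0))
  expect_error(estimate_f0(audio_signal(rnorm(1000), 48000)), "100 ms")
})

test_that("harmonic band powers satisfy Parseval and band exclusion", {
  fs <- 12000
  t <- (0:599) / fs
  A <- 0.02
  hp <- harmonic_powers(A * sin(2 * pi * 540 * t), fs, 540)
  expect_equal(unname(hp["P_f0"]), A^2 / 2, tolerance = 0.1)
  two <- A * sin(2 * pi * 540 * t) + A * sin(2 * pi * 1080 * t + 1)
  hp2 <- harmonic_powers(two, fs, 540)
  expect_equal(unname(hp2["P_f0f1"] / hp2["P_f0"]), 2, tolerance = 0.1)
  # a 4*f0 tone contributes nothing: higher harmonics are excluded
  high <- A * sin(2 * pi * 4 * 540 * t)
  hp3 <- harmonic_powers(high, fs, 540)
  expect_lt(unname(hp3["P_f0f1"]), 0.01 * A^2 / 2)
})

test_that("flow-model fitting recovers known coefficients", {
  phi <- exp(seq(-12, -6, length.out = 20))
  f <- exp(0.3 * log(phi) + 7)
  m <- fit_flow_model(phi, f, "power")
  expect_equal(unname(m$coef[["gamma"]]), 0.3, tolerance = 1e-9)
  expect_equal(unname(m$coef[["delta"]]), 7, tolerance = 1e-9)
  expect_equal(m$r2, 1)
  # noisy recovery at n = 80
  set.seed(41)
  phi2 <- exp(runif(80, -12, -6))
  f2 <- exp(0.3 * log(phi2) + 7 + rnorm(80, 0, 0.05))
  m2 <- fit_flow_model(phi2, f2, "power")
  expect_equal(unname(m2$coef[["gamma"]]), 0.3, tolerance = 0.02 / 0.3)
  # linear fit on an exact line
  ml <- fit_flow_model(1:10, 2 * (1:10) + 5, "linear")
  expect_equal(unname(ml$coef), c(2, 5), tolerance = 1e-9)
  expect_error(fit_flow_model(c(-1, 1, 2), c(10, 20, 30), "power"),
               "positive")
  expect_error(fit_flow_model(1:2, 1:2, "linear"), "3 points")
})

test_that("power-law fits are scale-equivariant in the feature", {
  set.seed(42)
  phi <- exp(runif(30, -12, -6))
  f <- exp(0.32 * log(phi) + 7.4 + rnorm(30, 0, 0.02))
  m1 <- fit_flow_model(phi, f, "power")
  cc <- 3.7
  m2 <- fit_flow_model(cc * phi, f, "power")
  expect_equal(m2$coef[["gamma"]], m1$coef[["gamma"]], tolerance = 1e-9)
  expect_equal(m2$coef[["delta"]],
               m1$coef[["delta"]] - m1$coef[["gamma"]] * log(cc),
               tolerance = 1e-9)
})

test_that("the default power model maps band power to plausible flows", {
  m <- default_flow_model()
  expect_equal(predict_flow(m, 2.2e-5), 59.9, tolerance = 0.005)
  expect_equal(predict_flow(m, 1), exp(7.5061), tolerance = 1e-9)
  # monotone increasing in the feature
  phis <- sort(exp(runif(20, -14, -4)))
  expect_true(all(diff(predict_flow(m, phis)) > 0))
})

test_that("flow profiles and volumes follow closed forms", {
  # constant 60 L/min for 2 s -> exactly 2 L
  prof <- structure(list(times = seq(0, 2, 0.025),
                         flows = rep(60, 81), pifr = 60,
                         volume = NA_real_), class = "flow_profile")
  expect_equal(estimate_volume(prof), 2.0, tolerance = 1e-12)
  # triangle peaking at 120 over 2 s -> 2 L within trapezoid error
  tt <- seq(0, 2, 0.025)
  tri <- structure(list(times = tt,
                        flows = 120 * (1 - abs(tt - 1)), pifr = 120,
                        volume = NA_real_), class = "flow_profile")
  expect_equal(estimate_volume(tri), 2.0, tolerance = 0.01)
  zero <- structure(list(times = tt, flows = rep(0, length(tt)),
                         pifr = 0, volume = NA_real_),
                    class = "flow_profile")
  expect_equal(estimate_volume(zero), 0)
  expect_error(estimate_volume(structure(list(times = 1, flows = 1),
                                         class = "flow_profile")),
               "2 frames")
  # independent trapezoid oracle at double resolution
  set.seed(43)
  f_of_t <- function(t) 100 * sin(pi * t / 2)^2
  coarse <- structure(list(times = seq(0, 2, 0.025),
                           flows = f_of_t(seq(0, 2, 0.025)), pifr = 100,
                           volume = NA_real_), class = "flow_profile")
  fine_t <- seq(0, 2, 0.0125)
  oracle <- sum(diff(fine_t) *
                  (head(f_of_t(fine_t), -1) + tail(f_of_t(fine_t), -1)) /
                  2) / 60
  expect_equal(estimate_volume(coarse), oracle, tolerance = 0.02)
})

test_that("estimated flow profiles track the programmed shape", {
  prof <- flow_profile(120, 2.0)
  inh <- synth_inhalation(prof, f0 = 540, fs = 48000, seed = 44)
  ff <- extract_flow_features(inh$sig)
  est <- estimate_flow_profile(ff)
  # peak of the estimated profile falls on the programmed plateau
  # (flow = PIFR there, so any plateau frame is a valid peak), +/- 2 frames
  plateau <- range(prof$times[prof$flows >= 0.999 * 120])
  t_peak_est <- est$times[which.max(est$flows)]
  expect_gte(t_peak_est, plateau[1] - 2 * 0.025)
  expect_lte(t_peak_est, plateau[2] + 2 * 0.025)
  expect_true(all(est$flows >= 0))
  expect_equal(est$pifr, est$flows[which.max(ff$P_f0)])
  # constant-feature segment gives a constant profile
  expect_lt(diff(range(est$flows[est$times >= plateau[1] + 0.1 &
                                   est$times <= plateau[2] - 0.1])) /
              max(est$flows), 0.15)
  # silence -> all-zero profile
  quiet <- audio_signal(rep(0, 48000), 48000)
  ffq <- suppressWarnings(extract_flow_features(quiet))
  estq <- estimate_flow_profile(ffq)
  expect_true(all(estq$flows == 0))
})

test_that("accuracy follows 100*(1 - relative error) floored at zero", {
  expect_equal(flow_accuracy(120, 120), 100)
  expect_equal(flow_accuracy(108, 120), 90)
  expect_equal(flow_accuracy(0, 120), 0)
  expect_equal(flow_accuracy(300, 120), 0)  # floor, not negative
  expect_error(flow_accuracy(10, 0), "positive")
})

test_that("added noise hits the requested SNR and is seed-reproducible", {
  sig <- tone_signal(540, dur = 0.5)
  noisy <- add_noise_snr(sig, 0, seed = 50)
  noise <- noisy$samples - sig$samples
  snr <- 10 * log10(mean(sig$samples^2) / mean(noise^2))
  expect_equal(snr, 0, tolerance = 0.1)
  n25 <- add_noise_snr(sig, 25, seed = 51)$samples - sig$samples
  nm10 <- add_noise_snr(sig, -10, seed = 51)$samples - sig$samples
  expect_equal(sqrt(mean(nm10^2)) / sqrt(mean(n25^2)), 10^(35 / 20),
               tolerance = 0.02)
  expect_identical(add_noise_snr(sig, 5, seed = 52)$samples,
                   add_noise_snr(sig, 5, seed = 52)$samples)
  expect_error(add_noise_snr(audio_signal(rep(0, 100), 48000), 10),
               "silent")
})

test_that("an SNR sweep on an empty grid returns an empty table", {
  out <- snr_sweep(list(), list(), snr_grid = numeric(0))
  expect_equal(nrow(out), 0L)
  expect_named(out, c("snr_db", "feature", "metric", "mean", "se"))
})

test_that("accuracy is monotone non-increasing as SNR drops", {
  val <- make_inhalation_set(c(70, 130, 190), seed0 = 520)
  models <- fit_feature_models(make_inhalation_set(c(50, 90, 150, 210),
                                                   seed0 = 510))
  sw <- snr_sweep(val, models, snr_grid = c(25, 5, -10), seed = 3)
  for (feat in c("E", "P_f0f1")) {
    acc <- sw[sw$feature == feat & sw$metric == "pifr", ]
    acc <- acc[order(acc$snr_db, decreasing = TRUE), "mean"]
    expect_true(all(diff(acc) <= 2))  # allow small Monte-Carlo jitter
  }
})

test_that("Bland-Altman statistics match their definitions", {
  expect_equal(bland_altman_stats(1:10, 1:10),
               list(bias = 0, sd = 0, loa = c(0, 0)))
  ba <- bland_altman_stats((1:10) + 2, 1:10)
  expect_equal(ba$bias, 2)
  expect_equal(ba$sd, 0)
  set.seed(53)
  ref <- runif(500, 50, 200)
  est <- ref + rnorm(500, 2.6, 5)
  ba2 <- bland_altman_stats(est, ref)
  expect_equal(ba2$bias, 2.6, tolerance = 0.25)
  expect_equal(ba2$loa[2] - ba2$loa[1], 2 * 1.96 * 5, tolerance = 1)
  expect_error(bland_altman_stats(1:3, 1:4), "paired")
})

test_that("synthetic inhalations round-trip the programmed PIFR", {
  # inverse power law in, power law out: errors only from the signal path
  for (p in c(60, 110, 200)) {
    prof <- flow_profile(p, 2.0)
    inh <- synth_inhalation(prof, f0 = 540, fs = 48000, seed = p)
    noisy <- add_noise_snr(inh$sig, 15, seed = p + 1)
    est <- estimate_pifr(extract_flow_features(noisy))
    expect_true(est$measurable)
    expect_equal(est$pifr, p, tolerance = 0.1)
  }
})
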