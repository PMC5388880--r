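mk_rec <- function(x, fs = 1000) lfp_recording(x, fs)

test_that("modulation index reproduces its analytic values", {
  n <- 6000
  ph <- seq(0, 2 * pi * 12, length.out = n + 1)[1:n]  # whole cycles
  expect_lt(modulation_index(ph, rep(1, n)), 1e-10)
  expect_equal(modulation_index(ph, 1 + cos(ph)), 0.5, tolerance = 1e-6)
  # 1-homogeneous in amplitude
  expect_equal(modulation_index(ph, 3.7 * (1 + cos(ph))), 3.7 * 0.5,
               tolerance = 1e-6)
  # bounded by the mean amplitude
  set.seed(1)
  a <- abs(rnorm(n)); p <- runif(n, -pi, pi)
  expect_lte(modulation_index(p, a), mean(a))
  expect_error(modulation_index(p, a[-1]), "length")
})

test_that("band phase advances at the carrier frequency", {
  fs <- 1000; t <- (0:29999) / fs
  rec <- mk_rec(cos(2 * pi * 6 * t))
  ph <- band_phase(rec, c(5.5, 6.5))
  v <- pac_valid(ph)
  slope <- mean(diff(unwrap_phase <- cumsum(c(v[1], atan2(
    sin(diff(v)), cos(diff(v))))))) * fs / (2 * pi)
  expect_lt(abs(slope - 6) / 6, 0.005)
  # phase of -cos is phase of cos shifted by pi
  ph2 <- pac_valid(band_phase(mk_rec(-cos(2 * pi * 6 * t)), c(5.5, 6.5)))
  d <- atan2(sin(ph2 - v), cos(ph2 - v))
  expect_lt(max(abs(abs(d) - pi)), 0.01)
})

test_that("band amplitude recovers a pure tone and the coupled envelope", {
  fs <- 1000; t <- (0:19999) / fs
  rec <- mk_rec(2.5 * cos(2 * pi * 80 * t))
  env <- pac_valid(band_amplitude(rec, c(78, 82)))
  expect_lt(max(abs(env - 2.5)) / 2.5, 0.01)
  expect_equal(pac_valid(band_amplitude(mk_rec(rep(0, 20000)), c(78, 82))),
               rep(0, length(pac_valid(band_amplitude(mk_rec(rep(0, 20000)),
                                                      c(78, 82))))))
  # clean generated PAC signal: envelope matches the ground truth
  cfg <- pac_signal_config(sampling_rate = 1000, duration = 30,
                           coupling_depth = 0.6, noise_white_sd = 0,
                           noise_pink_sd = 0, gamma_jitter_sd = 0, seed = 2)
  sig <- generate_pac_signal(cfg, return_components = TRUE)
  env2 <- band_amplitude(sig$recording, c(60, 100), cycles = 15)
  e <- attr(env2, "edge")
  v <- pac_valid(env2)
  tru <- sig$components$envelope[(e + 1):(length(env2) - e)]
  expect_lt(max(abs(v - tru) / tru), 0.02)
})

test_that("zero-phase filtering has no group delay (impulse test)", {
  x <- rep(0, 4000); x[2000] <- 1
  h <- neurovasc:::.fir_bandpass(1000, 30, 50)
  y <- neurovasc:::.fir_filtfilt(x, h)
  expect_equal(which.max(abs(y)), 2000)
  # symmetric response around the impulse
  expect_equal(y[2000 + 1:100], y[2000 - 1:100], tolerance = 1e-10)
})

test_that("preprocessing preserves the passband and rejects fast tones", {
  fs <- 20000; t <- (0:199999) / fs
  rec <- mk_rec(cos(2 * pi * 6 * t), fs)
  out <- preprocess_lfp(rec)
  expect_equal(out$sampling_rate, 1000)
  expect_lt(abs(max(abs(out$samples[2000:8000])) - 1), 0.01)
  # a 5 kHz tone is attenuated by more than 40 dB
  rec2 <- mk_rec(cos(2 * pi * 5000 * t), fs)
  h <- neurovasc:::.fir_lowpass(fs, 500)
  y <- neurovasc:::.fir_filtfilt(rec2$samples, h)
  expect_lt(max(abs(y[50000:150000])), 10^(-40 / 20))
  expect_warning(preprocess_lfp(mk_rec(rnorm(60000), 800)), "skipped")
})

test_that("surrogates are seeded, reproducible, and fft equals direct", {
  set.seed(3)
  n <- 30000
  p <- runif(n, -pi, pi); a <- abs(rnorm(n))
  s1 <- surrogate_mi(p, a, 25, seed = 7, method = "fft")
  s2 <- surrogate_mi(p, a, 25, seed = 7, method = "direct")
  expect_equal(as.numeric(s1), as.numeric(s2), tolerance = 1e-12)
  s3 <- surrogate_mi(p, a, 25, seed = 7)
  expect_identical(as.numeric(s1), as.numeric(s3))
  expect_error(surrogate_mi(p, a, 1), "at least 2")
  offs <- attr(s1, "offsets")
  expect_true(all(offs >= 0.1 * n & offs <= 0.9 * n))
})

test_that("a strongly coupled signal beats all its surrogates", {
  cfg <- pac_signal_config(sampling_rate = 1000, duration = 60,
                           coupling_depth = 0.8, noise_white_sd = 0.2,
                           noise_pink_sd = 0.2, seed = 4)
  sig <- generate_pac_signal(cfg)
  ph <- band_phase(sig$recording, c(5, 7))
  am <- band_amplitude(sig$recording, c(70, 90))
  edge <- max(attr(ph, "edge"), attr(am, "edge"))
  np <- length(ph)
  p <- ph[(edge + 1):(np - edge)]; a <- am[(edge + 1):(np - edge)]
  mi <- modulation_index(p, a)
  su <- surrogate_mi(p, a, 50, seed = 5)
  expect_true(all(mi > su))
})

test_that("surrogate z is invariant to amplitude scaling", {
  set.seed(6)
  n <- 20000
  p <- runif(n, -pi, pi); a <- abs(rnorm(n)) + 0.2
  z_of <- function(a) {
    mi <- modulation_index(p, a)
    s <- surrogate_mi(p, a, 40, seed = 9)
    (mi - mean(s)) / sd(s)
  }
  expect_equal(z_of(a), z_of(100 * a), tolerance = 1e-8)
})

test_that("band grid validates edges and builds the default bins", {
  g <- band_grid()
  expect_equal(nrow(g$phase_bands), 4)
  expect_equal(nrow(g$amplitude_bands), 27)
  expect_equal(g$amplitude_bands[1, ], c(low = 30, high = 34))
  expect_equal(g$amplitude_bands[27, ], c(low = 134, high = 138))
  expect_error(band_grid(phase_edges = c(4, 4)), "increasing")
})

test_that("comodulogram localizes strong coupling and flags it significant", {
  cfg <- pac_signal_config(sampling_rate = 1000, duration = 120,
                           coupling_depth = 0.8, seed = 8)
  cm <- comodulogram(generate_pac_signal(cfg)$recording, seed = 9)
  expect_true(all(cm$raw_mi >= 0))
  pk <- comodulogram_peak(cm)
  expect_true(peak_contains(pk, 6, 80))
  expect_true(pk$significant)
  # rerun with the same seed is identical
  cm2 <- comodulogram(generate_pac_signal(cfg)$recording, seed = 9)
  expect_identical(cm$z_mi, cm2$z_mi)
})

test_that("cohort summary orders groups by coupling strength", {
  mk <- function(m, s) {
    cfg <- pac_signal_config(sampling_rate = 1000, duration = 60,
                             coupling_depth = m, seed = s)
    comodulogram(generate_pac_signal(cfg, genotype = ifelse(m > 0.5,
                                                            "high", "low"))$
                   recording, seed = s + 1, min_duration = 60)
  }
  cms <- list(mk(0.8, 11), mk(0.8, 12), mk(0.2, 13), mk(0.2, 14))
  su <- cohort_mi_summary(cms)
  expect_gt(su$mean[su$group == "high"], su$mean[su$group == "low"])
  expect_equal(su$n_electrodes, c(2L, 2L))
  one <- cohort_mi_summary(cms[1], groups = "solo")
  expect_true(is.na(one$sem))
  identical_two <- cohort_mi_summary(list(cms[[1]], cms[[1]]),
                                     groups = c("g", "g"))
  expect_equal(identical_two$sem, 0)
})
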