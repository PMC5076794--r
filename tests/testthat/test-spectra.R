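test_that("synthesized FIDs put each peak at its frequency with seeded noise", {
  one <- spectrum_model(data.frame(name = "p", offset_hz = -900,
                                   amplitude = 1, damping_hz = 20,
                                   phase_rad = 0))
  fid <- synthesize_fid(one, n_points = 2048, bandwidth = 6000)
  sp <- fid_spectrum(fid)
  expect_equal(sp$freq_hz[which.max(Mod(sp$spectrum))], -900,
               tolerance = 3)   # within one 2.9 Hz bin
  # same seed reproduces the noise; different seeds share the clean part
  f1 <- synthesize_fid(one, noise_sd = 0.1, seed = 4)
  f2 <- synthesize_fid(one, noise_sd = 0.1, seed = 4)
  f3 <- synthesize_fid(one, noise_sd = 0.1, seed = 5)
  expect_identical(f1$samples, f2$samples)
  expect_false(identical(f1$samples, f3$samples))
  f0 <- synthesize_fid(one)
  expect_equal(f1$samples - f0$samples != f3$samples - f0$samples,
               rep(TRUE, 2048))
  expect_warning(synthesize_fid(spectrum_model(data.frame(
    name = "x", offset_hz = 4000, amplitude = 1, damping_hz = 20,
    phase_rad = 0))), "alias")
})

test_that("noise calibration reproduces the requested amplitude SNR", {
  mod <- default_31p_model()
  for (snr in c(18, 31, 44)) {
    ns <- noise_sd_for_snr(mod, snr)
    got <- vapply(1:60, function(s) {
      f <- synthesize_fid(mod, noise_sd = ns, seed = s)
      max(Mod(stats::fft(f$samples))) / (ns * sqrt(f$n_points))
    }, numeric(1))
    expect_rel_equal(mean(got), snr, 0.05)
  }
})

test_that("prior-knowledge fitting recovers a noiseless spectrum exactly", {
  mod <- default_31p_model()
  fid <- synthesize_fid(mod, n_points = 1024)
  prior <- mod
  prior$peaks$amplitude <- prior$peaks$amplitude * 1.4
  prior$peaks$offset_hz <- prior$peaks$offset_hz + 4
  prior$peaks$phase_rad <- 0.25
  fit <- fit_amares(fid, prior)
  expect_lt(fit$residual_energy, 1e-8)
  expect_equal(fit$model$peaks$offset_hz, mod$peaks$offset_hz,
               tolerance = 1e-6)
  expect_equal(fit$model$peaks$amplitude, mod$peaks$amplitude,
               tolerance = 1e-6)
  expect_equal(fit$model$peaks$phase_rad, mod$peaks$phase_rad,
               tolerance = 1e-6)
  # multiplet structure is honored: fitted CRLB table has one row per group
  expect_equal(nrow(fit$crlb), 4L)
})

test_that("fit is invariant to the ordering of prior peaks", {
  mod <- default_31p_model()
  fid <- synthesize_fid(mod, n_points = 512, noise_sd = 0.02, seed = 8)
  f1 <- fit_amares(fid, mod)
  swapped <- spectrum_model(mod$peaks[c(3, 1, 4, 2), ])
  f2 <- fit_amares(fid, swapped)
  o1 <- f1$model$peaks[order(f1$model$peaks$offset_hz), ]
  o2 <- f2$model$peaks[order(f2$model$peaks$offset_hz), ]
  expect_equal(o1$offset_hz, o2$offset_hz, tolerance = 1e-6)
  # phases are near zero; compare absolutely at the solver tolerance
  expect_lt(max(abs(o1$phase_rad - o2$phase_rad)), 1e-6)
})

test_that("partial saturation has its closed-form limits and Ernst maximum", {
  # fully relaxed limit
  expect_equal(saturation_signal(40, tr = 100, t1 = 1, m0 = 2),
               2 * sin(40 * pi / 180), tolerance = 1e-9)
  # theta = 90, TR = T1
  expect_equal(saturation_signal(90, 3, 3), 1 - exp(-1), tolerance = 1e-12)
  # numeric argmax equals the Ernst angle acos(exp(-TR/T1))
  tr <- 0.5; t1 <- 3.09
  th <- seq(1, 179, by = 0.01)
  ernst <- th[which.max(saturation_signal(th, tr, t1))]
  expect_equal(ernst, acos(exp(-tr / t1)) * 180 / pi, tolerance = 0.01)
  # monotone increasing in TR below 90 degrees
  s <- saturation_signal(45, c(0.5, 1, 2, 4, 8), 8.57)
  expect_true(all(diff(s) > 0))
  expect_error(saturation_signal(190, 1, 1), "theta")
})

test_that("multi-TR fitting recovers the generating flip angle", {
  trs <- c(0.5, 1, 2, 3, 4, 6, 8, 10); t1 <- 8.57; tp <- 300e-6
  sig <- saturation_signal(37.3, trs, t1, m0 = 2.7)
  fit <- fit_multi_tr(sig, trs, t1, tp = tp)
  expect_rel_equal(fit$theta_deg, 37.3, 1e-6)
  expect_rel_equal(fit$m0, 2.7, 1e-6)
  expect_rel_equal(fit$gamma_b1, b1_from_flip_angle(37.3, tp), 1e-6)
  # scale invariance: scaling the signals scales M0 only
  fit2 <- fit_multi_tr(3 * sig, trs, t1)
  expect_rel_equal(fit2$theta_deg, 37.3, 1e-6)
  expect_rel_equal(fit2$m0, 3 * 2.7, 1e-6)
  expect_error(fit_multi_tr(c(1, 1), c(2, 2), t1), "distinct")
  # 1 percent noise leaves the mean flip angle within 1 percent (the
  # phantom validation protocol)
  est <- vapply(1:100, function(s) {
    set.seed(s)
    fit_multi_tr(sig * (1 + stats::rnorm(8, 0, 0.01)), trs, t1)$theta_deg
  }, numeric(1))
  expect_rel_equal(mean(est), 37.3, 0.01)
})

test_that("dual-TR fitting inverts the saturation ratio", {
  t1 <- 1.8
  s1 <- saturation_signal(30, 2.2, t1); s2 <- saturation_signal(30, 0.37, t1)
  expect_rel_equal(fit_dual_tr(s1, s2, 2.2, 0.37, t1), 30, 1e-6)
  expect_error(fit_dual_tr(1, 1, 2, 2, t1), "differ")
  expect_error(fit_dual_tr(1, 100, 2.2, 0.37, t1), "attainable")
  # agreement with the multi-TR fit on the same noiseless two-TR data
  mt <- fit_multi_tr(c(s1, s2), c(2.2, 0.37), t1)
  expect_rel_equal(mt$theta_deg, 30, 1e-4)
})

test_that("multi-flip-angle calibration recovers B1-per-volt through the null", {
  tp <- 4e-3
  volts <- seq(10, 200, by = 10)
  cpv <- 0.9   # Hz per volt: max flip 259 degrees, well past the null
  amp <- 1.7 * sin(2 * pi * cpv * volts * tp)
  fit <- fit_multi_fa(amp, volts, tp)
  expect_rel_equal(fit$b1_per_volt, cpv, 1e-6)
  expect_rel_equal(fit$max_amplitude, 1.7, 1e-6)
  # predicted gamma*B1 is linear in voltage
  expect_equal(fit$gamma_b1_at(200), 2 * fit$gamma_b1_at(100))
  # complex amplitudes along a common phase axis work the same
  fitc <- fit_multi_fa(amp * exp(1i * 0.8), volts, tp)
  expect_rel_equal(fitc$b1_per_volt, cpv, 1e-6)
  # a sweep confined to small flips is flagged ill-conditioned
  expect_warning(fit_multi_fa(0.3 * sin(2 * pi * 0.02 * volts * tp),
                              volts, tp), "ill-conditioned")
})
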