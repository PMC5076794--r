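test_that("the linear phase model has the stated values and symmetries", {
  m <- bs_model(OPT_B_TILDE, 2000)
  expect_equal(bs_phase(0, m), 0)
  # closed-form evaluation at the representative cardiac amplitude
  expect_equal(bs_phase(277, m), pi * 277^2 * OPT_B_TILDE / 2000,
               tolerance = 1e-12)
  expect_equal(bs_phase(277, m), 0.15905, tolerance = 1e-4)
  # odd in the offset sign
  expect_equal(bs_phase(277, bs_model(OPT_B_TILDE, -2000)),
               -bs_phase(277, m))
  expect_error(bs_model(OPT_B_TILDE, 0), "omega_rf")
  expect_error(bs_model(-1, 2000), "b_tilde")
  expect_warning(bs_phase(900, m), "linear")
})

test_that("complex-division phase differencing is wrap-safe", {
  d2r <- pi / 180
  expect_equal(phase_difference(0.4, 0.4), 0)
  expect_equal(phase_difference(170 * d2r, -170 * d2r), -20 * d2r,
               tolerance = 1e-12)
  expect_equal(phase_difference(pi / 2, 0), pi / 2)
  # always lands in the principal interval
  set.seed(42)
  a <- runif(200, -20, 20); b <- runif(200, -20, 20)
  d <- phase_difference(a, b)
  expect_true(all(d > -pi - 1e-12 & d <= pi + 1e-12))
  expect_equal(exp(1i * d), exp(1i * (a - b)), tolerance = 1e-9)
})

test_that("manual unwrapping extends the dynamic range by sqrt(2)", {
  expect_equal(unwrap_phase_diff(0.5, 0L), 0.5)
  expect_equal(unwrap_phase_diff(0.5, 1L), 0.5 + 2 * pi)
  expect_error(unwrap_phase_diff(0.5, 0.3), "integer")
  m <- opt_model()
  expect_equal(dynamic_range(m, 2 * pi) / dynamic_range(m, pi), sqrt(2),
               tolerance = 1e-12)
  # round trip: a wrapped measurement of a B1 beyond the pi limit is
  # recovered after one unwrap
  b1 <- 1100   # beyond the pi wrap limit (and the cautious linearity warning)
  d_true <- 2 * suppressWarnings(bs_phase(b1, m))
  d_wrapped <- atan2(sin(d_true), cos(d_true))
  expect_lt(d_wrapped, 0)
  est <- estimate_A(unwrap_phase_diff(d_wrapped, 1L), m)
  expect_rel_equal(est$gamma_b1, b1, 1e-10)
})

test_that("worked-example phase differences invert to the published field values", {
  m <- opt_model()
  d2r <- pi / 180
  expect_rel_equal(estimate_A(55.6 * d2r, m)$gamma_b1, 484, 0.01)
  expect_rel_equal(estimate_A(86.9 * d2r, m)$gamma_b1, 605, 0.01)
  expect_equal(estimate_A(0, m)$gamma_b1, 0)
  # dynamic range limits of the same pulse/offset
  expect_rel_equal(dynamic_range(m, pi), 873, 0.01)
  expect_rel_equal(dynamic_range(m, 2 * pi), 1231, 0.01)
  expect_equal(dynamic_range(m, 0), 0)
})

test_that("all four estimators round-trip noiseless linear-model phases", {
  bt <- OPT_B_TILDE
  m <- bs_model(bt, 2000)
  b1 <- 277
  phi <- function(w) pi * b1^2 * bt / w
  # A: symmetric pair
  eA <- estimate_A(phi(2000) - phi(-2000), m)
  expect_rel_equal(eA$gamma_b1, b1, 1e-10)
  # B': on/off
  eB <- estimate_Bprime(phi(2000), 0, m)
  expect_rel_equal(eB$gamma_b1, b1, 1e-10)
  # B'': four peaks, the cardiac layout relative to a +2000 Hz pulse
  om <- c(2000, 2300, 2900, 3950)
  eBB <- estimate_Bdouble(phi(om), rep(0, 4), om, m)
  expect_rel_equal(eBB$gamma_b1, b1, 1e-10)
  # C: symmetric two-peak single acquisition, arbitrary common phase
  omc <- c(-975, 975)
  eC <- estimate_C(1.234 + phi(omc), omc, bs_model(bt, 975))
  expect_rel_equal(eC$gamma_b1, b1, 1e-10)
})

test_that("multi-peak estimators reduce to their single-peak forms", {
  m <- bs_model(OPT_B_TILDE, 2000)
  # one peak: B'' equals B'
  e1 <- estimate_Bdouble(0.12, 0.02, 2000, m)
  e2 <- estimate_Bprime(0.12, 0.02, m)
  expect_equal(e1$gamma_b1, e2$gamma_b1, tolerance = 1e-12)
  # two peaks: C equals the explicit pair formula
  phis <- c(0.31, 0.12); om <- c(975, 2925)
  gsq <- (phis[1] - phis[2]) / (pi * OPT_B_TILDE * (1 / om[1] - 1 / om[2]))
  expect_equal(estimate_C(phis, om, m)$gamma_b1, sqrt(gsq),
               tolerance = 1e-12)
  # B'' weights scale as 1/omega^2: a peak at twice the offset carries a
  # quarter of the weight
  phiA <- 0.2; phiB <- 0.05
  e <- estimate_Bdouble(c(phiA, phiB), c(0, 0), c(2000, 4000), m)
  gA <- phiA * 2000 / (pi * OPT_B_TILDE); gB <- phiB * 4000 / (pi * OPT_B_TILDE)
  expect_equal(e$gamma_b1^2, (gA + gB / 4) / 1.25, tolerance = 1e-9)
  expect_error(estimate_Bdouble(c(0.1, 0.2), 0.1, c(100, 200), m), "length")
  expect_error(estimate_C(c(0.1, 0.2), c(500, 500), m), "distinct")
})

test_that("estimates are invariant to a global receiver phase", {
  bt <- OPT_B_TILDE; m <- bs_model(bt, 2000); b1 <- 400
  phi <- function(w) pi * b1^2 * bt / w
  phi0 <- 2.1
  eA <- estimate_A(phase_difference(phi0 + phi(2000), phi0 + phi(-2000)), m)
  expect_rel_equal(eA$gamma_b1, b1, 1e-10)
  eB <- estimate_Bprime(phi0 + phi(2000), phi0, m)
  expect_rel_equal(eB$gamma_b1, b1, 1e-10)
  om <- c(-975, 975)
  eC <- estimate_C(phi0 + phi(om), om, bs_model(bt, 975))
  expect_rel_equal(eC$gamma_b1, b1, 1e-10)
})

test_that("negative phase differences yield flagged invalid estimates", {
  m <- bs_model(OPT_B_TILDE, 2000)
  e <- estimate_A(-5 * pi / 180, m)
  expect_false(e$valid)
  expect_equal(e$reason, "negative_phase_diff")
  e2 <- estimate_Bprime(0.0, 0.1, m)
  expect_false(e2$valid)
})

test_that("error propagation matches an independent finite-difference oracle", {
  bt <- OPT_B_TILDE
  b1 <- 350
  # Method C with the 4-peak layout: no closed form; compare the package's
  # gradient propagation with a coarse independent finite-difference of
  # the estimator expression written out here
  om <- c(2000, 2300, 2900, 3950)
  m <- bs_model(bt, 2000)
  phis <- pi * b1^2 * bt / om
  crlbs <- c(0.02, 0.03, 0.04, 0.05)
  est_fun <- function(ph) {
    u <- 1 / om
    pairs <- utils::combn(4, 2)
    du <- u[pairs[1, ]] - u[pairs[2, ]]
    dphi <- ph[pairs[1, ]] - ph[pairs[2, ]]
    sqrt(sum(dphi * du) / (pi * bt * sum(du^2)))
  }
  g <- vapply(1:4, function(i) {
    h <- 1e-6; up <- phis; up[i] <- up[i] + h; dn <- phis; dn[i] <- dn[i] - h
    (est_fun(up) - est_fun(dn)) / (2 * h)
  }, numeric(1))
  oracle <- sqrt(sum((g * crlbs)^2))
  expect_rel_equal(propagate_error("C", phis, crlbs, m, omegas = om),
                   oracle, 1e-6)
  # closed forms for the single-peak strategies
  dphiA <- 2 * pi * b1^2 * bt / 2000
  pa <- propagate_error("A", c(dphiA / 2, -dphiA / 2), 0.03, m)
  expect_rel_equal(pa, bsb1map:::propagate_A_closed(dphiA, 0.03, m), 1e-6)
  pb <- propagate_error("Bprime", c(dphiA / 2, 0), 0.03, m)
  expect_rel_equal(pb, bsb1map:::propagate_Bprime_closed(dphiA / 2, 0, 0.03, m),
                   1e-6)
  # linearity: doubling all phase uncertainties doubles the SD
  expect_equal(propagate_error("C", phis, 2 * crlbs, m, omegas = om),
               2 * propagate_error("C", phis, crlbs, m, omegas = om),
               tolerance = 1e-9)
})

test_that("flip-angle conversion follows the hard-pulse relation", {
  expect_equal(flip_angle_from_b1(500, 1e-3), 180)
  expect_equal(flip_angle_from_b1(500, 300e-6), 54)
  expect_equal(flip_angle_from_b1(0, 1e-3), 0)
  expect_equal(b1_from_flip_angle(54, 300e-6), 500)
  expect_error(flip_angle_from_b1(500, 0), "tp")
})

test_that("voxel masking applies the stated exclusion rules exhaustively", {
  set.seed(7)
  n <- c(4, 3, 2)
  gb1 <- array(runif(prod(n), 0, 800), n)
  dphi <- array(runif(prod(n), -0.3, 2), n)
  crlb <- array(runif(prod(n), 0, 30), n)
  map <- b1_map(gb1, delta_phi = dphi, crlb_deg = crlb)
  geom <- array(TRUE, n); geom[1, , ] <- FALSE
  masked <- mask_voxels(map, crlb_threshold = 10, geometry_mask = geom)
  # brute-force reference classification
  ref <- array("none", n)
  ref[!geom] <- "outside_mask"
  ref[ref == "none" & crlb > 10] <- "crlb_exceeded"
  ref[ref == "none" & dphi < 0] <- "negative_phase_diff"
  expect_identical(masked$exclusion, ref)
  # values are retained for every voxel
  expect_equal(masked$gamma_b1, map$gamma_b1)
  # permissive thresholds with positive phases are the identity
  clean <- b1_map(gb1, delta_phi = abs(dphi), crlb_deg = crlb * 0)
  expect_true(all(mask_voxels(clean, 20)$exclusion == "none"))
  expect_error(mask_voxels(clean, -1), "crlb_threshold")
})
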