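#' Bloch-Siegert phase model
#'
#' Minimal description of the phase-to-B1 relationship for a given
#' sensitizing pulse and frequency offset: the pulse's normalized
#' squared integral `b_tilde` (seconds) and the signed frequency offset
#' `omega_rf` (Hz) from the pulse to the peak of interest.
#'
#' @param b_tilde Normalized pulse-envelope squared integral in seconds
#'   (see [normalized_squared_integral()]); must be > 0.
#' @param omega_rf Signed pulse-to-peak offset in Hz; must be nonzero.
#' @param gamma Gyromagnetic ratio in Hz/T; default 17.235e6 for 31P.
#'   Carried as metadata (the package works in gamma*B1 units of Hz).
#' @return An object of class `bs_phase_model`.
#' @export
bs_model <- function(b_tilde, omega_rf, gamma = 17.235e6) {
  if (!is.numeric(b_tilde) || b_tilde <= 0)
    stop("b_tilde must be > 0")
  if (!is.numeric(omega_rf) || any(omega_rf == 0))
    stop("omega_rf must be nonzero")
  structure(list(b_tilde = b_tilde, omega_rf = omega_rf, gamma = gamma),
            class = "bs_phase_model")
}

#' Bloch-Siegert phase for a given peak amplitude
#'
#' Linear-regime phase accumulated by a spin at offset `omega_rf` from a
#' unit-peak-normalized sensitizing pulse of peak amplitude `gamma_b1_peak`:
#' \deqn{\phi_{BS} = \pi\, (\gamma B_1^+)^2\, \tilde{B} / \omega_{RF}}
#' The sign of the phase follows the sign of the offset.
#'
#' @param gamma_b1_peak Peak amplitude in Hz.
#' @param model A [bs_model()].
#' @return Phase in radians. A warning is issued outside the comfortable
#'   linear regime (`|omega_rf| < 3 * gamma_b1`).
#' @export
#' @examples
#' m <- bs_model(1.3197e-3, 2000)
#' bs_phase(277, m)   # ~0.159 rad (9.1 degrees)
bs_phase <- function(gamma_b1_peak, model) {
  stopifnot(inherits(model, "bs_phase_model"))
  if (any(abs(model$omega_rf) < 3 * abs(gamma_b1_peak)))
    warning("|omega_rf| < 3 * gamma_b1: linear Bloch-Siegert approximation is inaccurate")
  pi * gamma_b1_peak^2 * model$b_tilde / model$omega_rf
}

#' Wrap-safe phase difference by complex division
#'
#' Computes the principal-value difference `phi1 - phi2` through the
#' two-argument arctangent of the complex ratio
#' `exp(1i*phi1) / exp(1i*phi2)`, so raw phase wraps in the operands cannot
#' produce artifacts.
#'
#' @param phi1,phi2 Phases in radians (vectorized).
#' @return Difference in `(-pi, pi]`.
#' @export
#' @examples
#' phase_difference(170 * pi / 180, -170 * pi / 180)  # -20 degrees, not +340
phase_difference <- function(phi1, phi2) {
  z <- exp(1i * phi1) / exp(1i * phi2)
  atan2(Im(z), Re(z))
}

#' Re-apply integer phase wraps to a phase difference
#'
#' Phase differences beyond the principal interval (large gamma*B1) wrap;
#' the wrap count is supplied explicitly by the caller per voxel or region
#' (manual unwrapping), mirroring how high-B1 voxels near a surface coil are
#' handled in practice. `k = 1` extends the measurable gamma*B1 range by a
#' factor sqrt(2) (see [dynamic_range()]).
#'
#' @param delta_phi Principal-value phase difference, radians.
#' @param k Integer number of extra 2*pi wraps (typically 0 or 1).
#' @return `delta_phi + 2*pi*k` in radians.
#' @export
unwrap_phase_diff <- function(delta_phi, k = 0L) {
  if (any(k != round(k))) stop("k must be integer-valued")
  delta_phi + 2 * pi * k
}

#' B1 estimate container
#'
#' @param gamma_b1 Estimated peak amplitude in Hz (NA when invalid).
#' @param sd Propagated standard deviation in Hz (optional).
#' @param valid Logical validity flag.
#' @param reason One of `"none"`, `"negative_phase_diff"`, `"crlb_exceeded"`,
#'   `"wrap_suspected"`.
#' @return An object of class `b1_estimate`.
#' @export
b1_estimate <- function(gamma_b1, sd = NA_real_, valid = TRUE,
                        reason = "none") {
  if (valid && (!is.finite(gamma_b1) || gamma_b1 < 0))
    stop("a valid estimate requires finite gamma_b1 >= 0")
  structure(list(gamma_b1 = gamma_b1, sd = sd, valid = valid, reason = reason),
            class = "b1_estimate")
}

#' @export
print.b1_estimate <- function(x, ...) {
  if (x$valid) {
    cat(sprintf("gamma*B1+ = %.4g Hz", x$gamma_b1))
    if (is.finite(x$sd)) cat(sprintf(" (sd %.3g Hz)", x$sd))
    cat("\n")
  } else {
    cat(sprintf("invalid estimate (%s)\n", x$reason))
  }
  invisible(x)
}

# internal: gamma_b1^2 from a set of phases, vectorized over draws.
# phases: matrix [draws x phases] (or vector for one draw)
gsq_from_phases <- function(strategy, phases, omegas, b_tilde) {
  if (is.null(dim(phases))) phases <- matrix(phases, nrow = 1L)
  switch(strategy,
    A = {
      # phases: [,1] at +|omega|, [,2] at -|omega|; omegas = |omega|
      (phases[, 1] - phases[, 2]) * abs(omegas[1]) / (2 * pi * b_tilde)
    },
    Bprime = {
      # phases: [,1] on, [,2] off; omegas = signed omega
      (phases[, 1] - phases[, 2]) * omegas[1] / (pi * b_tilde)
    },
    Bdouble = {
      # phases: [, 1:n] on, [, n + 1:n] off
      n <- length(omegas)
      gi <- (phases[, seq_len(n), drop = FALSE] -
             phases[, n + seq_len(n), drop = FALSE]) *
        rep(omegas, each = nrow(phases)) / (pi * b_tilde)
      w <- omegas^-2
      as.numeric(gi %*% w) / sum(w)
    },
    C = {
      n <- length(omegas)
      u <- 1 / omegas
      pairs <- utils::combn(n, 2)
      du <- u[pairs[1, ]] - u[pairs[2, ]]
      dphi <- phases[, pairs[1, ], drop = FALSE] -
        phases[, pairs[2, ], drop = FALSE]
      # per-pair gsq = dphi / (pi * b_tilde * du); weights du^2
      as.numeric(dphi %*% du) / (pi * b_tilde * sum(du^2))
    },
    stop("unknown strategy"))
}

gsq_to_estimate <- function(gsq) {
  if (!is.finite(gsq)) return(b1_estimate(NA_real_, valid = FALSE,
                                          reason = "negative_phase_diff"))
  if (gsq < 0) return(b1_estimate(NA_real_, valid = FALSE,
                                  reason = "negative_phase_diff"))
  b1_estimate(sqrt(gsq))
}

#' Method A: dual-acquisition at symmetric offsets
#'
#' Inverts the phase difference between two acquisitions with the
#' sensitizing pulse at +omega and -omega from the peak:
#' \deqn{\gamma B_1^+ = \sqrt{\Delta\phi\, \omega_{RF} / (2\pi \tilde{B})}}
#' A negative phase difference (very low B1, or an uncorrected wrap) yields
#' an invalid estimate with reason `"negative_phase_diff"`.
#'
#' @param delta_phi Phase difference `phi(+omega) - phi(-omega)` in radians.
#' @param model A [bs_model()]; `omega_rf` is interpreted as the magnitude
#'   of the symmetric offset.
#' @return A [b1_estimate()].
#' @export
#' @examples
#' m <- bs_model(1.3197e-3, 2000)
#' estimate_A(55.6 * pi / 180, m)   # ~484 Hz
estimate_A <- function(delta_phi, model) {
  stopifnot(inherits(model, "bs_phase_model"))
  gsq_to_estimate(gsq_from_phases("A", c(delta_phi, 0), abs(model$omega_rf),
                                  model$b_tilde))
}

#' Method B': single-peak dual-acquisition on/off
#'
#' One acquisition with the sensitizing pulse at signed offset `omega_rf`
#' from the peak and one without:
#' \deqn{\gamma B_1^+ = \sqrt{(\phi_{on}-\phi_{off})\, \omega_{RF} / (\pi \tilde{B})}}
#'
#' @param phi_on,phi_off Fitted peak phases (radians) with and without the
#'   sensitizing pulse.
#' @param model A [bs_model()] with signed `omega_rf`.
#' @return A [b1_estimate()].
#' @export
estimate_Bprime <- function(phi_on, phi_off, model) {
  stopifnot(inherits(model, "bs_phase_model"))
  gsq_to_estimate(gsq_from_phases("Bprime", c(phi_on, phi_off),
                                  model$omega_rf, model$b_tilde))
}

#' Method B'': multi-peak dual-acquisition on/off
#'
#' Generalizes [estimate_Bprime()] to several peaks observed in the same
#' on/off acquisition pair. Per-peak squared-amplitude estimates
#' `(phi_on_i - phi_off_i) * omega_i / (pi * b_tilde)` are combined as an
#' inverse-variance-weighted (maximum-likelihood, equal phase variances)
#' mean with weights `omega_i^-2`, so distant peaks -- which encode less
#' Bloch-Siegert phase -- contribute less.
#'
#' @param phis_on,phis_off Per-peak fitted phases, radians.
#' @param omegas Signed per-peak offsets from the pulse, Hz.
#' @param model A [bs_model()] (its `b_tilde` is used).
#' @return A [b1_estimate()].
#' @export
estimate_Bdouble <- function(phis_on, phis_off, omegas, model) {
  stopifnot(inherits(model, "bs_phase_model"))
  n <- length(omegas)
  if (length(phis_on) != n || length(phis_off) != n)
    stop("phis_on, phis_off and omegas must have equal lengths")
  gsq_to_estimate(gsq_from_phases("Bdouble", c(phis_on, phis_off), omegas,
                                  model$b_tilde))
}

#' Method C: single-acquisition multi-peak estimator
#'
#' Uses the phase differences between every pair of peaks in a single
#' sensitized acquisition. For peaks j and i at offsets `omega_j`,
#' `omega_i`:
#' \deqn{(\gamma B_1^+)^2_{ji} = (\phi_j-\phi_i) / (\pi \tilde{B}\,(\omega_j^{-1}-\omega_i^{-1}))}
#' combined across pairs with weights
#' \eqn{(\omega_j^{-1}-\omega_i^{-1})^2}. The common phase offset of the
#' acquisition cancels in every pair; zeroth- and first-order phase are
#' assumed corrected by the caller.
#'
#' @param phis Per-peak fitted phases, radians (length >= 2).
#' @param omegas Signed per-peak offsets from the pulse, Hz; all distinct.
#' @param model A [bs_model()] (its `b_tilde` is used).
#' @return A [b1_estimate()].
#' @export
estimate_C <- function(phis, omegas, model) {
  stopifnot(inherits(model, "bs_phase_model"))
  if (length(phis) < 2L) stop("Method C needs at least 2 peaks")
  if (length(phis) != length(omegas))
    stop("phis and omegas must have equal lengths")
  if (anyDuplicated(omegas)) stop("peak offsets must be distinct")
  gsq_to_estimate(gsq_from_phases("C", phis, omegas, model$b_tilde))
}

# internal: noiseless phases each strategy expects, given true gamma_b1
strategy_phases <- function(strategy, gamma_b1, omegas, b_tilde) {
  phi <- function(w) pi * gamma_b1^2 * b_tilde / w
  switch(strategy,
    A = c(phi(abs(omegas[1])), -phi(abs(omegas[1]))),
    Bprime = c(phi(omegas[1]), 0),
    Bdouble = c(phi(omegas), rep(0, length(omegas))),
    C = phi(omegas),
    stop("unknown strategy"))
}

# internal: number of phase observations per strategy
strategy_n_phases <- function(strategy, omegas) {
  switch(strategy,
    A = 2L, Bprime = 2L,
    Bdouble = 2L * length(omegas),
    C = length(omegas),
    stop("unknown strategy"))
}

#' Propagated uncertainty of a B1 estimate
#'
#' First-order propagation of errors
#' \deqn{\Delta q = \sqrt{\sum_i (\partial q/\partial \phi_i \cdot \Delta\phi_i)^2}}
#' applied to the chosen estimator, with the partial derivatives evaluated
#' numerically (central differences) at the supplied phases. This covers all
#' four strategies uniformly, including Method C whose closed form is
#' unwieldy for general peak counts.
#'
#' @param strategy One of `"A"`, `"Bprime"`, `"Bdouble"`, `"C"`.
#' @param phases Phase observations in the strategy's canonical order:
#'   `A`: `c(phi_plus, phi_minus)`; `Bprime`: `c(phi_on, phi_off)`;
#'   `Bdouble`: `c(phis_on, phis_off)`; `C`: per-peak phases.
#' @param crlbs Per-phase standard deviations (radians), recycled if scalar.
#' @param model A [bs_model()].
#' @param omegas Per-peak offsets in Hz (defaults to `model$omega_rf`).
#' @return Standard deviation of gamma*B1 in Hz; `Inf` (with a warning) at a
#'   zero estimate where the first-order expansion degenerates.
#' @export
propagate_error <- function(strategy = c("A", "Bprime", "Bdouble", "C"),
                            phases, crlbs, model, omegas = NULL) {
  strategy <- match.arg(strategy)
  stopifnot(inherits(model, "bs_phase_model"))
  if (is.null(omegas)) omegas <- model$omega_rf
  np <- strategy_n_phases(strategy, omegas)
  if (length(phases) != np)
    stop(sprintf("strategy %s expects %d phases", strategy, np))
  crlbs <- rep_len(crlbs, np)
  if (any(crlbs < 0)) stop("phase uncertainties must be >= 0")
  g <- function(ph) {
    gsq <- gsq_from_phases(strategy, ph, omegas, model$b_tilde)
    if (gsq < 0) NA_real_ else sqrt(gsq)
  }
  g0 <- g(phases)
  if (is.na(g0)) stop("estimate invalid (negative discriminant); cannot propagate")
  if (g0 == 0) {
    warning("zero estimate: propagated SD is infinite")
    return(Inf)
  }
  h <- 1e-7
  grad <- vapply(seq_len(np), function(i) {
    up <- phases; up[i] <- up[i] + h
    dn <- phases; dn[i] <- dn[i] - h
    (g(up) - g(dn)) / (2 * h)
  }, numeric(1))
  sqrt(sum((grad * crlbs)^2))
}

# internal closed forms (used as oracles in the test suite)
propagate_A_closed <- function(delta_phi, crlbs, model) {
  g <- sqrt(delta_phi * abs(model$omega_rf) / (2 * pi * model$b_tilde))
  crlbs <- rep_len(crlbs, 2L)
  g / (2 * delta_phi) * sqrt(sum(crlbs^2))
}

propagate_Bprime_closed <- function(phi_on, phi_off, crlbs, model) {
  d <- phi_on - phi_off
  g <- sqrt(d * model$omega_rf / (pi * model$b_tilde))
  crlbs <- rep_len(crlbs, 2L)
  g / (2 * d) * sqrt(sum(crlbs^2))
}

#' Dynamic range of the phase-difference measurement
#'
#' The largest gamma*B1 whose Method-A phase difference stays within
#' `max_phase` before wrapping:
#' \deqn{\gamma B_{1,max}^+ = \sqrt{\phi_{max}\, \omega_{RF} / (2\pi \tilde{B})}}
#' With the principal interval (`max_phase = pi`) and one manual unwrap
#' (`max_phase = 2*pi`) the range extends by a factor sqrt(2).
#'
#' @param model A [bs_model()].
#' @param max_phase Largest measurable phase difference, radians (typically
#'   `pi` or `2*pi`).
#' @return Maximum gamma*B1 in Hz.
#' @export
#' @examples
#' m <- bs_model(1.3197e-3, 2000)
#' dynamic_range(m, pi)      # ~871 Hz
#' dynamic_range(m, 2 * pi)  # ~1231 Hz
dynamic_range <- function(model, max_phase) {
  stopifnot(inherits(model, "bs_phase_model"))
  if (max_phase < 0) stop("max_phase must be >= 0")
  sqrt(max_phase * abs(model$omega_rf) / (2 * pi * model$b_tilde))
}

#' Flip angle of a hard pulse from gamma*B1
#'
#' For a rectangular excitation pulse of duration `tp`, the on-resonance
#' flip angle is `theta = 360 * gamma_b1 * tp` degrees (e.g. 500 Hz for
#' 1 ms gives 180 degrees).
#'
#' @param gamma_b1 Peak amplitude in Hz.
#' @param tp Pulse duration in seconds (> 0).
#' @return Flip angle in degrees.
#' @export
flip_angle_from_b1 <- function(gamma_b1, tp) {
  if (any(tp <= 0)) stop("tp must be > 0")
  360 * gamma_b1 * tp
}

#' Inverse of [flip_angle_from_b1()]
#' @param theta Flip angle in degrees.
#' @param tp Hard-pulse duration in seconds (> 0).
#' @return gamma*B1 in Hz.
#' @export
b1_from_flip_angle <- function(theta, tp) {
  if (any(tp <= 0)) stop("tp must be > 0")
  theta / (360 * tp)
}
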