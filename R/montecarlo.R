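#' Monte Carlo configuration for strategy comparison
#'
#' @param strategy One of `"A"`, `"Bprime"`, `"Bdouble"`, `"C"`.
#' @param gamma_b1_true True peak amplitude in Hz (default 277, the
#'   representative cardiac value).
#' @param phase_sd Per-phase standard deviation(s) in radians (recycled to
#'   the strategy's phase count).
#' @param omegas Peak offset(s) from the sensitizing pulse in Hz. For
#'   strategy `"A"` give the magnitude of the symmetric offset.
#' @param b_tilde Pulse squared integral in seconds; defaults to the
#'   optimized 3.5 ms Fermi pulse's value.
#' @param n_draws Number of Monte Carlo draws (>= 1000; default 1e6).
#' @param seed Integer RNG seed.
#' @return An object of class `mc_config`.
#' @export
mc_config <- function(strategy = c("A", "Bprime", "Bdouble", "C"),
                      gamma_b1_true = 277, phase_sd, omegas = 2000,
                      b_tilde = optimized_b_tilde(), n_draws = 1e6,
                      seed = 1L) {
  strategy <- match.arg(strategy)
  if (n_draws < 1e3) stop("n_draws must be >= 1000")
  if (any(phase_sd < 0)) stop("phase_sd must be >= 0")
  structure(list(strategy = strategy, gamma_b1_true = gamma_b1_true,
                 phase_sd = phase_sd, omegas = omegas, b_tilde = b_tilde,
                 n_draws = as.integer(n_draws), seed = as.integer(seed)),
            class = "mc_config")
}

#' Squared integral of the optimized 3.5 ms Fermi pulse
#'
#' Convenience accessor: synthesizes the optimized Fermi pulse
#' (TP = 3.5 ms, T0 = 0.875 ms, a = 0.224 ms) at 1 us resolution and
#' returns its normalized squared integral (~1.3197e-3 s). The value is
#' cached for the session.
#'
#' @return B-tilde in seconds.
#' @export
optimized_b_tilde <- local({
  val <- NULL
  function() {
    if (is.null(val))
      val <<- normalized_squared_integral(make_fermi(optimized_fermi_params()))
    val
  }
})

#' Monte Carlo bias and precision of a measurement strategy
#'
#' Draws per-phase observations from Normal distributions centered on the
#' linear-regime Bloch-Siegert phases for the true gamma*B1 and the
#' configured offsets, applies the strategy's estimator to every draw, and
#' summarizes accuracy as the mean percent deviation from truth and
#' precision as the SD / coefficient of variation over valid draws. Draws
#' with a negative discriminant are counted as invalid and excluded from
#' the summaries; their fraction is reported.
#'
#' @param config An [mc_config()].
#' @return An object of class `mc_result` with `bias_hz`, `bias_percent`,
#'   `sd_hz`, `cv_percent`, `n_valid`, `n_invalid`.
#' @export
#' @examples
#' cfg <- mc_config("A", phase_sd = 0.045, omegas = 2000, n_draws = 1e5)
#' mc_evaluate(cfg)
mc_evaluate <- function(config) {
  stopifnot(inherits(config, "mc_config"))
  set.seed(config$seed)
  np <- strategy_n_phases(config$strategy, config$omegas)
  mu <- strategy_phases(config$strategy, config$gamma_b1_true, config$omegas,
                        config$b_tilde)
  sds <- rep_len(config$phase_sd, np)
  phases <- matrix(stats::rnorm(config$n_draws * np,
                                mean = rep(mu, each = config$n_draws),
                                sd = rep(sds, each = config$n_draws)),
                   nrow = config$n_draws)
  gsq <- gsq_from_phases(config$strategy, phases, config$omegas,
                         config$b_tilde)
  valid <- gsq >= 0
  if (!any(valid))
    stop(sprintf("all %d draws invalid (negative discriminant); phase_sd likely too large for gamma_b1_true = %g",
                 config$n_draws, config$gamma_b1_true))
  g <- sqrt(gsq[valid])
  bias_hz <- mean(g) - config$gamma_b1_true
  sd_hz <- stats::sd(g)
  structure(list(bias_hz = bias_hz,
                 bias_percent = 100 * bias_hz / config$gamma_b1_true,
                 sd_hz = sd_hz,
                 cv_percent = 100 * sd_hz / config$gamma_b1_true,
                 n_valid = sum(valid),
                 n_invalid = sum(!valid),
                 config = config),
            class = "mc_result")
}

#' @export
print.mc_result <- function(x, ...) {
  cat(sprintf("Monte Carlo (%s, n = %d, %d invalid): bias %+.3g Hz (%+.3g%%), SD %.3g Hz (CV %.3g%%)\n",
              x$config$strategy, x$n_valid + x$n_invalid, x$n_invalid,
              x$bias_hz, x$bias_percent, x$sd_hz, x$cv_percent))
  invisible(x)
}

#' Cramer-Rao lower bound on fitted peak phases
#'
#' Builds the Fisher information matrix of the damped complex-exponential
#' FID model (four free parameters per peak group: amplitude, frequency,
#' damping, phase; multiplet structure fixed) under white complex Gaussian
#' noise, and returns the square root of the phase-phase diagonal of its
#' inverse, divided by `sqrt(n_scans)`.
#'
#' @param model A [spectrum_model()].
#' @param noise_sd Noise standard deviation per complex point per channel
#'   (real and imaginary each have this SD).
#' @param dwell Dwell time in seconds.
#' @param n_points Number of FID points.
#' @param n_scans Number of averaged scans per measurement (sqrt-N law).
#' @return Named vector of per-peak phase CRLBs in radians.
#' @export
crlb_phase <- function(model, noise_sd, dwell, n_points, n_scans = 1) {
  stopifnot(inherits(model, "spectrum_model"))
  if (noise_sd <= 0) stop("noise_sd must be > 0")
  if (anyDuplicated(model$peaks$offset_hz))
    stop("model not identifiable: duplicate peak frequencies")
  J <- fid_jacobian(model, dwell, n_points)
  # noise_sd is the per-channel SD: -lnL = sum(|r|^2) / (2 sd^2), so
  # FIM = Re(J^H J) / sd^2 (verified against the empirical fit SD)
  fim <- Re(Conj(t(J)) %*% J) / noise_sd^2
  cov <- tryCatch(solve(fim), error = function(e)
    stop("singular Fisher matrix: degenerate parameters (",
         conditionMessage(e), ")"))
  idx <- seq(4, ncol(J), by = 4)   # phase entries: (a, f, d, phi) per group
  out <- sqrt(diag(cov)[idx]) / sqrt(n_scans)
  names(out) <- model$peaks$name
  out
}

# internal: complex Jacobian of the noiseless FID wrt (a, f, d, phi) per group
fid_jacobian <- function(model, dwell, n_points) {
  t <- (seq_len(n_points) - 1L) * dwell
  G <- nrow(model$peaks)
  J <- matrix(0i, n_points, 4L * G)
  for (g in seq_len(G)) {
    pk <- model$peaks[g, ]
    lines <- expand_multiplet(pk)
    d <- pi * pk$damping_hz           # Lorentzian FWHM (Hz) -> decay rate (1/s)
    Sg <- rowSums(vapply(seq_len(nrow(lines)), function(l)
      lines$rel_amp[l] * exp((-d + 2i * pi * lines$offset_hz[l]) * t),
      complex(length(t)))) * exp(1i * pk$phase_rad)
    j0 <- 4L * (g - 1L)
    J[, j0 + 1L] <- Sg                              # d/da
    J[, j0 + 2L] <- 2i * pi * t * pk$amplitude * Sg # d/df (common shift)
    J[, j0 + 3L] <- -t * pk$amplitude * Sg          # d/d(decay rate)
    J[, j0 + 4L] <- 1i * pk$amplitude * Sg          # d/dphi
  }
  J
}

#' Sweep analytic and Monte Carlo performance over a grid
#'
#' For each grid point, computes the analytic propagated CV
#' ([propagate_error()]) and Monte Carlo bias/CV ([mc_evaluate()]) of the
#' chosen strategies, sweeping either the pulse offset or the true peak
#' amplitude.
#'
#' @param strategies Character vector of strategy ids.
#' @param variable `"omega_rf"` or `"gamma_b1"`.
#' @param values Grid values (Hz).
#' @param phase_sd Per-phase SD in radians.
#' @param gamma_b1_true True amplitude in Hz (used when sweeping omega).
#' @param omegas Offsets in Hz (used when sweeping gamma_b1).
#' @param b_tilde Pulse squared integral, seconds.
#' @param n_draws Monte Carlo draws per grid point.
#' @param seed Base RNG seed.
#' @return Data frame with one row per (strategy, value): analytic SD/CV and
#'   Monte Carlo bias/SD/CV.
#' @export
mc_sweep <- function(strategies, variable = c("omega_rf", "gamma_b1"),
                     values, phase_sd, gamma_b1_true = 277, omegas = 2000,
                     b_tilde = optimized_b_tilde(), n_draws = 1e5,
                     seed = 1L) {
  variable <- match.arg(variable)
  rows <- list()
  for (s in strategies) {
    for (v in values) {
      g_true <- if (variable == "gamma_b1") v else gamma_b1_true
      om <- if (variable == "omega_rf") v else omegas
      mu <- strategy_phases(s, g_true, om, b_tilde)
      sd_an <- propagate_error(s, mu, phase_sd, bs_model(b_tilde, om[1]),
                               omegas = om)
      mc <- mc_evaluate(mc_config(s, gamma_b1_true = g_true,
                                  phase_sd = phase_sd, omegas = om,
                                  b_tilde = b_tilde, n_draws = n_draws,
                                  seed = seed))
      rows[[length(rows) + 1L]] <- data.frame(
        strategy = s, variable = variable, value = v,
        analytic_sd_hz = sd_an, analytic_cv_percent = 100 * sd_an / g_true,
        mc_bias_hz = mc$bias_hz, mc_bias_percent = mc$bias_percent,
        mc_sd_hz = mc$sd_hz, mc_cv_percent = mc$cv_percent,
        n_valid = mc$n_valid)
    }
  }
  do.call(rbind, rows)
}
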