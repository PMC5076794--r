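#' Spectral prior-knowledge model
#'
#' A set of Lorentzian peaks, each optionally a multiplet with fixed
#' amplitude ratios and scalar coupling. `damping_hz` is the Lorentzian
#' full width at half maximum in Hz (decay rate `pi * damping_hz` 1/s).
#'
#' @param peaks Data frame with columns `name`, `offset_hz`, `amplitude`,
#'   `damping_hz`, `phase_rad`, and optionally `n_lines` (default 1) and
#'   `j_hz` (default 0). Multiplet amplitude ratios default to the binomial
#'   pattern (1:1 doublet, 1:2:1 triplet) and are normalized so `amplitude`
#'   is the total peak amplitude.
#' @return An object of class `spectrum_model`.
#' @export
spectrum_model <- function(peaks) {
  req <- c("name", "offset_hz", "amplitude", "damping_hz", "phase_rad")
  if (!all(req %in% names(peaks)))
    stop("peaks must have columns: ", paste(req, collapse = ", "))
  if (any(!is.finite(peaks$offset_hz))) stop("peak offsets must be finite")
  if (any(peaks$damping_hz <= 0)) stop("damping must be > 0")
  if (is.null(peaks$n_lines)) peaks$n_lines <- 1L
  if (is.null(peaks$j_hz)) peaks$j_hz <- 0
  structure(list(peaks = as.data.frame(peaks)), class = "spectrum_model")
}

#' @export
print.spectrum_model <- function(x, ...) {
  cat(sprintf("Spectrum model with %d peak group(s):\n", nrow(x$peaks)))
  print(x$peaks[, c("name", "offset_hz", "amplitude", "damping_hz",
                    "phase_rad", "n_lines", "j_hz")], row.names = FALSE)
  invisible(x)
}

# internal: expand one peak row into component lines (offset, rel_amp with
# sum 1). Binomial amplitude ratios, lines centered on the group offset.
expand_multiplet <- function(pk) {
  n <- pk$n_lines
  if (is.null(n) || is.na(n) || n <= 1L) {
    return(data.frame(offset_hz = pk$offset_hz, rel_amp = 1))
  }
  ratios <- choose(n - 1L, 0:(n - 1L))
  shift <- ((0:(n - 1L)) - (n - 1L) / 2) * pk$j_hz
  data.frame(offset_hz = pk$offset_hz + shift, rel_amp = ratios / sum(ratios))
}

#' Default 7T 31P spectrum model
#'
#' Four-group model with PCr at 0 Hz and the gamma-, alpha-, beta-ATP
#' resonances at -300, -900 and -1950 Hz. ATP multiplets default to a
#' doublet/doublet/triplet with J = 16.3 Hz and binomial amplitude ratios
#' (literature convention). Amplitudes default to a PCr/ATP ratio of 2;
#' linewidths to 20 Hz, representative of human cardiac 31P spectra at 7T.
#'
#' @param pcr_amplitude PCr total amplitude (arbitrary units).
#' @param atp_amplitude Per-ATP-resonance total amplitude.
#' @param damping_hz Lorentzian FWHM in Hz for all groups.
#' @param multiplets If `FALSE`, all groups are singlets.
#' @return A [spectrum_model()].
#' @export
default_31p_model <- function(pcr_amplitude = 1, atp_amplitude = 0.5,
                              damping_hz = 20, multiplets = TRUE) {
  spectrum_model(data.frame(
    name = c("PCr", "gATP", "aATP", "bATP"),
    offset_hz = c(0, -300, -900, -1950),
    amplitude = c(pcr_amplitude, rep(atp_amplitude, 3)),
    damping_hz = damping_hz,
    phase_rad = 0,
    n_lines = if (multiplets) c(1L, 2L, 2L, 3L) else 1L,
    j_hz = if (multiplets) c(0, 16.3, 16.3, 16.3) else 0))
}

# internal: noiseless complex FID of a model
model_fid <- function(model, dwell, n_points) {
  t <- (seq_len(n_points) - 1L) * dwell
  s <- complex(n_points)
  for (g in seq_len(nrow(model$peaks))) {
    pk <- model$peaks[g, ]
    lines <- expand_multiplet(pk)
    d <- pi * pk$damping_hz
    for (l in seq_len(nrow(lines)))
      s <- s + pk$amplitude * lines$rel_amp[l] * exp(1i * pk$phase_rad) *
        exp((-d + 2i * pi * lines$offset_hz[l]) * t)
  }
  s
}

#' Synthesize a multi-peak FID
#'
#' Sum of damped complex exponentials plus white complex Gaussian noise
#' (independent real and imaginary components of SD `noise_sd` per point).
#'
#' @param model A [spectrum_model()].
#' @param n_points Number of complex samples (default 2048).
#' @param bandwidth Spectral bandwidth in Hz (default 6000); dwell time is
#'   `1 / bandwidth`.
#' @param noise_sd Per-point per-channel noise SD (0 = noiseless).
#' @param seed Optional integer seed for the noise draw.
#' @return An object of class `fid`: list with complex `samples`, `dwell`
#'   (s), `n_points`, `bandwidth` (Hz).
#' @export
synthesize_fid <- function(model, n_points = 2048L, bandwidth = 6000,
                           noise_sd = 0, seed = NULL) {
  stopifnot(inherits(model, "spectrum_model"))
  if (any(abs(model$peaks$offset_hz) > bandwidth / 2))
    warning("peak offset beyond half the bandwidth: the line will alias")
  dwell <- 1 / bandwidth
  s <- model_fid(model, dwell, n_points)
  if (noise_sd > 0) {
    if (!is.null(seed)) set.seed(seed)
    s <- s + complex(real = stats::rnorm(n_points, 0, noise_sd),
                     imaginary = stats::rnorm(n_points, 0, noise_sd))
  }
  structure(list(samples = s, dwell = dwell, n_points = as.integer(n_points),
                 bandwidth = bandwidth),
            class = "fid")
}

#' Discrete spectrum of an FID
#'
#' Unnormalized FFT with the frequency axis in Hz (DC-centered).
#'
#' @param fid An `fid` object.
#' @return Data frame with `freq_hz` and complex `spectrum`.
#' @export
fid_spectrum <- function(fid) {
  n <- fid$n_points
  sp <- stats::fft(fid$samples)
  f <- (seq_len(n) - 1L) / (n * fid$dwell)
  f[f >= fid$bandwidth / 2] <- f[f >= fid$bandwidth / 2] - fid$bandwidth
  ord <- order(f)
  data.frame(freq_hz = f[ord], spectrum = sp[ord])
}

#' Noise level that produces a requested amplitude SNR
#'
#' Amplitude SNR is defined as the height of the tallest peak in the
#' magnitude spectrum divided by the spectral noise SD (per channel). For
#' an unnormalized length-N FFT of white time-domain noise of SD `sigma`
#' per channel, the spectral noise SD is `sigma * sqrt(N)`.
#'
#' @param model A [spectrum_model()].
#' @param snr Target amplitude SNR (e.g. 18, 31, 44).
#' @param n_points,bandwidth Acquisition geometry.
#' @return Time-domain per-channel noise SD.
#' @export
noise_sd_for_snr <- function(model, snr, n_points = 2048L, bandwidth = 6000) {
  fid <- synthesize_fid(model, n_points = n_points, bandwidth = bandwidth)
  peak <- max(Mod(stats::fft(fid$samples)))
  peak / (snr * sqrt(n_points))
}

#' Time-domain prior-knowledge fit of a multi-peak FID
#'
#' Nonlinear least squares in the time domain of the damped
#' complex-exponential model, with fixed multiplet amplitude ratios and
#' scalar couplings (equality constraints realized through the
#' parameterization: four free parameters per peak group -- amplitude,
#' frequency shift, damping, phase). Starting values come from the prior.
#' Per-group CRLBs are computed from the Fisher matrix at the solution
#' using the residual noise estimate.
#'
#' @param fid An `fid` object.
#' @param prior A [spectrum_model()] giving starting values and multiplet
#'   structure.
#' @param max_iter Maximum Levenberg-Marquardt iterations.
#' @return A list of class `amares_fit`: `model` (fitted
#'   [spectrum_model()]), `crlb` (data frame of per-group parameter CRLBs,
#'   phases in radians), `noise_sd` (residual estimate), `residual_energy`
#'   (fraction of signal energy), `converged`.
#' @export
fit_amares <- function(fid, prior, max_iter = 200L) {
  stopifnot(inherits(fid, "fid"), inherits(prior, "spectrum_model"))
  peaks <- prior$peaks
  G <- nrow(peaks)
  par0 <- as.numeric(rbind(peaks$amplitude, peaks$offset_hz,
                           peaks$damping_hz, peaks$phase_rad))
  unpack <- function(par) {
    m <- matrix(par, nrow = 4L)
    pk <- peaks
    pk$amplitude <- m[1, ]; pk$offset_hz <- m[2, ]
    pk$damping_hz <- m[3, ]; pk$phase_rad <- m[4, ]
    pk
  }
  resid_fn <- function(par) {
    pk <- unpack(par)
    pk$damping_hz <- pmax(pk$damping_hz, 1e-6)
    s <- model_fid(spectrum_model(pk), fid$dwell, fid$n_points)
    r <- s - fid$samples
    c(Re(r), Im(r))
  }
  fit <- minpack.lm::nls.lm(par = par0, fn = resid_fn,
                            control = minpack.lm::nls.lm.control(
                              maxiter = max_iter, ftol = 1e-12, ptol = 1e-12))
  if (fit$info %in% c(0, 5, 9)) {
    stop(sprintf("AMARES fit did not converge (nls.lm info %d, residual norm %.3g)",
                 fit$info, sqrt(fit$deviance)))
  }
  pk <- unpack(fit$par)
  pk$phase_rad <- atan2(sin(pk$phase_rad), cos(pk$phase_rad))
  fitted <- spectrum_model(pk)
  r <- resid_fn(fit$par)
  dof <- max(1L, 2L * fid$n_points - length(par0))
  noise_sd <- sqrt(sum(r^2) / dof)
  sig_energy <- sum(Mod(fid$samples)^2)
  crlb <- tryCatch({
    J <- fid_jacobian(fitted, fid$dwell, fid$n_points)
    fim <- Re(Conj(t(J)) %*% J) / noise_sd^2
    se <- sqrt(diag(solve(fim)))
    data.frame(name = pk$name,
               amplitude = se[seq(1, 4 * G, by = 4)],
               offset_hz = se[seq(2, 4 * G, by = 4)] / (2 * pi),
               damping = se[seq(3, 4 * G, by = 4)],
               phase_rad = se[seq(4, 4 * G, by = 4)])
  }, error = function(e) NULL)
  structure(list(model = fitted, crlb = crlb, noise_sd = noise_sd,
                 residual_energy = sum(r^2) / sig_energy,
                 converged = TRUE, info = fit$info, niter = fit$niter),
            class = "amares_fit")
}

#' @export
print.amares_fit <- function(x, ...) {
  cat(sprintf("Prior-knowledge fit: %d group(s), residual energy %.3g, noise sd %.3g\n",
              nrow(x$model$peaks), x$residual_energy, x$noise_sd))
  print(x$model)
  invisible(x)
}

#' Partial saturation signal
#'
#' Steady-state signal of a spoiled acquisition at repetition time `tr` and
#' flip angle `theta`:
#' \deqn{S = M_0 \sin\theta\,(1 - e^{-TR/T_1}) / (1 - e^{-TR/T_1}\cos\theta)}
#'
#' @param theta Flip angle in degrees (0 < theta < 180).
#' @param tr Repetition time in seconds (> 0).
#' @param t1 Longitudinal relaxation time in seconds (> 0).
#' @param m0 Equilibrium magnetization (arbitrary units).
#' @return Signal in the units of `m0`. Vectorized over all arguments.
#' @export
saturation_signal <- function(theta, tr, t1, m0 = 1) {
  if (any(theta <= 0 | theta >= 180)) stop("theta must be in (0, 180) degrees")
  if (any(tr <= 0) || any(t1 <= 0)) stop("tr and t1 must be > 0")
  th <- theta * pi / 180
  e1 <- exp(-tr / t1)
  m0 * sin(th) * (1 - e1) / (1 - e1 * cos(th))
}

#' Multi-TR reference flip-angle fit
#'
#' Least-squares fit of the partial saturation equation over (theta, M0) to
#' signal magnitudes acquired at several repetition times with known T1
#' (the eight-TR protocol: 0.5, 1, 2, 3, 4, 6, 8, 10 s). Given the
#' excitation pulse duration, the fitted flip angle is also converted to
#' gamma*B1.
#'
#' @param signals Per-TR signal magnitudes.
#' @param trs Repetition times in seconds (>= 2 distinct values).
#' @param t1 Known T1 in seconds (e.g. 8.57 s for the phosphate phantom).
#' @param tp Hard excitation pulse duration in seconds (for the gamma*B1
#'   conversion); optional.
#' @return List with `theta_deg`, `m0`, `gamma_b1` (Hz, `NA` if `tp`
#'   missing), `rss`.
#' @export
fit_multi_tr <- function(signals, trs, t1, tp = NULL) {
  if (length(signals) != length(trs)) stop("signals and trs must match")
  if (length(unique(trs)) < 2L) stop("need at least 2 distinct TRs")
  # M0 is linear given theta: profile it out
  rss_theta <- function(theta) {
    s1 <- saturation_signal(theta, trs, t1, m0 = 1)
    m0 <- sum(s1 * signals) / sum(s1^2)
    sum((signals - m0 * s1)^2)
  }
  opt <- stats::optimize(rss_theta, interval = c(1e-3, 180 - 1e-3),
                         tol = 1e-10)
  theta <- opt$minimum
  s1 <- saturation_signal(theta, trs, t1, m0 = 1)
  m0 <- sum(s1 * signals) / sum(s1^2)
  list(theta_deg = theta, m0 = m0,
       gamma_b1 = if (is.null(tp)) NA_real_ else b1_from_flip_angle(theta, tp),
       rss = opt$objective)
}

#' Dual-TR reference flip-angle estimate
#'
#' Solves `S(theta, tr1, t1) / S(theta, tr2, t1) = s1 / s2` for theta by
#' bracketed root finding on (0, 180) degrees, given a known (e.g.
#' literature) T1.
#'
#' @param s1,s2 Signal magnitudes at the two repetition times.
#' @param tr1,tr2 Repetition times in seconds (distinct).
#' @param t1 Known T1 in seconds.
#' @return Flip angle in degrees.
#' @export
fit_dual_tr <- function(s1, s2, tr1, tr2, t1) {
  if (tr1 == tr2) stop("tr1 and tr2 must differ")
  target <- s1 / s2
  f <- function(theta) saturation_signal(theta, tr1, t1) /
    saturation_signal(theta, tr2, t1) - target
  lo <- 1e-6; hi <- 180 - 1e-6
  flo <- f(lo); fhi <- f(hi)
  if (is.na(flo) || is.na(fhi) || flo * fhi > 0)
    stop(sprintf("signal ratio %.4g outside the range attainable for TR = %g/%g s, T1 = %g s",
                 target, tr1, tr2, t1))
  stats::uniroot(f, c(lo, hi), tol = 1e-10)$root
}

#' Multi-flip-angle (sin-alpha) calibration fit
#'
#' Fits `A * sin(2*pi * c * V * tp)` to fully relaxed FID amplitudes
#' acquired over a transmit-voltage sweep, where `c` is the B1-per-volt
#' scaling (Hz/V) and `c * V * tp * 360` degrees is the flip angle. A sweep
#' through the signal null (flip > 180 degrees) pins down `c` without
#' ambiguity; the coarse grid over `c` followed by Levenberg-Marquardt
#' refinement handles the multimodal objective.
#'
#' @param amplitudes Signed (or complex, projected to signed) per-voltage
#'   peak amplitudes.
#' @param voltages Transmit voltages in volts.
#' @param tp Hard pulse duration in seconds.
#' @return List with `b1_per_volt` (Hz/V), `max_amplitude`,
#'   `gamma_b1_at` (function of voltage), `rss`. Warns when the sweep stays
#'   in the small-flip linear region (< 30 degrees), where `A` and `c` are
#'   nearly unidentifiable.
#' @export
fit_multi_fa <- function(amplitudes, voltages, tp) {
  if (length(amplitudes) != length(voltages))
    stop("amplitudes and voltages must match")
  if (is.complex(amplitudes)) {
    # project onto the dominant phase axis
    ph <- Arg(amplitudes[which.max(Mod(amplitudes))])
    amplitudes <- Re(amplitudes * exp(-1i * ph))
  }
  model <- function(par) par[1] * sin(2 * pi * par[2] * voltages * tp)
  rss <- function(par) sum((amplitudes - model(par))^2)
  # coarse grid over c: up to 2 full cycles across the sweep
  cmax <- 2 / (max(voltages) * tp)
  cgrid <- seq(cmax / 400, cmax, length.out = 400)
  best <- NULL
  for (cc in cgrid) {
    s <- sin(2 * pi * cc * voltages * tp)
    A <- sum(s * amplitudes) / sum(s^2)
    if (!is.finite(A)) next
    r <- rss(c(A, cc))
    if (is.null(best) || r < best$rss) best <- list(par = c(A, cc), rss = r)
  }
  fit <- minpack.lm::nls.lm(par = best$par,
                            fn = function(p) amplitudes - model(p),
                            control = minpack.lm::nls.lm.control(maxiter = 200))
  par <- fit$par
  if (par[1] < 0) { par[1] <- -par[1]; par[2] <- -par[2] }   # sign gauge
  max_flip <- 360 * abs(par[2]) * max(voltages) * tp
  if (max_flip < 30)
    warning("all flip angles < 30 degrees: amplitude and B1-per-volt are nearly collinear (ill-conditioned fit)")
  list(b1_per_volt = abs(par[2]), max_amplitude = par[1],
       gamma_b1_at = function(v) abs(par[2]) * v,
       rss = sum((amplitudes - model(par))^2))
}
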