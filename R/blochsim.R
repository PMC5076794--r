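# envelope values on the integration intervals (midpoints of the grid
# samples), so the integrated duration equals pulse_duration() exactly
midpoint_envelope <- function(pulse) {
  s <- pulse$samples
  n <- length(s)
  if (n < 2L) stop("pulse must have at least 2 samples")
  (s[-1] + s[-n]) / 2
}

#' Simulate spin evolution under a shaped off-resonance pulse
#'
#' Hard-pulse (piecewise-constant rotation) integration of the Bloch
#' equation without relaxation, vectorized over resonance offsets. Offsets
#' are expressed as (spin frequency minus pulse carrier) in Hz, so a peak
#' sitting 2000 Hz above the sensitizing pulse has offset +2000. By
#' convention a spin at positive offset accumulates positive free-precession
#' phase, and hence a positive Bloch-Siegert phase, matching the sign of the
#' pulse-to-peak offset.
#'
#' @param pulse A `pulse_shape`.
#' @param offsets Resonance offsets in Hz (finite).
#' @param gamma_b1 Peak amplitude in Hz; defaults to `pulse$gamma_b1_peak`.
#' @param initial Initial magnetization `c(Mx, My, Mz)` (norm <= 1);
#'   default equilibrium `c(0, 0, 1)`.
#' @param derotate If `TRUE` (default), the returned transverse
#'   magnetization is expressed in each spin's own rotating frame, i.e. the
#'   trivial free-precession phase `2*pi*offset*TP` is removed. A
#'   zero-amplitude pulse then leaves the state exactly unchanged, and the
#'   residual phase of an initially transverse state is the Bloch-Siegert
#'   phase (plus any direct-excitation perturbation).
#' @return A data frame of class `offset_response` with columns `offset_hz`,
#'   `mx`, `my`, `mz`, and `mxy` (complex `mx + 1i*my`).
#' @export
#' @examples
#' p <- make_fermi(optimized_fermi_params())
#' r <- simulate_pulse(p, offsets = 2000, gamma_b1 = 277,
#'                     initial = c(1, 0, 0))
#' Arg(r$mxy)   # ~ Bloch-Siegert phase, 0.159 rad
simulate_pulse <- function(pulse, offsets, gamma_b1 = NULL,
                           initial = c(0, 0, 1), derotate = TRUE) {
  stopifnot(inherits(pulse, "pulse_shape"))
  if (is.null(gamma_b1)) gamma_b1 <- pulse$gamma_b1_peak
  if (!is.numeric(gamma_b1) || !is.finite(gamma_b1))
    stop("gamma_b1 must be supplied (pulse has no gamma_b1_peak)")
  if (any(!is.finite(offsets))) stop("offsets must be finite")
  if (length(initial) != 3L || sqrt(sum(initial^2)) > 1 + 1e-9)
    stop("initial state must be a 3-vector with norm <= 1")
  # resolution guard: worst-case rotation per step <= 36 degrees
  wmax <- 2 * pi * sqrt(gamma_b1^2 + max(abs(offsets))^2)
  if (wmax * pulse$dt > 2 * pi / 10)
    stop(sprintf(paste0("dt = %g s too coarse for gamma_b1/offsets up to %g Hz ",
                        "(> 36 degrees rotation per step); reduce dt"),
                 pulse$dt, wmax / (2 * pi)))
  env <- midpoint_envelope(pulse)
  m <- bloch_profile_cpp(Re(env), Im(env), pulse$dt,
                         gamma_b1, as.numeric(offsets), as.numeric(initial))
  mxy <- complex(real = m[, 1], imaginary = m[, 2])
  if (derotate) mxy <- mxy * exp(-2i * pi * offsets * pulse_duration(pulse))
  structure(data.frame(offset_hz = as.numeric(offsets),
                       mx = Re(mxy), my = Im(mxy), mz = m[, 3],
                       mxy = mxy),
            class = c("offset_response", "data.frame"))
}

#' Stop-band deviation metric of a sensitizing pulse
#'
#' Quantifies unwanted direct excitation within the stop-band window as the
#' windowed sum of `|Mxy|^2` starting from thermal equilibrium (Mz = 1),
#' normalized to the 1 Hz-spacing convention: at 1 Hz spacing over
#' 1500-2500 Hz the metric is `sum(|Mxy|^2) / 1000` over 1001 offsets; a
#' coarser grid of `n` offsets is rescaled by `1001/n` so values remain
#' comparable.
#'
#' @param pulse A `pulse_shape`.
#' @param gamma_b1 Peak amplitude in Hz.
#' @param window Stop-band window in Hz (default `c(1500, 2500)`).
#' @param n_offsets Number of equally spaced offsets across the window
#'   (default 1001, i.e. 1 Hz spacing for the default window).
#' @return The dimensionless stop-band metric.
#' @export
stopband_metric <- function(pulse, gamma_b1, window = c(1500, 2500),
                            n_offsets = 1001L) {
  stopifnot(inherits(pulse, "pulse_shape"))
  if (length(window) != 2L || diff(window) <= 0)
    stop("stop-band window must be an increasing range of length 2")
  n_offsets <- as.integer(n_offsets)
  if (n_offsets < 2L) stop("n_offsets must be >= 2")
  offsets <- seq(window[1], window[2], length.out = n_offsets)
  env <- midpoint_envelope(pulse)
  mean_mxy2 <- stopband_mxy2_cpp(Re(env), Im(env),
                                 pulse$dt, gamma_b1, offsets)
  mean_mxy2 * 1001 / 1000
}

#' Estimator error caused by direct excitation
#'
#' Simulates noiseless Bloch-Siegert acquisitions for one measurement
#' strategy with a full Bloch simulation (so the fitted phases contain the
#' direct-excitation perturbation as well as the Bloch-Siegert phase), feeds
#' the simulated phases to the corresponding estimator, and returns the
#' percent error of the recovered gamma*B1.
#'
#' Peak offsets are given relative to the sensitizing pulse carrier. For
#' strategy `"A"` supply the two symmetric arm offsets (e.g. `c(2000,
#' -2000)`); for `"Bprime"` a single offset; for `"Bdouble"` and `"C"` the
#' vector of per-peak offsets of the single carrier placement.
#'
#' @param pulse A `pulse_shape`.
#' @param strategy One of `"A"`, `"Bprime"`, `"Bdouble"`, `"C"`.
#' @param peaks Peak offset(s) from the pulse carrier, Hz.
#' @param gamma_b1_true True peak amplitude in Hz.
#' @return Percent error `100 * (estimate - true) / true`. If the phase
#'   geometry is invalid for the estimator (negative discriminant), returns
#'   `NA` with attribute `reason`.
#' @export
#' @examples
#' p <- make_fermi(optimized_fermi_params(), dt = 2e-6)
#' # symmetric two-peak single acquisition, 1950 Hz separation: ~19% error
#' direct_excitation_error(p, "C", peaks = c(-975, 975), gamma_b1_true = 277)
direct_excitation_error <- function(pulse, strategy = c("A", "Bprime", "Bdouble", "C"),
                                    peaks, gamma_b1_true) {
  strategy <- match.arg(strategy)
  bt <- normalized_squared_integral(pulse)
  sim_phase <- function(offs) {
    r <- simulate_pulse(pulse, offsets = offs, gamma_b1 = gamma_b1_true,
                        initial = c(1, 0, 0))
    Arg(r$mxy)
  }
  est <- switch(strategy,
    A = {
      if (length(peaks) != 2L || sum(peaks) != 0)
        stop("strategy A requires two symmetric arm offsets, e.g. c(2000, -2000)")
      w <- abs(peaks[1])
      ph <- sim_phase(peaks)     # phases at +w and -w
      dphi <- ph[which(peaks > 0)] - ph[which(peaks < 0)]
      estimate_A(dphi, bs_model(bt, w))
    },
    Bprime = {
      if (length(peaks) != 1L) stop("strategy Bprime uses a single peak offset")
      estimate_Bprime(sim_phase(peaks), 0, bs_model(bt, peaks))
    },
    Bdouble = {
      estimate_Bdouble(sim_phase(peaks), rep(0, length(peaks)), peaks,
                       bs_model(bt, peaks[1]))
    },
    C = {
      estimate_C(sim_phase(peaks), peaks, bs_model(bt, peaks[1]))
    })
  if (!est$valid) {
    out <- NA_real_
    attr(out, "reason") <- est$reason
    return(out)
  }
  100 * (est$gamma_b1 - gamma_b1_true) / gamma_b1_true
}

#' Export an offset response as CSV
#' @param response An `offset_response` from [simulate_pulse()].
#' @param path Output CSV path.
#' @return `path`, invisibly.
#' @export
write_offset_response_csv <- function(response, path) {
  utils::write.csv(data.frame(offset_hz = response$offset_hz,
                              re = response$mx, im = response$my,
                              mz = response$mz),
                   path, row.names = FALSE)
  invisible(path)
}
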