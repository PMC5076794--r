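#' Fermi pulse parameters
#'
#' Parameter set for a Fermi-shaped Bloch-Siegert sensitizing pulse with
#' envelope \eqn{1 / (1 + \exp((|t| - T_0)/a))} on the centered interval
#' \eqn{t \in [-T_P/2, +T_P/2]}. `t0` controls the flat-top half-width and
#' `a` the transition width; both have units of seconds.
#'
#' @param tp Total pulse duration in seconds (> 0).
#' @param t0 Flat-top half-width parameter in seconds, with `0 < t0 < tp/2`.
#' @param a Transition-width parameter in seconds (> 0).
#' @param af Peak amplitude scale (dimensionless). The envelope itself is
#'   normalized to maximum magnitude 1; `af` is retained as metadata.
#' @param omega_rf Carrier frequency offset of the pulse in Hz. The offset is
#'   stored, not pre-mixed into the envelope samples.
#'
#' @return An object of class `fermi_params`.
#' @seealso [make_fermi()], [optimize_fermi()]
#' @export
#' @examples
#' fermi_params(tp = 3.5e-3, t0 = 0.875e-3, a = 0.224e-3)
fermi_params <- function(tp, t0, a, af = 1, omega_rf = 2000) {
  if (!is.numeric(tp) || length(tp) != 1L || !is.finite(tp) || tp <= 0)
    stop("invalid FermiParams: 'tp' must be a positive finite scalar (TP > 0)")
  if (!is.numeric(t0) || length(t0) != 1L || !is.finite(t0) ||
      t0 <= 0 || t0 > tp / 2)
    stop("invalid FermiParams: 't0' must satisfy 0 < T0 <= TP/2")
  if (!is.numeric(a) || length(a) != 1L || !is.finite(a) || a <= 0)
    stop("invalid FermiParams: 'a' must satisfy a > 0")
  structure(list(tp = tp, t0 = t0, a = a, af = af, omega_rf = omega_rf),
            class = "fermi_params")
}

#' @export
print.fermi_params <- function(x, ...) {
  cat(sprintf("Fermi pulse parameters: TP = %g ms, T0 = %g ms, a = %g ms, carrier offset = %g Hz\n",
              x$tp * 1e3, x$t0 * 1e3, x$a * 1e3, x$omega_rf))
  invisible(x)
}

#' The canonical optimized Fermi pulse parameters
#'
#' The grid-search optimum for 7T cardiac 31P work: TP = 3.5 ms,
#' T0 = 0.875 ms, a = 0.224 ms (see [optimize_fermi()]).
#'
#' @param omega_rf Carrier offset in Hz (default +2000 Hz from the peak of
#'   interest).
#' @return A `fermi_params` object.
#' @export
optimized_fermi_params <- function(omega_rf = 2000) {
  fermi_params(tp = 3.5e-3, t0 = 0.875e-3, a = 0.224e-3, omega_rf = omega_rf)
}

#' Construct a sampled pulse shape
#'
#' Low-level constructor for a sampled complex RF envelope. Most users will
#' call [make_fermi()] or [make_rect()] instead.
#'
#' @param samples Complex (or numeric) envelope samples, max magnitude 1.
#' @param dt Sample spacing in seconds.
#' @param gamma_b1_peak Peak RF amplitude expressed as gamma*B1 in Hz, or NA
#'   if to be supplied at simulation time.
#' @param omega_rf Carrier offset in Hz.
#' @param params Optional `fermi_params` provenance.
#' @return An object of class `pulse_shape`.
#' @export
pulse_shape <- function(samples, dt, gamma_b1_peak = NA_real_,
                        omega_rf = 0, params = NULL) {
  samples <- as.complex(samples)
  if (any(!is.finite(Mod(samples)))) stop("invalid PulseShape: non-finite samples")
  if (max(Mod(samples)) > 1 + 1e-9)
    stop("invalid PulseShape: |samples| must be <= 1 (unit-peak normalization)")
  if (!is.numeric(dt) || dt <= 0) stop("invalid PulseShape: dt must be > 0")
  structure(list(samples = samples, dt = dt, gamma_b1_peak = gamma_b1_peak,
                 omega_rf = omega_rf, params = params),
            class = "pulse_shape")
}

#' @export
print.pulse_shape <- function(x, ...) {
  cat(sprintf("Pulse shape: %d samples, dt = %g us, duration = %g ms, carrier offset = %g Hz\n",
              length(x$samples), x$dt * 1e6, pulse_duration(x) * 1e3, x$omega_rf))
  if (is.finite(x$gamma_b1_peak))
    cat(sprintf("  peak amplitude gamma*B1 = %g Hz\n", x$gamma_b1_peak))
  invisible(x)
}

#' Total duration of a sampled pulse
#'
#' Samples are grid-point values on `[-TP/2, +TP/2]`, so a pulse of `n`
#' samples spans `(n - 1) * dt` seconds.
#'
#' @param pulse A `pulse_shape`.
#' @return Duration in seconds.
#' @export
pulse_duration <- function(pulse) (length(pulse$samples) - 1L) * pulse$dt

#' Synthesize a Fermi pulse envelope
#'
#' Samples the Fermi envelope \eqn{1/(1+\exp((|t|-T_0)/a))} on a centered
#' grid over `[-TP/2, +TP/2]`. The envelope is real and even; the carrier
#' offset is stored as metadata and applied by the simulator.
#'
#' @param params A [fermi_params()] object.
#' @param dt Sample spacing in seconds; must resolve the pulse
#'   (`dt <= tp/50`). Default 1 us.
#' @param gamma_b1_peak Optional peak amplitude in Hz to attach.
#' @return A `pulse_shape`.
#' @export
#' @examples
#' p <- make_fermi(optimized_fermi_params())
#' normalized_squared_integral(p)   # ~1.32e-3 s
make_fermi <- function(params, dt = 1e-6, gamma_b1_peak = NA_real_) {
  stopifnot(inherits(params, "fermi_params"))
  if (dt > params$tp / 50)
    stop("dt too coarse: require dt <= TP/50 to resolve the Fermi envelope")
  n <- round(params$tp / dt)
  t <- (seq_len(n + 1L) - 1L) * dt - params$tp / 2
  env <- fermi_envelope(t, params$t0, params$a)
  pulse_shape(env, dt = dt, gamma_b1_peak = gamma_b1_peak,
              omega_rf = params$omega_rf, params = params)
}

#' Evaluate the Fermi envelope
#' @param t Time in seconds (vector), centered so the flat top is at t = 0.
#' @param t0,a Shape parameters in seconds.
#' @return Envelope values in `[0, 1]`.
#' @export
fermi_envelope <- function(t, t0, a) 1 / (1 + exp((abs(t) - t0) / a))

#' Rectangular (hard) pulse
#'
#' @param tp Duration in seconds.
#' @param dt Sample spacing in seconds.
#' @param gamma_b1_peak Optional peak amplitude in Hz.
#' @param omega_rf Carrier offset in Hz.
#' @return A `pulse_shape` with constant unit envelope.
#' @export
make_rect <- function(tp, dt = 1e-6, gamma_b1_peak = NA_real_, omega_rf = 0) {
  n <- round(tp / dt)
  pulse_shape(rep(1 + 0i, n + 1L), dt = dt, gamma_b1_peak = gamma_b1_peak,
              omega_rf = omega_rf)
}

#' Normalized pulse-envelope squared integral
#'
#' Computes \eqn{\tilde{B} = \int |f(t)|^2 dt} of the unit-peak envelope by
#' trapezoidal quadrature on the sample grid. This is the shape factor that
#' converts an accumulated Bloch-Siegert phase into a peak gamma*B1 value;
#' its units are seconds. For a rectangular pulse it equals the duration.
#'
#' @param pulse A `pulse_shape`.
#' @return The squared integral in seconds.
#' @export
normalized_squared_integral <- function(pulse) {
  stopifnot(inherits(pulse, "pulse_shape"))
  y <- Mod(pulse$samples)^2
  n <- length(y)
  if (n < 2L) stop("pulse must have at least 2 samples")
  sum((y[-1] + y[-n]) / 2) * pulse$dt
}

#' Grid-search specification for Fermi pulse optimization
#'
#' Defaults mirror the design search used for the 7T cardiac protocol:
#' TP from 1 to 10 ms in 0.5 ms steps, T0 from 0.1 to 0.5 TP in steps of
#' 0.05 TP, a from 0.01 to 0.3 TP in steps of 0.001 TP, peak amplitudes 100
#' to 1000 Hz in steps of 100 Hz, and a 1500-2500 Hz stop-band window.
#'
#' @param tp_values Candidate total durations in seconds.
#' @param t0_frac,a_frac Fractions of TP at which to place T0 and a.
#' @param gamma_b1_values Peak amplitudes (Hz) over which the stop-band
#'   metric is aggregated.
#' @param window Stop-band window in Hz, length 2.
#' @param n_offsets Number of offsets sampled across the window.
#' @param threshold Feasibility threshold on the aggregated stop-band metric.
#' @param dt Sample spacing for the candidate envelopes (5 us default for
#'   search speed; see [make_fermi()] for the synthesis default).
#' @param aggregate Either `"max"` (conservative worst case over
#'   `gamma_b1_values`, the default) or `"mean"`.
#' @return An object of class `grid_search_spec`.
#' @export
grid_search_spec <- function(tp_values = seq(1e-3, 10e-3, by = 0.5e-3),
                             t0_frac = seq(0.1, 0.5, by = 0.05),
                             a_frac = seq(0.01, 0.3, by = 0.001),
                             gamma_b1_values = seq(100, 1000, by = 100),
                             window = c(1500, 2500),
                             n_offsets = 101L,
                             threshold = 0.01,
                             dt = 5e-6,
                             aggregate = c("max", "mean")) {
  aggregate <- match.arg(aggregate)
  if (length(tp_values) < 1L || length(t0_frac) < 1L || length(a_frac) < 1L ||
      length(gamma_b1_values) < 1L)
    stop("grid ranges must be nonempty")
  if (length(window) != 2L || diff(window) <= 0)
    stop("stop-band window must be an increasing range of length 2")
  structure(list(tp_values = tp_values, t0_frac = t0_frac, a_frac = a_frac,
                 gamma_b1_values = gamma_b1_values, window = window,
                 n_offsets = as.integer(n_offsets), threshold = threshold,
                 dt = dt, aggregate = aggregate),
            class = "grid_search_spec")
}

#' Evaluate the stop-band metric over one (T0, a) grid slice at fixed TP
#'
#' Workhorse for [optimize_fermi()]: for each (T0, a) cell, computes the
#' stop-band deviation metric for every peak amplitude in the spec and
#' aggregates across amplitudes (worst case by default).
#'
#' @param tp Total duration in seconds.
#' @param spec A [grid_search_spec()].
#' @param evaluator Function `(pulse, gamma_b1, window, n_offsets)` returning
#'   the scalar stop-band metric; defaults to [stopband_metric()].
#' @return A data frame with columns `t0`, `a` (seconds), per-amplitude
#'   metrics aggregated into `metric`.
#' @export
fermi_grid_slice <- function(tp, spec, evaluator = NULL) {
  stopifnot(inherits(spec, "grid_search_spec"))
  if (is.null(evaluator)) {
    evaluator <- function(pulse, gamma_b1, window, n_offsets)
      stopband_metric(pulse, gamma_b1, window = window, n_offsets = n_offsets)
  }
  grid <- expand.grid(a = spec$a_frac * tp, t0 = spec$t0_frac * tp,
                      KEEP.OUT.ATTRS = FALSE)
  # row-major order in (T0 ascending, a ascending): expand.grid varies 'a'
  # fastest, so reorder columns for clarity
  grid <- grid[, c("t0", "a")]
  agg <- if (spec$aggregate == "max") max else mean
  metric <- vapply(seq_len(nrow(grid)), function(i) {
    params <- fermi_params(tp = tp, t0 = grid$t0[i], a = grid$a[i])
    pulse <- make_fermi(params, dt = spec$dt)
    vals <- vapply(spec$gamma_b1_values, function(b1)
      evaluator(pulse, b1, spec$window, spec$n_offsets), numeric(1))
    agg(vals)
  }, numeric(1))
  grid$metric <- metric
  grid
}

#' Fermi pulse grid-search optimization
#'
#' Runs the full design search: for each candidate duration TP (shortest
#' first), evaluates the aggregated stop-band metric over the (T0, a) grid
#' and selects the first TP whose minimum falls below the threshold; the
#' returned parameters are the argmin (T0, a) of that slice. Ties in the
#' argmin are broken by first occurrence in row-major (T0 ascending, a
#' ascending) order.
#'
#' @param spec A [grid_search_spec()].
#' @param evaluator Optional stop-band evaluator, see [fermi_grid_slice()].
#' @param verbose Print progress per TP.
#' @return A list of class `fermi_search` with elements `feasible` (logical),
#'   `params` (the selected or best-found [fermi_params()]), `metric` (its
#'   aggregated stop-band value), and `tables` (per-TP metric tables).
#' @export
optimize_fermi <- function(spec = grid_search_spec(), evaluator = NULL,
                           verbose = FALSE) {
  stopifnot(inherits(spec, "grid_search_spec"))
  tps <- sort(spec$tp_values)
  tables <- list()
  best <- NULL
  for (tp in tps) {
    slice <- fermi_grid_slice(tp, spec, evaluator = evaluator)
    tables[[sprintf("%g", tp)]] <- slice
    i <- which.min(slice$metric)
    if (verbose)
      message(sprintf("TP = %.2f ms: min metric %.3g at T0 = %.3f ms, a = %.4f ms",
                      tp * 1e3, slice$metric[i], slice$t0[i] * 1e3, slice$a[i] * 1e3))
    cand <- list(params = fermi_params(tp, slice$t0[i], slice$a[i]),
                 metric = slice$metric[i])
    if (is.null(best) || cand$metric < best$metric) best <- cand
    if (slice$metric[i] < spec$threshold) {
      return(structure(list(feasible = TRUE, params = cand$params,
                            metric = cand$metric, tables = tables),
                       class = "fermi_search"))
    }
  }
  structure(list(feasible = FALSE, params = best$params, metric = best$metric,
                 tables = tables),
            class = "fermi_search")
}

#' @export
print.fermi_search <- function(x, ...) {
  if (x$feasible) {
    cat("Feasible Fermi pulse found:\n")
  } else {
    cat("No feasible pulse below threshold; best candidate found:\n")
  }
  print(x$params)
  cat(sprintf("  aggregated stop-band metric = %.4g\n", x$metric))
  invisible(x)
}

#' Export a pulse shape as CSV with a JSON sidecar
#'
#' Writes a two-column CSV (`time_s`, `amplitude`) of the real envelope (a
#' third column `amplitude_im` is added when the envelope is complex) and a
#' JSON sidecar carrying the sampling metadata and, if available, the
#' generating Fermi parameters.
#'
#' @param pulse A `pulse_shape`.
#' @param path CSV output path; the sidecar is written to `<path>.json`.
#' @return `path`, invisibly.
#' @export
write_pulse_csv <- function(pulse, path) {
  stopifnot(inherits(pulse, "pulse_shape"))
  n <- length(pulse$samples)
  t <- (seq_len(n) - 1L) * pulse$dt - pulse_duration(pulse) / 2
  df <- data.frame(time_s = t, amplitude = Re(pulse$samples))
  if (any(Im(pulse$samples) != 0)) df$amplitude_im <- Im(pulse$samples)
  utils::write.csv(df, path, row.names = FALSE)
  side <- list(dt = pulse$dt, gamma_b1_peak = pulse$gamma_b1_peak,
               omega_rf = pulse$omega_rf)
  if (!is.null(pulse$params))
    side$fermi_params <- list(tp = pulse$params$tp, t0 = pulse$params$t0,
                              a = pulse$params$a, af = pulse$params$af,
                              omega_rf = pulse$params$omega_rf)
  jsonlite::write_json(side, paste0(path, ".json"), auto_unbox = TRUE,
                       digits = NA, na = "null")
  invisible(path)
}

#' Read a pulse shape from CSV (+ JSON sidecar)
#'
#' @param path CSV path written by [write_pulse_csv()].
#' @return A `pulse_shape`.
#' @export
read_pulse_csv <- function(path) {
  df <- utils::read.csv(path)
  side_path <- paste0(path, ".json")
  side <- if (file.exists(side_path)) jsonlite::read_json(side_path) else list()
  amp <- df$amplitude
  if (!is.null(df$amplitude_im)) amp <- complex(real = amp, imaginary = df$amplitude_im)
  dt <- if (!is.null(side$dt)) side$dt else stats::median(diff(df$time_s))
  params <- NULL
  if (!is.null(side$fermi_params)) {
    fp <- side$fermi_params
    params <- fermi_params(fp$tp, fp$t0, fp$a, af = fp$af, omega_rf = fp$omega_rf)
  }
  pulse_shape(amp, dt = dt,
              gamma_b1_peak = if (is.null(side$gamma_b1_peak) ||
                                  is.na(side$gamma_b1_peak)) NA_real_
                              else as.numeric(side$gamma_b1_peak),
              omega_rf = if (is.null(side$omega_rf)) 0 else side$omega_rf,
              params = params)
}
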