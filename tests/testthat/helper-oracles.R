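# Shared fixtures for the suite. The optimized sensitizing pulse and its
# squared integral are computed once per test run; the frozen constants
# below were obtained from an independent fine-grid quadrature oracle
# (stats::integrate at rel.tol 1e-12 agrees with the 10 ns trapezoid to
# 10 digits).

OPT_B_TILDE <- 1.319668339e-3          # seconds
GAMMA_B1_TRUE <- 277                   # Hz, representative cardiac value

opt_pulse <- local({
  p <- NULL
  function(dt = 1e-6) {
    if (is.null(p) || abs(p$dt - dt) > 1e-12)
      p <<- make_fermi(optimized_fermi_params(), dt = dt)
    p
  }
})

opt_model <- function(omega_rf = 2000)
  bs_model(normalized_squared_integral(opt_pulse()), omega_rf)

expect_rel_equal <- function(object, expected, tol) {
  expect_lt(abs(object - expected) / abs(expected), tol)
}
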