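#' Self-contained worked-example fixtures
#'
#' Generates, entirely in code, the bundle of inputs used by the examples
#' and the test suite: the optimized Fermi sensitizing pulse, the
#' thigh/cardiac worked-example phase differences (55.6 and 86.9 degrees at
#' a 2000 Hz offset), a small point-source CSI simulation (a 2 cm phosphate
#' cube in a 4 x 4 x 4 grid), a uniform-phantom 16 x 8 x 8 CSI simulation
#' under a 10 cm loop, and the symmetric two-peak single-acquisition
#' direct-excitation scenario.
#'
#' @param seed Integer seed applied to every stochastic component (the
#'   default fixtures are noiseless, so regeneration is bit-identical).
#' @param with_csi If `FALSE`, the two CSI simulations are skipped (they
#'   dominate the runtime).
#' @return Named list of fixtures.
#' @export
make_fixtures <- function(seed = 1L, with_csi = TRUE) {
  pulse <- make_fermi(optimized_fermi_params())
  bt <- normalized_squared_integral(pulse)
  model <- bs_model(bt, 2000)
  fx <- list(
    seed = seed,
    pulse = pulse,
    b_tilde = bt,
    model = model,
    phase_pairs = data.frame(
      label = c("thigh", "cardiac"),
      delta_phi_deg = c(55.6, 86.9),
      gamma_b1_hz = c(estimate_A(55.6 * pi / 180, model)$gamma_b1,
                      estimate_A(86.9 * pi / 180, model)$gamma_b1)),
    method_c_scenario = list(peaks = c(-975, 975), gamma_b1_true = 277)
  )
  if (with_csi) {
    singlet <- spectrum_model(data.frame(
      name = "phosphate", offset_hz = 0, amplitude = 1, damping_hz = 15,
      phase_rad = 0))
    # 2 cm cube centered inside the voxel at grid position (2, 2, 2)
    cube <- phantom_scene(list(list(
      center = c(0.07, -0.01, -0.01), size = c(0.02, 0.02, 0.02),
      model = singlet, t1 = 8.57)))
    fx$point_source_csi <- simulate_csi(
      cube,
      csi_protocol(matrix_size = c(4L, 4L, 4L), fov_mm = c(80, 80, 80),
                   center_mm = c(60, 0, 0), n_points = 256L),
      coil = NULL, sens_pulse = pulse, carriers_hz = c(2000, -2000),
      sens_gamma_b1_ref = 300, exc_gamma_b1_ref = 300, subgrid = 2L,
      seed = seed)
    box <- phantom_scene(list(list(
      center = c(0.075, 0, 0), size = c(0.12, 0.27, 0.27),
      model = singlet, t1 = 8.57)))
    # ideal-voxel sampling (subgrid = 1): each voxel sees the field at its
    # center, as in a per-voxel map display; intravoxel dispersion is
    # studied separately with intravoxel_analysis()
    fx$uniform_csi <- simulate_csi(
      box,
      csi_protocol(matrix_size = c(16L, 8L, 8L), fov_mm = c(150, 320, 320),
                   center_mm = c(75, 0, 0), n_points = 256L),
      coil = loop_coil(radius = 0.05), sens_pulse = pulse,
      carriers_hz = c(2000, -2000), ref_point = c(0, 0, 0.1),
      sens_gamma_b1_ref = 450, exc_gamma_b1_ref = 250, subgrid = 1L,
      seed = seed)
  }
  fx
}
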