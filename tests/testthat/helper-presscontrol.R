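# Shared fixtures: everything is generated in code from the packaged
# parameter sets; no stored data.

nominal_params <- function() press_params("no_pmm")
nominal_geom <- function() tooling_geometry()

zero_noise <- c(weight = 0, f_pc = 0, f_mc = 0, rate = 0)

# a noise-free measurement window of n records from a plant with `params`,
# probed at small deterministic input perturbations around the nominal point
make_window <- function(params, n = 31, geometry = nominal_geom(),
                        glidant_density = FALSE, cl = 0.2,
                        u0 = NULL) {
  if (is.null(u0)) {
    u0 <- calibrate_nominal_inputs(press_params(
      if (glidant_density) "cs2_nominal" else "no_pmm"
    ), geometry, glidant_density = glidant_density)
  }
  # deterministic excitation so several parameters are identifiable
  wig <- function(amp, per, t) amp * sin(2 * pi * t / per)
  u <- tibble::tibble(
    h_fill = u0[["h_fill"]] + wig(0.15, 11, 1:n),
    h_pc = u0[["h_pc"]] + wig(0.08, 7, 1:n),
    h_in_die = u0[["h_in_die"]] + 0.08 + wig(0.02, 5, 1:n),
    n_t = u0[["n_t"]] + wig(0.8, 13, 1:n),
    cl = cl
  )
  out <- evaluate_outputs(u, params, geometry, glidant_density = glidant_density)
  tibble::tibble(
    time = 1:n,
    weight = out$weight, f_pc = out$f_pc, f_mc = out$f_mc, rate = out$rate,
    h_fill = u$h_fill, h_pc = u$h_pc, h_in_die = u$h_in_die, n_t = u$n_t,
    cl = u$cl
  )
}
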