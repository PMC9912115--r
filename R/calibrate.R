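#' Calibrate nominal inputs to the nominal operating point
#'
#' The case studies operate around the steady outputs 210 mg tablet weight,
#' 0.3 kN pre-compression force, 6.9 kg/h production rate and 4.2 MPa tensile
#' strength. The tooling geometry fixes the die, turret and feed frame, so
#' the nominal manipulated inputs are obtained by inverting the output map at
#' those targets. The inversion is triangular -- turret speed follows from
#' weight and rate, the dosing position from weight, the pre-compression
#' thickness from the pre-compression force, and the main compression
#' thickness from the tensile strength -- and each stage is solved with a
#' bracketed root find on the full forward model.
#'
#' @param params a [model_parameters()] object.
#' @param geometry a [tooling_geometry()].
#' @param glidant_density whether the glidant bulk-density sub-model is
#'   active (case study 2).
#' @param targets named numeric vector with elements `weight` (mg), `f_pc`
#'   (kN), `rate` (kg/h), `sigma_t` (MPa).
#' @param cl nominal glidant concentration, % w/w.
#' @param tol relative root-finding tolerance.
#' @return a [process_inputs()] vector reproducing the targets.
#' @examples
#' u0 <- calibrate_nominal_inputs(press_params("no_pmm"), tooling_geometry())
#' evaluate_outputs(u0, press_params("no_pmm"), tooling_geometry())
#' @export
calibrate_nominal_inputs <- function(params, geometry,
                                     glidant_density = FALSE,
                                     targets = c(weight = 210, f_pc = 0.3,
                                                 rate = 6.9, sigma_t = 4.2),
                                     cl = 0.2, tol = 1e-10) {
  stopifnot(all(c("weight", "f_pc", "rate", "sigma_t") %in% names(targets)))
  n_t <- targets[["rate"]] /
    (targets[["weight"]] * geometry$n_stations * 60 * 1e-6)

  eval1 <- function(h_fill, h_pc, h_in_die) {
    press_eval_core(
      list(h_fill = h_fill, h_pc = h_pc, h_in_die = h_in_die,
           n_t = n_t, cl = cl),
      params, geometry, glidant_density
    )
  }

  f_w <- function(h) eval1(h, h / 2, h / 4)$weight - targets[["weight"]]
  h_fill <- stats::uniroot(f_w, c(0.5, 20), tol = tol)$root

  f_pc <- function(h) eval1(h_fill, h, h / 2)$f_pc - targets[["f_pc"]]
  h_pc <- stats::uniroot(f_pc, c(0.5, h_fill), tol = tol)$root

  f_st <- function(h) eval1(h_fill, h_pc, h)$sigma_t - targets[["sigma_t"]]
  h_in_die <- stats::uniroot(f_st, c(0.4, h_pc), tol = tol)$root

  process_inputs(h_fill = h_fill, h_pc = h_pc, h_in_die = h_in_die,
                 n_t = n_t, cl = cl)
}
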