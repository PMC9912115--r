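#' Compaction-model parameter set
#'
#' Bundles every fitted constant of the tablet-press mechanistic model into a
#' validated named list. Defaults are the case-study-1 nominal (no-mismatch)
#' values; the glidant bulk-density block (`rho_b_inf`, `rho_b_0`, `r1`--`r3`)
#' may be left `NA` when that sub-model is inactive.
#'
#' @param xi1,xi2 dimensionless die-filling correction constants.
#' @param rho_b bulk density in g/cm^3, used when the glidant bulk-density
#'   model is inactive.
#' @param rho_c Kawakita critical relative density (0 < rho_c < 1).
#' @param kaw_a Kawakita `a`, the maximum degree of compression (0 < a < 1).
#' @param kaw_inv_b Kawakita `1/b` pressure scale in MPa.
#' @param rho_t true (solid) density in g/cm^3.
#' @param eps0 in-die elastic recovery at full compaction.
#' @param rho_c_eps relative density below which tablets show no elastic
#'   recovery.
#' @param sigma0 tensile strength at zero porosity in MPa (the glidant-free
#'   asymptote `sigma_0,phi`).
#' @param rho_c0,rho_cinf critical tensile-strength relative density at zero
#'   and infinite glidant shear.
#' @param b1,b2,b3 glidant tensile-strength lumping constants.
#' @param rho_b_inf,rho_b_0 bulk density at infinite and zero glidant shear,
#'   g/cm^3 (`NA` when inactive).
#' @param r1,r2,r3 glidant bulk-density lumping constants (`NA` when inactive).
#' @return an object of class `press_params` (a validated named list).
#' @seealso [press_params()] for the packaged parameter sets.
#' @examples
#' p <- model_parameters()
#' p$kaw_inv_b
#' @export
model_parameters <- function(xi1 = 0.036, xi2 = 0.030, rho_b = 0.365,
                             rho_c = 0.265, kaw_a = 0.80, kaw_inv_b = 10.26,
                             rho_t = 1.53, eps0 = 0.08, rho_c_eps = 0.57,
                             sigma0 = 11.67, rho_c0 = 0.57, rho_cinf = 0.61,
                             b1 = 0.31, b2 = 0.38, b3 = 8.40,
                             rho_b_inf = NA_real_, rho_b_0 = NA_real_,
                             r1 = NA_real_, r2 = NA_real_, r3 = NA_real_) {
  p <- list(
    xi1 = xi1, xi2 = xi2, rho_b = rho_b, rho_c = rho_c, kaw_a = kaw_a,
    kaw_inv_b = kaw_inv_b, rho_t = rho_t, eps0 = eps0, rho_c_eps = rho_c_eps,
    sigma0 = sigma0, rho_c0 = rho_c0, rho_cinf = rho_cinf,
    b1 = b1, b2 = b2, b3 = b3,
    rho_b_inf = rho_b_inf, rho_b_0 = rho_b_0, r1 = r1, r2 = r2, r3 = r3
  )
  p <- lapply(p, as.numeric)
  validate_model_parameters(p)
  structure(p, class = "press_params")
}

validate_model_parameters <- function(p) {
  stopifnot(
    p$rho_b > 0, p$rho_t > 0,
    p$rho_c > 0, p$rho_c < 1,
    p$kaw_a > 0, p$kaw_a < 1,
    p$kaw_inv_b > 0,
    p$eps0 >= 0,
    p$rho_c_eps >= 0, p$rho_c_eps < 1,
    p$sigma0 > 0,
    p$rho_c0 < p$rho_cinf, p$rho_cinf < 1
  )
  gl <- c(p$rho_b_inf, p$rho_b_0, p$r1, p$r2, p$r3)
  if (any(!is.na(gl))) {
    if (any(is.na(gl))) {
      rlang::abort("glidant bulk-density block must be fully specified or fully NA")
    }
    stopifnot(p$rho_b_0 > 0, p$rho_b_0 < p$rho_b_inf, p$r3 > 0)
  }
  invisible(p)
}

#' Load a packaged parameter set
#'
#' The four fitted parameter columns used by the two case studies ship as
#' plain-text YAML fixtures: `"no_pmm"`, `"mild_pmm"`, `"high_pmm"` (plant
#' sets for case study 1) and `"cs2_nominal"` (case study 2, with the glidant
#' bulk-density block active).
#'
#' @param name one of `"no_pmm"`, `"mild_pmm"`, `"high_pmm"`, `"cs2_nominal"`,
#'   or a path to a YAML file with one key per model constant.
#' @return a [model_parameters()] object.
#' @examples
#' press_params("mild_pmm")$rho_b
#' @export
press_params <- function(name) {
  path <- if (file.exists(name)) {
    name
  } else {
    system.file("extdata", "params", paste0(name, ".yaml"),
                package = "presscontrol")
  }
  if (!nzchar(path) || !file.exists(path)) {
    rlang::abort(sprintf(
      "unknown parameter set '%s'; packaged sets are no_pmm, mild_pmm, high_pmm, cs2_nominal",
      name
    ))
  }
  vals <- yaml::read_yaml(path)
  vals <- lapply(vals, function(v) if (is.null(v)) NA_real_ else as.numeric(v))
  do.call(model_parameters, vals)
}

#' Write a parameter set to a YAML file
#'
#' @param params a [model_parameters()] object.
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_press_params <- function(params, path) {
  vals <- unclass(params)
  yaml::write_yaml(vals, path)
  invisible(path)
}

#' Tooling and press geometry
#'
#' Die/turret constants of the rotary press. The defaults describe a 10 mm
#' round D-type tool with a shallow 1 mm cup on a 10-station turret; the feed
#' frame speed is fixed so that the turret-to-feed-frame speed ratio is one at
#' the nominal operating point, and the feed-frame/hopper holdup and baseline
#' mixing time set the glidant shear model.
#'
#' @param die_diameter_D die diameter, mm.
#' @param cup_depth_h punch cup depth, mm (must be smaller than the die
#'   diameter).
#' @param n_stations number of turret stations.
#' @param feed_frame_speed_nF feed frame paddle speed, rev/min (held constant).
#' @param holdup_mfh powder holdup in feed frame and hopper, kg.
#' @param gamma0 baseline shear strain expressed as an equivalent blender
#'   mixing time, min.
#' @return an object of class `press_geometry`.
#' @examples
#' g <- tooling_geometry()
#' fill_volume(g, 8)
#' @export
tooling_geometry <- function(die_diameter_D = 10, cup_depth_h = 1,
                             n_stations = 10,
                             feed_frame_speed_nF = 6.9 / 0.126,
                             holdup_mfh = 1, gamma0 = 10) {
  g <- list(
    die_diameter_D = die_diameter_D, cup_depth_h = cup_depth_h,
    n_stations = n_stations, feed_frame_speed_nF = feed_frame_speed_nF,
    holdup_mfh = holdup_mfh, gamma0 = gamma0
  )
  stopifnot(all(unlist(g) > 0), g$cup_depth_h < g$die_diameter_D)
  structure(g, class = "press_geometry")
}

#' Manipulated process inputs
#'
#' The five manipulated variables of the press: dosing position (die-fill
#' depth), pre-compression thickness, main (in-die) compression thickness,
#' turret speed, and glidant (silica) concentration. Case study 2 treats the
#' silica concentration as an uncertain plant parameter rather than an input,
#' but the container always carries all five fields.
#'
#' @param h_fill dosing position, mm.
#' @param h_pc pre-compression thickness, mm.
#' @param h_in_die main compression thickness, mm.
#' @param n_t turret speed, rev/min.
#' @param cl glidant concentration, % w/w.
#' @param validate enforce the physical compression ordering
#'   `h_in_die <= h_pc <= h_fill` (disable only for optimizer iterates).
#' @return a named numeric vector of class `press_inputs`.
#' @examples
#' process_inputs(h_fill = 7, h_pc = 4, h_in_die = 1.1, n_t = 55, cl = 0.2)
#' @export
process_inputs <- function(h_fill, h_pc, h_in_die, n_t, cl = 0.2,
                           validate = TRUE) {
  u <- c(h_fill = h_fill, h_pc = h_pc, h_in_die = h_in_die,
         n_t = n_t, cl = cl)
  if (any(!is.finite(u)) || any(u[c("h_fill", "h_pc", "h_in_die", "n_t")] <= 0) || u["cl"] < 0) {
    rlang::abort("process inputs must be finite and positive (glidant concentration >= 0)")
  }
  if (validate && !(h_in_die <= h_pc && h_pc <= h_fill)) {
    rlang::abort("physical ordering violated: need h_in_die <= h_pc <= h_fill")
  }
  structure(u, class = "press_inputs")
}

#' @export
print.press_params <- function(x, ...) {
  cat("<press_params>\n")
  v <- unlist(unclass(x))
  print(v)
  invisible(x)
}

#' @export
print.press_inputs <- function(x, ...) {
  cat("<press_inputs>  (mm, mm, mm, rpm, % w/w)\n")
  print(unclass(x))
  invisible(x)
}

.input_names <- c("h_fill", "h_pc", "h_in_die", "n_t", "cl")

# coerce inputs (press_inputs, named vector, list, or data frame) to a
# plain list of equal-length numeric columns for the vectorised core
as_input_cols <- function(u) {
  if (inherits(u, "press_inputs")) u <- as.list(unclass(u))
  if (is.data.frame(u)) u <- as.list(u)
  if (is.numeric(u) && !is.null(names(u))) u <- as.list(u)
  missing <- setdiff(.input_names, names(u))
  if (length(missing)) {
    rlang::abort(paste0("missing input columns: ", paste(missing, collapse = ", ")))
  }
  lapply(u[.input_names], as.numeric)
}
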