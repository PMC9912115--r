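# Mechanistic tablet-press model.
#
# Chain: bulk density (glidant sub-model or constant) -> die-fill weight ->
# production rate -> pre- and main-compression Kawakita forces -> elastic
# recovery / out-of-die density -> tensile strength. All relations are
# algebraic (no differential states), so the same code serves as the plant
# truth, the estimator's prediction model and the controller's internal model.
#
# Internal units: mm, mg, MPa (forces in N, converted to kN at the boundary);
# production rate reported in kg/h, shear as equivalent mixing time in min.

.CORR_MIN <- 0.05   # floor on the die-filling correction factor
.KAW_DEN_MIN <- 1e-3 # floor on the Kawakita denominator
.RATE_MIN <- 1e-9   # floor on production rate (kg/h) inside the shear model

cup_volume <- function(geom) {
  # single punch-cup volume term of the die cavity (divisor 6); the
  # compression volumes carry two cups (divisor 3)
  pi * geom$cup_depth_h * (3 * geom$die_diameter_D^2 / 4 + geom$cup_depth_h^2) / 6
}

#' Die cavity fill volume
#'
#' Volume available at the dosing position for a round die with convex punch
#' cups: a cylinder of height `h_fill` plus a single spherical-cap cup term.
#'
#' @param geometry a [tooling_geometry()].
#' @param h_fill dosing position, mm (>= 0; the degenerate `h_fill = 0`
#'   leaves the cup term only).
#' @return fill volume in mm^3.
#' @examples
#' fill_volume(tooling_geometry(cup_depth_h = 1e-9), 8) # ~ cylinder only
#' @export
fill_volume <- function(geometry, h_fill) {
  if (any(h_fill < 0)) rlang::abort("dosing position h_fill must be non-negative")
  pi * geometry$die_diameter_D^2 * h_fill / 4 + cup_volume(geometry)
}

#' Tablet weight from the die-filling model
#'
#' Weight of a convex tablet: fill volume times effective bulk density, with
#' a speed/fill-depth correction `1 - xi1 * nT/nF + xi2 * h_fill/D`.
#'
#' @param params a [model_parameters()] object (for `xi1`, `xi2`).
#' @param geometry a [tooling_geometry()].
#' @param u a [process_inputs()] vector.
#' @param rho_b_effective effective bulk density, g/cm^3. Defaults to
#'   `params$rho_b`; pass the glidant-model value when that sub-model is
#'   active.
#' @return tablet weight in mg.
#' @export
tablet_weight <- function(params, geometry, u, rho_b_effective = params$rho_b) {
  u <- as_input_cols(u)
  if (any(rho_b_effective <= 0)) rlang::abort("effective bulk density must be positive")
  corr <- 1 - params$xi1 * u$n_t / geometry$feed_frame_speed_nF +
    params$xi2 * u$h_fill / geometry$die_diameter_D
  if (any(corr <= 0)) {
    rlang::abort("die-filling correction factor is non-positive: inputs outside model validity")
  }
  rho_b_effective * fill_volume(geometry, u$h_fill) * corr
}

#' Tablet production rate
#'
#' @param w tablet weight, mg.
#' @param n_t turret speed, rev/min.
#' @param n_stations number of turret stations.
#' @return production rate in kg/h.
#' @examples
#' production_rate(210, 54.76, 10) # ~ 6.9 kg/h
#' @export
production_rate <- function(w, n_t, n_stations) {
  if (any(w < 0) || any(n_t < 0) || any(n_stations <= 0)) {
    rlang::abort("weight, turret speed and station count must be non-negative")
  }
  # mg/min -> kg/h
  w * n_t * n_stations * 60 * 1e-6
}

#' Relative density of the compact
#'
#' @param w tablet weight, mg.
#' @param v compression volume, mm^3 (pre-compression or in-die, both of
#'   which carry two punch-cup terms).
#' @param rho_t true density, g/cm^3.
#' @return dimensionless relative density.
#' @export
relative_density <- function(w, v, rho_t) {
  if (any(v <= 0) || any(rho_t <= 0)) rlang::abort("volume and true density must be positive")
  w / (v * rho_t)
}

#' Kawakita compression force
#'
#' Punch force at a given relative density from the Kawakita isotherm, valid
#' for `rho_c <= rho_rel < rho_c / (1 - a)` (positive denominator).
#'
#' @param rho_rel relative density of the compact.
#' @param params a [model_parameters()] object (`kaw_a`, `kaw_inv_b`, `rho_c`).
#' @param D die diameter, mm.
#' @return force in kN.
#' @examples
#' kawakita_force(0.53, model_parameters(), 10) # ~ 1.343 kN
#' @export
kawakita_force <- function(rho_rel, params, D) {
  upper <- params$rho_c / (1 - params$kaw_a)
  if (any(rho_rel < params$rho_c) || any(rho_rel >= upper)) {
    rlang::abort(sprintf(
      "relative density %.4f outside Kawakita validity [%.4f, %.4f)",
      rho_rel[which(rho_rel < params$rho_c | rho_rel >= upper)][1],
      params$rho_c, upper
    ))
  }
  den <- rho_rel * (params$kaw_a - 1) + params$rho_c
  pi * D^2 / 4 * params$kaw_inv_b * (rho_rel - params$rho_c) / den / 1e3
}

#' In-die elastic recovery
#'
#' Fractional axial recovery on decompression; linear in the in-die relative
#' density above the no-recovery threshold `rho_c_eps`, clamped to zero below
#' it. The out-of-die (tablet) relative density is
#' `(1 - elastic_recovery) * rho_in_die`.
#'
#' @param rho_in_die in-die relative density.
#' @param params a [model_parameters()] object (`eps0`, `rho_c_eps`).
#' @return dimensionless recovery fraction.
#' @examples
#' elastic_recovery(1, model_parameters()) # eps0
#' @export
elastic_recovery <- function(rho_in_die, params) {
  eps <- params$eps0 * (rho_in_die - params$rho_c_eps) / (1 - params$rho_c_eps)
  below <- eps < 0
  if (any(below)) {
    rlang::inform("in-die relative density below rho_c_eps: elastic recovery clamped to 0")
    eps[below] <- 0
  }
  eps
}

#' Equivalent glidant mixing time
#'
#' Total shear imparted to the blend, expressed as an equivalent mixing time:
#' the blender baseline plus the mean residence time in the feed frame and
#' hopper.
#'
#' @param geometry a [tooling_geometry()] (`gamma0`, `holdup_mfh`).
#' @param production_rate tablet production rate, kg/h (> 0).
#' @return equivalent mixing time in min.
#' @examples
#' glidant_shear(tooling_geometry(), 6.9) # gamma0 + 60/6.9
#' @export
glidant_shear <- function(geometry, production_rate) {
  if (any(production_rate <= 0)) {
    rlang::abort("production rate must be positive (residence time would be infinite)")
  }
  geometry$gamma0 + unit_convert(geometry$holdup_mfh, "kg", "mg") /
    unit_convert(production_rate, "kg_h", "mg_s") / 60
}

# ---- lumped glidant mixing parameters ------------------------------------
# Each reading is isolated here so an alternative type-setting of the lumped
# forms is a one-line change. The divided form (exponentiated concentration
# and shear over the scale constant) is the only reading consistent with the
# fitted constants at the reported operating points; see the methods vignette.

#' Glidant lumped mixing parameter and bulk density
#'
#' `lumped_c_sigma()` and `lumped_c_rho()` compute the dimensionless lumped
#' glidant mixing parameters `C_sigma = cl^b1 * gamma^b2 / b3` and
#' `C_rho = cl^r1 * (gamma + gamma0)^r2 / r3`. `bulk_density_from_c()` maps
#' `C_rho` to bulk density, which saturates from `rho_b_0` (no glidant
#' action) to `rho_b_inf` (infinite shear); `glidant_bulk_density()` chains
#' the two.
#'
#' @param cl glidant concentration, % w/w (>= 0).
#' @param gamma equivalent mixing time, min.
#' @param gamma0 baseline mixing time, min (from the geometry).
#' @param c_rho lumped bulk-density mixing parameter (>= 0).
#' @param params a [model_parameters()] object with the glidant block set.
#' @return `lumped_*` return the dimensionless lumped parameter;
#'   `bulk_density_from_c()` and `glidant_bulk_density()` return bulk density
#'   in g/cm^3.
#' @examples
#' p <- press_params("cs2_nominal")
#' bulk_density_from_c(0, p)    # rho_b_0
#' bulk_density_from_c(1e9, p)  # ~ rho_b_inf
#' glidant_bulk_density(0.2, 18.7, p)
#' @export
lumped_c_rho <- function(cl, gamma, params, gamma0 = 10) {
  if (any(cl < 0)) rlang::abort("glidant concentration must be non-negative")
  cl^params$r1 * (gamma + gamma0)^params$r2 / params$r3
}

#' @rdname lumped_c_rho
#' @export
lumped_c_sigma <- function(cl, gamma, params) {
  if (any(cl < 0)) rlang::abort("glidant concentration must be non-negative")
  cl^params$b1 * gamma^params$b2 / params$b3
}

#' @rdname lumped_c_rho
#' @export
bulk_density_from_c <- function(c_rho, params) {
  if (any(c_rho < 0)) rlang::abort("lumped parameter C_rho must be non-negative")
  params$rho_b_inf - (params$rho_b_inf - params$rho_b_0) / (1 + c_rho)
}

#' @rdname lumped_c_rho
#' @export
glidant_bulk_density <- function(cl, gamma, params, gamma0 = 10) {
  bulk_density_from_c(lumped_c_rho(cl, gamma, params, gamma0), params)
}

#' Tablet tensile strength
#'
#' Tensile strength from out-of-die relative density, with the zero-porosity
#' strength and the critical density both shifted by the glidant mixing
#' conditions through the lumped parameter `C_sigma`. Below the glidant-
#' dependent critical density (where a tablet does not yet form) the strength
#' is zero.
#'
#' @param rho_tablet out-of-die relative density (<= 1).
#' @param cl glidant concentration, % w/w.
#' @param gamma equivalent mixing time, min.
#' @param params a [model_parameters()] object.
#' @return tensile strength in MPa. The attribute `"tablet_forms"` flags
#'   whether `rho_tablet` exceeded the critical density.
#' @examples
#' tensile_strength(1, 0, 18.7, model_parameters()) # sigma0
#' @export
tensile_strength <- function(rho_tablet, cl, gamma, params) {
  if (any(rho_tablet > 1 + 1e-12)) rlang::abort("tablet relative density cannot exceed 1")
  cs <- lumped_c_sigma(cl, gamma, params)
  rho_cs <- (params$rho_c0 - params$rho_cinf) / (1 + cs) + params$rho_cinf
  s0 <- params$sigma0 / (1 + cs)
  st <- s0 * (1 - (1 - rho_tablet) / (1 - rho_cs) * exp(rho_tablet - rho_cs))
  forms <- rho_tablet >= rho_cs
  st[!forms] <- 0
  attr(st, "tablet_forms") <- forms
  st
}

# ---- vectorised core -------------------------------------------------------
# Fast, allocation-light evaluation of the full output map over n input rows.
# Used by the plant, the estimator and the controller. Invalid iterates are
# clamped smoothly and accumulated into `penalty` so NLP line searches can
# traverse them; `valid` flags bitwise which rows were clamped.
press_eval_core <- function(u, par, geom, glidant_density = FALSE) {
  hf <- u$h_fill; hp <- u$h_pc; hd <- u$h_in_die; nt <- u$n_t
  cl <- pmax(u$cl, 0)
  n <- max(lengths(u))
  pen <- 0

  D <- geom$die_diameter_D
  area <- pi * D^2 / 4
  cup1 <- cup_volume(geom)
  cup2 <- 2 * cup1

  # physical ordering (soft)
  pen <- pen + pmax(hd - hp, 0)^2 + pmax(hp - hf, 0)^2 + pmax(-u$cl, 0)^2 +
    pmax(0.1 - hf, 0)^2 + pmax(0.1 - hp, 0)^2 + pmax(0.1 - hd, 0)^2 + pmax(1 - nt, 0)^2
  hf <- pmax(hf, 0.1); hp <- pmax(hp, 0.1); hd <- pmax(hd, 0.1); nt <- pmax(nt, 1)

  corr <- 1 - par$xi1 * nt / geom$feed_frame_speed_nF + par$xi2 * hf / D
  pen <- pen + pmax(.CORR_MIN - corr, 0)^2
  corr <- pmax(corr, .CORR_MIN)

  vfill <- area * hf + cup1
  rate_const <- nt * geom$n_stations * 60 * 1e-6 # mg -> kg/h at this speed

  if (glidant_density) {
    # bulk density and shear are mutually dependent through the production
    # rate; the composition is a strong contraction (loop gain ~ 0.03), so a
    # plain fixed-point iteration converges to machine precision quickly
    rho_b <- rep((par$rho_b_inf + par$rho_b_0) / 2, n)
    for (it in 1:80) {
      w <- rho_b * vfill * corr
      rate <- pmax(w * rate_const, .RATE_MIN)
      gamma <- geom$gamma0 + 60 * geom$holdup_mfh / rate
      crho <- cl^par$r1 * (gamma + geom$gamma0)^par$r2 / par$r3
      rho_new <- par$rho_b_inf - (par$rho_b_inf - par$rho_b_0) / (1 + crho)
      delta <- max(abs(rho_new - rho_b))
      rho_b <- rho_new
      if (delta < 1e-13) break
    }
  } else {
    rho_b <- rep_len(unlist(par["rho_b"], use.names = FALSE), n)
  }

  w <- rho_b * vfill * corr
  rate <- pmax(w * rate_const, .RATE_MIN)
  gamma <- geom$gamma0 + 60 * geom$holdup_mfh / rate

  kaw <- function(rho) {
    num <- rho - par$rho_c
    den <- rho * (par$kaw_a - 1) + par$rho_c
    p <- pmax(.KAW_DEN_MIN - den, 0)^2 * 1e4 + pmax(-num, 0)^2
    den <- pmax(den, .KAW_DEN_MIN)
    list(f = area * par$kaw_inv_b * pmax(num, 0) / den / 1e3, pen = p,
         ok = num >= 0 & den > .KAW_DEN_MIN)
  }

  rho_pc <- w / ((area * hp + cup2) * par$rho_t)
  kpc <- kaw(rho_pc)
  rho_ind <- w / ((area * hd + cup2) * par$rho_t)
  kmc <- kaw(rho_ind)
  pen <- pen + kpc$pen + kmc$pen + pmax(rho_ind - 0.995, 0)^2 * 1e4

  eps <- pmax(par$eps0 * (rho_ind - par$rho_c_eps) / (1 - par$rho_c_eps), 0)
  rho_tab <- pmin((1 - eps) * rho_ind, 1)

  cs <- cl^par$b1 * gamma^par$b2 / par$b3
  rho_cs <- (par$rho_c0 - par$rho_cinf) / (1 + cs) + par$rho_cinf
  s0 <- par$sigma0 / (1 + cs)
  st <- s0 * (1 - (1 - rho_tab) / (1 - rho_cs) * exp(rho_tab - rho_cs))
  forms <- st >= 0
  st <- pmax(st, 0)

  list(
    weight = w, f_pc = kpc$f, f_mc = kmc$f, rate = rate, sigma_t = st,
    rho_tablet = rho_tab, rho_in_die = rho_ind, rho_pc = rho_pc,
    rho_b_eff = rho_b, gamma = gamma, c_sigma = cs,
    elastic = eps, corr = corr,
    valid = kpc$ok & kmc$ok & forms & rho_ind < 0.995,
    penalty = pen
  )
}

#' Evaluate the full tablet-press output map
#'
#' Composes the whole mechanistic chain -- effective bulk density, tablet
#' weight, production rate, pre- and main-compression forces, elastic
#' recovery, out-of-die density and tensile strength -- for one or more input
#' rows. Deterministic and noise-free; this is the map the virtual plant
#' perturbs and the estimator/controller invert.
#'
#' @param u a [process_inputs()] vector, or a data frame with columns
#'   `h_fill`, `h_pc`, `h_in_die`, `n_t`, `cl` (one row per operating point).
#' @param params a [model_parameters()] object.
#' @param geometry a [tooling_geometry()].
#' @param glidant_density if `TRUE`, bulk density is computed from the
#'   glidant sub-model (requires the glidant block of `params`); otherwise
#'   `params$rho_b` is used.
#' @param strict if `TRUE`, out-of-validity operating points raise an error
#'   naming the offending quantity; if `FALSE`, outputs are clamped and the
#'   `valid` column flags the violation (used inside optimizers).
#' @return a tibble with columns `weight` (mg), `f_pc` (kN), `f_mc` (kN),
#'   `rate` (kg/h), `sigma_t` (MPa), `rho_tablet`, `rho_in_die`, `rho_b_eff`
#'   (g/cm^3), `gamma` (min), `valid`.
#' @examples
#' u <- process_inputs(h_fill = 7, h_pc = 4.2, h_in_die = 1.1, n_t = 55)
#' evaluate_outputs(u, model_parameters(), tooling_geometry())
#' @export
evaluate_outputs <- function(u, params, geometry, glidant_density = FALSE,
                             strict = TRUE) {
  cols <- as_input_cols(u)
  out <- press_eval_core(cols, params, geometry, glidant_density)
  if (strict && !all(out$valid)) {
    i <- which(!out$valid)[1]
    rlang::abort(sprintf(
      paste0("model validity violated at input row %d ",
             "(rho_pc = %.4f, rho_in_die = %.4f, rho_tablet = %.4f): ",
             "density outside the Kawakita or tensile-strength validity range"),
      i, out$rho_pc[i], out$rho_in_die[i], out$rho_tablet[i]
    ))
  }
  tibble::tibble(
    weight = out$weight, f_pc = out$f_pc, f_mc = out$f_mc, rate = out$rate,
    sigma_t = out$sigma_t, rho_tablet = out$rho_tablet,
    rho_in_die = out$rho_in_die, rho_b_eff = out$rho_b_eff,
    gamma = out$gamma, valid = out$valid
  )
}
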