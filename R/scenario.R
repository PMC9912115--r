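# Virtual plant: the compaction model evaluated with scenario-specific
# (possibly mismatched) parameters, plus Gaussian sensor noise and timed
# disturbance/setpoint schedules. This module is also the synthetic-data
# generator for the whole test suite.

.measured_outputs <- c("weight", "f_pc", "f_mc", "rate")
.controlled_outputs <- c("weight", "f_pc", "rate", "sigma_t")

.default_noise_sd <- c(weight = 1, f_pc = 0.02, f_mc = 0.2, rate = 0.05)

#' Build a case-study scenario
#'
#' A scenario pairs the controller's model parameters with the (possibly
#' mismatched) plant parameters and fixes the timeline: sensor noise levels,
#' timed parameter disturbances, the setpoint schedule, the phase switches
#' (open loop, estimation only, closed loop) and the horizon.
#'
#' Available scenarios:
#' \describe{
#'   \item{`cs1_no_pmm`}{plant == model, nominal parameter set; setpoint
#'     steps at 400/600/600/800 s (weight 210 -> 240 mg, pre-compression
#'     force 0.3 -> 0.6 kN, tensile strength 4.2 -> 6 MPa, production rate
#'     6.9 -> 8 kg/h); glidant concentration is a manipulated input.}
#'   \item{`cs1_mild_pmm`}{as above with plant `rho_b = 0.390`,
#'     `rho_c = 0.290`, `a = 0.77` against the nominal model.}
#'   \item{`cs1_high_pmm`}{as above with plant mismatch in six constants
#'     (`xi2`, `rho_b`, `rho_c`, `a`, `1/b`, `rho_t`).}
#'   \item{`cs2_silica_steps`}{4x4 system with the glidant bulk-density
#'     sub-model active; plant silica concentration steps from 0.2 to 0.35 %
#'     over 300--700 s and from 0.2 to 0.05 % over 1100--1500 s; constant
#'     setpoints at the nominal operating point.}
#' }
#'
#' @param name scenario name (see Details).
#' @param seed integer seed recorded in the scenario; every derived
#'   measurement stream is a pure function of (scenario, seed).
#' @param noise_sd named per-output measurement noise standard deviations in
#'   measurement units (mg, kN, kN, kg/h).
#' @param horizon_end override the simulated horizon in seconds.
#' @return an object of class `press_scenario`.
#' @examples
#' sc <- make_scenario("cs1_mild_pmm")
#' sc$plant_params$rho_b
#' @export
make_scenario <- function(name, seed = 1L, noise_sd = .default_noise_sd,
                          horizon_end = NULL) {
  valid <- c("cs1_no_pmm", "cs1_mild_pmm", "cs1_high_pmm", "cs2_silica_steps")
  if (!name %in% valid) {
    rlang::abort(paste0("unknown scenario '", name, "'; valid names: ",
                        paste(valid, collapse = ", ")))
  }
  stopifnot(all(noise_sd >= 0), all(.measured_outputs %in% names(noise_sd)))
  geometry <- tooling_geometry()

  if (name == "cs2_silica_steps") {
    model_params <- press_params("cs2_nominal")
    plant_params <- model_params
    glidant_density <- TRUE
    manipulated <- c("h_fill", "h_pc", "h_in_die", "n_t")
    plant_cl <- 0.2
    disturbance_schedule <- tibble::tibble(
      time = c(300, 700, 1100, 1500),
      param = "cl",
      value = c(0.35, 0.2, 0.05, 0.2)
    )
    setpoint_schedule <- tibble::tibble(
      time = numeric(), output = character(), value = numeric()
    )
    end <- 1500
  } else {
    model_params <- press_params("no_pmm")
    plant_params <- switch(name,
      cs1_no_pmm = press_params("no_pmm"),
      cs1_mild_pmm = press_params("mild_pmm"),
      cs1_high_pmm = press_params("high_pmm")
    )
    glidant_density <- FALSE
    manipulated <- c("h_fill", "h_pc", "h_in_die", "n_t", "cl")
    plant_cl <- NA_real_ # silica is an input in case study 1
    disturbance_schedule <- tibble::tibble(
      time = numeric(), param = character(), value = numeric()
    )
    setpoint_schedule <- tibble::tibble(
      time = c(400, 600, 600, 800),
      output = c("weight", "f_pc", "sigma_t", "rate"),
      value = c(240, 0.6, 6, 8)
    )
    end <- 1000
  }
  if (!is.null(horizon_end)) end <- horizon_end
  # events beyond a shortened horizon never fire; keep schedules within it
  setpoint_schedule <- setpoint_schedule[setpoint_schedule$time <= end, ]
  disturbance_schedule <- disturbance_schedule[disturbance_schedule$time <= end, ]

  u_nominal <- calibrate_nominal_inputs(model_params, geometry,
                                        glidant_density = glidant_density)
  y_nominal <- c(weight = 210, f_pc = 0.3, rate = 6.9, sigma_t = 4.2)

  structure(list(
    name = name,
    plant_params = plant_params,
    model_params = model_params,
    geometry = geometry,
    glidant_density = glidant_density,
    manipulated = manipulated,
    plant_cl = plant_cl,
    noise_sd = noise_sd[.measured_outputs],
    disturbance_schedule = disturbance_schedule,
    setpoint_schedule = setpoint_schedule,
    y_nominal = y_nominal,
    u_nominal = u_nominal,
    mhe_start = 100, control_start = 200,
    horizon_end = end,
    seed = as.integer(seed)
  ), class = "press_scenario")
}

#' @export
print.press_scenario <- function(x, ...) {
  cat("<press_scenario>", x$name, "\n")
  cat("  horizon:", x$horizon_end, "s; seed:", x$seed, "\n")
  cat("  manipulated:", paste(x$manipulated, collapse = ", "), "\n")
  cat("  disturbances:", nrow(x$disturbance_schedule),
      "; setpoint events:", nrow(x$setpoint_schedule), "\n")
  invisible(x)
}

# plant-side parameter state at time t: scenario plant params with every
# schedule entry at time <= t applied; returns list(params, cl)
plant_state_at <- function(scenario, t) {
  par <- scenario$plant_params
  cl <- scenario$plant_cl
  sched <- scenario$disturbance_schedule
  if (nrow(sched)) {
    due <- sched[sched$time <= t, , drop = FALSE]
    if (nrow(due)) {
      for (i in seq_len(nrow(due))) {
        if (due$param[i] == "cl") cl <- due$value[i] else par[[due$param[i]]] <- due$value[i]
      }
    }
  }
  list(params = par, cl = cl)
}

# setpoints active at time t
setpoints_at <- function(scenario, t) {
  sp <- scenario$y_nominal
  sched <- scenario$setpoint_schedule
  if (nrow(sched)) {
    due <- sched[sched$time <= t, , drop = FALSE]
    if (nrow(due)) for (i in seq_len(nrow(due))) sp[[due$output[i]]] <- due$value[i]
  }
  sp[.controlled_outputs]
}

#' Advance the virtual plant by one second
#'
#' Applies every scheduled disturbance with time `<= t` to the plant
#' parameters, evaluates the noise-free output map at the applied inputs,
#' and adds independent zero-mean Gaussian sensor noise to the four measured
#' outputs. Noise is drawn from the session RNG: seed it (or use
#' [run_closed_loop()], which seeds per run) for reproducible streams.
#'
#' @param scenario a [make_scenario()] object.
#' @param t time, s (on the 1 s grid).
#' @param u applied [process_inputs()]. In case study 2 the silica input
#'   channel is overridden by the plant's scheduled true concentration.
#' @return a list with `record` (one-row tibble: time, measured outputs,
#'   applied inputs) and `truth` (one-row tibble of noise-free outputs; test
#'   and audit use only -- the controller-facing API is `record`).
#' @export
plant_step <- function(scenario, t, u) {
  st <- plant_state_at(scenario, t)
  cols <- as_input_cols(u)
  cl_applied <- cols$cl
  if (!is.na(st$cl)) cols$cl <- st$cl
  out <- press_eval_core(cols, st$params, scenario$geometry,
                         scenario$glidant_density)
  if (!all(out$valid)) {
    rlang::abort(sprintf("plant left the model validity region at t = %g s", t))
  }
  sd <- scenario$noise_sd
  noise <- stats::rnorm(4, 0, sd)
  record <- tibble::tibble(
    time = t,
    weight = out$weight + noise[1],
    f_pc = out$f_pc + noise[2],
    f_mc = out$f_mc + noise[3],
    rate = out$rate + noise[4],
    h_fill = cols$h_fill, h_pc = cols$h_pc, h_in_die = cols$h_in_die,
    n_t = cols$n_t, cl = cl_applied
  )
  truth <- tibble::tibble(
    time = t, weight = out$weight, f_pc = out$f_pc, f_mc = out$f_mc,
    rate = out$rate, sigma_t = out$sigma_t, rho_tablet = out$rho_tablet,
    rho_b_eff = out$rho_b_eff, cl_plant = if (is.na(st$cl)) cols$cl else st$cl
  )
  list(record = record, truth = truth)
}
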