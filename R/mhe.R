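# Moving-horizon estimation of uncertain model parameters and of the
# output-disturbance median. The compaction model is purely algebraic, so
# the state-propagation constraints of the general moving-horizon program
# collapse to the static output map and the decision vector is the parameter
# vector alone; the window and the incumbent estimate are carried forward
# between calls.

#' Estimator configuration
#'
#' @param theta_names ordered names of the estimated quantities; model
#'   constant names (e.g. `"rho_b"`) or `"cl"` for the silica concentration
#'   (case study 2, where silica is an uncertain plant parameter).
#' @param theta_nominal named nominal values (also the optimizer scaling).
#' @param theta_lower,theta_upper named box bounds (the compact feasible set).
#' @param n_past length of the past window, s (steps). Windows shorter than
#'   `n_past` -- during start-up -- use all available records.
#' @param w_e named residual weights per measured output; defaults to the
#'   inverse noise variances of the default sensor noise.
#' @param w_theta regularization weight on the normalized step from the
#'   previous estimate.
#' @param residual_outputs measured outputs entering the residual. The main
#'   compression force is measured and used here even though it is never a
#'   controlled output.
#' @param maxit iteration cap per call, keeping one loop iteration well
#'   inside the 1 s sampling interval.
#' @param solver_tol objective tolerance of the bounded quasi-Newton solve.
#' @return an object of class `press_est_config`.
#' @seealso [default_estimator_config()] for the per-scenario defaults.
#' @export
estimator_config <- function(theta_names, theta_nominal, theta_lower,
                             theta_upper, n_past = 30,
                             w_e = 1 / .default_noise_sd^2,
                             w_theta = 1e-2,
                             residual_outputs = .measured_outputs,
                             maxit = 60, solver_tol = 1e-8) {
  stopifnot(
    n_past >= 1,
    all(theta_names %in% names(theta_nominal)),
    all(theta_names %in% names(theta_lower)),
    all(theta_names %in% names(theta_upper)),
    all(theta_lower[theta_names] <= theta_nominal[theta_names]),
    all(theta_nominal[theta_names] <= theta_upper[theta_names]),
    all(w_e >= 0), w_theta >= 0,
    all(residual_outputs %in% .measured_outputs)
  )
  structure(list(
    theta_names = theta_names,
    theta_nominal = theta_nominal[theta_names],
    theta_lower = theta_lower[theta_names],
    theta_upper = theta_upper[theta_names],
    n_past = n_past, w_e = w_e, w_theta = w_theta,
    residual_outputs = residual_outputs,
    maxit = maxit, solver_tol = solver_tol
  ), class = "press_est_config")
}

#' Default estimator configuration for a scenario
#'
#' Case study 1 tracks bulk density, critical density and Kawakita `a`
#' within +/- 30 % of their nominal values (Kawakita `a` capped below 1);
#' case study 2 tracks the silica concentration on `[0, 1]` % w/w. Residuals
#' are weighted by the inverse of the scenario's noise variances.
#'
#' @param scenario a [make_scenario()] object.
#' @param ... overrides passed on to [estimator_config()].
#' @return a `press_est_config`.
#' @export
default_estimator_config <- function(scenario, ...) {
  mp <- scenario$model_params
  if (scenario$name == "cs2_silica_steps") {
    nom <- c(cl = 0.2); lo <- c(cl = 0); hi <- c(cl = 1)
    nm <- "cl"
  } else {
    nm <- c("rho_b", "rho_c", "kaw_a")
    nom <- c(rho_b = mp$rho_b, rho_c = mp$rho_c, kaw_a = mp$kaw_a)
    lo <- nom * 0.7
    hi <- pmin(nom * 1.3, c(rho_b = Inf, rho_c = Inf, kaw_a = 0.99))
  }
  # floor the noise SDs entering the weights so that noise-free studies get
  # large-but-finite inverse-variance weights
  sd_floor <- 1e-3 * .default_noise_sd
  args <- list(theta_names = nm, theta_nominal = nom, theta_lower = lo,
               theta_upper = hi,
               w_e = 1 / pmax(scenario$noise_sd, sd_floor)^2)
  args <- utils::modifyList(args, list(...))
  do.call(estimator_config, args)
}

#' Componentwise median of output residuals
#'
#' The single-point summary of the windowed error distribution used as the
#' additive output-disturbance term: robust to outliers, unlike the mean.
#' Even-length windows take the midpoint of the two central order statistics.
#'
#' @param residuals a data frame or matrix of per-output residual series
#'   (rows = time, columns = outputs); must be non-empty.
#' @return named numeric vector of per-output medians.
#' @examples
#' median_disturbance(data.frame(weight = c(1, 2, 100))) # robust: 2
#' @export
median_disturbance <- function(residuals) {
  residuals <- as.data.frame(residuals)
  if (nrow(residuals) == 0) rlang::abort("residual series is empty")
  vapply(residuals, stats::median, numeric(1))
}

# substitute theta into (params, input-columns); "cl" overrides the input
# channel, anything else is a model constant
substitute_theta <- function(theta, params, cols) {
  for (nm in names(theta)) {
    if (nm == "cl") cols$cl <- rep_len(theta[[nm]], length(cols$h_fill))
    else params[[nm]] <- theta[[nm]]
  }
  list(params = params, cols = cols)
}

#' One moving-horizon estimation update
#'
#' Minimizes the inverse-variance-weighted sum of squared output residuals
#' over the past window plus a quadratic regularization toward the previous
#' estimate, subject to box bounds, and summarizes the optimal residuals by
#' their componentwise median. The returned estimate is never worse (in
#' objective value) than the incumbent: if the solver fails or degrades the
#' objective, the previous estimate is kept and flagged.
#'
#' @param window tibble of measurement records (most recent rows are used:
#'   at most `n_past + 1`), with measured-output and applied-input columns as
#'   produced by [plant_step()].
#' @param theta_prev named incumbent parameter vector.
#' @param model_params the controller's [model_parameters()].
#' @param geometry a [tooling_geometry()].
#' @param cfg an [estimator_config()].
#' @param glidant_density whether the glidant bulk-density sub-model is
#'   active.
#' @return an object of class `press_estimate`: `theta_hat`, `zeta`
#'   (per-output residual medians), `y_hat_window`, `objective_value`,
#'   `converged`.
#' @export
mhe_update <- function(window, theta_prev, model_params, geometry, cfg,
                       glidant_density = FALSE) {
  n_keep <- min(nrow(window), cfg$n_past + 1)
  window <- window[seq.int(nrow(window) - n_keep + 1, nrow(window)), , drop = FALSE]
  cols <- lapply(window[.input_names], as.numeric)
  ymat <- lapply(cfg$residual_outputs, function(o) as.numeric(window[[o]]))
  names(ymat) <- cfg$residual_outputs
  w_e <- cfg$w_e[cfg$residual_outputs]
  scale <- cfg$theta_nominal
  theta_prev <- pmin(pmax(theta_prev[cfg$theta_names], cfg$theta_lower), cfg$theta_upper)
  z_prev <- theta_prev / scale

  predict_at <- function(theta) {
    sub <- substitute_theta(as.list(theta), model_params, cols)
    press_eval_core(sub$cols, sub$params, geometry, glidant_density)
  }
  obj_z <- function(z) {
    theta <- z * scale
    out <- predict_at(theta)
    j <- sum(cfg$w_theta * (z - z_prev)^2) + 1e4 * sum(out$penalty)
    for (o in cfg$residual_outputs) {
      j <- j + w_e[[o]] * sum((ymat[[o]] - out[[o]])^2)
    }
    j
  }
  grad_z <- function(z) {
    f0 <- obj_z(z)
    h <- 1e-7 * pmax(abs(z), 1)
    vapply(seq_along(z), function(i) {
      zi <- z; zi[i] <- zi[i] + h[i]
      (obj_z(zi) - f0) / h[i]
    }, numeric(1))
  }

  fit <- tryCatch(
    stats::optim(z_prev, obj_z, grad_z, method = "L-BFGS-B",
                 lower = cfg$theta_lower / scale,
                 upper = cfg$theta_upper / scale,
                 control = list(maxit = cfg$maxit,
                                factr = cfg$solver_tol / .Machine$double.eps)),
    error = function(e) NULL
  )

  j_prev <- obj_z(z_prev)
  if (is.null(fit) || fit$value > j_prev) {
    z_hat <- z_prev; j_hat <- j_prev; converged <- FALSE
  } else {
    z_hat <- fit$par; j_hat <- fit$value; converged <- fit$convergence == 0
  }
  theta_hat <- z_hat * scale

  out <- predict_at(theta_hat)
  resid <- as.data.frame(lapply(cfg$residual_outputs, function(o) ymat[[o]] - out[[o]]))
  names(resid) <- cfg$residual_outputs
  zeta <- median_disturbance(resid)

  structure(list(
    theta_hat = theta_hat,
    zeta = zeta,
    y_hat_window = tibble::tibble(
      time = window$time, weight = out$weight, f_pc = out$f_pc,
      f_mc = out$f_mc, rate = out$rate
    ),
    objective_value = j_hat,
    converged = converged
  ), class = "press_estimate")
}
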