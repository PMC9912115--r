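# Receding-horizon nonlinear MPC with move blocking. The internal model is
# the same algebraic output map used by the estimator, updated with the
# current parameter estimate and shifted by the output-disturbance median on
# the measured controlled outputs (the offset-free correction). Only the
# first input move is ever applied; re-solving at the next sample with the
# realized measurement is the closed loop's job.

#' Controller configuration
#'
#' @param n_pred prediction window, steps.
#' @param n_ctrl control window, steps (moves beyond it are zero).
#' @param w_y named tracking weights on setpoint-normalized controlled
#'   outputs.
#' @param w_du move-suppression weight on moves normalized by their per-step
#'   limits.
#' @param u_lower,u_upper named input box bounds (mm, mm, mm, rpm, % w/w).
#' @param du_max named per-step move limits; default 2 % of each input range
#'   so every move is realistic during normal operation.
#' @param controlled_outputs ordered controlled outputs.
#' @param manipulated ordered manipulated inputs (5 for case study 1, 4 for
#'   case study 2).
#' @param maxit solver iteration cap per call.
#' @param penalty_weight weight on the smooth model-validity penalty that
#'   lets line searches traverse invalid iterates.
#' @return an object of class `press_ctl_config`.
#' @seealso [default_controller_config()]
#' @export
controller_config <- function(n_pred = 60, n_ctrl = 10,
                              w_y = c(weight = 1, f_pc = 1, rate = 1, sigma_t = 1),
                              w_du = 0.01,
                              u_lower = c(h_fill = 2, h_pc = 2, h_in_die = 1,
                                          n_t = 10, cl = 0),
                              u_upper = c(h_fill = 16, h_pc = 8, h_in_die = 6,
                                          n_t = 100, cl = 1),
                              du_max = NULL,
                              controlled_outputs = .controlled_outputs,
                              manipulated = .input_names,
                              maxit = 40, penalty_weight = 1e3) {
  stopifnot(
    n_ctrl >= 1, n_ctrl <= n_pred,
    all(manipulated %in% .input_names),
    all(controlled_outputs %in% c(.measured_outputs, "sigma_t")),
    all(u_lower[manipulated] < u_upper[manipulated]),
    all(w_y >= 0), w_du >= 0
  )
  if (is.null(du_max)) du_max <- 0.02 * (u_upper - u_lower)
  stopifnot(all(du_max[manipulated] > 0))
  structure(list(
    n_pred = n_pred, n_ctrl = n_ctrl, w_y = w_y, w_du = w_du,
    u_lower = u_lower, u_upper = u_upper, du_max = du_max,
    controlled_outputs = controlled_outputs, manipulated = manipulated,
    maxit = maxit, penalty_weight = penalty_weight
  ), class = "press_ctl_config")
}

#' Default controller configuration for a scenario
#'
#' Case study 1 manipulates all five inputs (4x5 non-square system); case
#' study 2 drops the silica channel (4x4).
#'
#' @param scenario a [make_scenario()] object.
#' @param ... overrides passed on to [controller_config()].
#' @return a `press_ctl_config`.
#' @export
default_controller_config <- function(scenario, ...) {
  args <- list(manipulated = scenario$manipulated)
  args <- utils::modifyList(args, list(...))
  do.call(controller_config, args)
}

# outputs with the disturbance correction applied: zeta shifts the measured
# controlled outputs; the soft-sensed tensile strength carries no
# disturbance term (it has no real-time measurement)
.zeta_outputs <- c("weight", "f_pc", "rate")

#' Predict controlled outputs over an input trajectory
#'
#' Static-map evaluation of the controlled outputs at each horizon step,
#' with the output-disturbance median added to every measured controlled
#' output (held at its current value over the whole horizon).
#'
#' @param theta_hat named current parameter estimate (possibly empty).
#' @param zeta named output-disturbance medians (from [mhe_update()] or
#'   residual medians; missing outputs default to 0).
#' @param u_traj data frame of inputs, one row per horizon step.
#' @param model_params,geometry model and tooling.
#' @param glidant_density whether the glidant bulk-density sub-model is
#'   active.
#' @return tibble of corrected controlled outputs plus `valid`.
#' @export
predict_horizon <- function(theta_hat, zeta, u_traj, model_params, geometry,
                            glidant_density = FALSE) {
  cols <- as_input_cols(u_traj)
  sub <- substitute_theta(as.list(theta_hat), model_params, cols)
  out <- press_eval_core(sub$cols, sub$params, geometry, glidant_density)
  z <- function(o) if (o %in% names(zeta)) zeta[[o]] else 0
  tibble::tibble(
    weight = out$weight + z("weight"),
    f_pc = out$f_pc + z("f_pc"),
    rate = out$rate + z("rate"),
    sigma_t = out$sigma_t,
    valid = out$valid
  )
}

#' Solve one receding-horizon NMPC problem
#'
#' Minimizes the setpoint-normalized squared tracking error over the
#' prediction window plus a move-suppression term over the control window,
#' with moves blocked to zero beyond the control window, subject to input
#' box bounds and per-step move limits. Returns the first move only. On
#' solver failure the input is held (zero move) and flagged.
#'
#' @param theta_hat named parameter estimate used in the internal model.
#' @param zeta named output-disturbance medians added to the measured
#'   controlled outputs.
#' @param y_sp named setpoints for the controlled outputs.
#' @param u_prev currently applied [process_inputs()] (named vector).
#' @param model_params,geometry model and tooling.
#' @param cfg a [controller_config()].
#' @param glidant_density whether the glidant bulk-density sub-model is
#'   active.
#' @param warm optional warm-start move matrix from the previous solve
#'   (shifted internally by one step).
#' @return an object of class `press_move`: `du_first`, `u_applied`,
#'   `predicted_outputs` (trajectory over the prediction window),
#'   `objective_value`, `converged`, and `warm` for the next call.
#' @export
nmpc_solve <- function(theta_hat, zeta, y_sp, u_prev, model_params, geometry,
                       cfg, glidant_density = FALSE, warm = NULL) {
  m <- cfg$manipulated
  nm <- length(m)
  nc <- cfg$n_ctrl
  du <- cfg$du_max[m]
  lo <- cfg$u_lower[m]; hi <- cfg$u_upper[m]
  u0 <- unclass(u_prev)[.input_names]
  w_y <- cfg$w_y[cfg$controlled_outputs]
  ysp <- y_sp[cfg$controlled_outputs]
  term_w <- cfg$n_pred - nc + 1 # stages riding on the blocked terminal input

  sub0 <- substitute_theta(as.list(theta_hat), model_params,
                           lapply(u0, function(v) rep(v, nc)))
  base_cols <- sub0$cols # fixed channels (e.g. silica in case study 2) set
  par2 <- sub0$params

  # decision: moves normalized by the per-step limits, d in [-1, 1]^(nc*nm)
  traj_from <- function(dmat) {
    # nc x nm matrix of absolute inputs after cumulative moves
    um <- apply(dmat * rep(du, each = nc), 2, cumsum)
    if (nc == 1) um <- matrix(um, 1, nm)
    sweep(um, 2, unlist(u0[m]), "+")
  }
  stage_cost <- function(umat) {
    cols <- lapply(base_cols, rep_len, nrow(umat))
    for (j in seq_len(nm)) cols[[m[j]]] <- umat[, j]
    out <- press_eval_core(cols, par2, geometry, glidant_density)
    cost <- cfg$penalty_weight * out$penalty
    for (o in cfg$controlled_outputs) {
      yo <- out[[o]] + (if (o %in% .zeta_outputs && o %in% names(zeta)) zeta[[o]] else 0)
      cost <- cost + w_y[[o]] * ((yo - ysp[[o]]) / ysp[[o]])^2
    }
    # box-bound violation as smooth penalty (the applied move is clamped)
    for (j in seq_len(nm)) {
      cost <- cost + cfg$penalty_weight *
        (pmax(umat[, j] - hi[j], 0)^2 + pmax(lo[j] - umat[, j], 0)^2)
    }
    cost
  }
  stage_w <- c(rep(1, nc - 1), term_w)
  obj <- function(d) {
    dmat <- matrix(d, nc, nm)
    sum(stage_w * stage_cost(traj_from(dmat))) + cfg$w_du * sum(d^2)
  }
  grad <- function(d) {
    dmat <- matrix(d, nc, nm)
    umat <- traj_from(dmat)
    c0 <- stage_cost(umat)
    h <- 1e-6
    # d(stage cost)/d(u_j) for all stages and channels in one vectorised call
    big <- umat[rep(seq_len(nc), nm), , drop = FALSE]
    for (j in seq_len(nm)) {
      rows <- (j - 1) * nc + seq_len(nc)
      big[rows, j] <- big[rows, j] + h
    }
    cbig <- stage_cost(big)
    gmat <- matrix(0, nc, nm)
    for (j in seq_len(nm)) {
      gj <- (cbig[(j - 1) * nc + seq_len(nc)] - c0) / h
      # u_i depends on every earlier move: reverse-cumulate stage gradients
      gmat[, j] <- rev(cumsum(rev(stage_w * gj))) * du[j]
    }
    as.vector(gmat) + 2 * cfg$w_du * d
  }

  d0 <- if (is.null(warm)) rep(0, nc * nm) else {
    w <- matrix(warm, nc, nm)
    as.vector(rbind(w[-1, , drop = FALSE], 0)) # receding-horizon shift
  }
  d0 <- pmin(pmax(d0, -1), 1)

  fit <- tryCatch(
    stats::optim(d0, obj, grad, method = "L-BFGS-B", lower = -1, upper = 1,
                 control = list(maxit = cfg$maxit, factr = 1e7)),
    error = function(e) NULL
  )
  if (is.null(fit)) {
    d <- rep(0, nc * nm); objective <- obj(d); converged <- FALSE
  } else {
    d <- fit$par; objective <- fit$value; converged <- fit$convergence == 0
    if (objective > obj(d0)) { d <- d0; objective <- obj(d0); converged <- FALSE }
  }

  dmat <- matrix(d, nc, nm)
  du_first <- dmat[1, ] * du
  names(du_first) <- m
  u_new <- u0
  for (j in seq_len(nm)) {
    u_new[[m[j]]] <- min(max(u0[[m[j]]] + du_first[[j]], lo[[j]]), hi[[j]])
    du_first[[j]] <- u_new[[m[j]]] - u0[[m[j]]]
  }
  u_applied <- structure(unlist(u_new), class = "press_inputs")

  # full prediction-window trajectory at the solution (blocked after n_ctrl)
  umat <- traj_from(dmat)
  full <- umat[c(seq_len(nc), rep(nc, cfg$n_pred - nc)), , drop = FALSE]
  u_traj <- as.data.frame(lapply(u0, function(v) rep(v, nrow(full))))
  for (j in seq_len(nm)) u_traj[[m[j]]] <- full[, j]
  pred <- predict_horizon(theta_hat, zeta, u_traj, model_params, geometry,
                          glidant_density)

  structure(list(
    du_first = du_first,
    u_applied = u_applied,
    predicted_outputs = pred,
    objective_value = objective,
    converged = converged,
    warm = dmat
  ), class = "press_move")
}
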