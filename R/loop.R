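# Closed-loop orchestration on the 1 s grid. Timeline (per scenario):
# open-loop operation first, then estimation only, then estimation plus
# control. Every step: read the plant measurement, update the estimate (or
# only the residual median, depending on mode), solve the receding-horizon
# problem, apply the first move. Any solver failure is logged in the traces
# and the loop continues with held inputs.

#' Run a closed-loop case study
#'
#' Simulates the full measurement -> estimation -> control loop for a
#' scenario. Modes:
#' \describe{
#'   \item{`mhe_nmpc`}{moving-horizon estimation from 100 s, closed-loop
#'     control from 200 s (the full framework).}
#'   \item{`nmpc_only`}{no parameter estimation (the model parameters stay
#'     nominal); the output-disturbance median is still formed from model
#'     residuals, and control starts at 200 s.}
#'   \item{`open`}{no estimation, no control: nominal inputs throughout.}
#' }
#'
#' @param scenario a [make_scenario()] object.
#' @param est_cfg an [estimator_config()]; default
#'   [default_estimator_config()].
#' @param ctl_cfg a [controller_config()]; default
#'   [default_controller_config()].
#' @param mode one of `"mhe_nmpc"`, `"nmpc_only"`, `"open"`.
#' @param seed integer; overrides the scenario seed. A run is a pure
#'   function of (scenario, configs, mode, seed): identical arguments give
#'   byte-identical traces.
#' @param progress print a progress line every 200 s.
#' @return an object of class `press_run`: tibbles `measurements`, `truth`,
#'   `estimates`, `moves`, `soft_tensile`, plus `metrics` (see
#'   [run_metrics()]) and the run configuration.
#' @examples
#' \donttest{
#' run <- run_closed_loop(make_scenario("cs1_no_pmm", horizon_end = 260))
#' run$metrics
#' }
#' @export
run_closed_loop <- function(scenario, est_cfg = NULL, ctl_cfg = NULL,
                            mode = c("mhe_nmpc", "nmpc_only", "open"),
                            seed = scenario$seed, progress = FALSE) {
  mode <- match.arg(mode)
  if (is.null(est_cfg)) est_cfg <- default_estimator_config(scenario)
  if (is.null(ctl_cfg)) ctl_cfg <- default_controller_config(scenario)

  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    old_seed <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old_seed, envir = globalenv()), add = TRUE)
  }
  set.seed(seed)

  tmax <- scenario$horizon_end
  mp <- scenario$model_params
  geom <- scenario$geometry
  gl <- scenario$glidant_density
  theta <- est_cfg$theta_nominal
  zeta <- c(weight = 0, f_pc = 0, f_mc = 0, rate = 0)
  u <- scenario$u_nominal
  warm <- NULL

  meas <- matrix(NA_real_, tmax, 10,
                 dimnames = list(NULL, c("time", .measured_outputs, .input_names)))
  truth <- matrix(NA_real_, tmax, 9,
                  dimnames = list(NULL, c("time", .measured_outputs, "sigma_t",
                                          "rho_tablet", "rho_b_eff", "cl_plant")))
  nest <- length(theta)
  est_mat <- matrix(NA_real_, tmax, nest + 7,
                    dimnames = list(NULL, c("time", paste0("theta_", names(theta)),
                                            paste0("zeta_", .measured_outputs),
                                            "objective", "converged")))
  mv_mat <- matrix(NA_real_, tmax, 1 + 5 + length(ctl_cfg$manipulated) + 2,
                   dimnames = list(NULL, c("time", .input_names,
                                           paste0("du_", ctl_cfg$manipulated),
                                           "objective", "converged")))
  soft <- matrix(NA_real_, tmax, 2, dimnames = list(NULL, c("time", "sigma_t_soft")))

  mhe_on <- mode == "mhe_nmpc"
  zeta_on <- mode %in% c("mhe_nmpc", "nmpc_only")
  ctl_on <- mode %in% c("mhe_nmpc", "nmpc_only")

  for (t in seq_len(tmax)) {
    step <- plant_step(scenario, t, u)
    meas[t, ] <- as.numeric(step$record[1, colnames(meas)])
    truth[t, ] <- as.numeric(step$truth[1, colnames(truth)])

    if (zeta_on && t >= scenario$mhe_start) {
      i0 <- max(1, t - est_cfg$n_past)
      win <- as.data.frame(meas[i0:t, , drop = FALSE])
      if (mhe_on) {
        est <- mhe_update(win, theta, mp, geom, est_cfg, gl)
        theta <- est$theta_hat
        zeta[names(est$zeta)] <- est$zeta
        est_mat[t, ] <- c(t, theta, zeta[.measured_outputs],
                          est$objective_value, as.numeric(est$converged))
      } else {
        # fixed nominal parameters: only the residual median is updated
        sub <- substitute_theta(as.list(theta), mp,
                                lapply(win[.input_names], as.numeric))
        out <- press_eval_core(sub$cols, sub$params, geom, gl)
        res <- data.frame(
          weight = win$weight - out$weight, f_pc = win$f_pc - out$f_pc,
          f_mc = win$f_mc - out$f_mc, rate = win$rate - out$rate
        )
        zeta[.measured_outputs] <- median_disturbance(res)
        est_mat[t, ] <- c(t, theta, zeta[.measured_outputs], NA, NA)
      }
    }

    # model-based soft sensor for the tensile strength at the current inputs
    sub <- substitute_theta(as.list(theta), mp, as_input_cols(u))
    soft[t, ] <- c(t, press_eval_core(sub$cols, sub$params, geom, gl)$sigma_t)

    if (ctl_on && t >= scenario$control_start && t < tmax) {
      ysp <- setpoints_at(scenario, t)
      mv <- nmpc_solve(theta, zeta, ysp, u, mp, geom, ctl_cfg, gl, warm = warm)
      u <- mv$u_applied
      warm <- mv$warm
      mv_mat[t, ] <- c(t, unclass(u)[.input_names], mv$du_first,
                       mv$objective_value, as.numeric(mv$converged))
    }
    if (progress && t %% 200 == 0) {
      message(sprintf("t = %4d s  (%s, %s)", t, scenario$name, mode))
    }
  }

  run <- structure(list(
    scenario = scenario, mode = mode, seed = seed,
    est_cfg = est_cfg, ctl_cfg = ctl_cfg,
    measurements = tibble::as_tibble(as.data.frame(meas)),
    truth = tibble::as_tibble(as.data.frame(truth)),
    estimates = tibble::as_tibble(as.data.frame(
      est_mat[!is.na(est_mat[, "time"]), , drop = FALSE])),
    moves = tibble::as_tibble(as.data.frame(
      mv_mat[!is.na(mv_mat[, "time"]), , drop = FALSE])),
    soft_tensile = tibble::as_tibble(as.data.frame(soft))
  ), class = "press_run")
  run$metrics <- run_metrics(run)
  run
}

#' @export
print.press_run <- function(x, ...) {
  cat("<press_run>", x$scenario$name, "| mode:", x$mode,
      "| seed:", x$seed, "| horizon:", x$scenario$horizon_end, "s\n")
  cat("metrics (window", x$metrics$t_start[1], "-", x$metrics$t_end[1], "s):\n")
  print(as.data.frame(x$metrics[, c("output", "iae", "m2p", "d2r")]),
        row.names = FALSE, digits = 4)
  invisible(x)
}

#' Write a closed-loop run to plain-text files
#'
#' Writes `measurements.csv`, `truth.csv`, `estimates.csv`, `moves.csv`,
#' `soft_tensile.csv`, `metrics.csv` and a `config.yaml` echo of the run
#' configuration into a directory.
#'
#' @param run a `press_run`.
#' @param dir output directory (created if missing).
#' @return `dir`, invisibly.
#' @export
write_run <- function(run, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  readr::write_csv(run$measurements, file.path(dir, "measurements.csv"))
  readr::write_csv(run$truth, file.path(dir, "truth.csv"))
  readr::write_csv(run$estimates, file.path(dir, "estimates.csv"))
  readr::write_csv(run$moves, file.path(dir, "moves.csv"))
  readr::write_csv(run$soft_tensile, file.path(dir, "soft_tensile.csv"))
  readr::write_csv(run$metrics, file.path(dir, "metrics.csv"))
  sc <- run$scenario
  yaml::write_yaml(list(
    scenario = sc$name, mode = run$mode, seed = run$seed,
    horizon_end = sc$horizon_end,
    noise_sd = as.list(sc$noise_sd),
    u_nominal = as.list(unclass(sc$u_nominal)),
    y_nominal = as.list(sc$y_nominal),
    setpoint_schedule = lapply(seq_len(nrow(sc$setpoint_schedule)), function(i)
      as.list(sc$setpoint_schedule[i, ])),
    disturbance_schedule = lapply(seq_len(nrow(sc$disturbance_schedule)), function(i)
      as.list(sc$disturbance_schedule[i, ])),
    estimator = list(n_past = run$est_cfg$n_past,
                     theta = names(run$est_cfg$theta_nominal)),
    controller = list(n_pred = run$ctl_cfg$n_pred, n_ctrl = run$ctl_cfg$n_ctrl,
                      manipulated = run$ctl_cfg$manipulated)
  ), file.path(dir, "config.yaml"))
  invisible(dir)
}

#' Read back a written run
#'
#' Reconstructs enough of a run from [write_run()] output to recompute
#' metrics and draw plots: the stored series plus a scenario skeleton
#' (name, schedules, horizon).
#'
#' @param dir directory written by [write_run()].
#' @return a `press_run`-shaped list.
#' @export
read_run <- function(dir) {
  cfg <- yaml::read_yaml(file.path(dir, "config.yaml"))
  sc <- make_scenario(cfg$scenario, seed = cfg$seed,
                      horizon_end = cfg$horizon_end)
  run <- structure(list(
    scenario = sc, mode = cfg$mode, seed = cfg$seed,
    measurements = readr::read_csv(file.path(dir, "measurements.csv"),
                                   show_col_types = FALSE),
    truth = readr::read_csv(file.path(dir, "truth.csv"), show_col_types = FALSE),
    estimates = readr::read_csv(file.path(dir, "estimates.csv"),
                                show_col_types = FALSE),
    moves = readr::read_csv(file.path(dir, "moves.csv"), show_col_types = FALSE),
    soft_tensile = readr::read_csv(file.path(dir, "soft_tensile.csv"),
                                   show_col_types = FALSE)
  ), class = "press_run")
  run$metrics <- run_metrics(run)
  run
}
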