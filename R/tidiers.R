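#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot

#' Tidy the output series of a closed-loop run
#'
#' Long tibble with one row per time point, output and source: the noisy
#' plant measurements (`measured`), the noise-free plant truth (`truth`) and
#' the model-based tensile-strength soft sensor (`soft_sensor`), each with
#' the setpoint active at that time.
#'
#' @param x a `press_run`.
#' @param ... unused.
#' @return a tibble with columns `time`, `output`, `source`, `value`,
#'   `setpoint`.
#' @export
#' @exportS3Method generics::tidy
tidy.press_run <- function(x, ...) {
  sc <- x$scenario
  sp_of <- function(o, time) {
    vapply(time, function(t) {
      sp <- setpoints_at(sc, t)
      if (o %in% names(sp)) sp[[o]] else NA_real_
    }, numeric(1))
  }
  meas <- tidyr::pivot_longer(
    x$measurements[, c("time", .measured_outputs)],
    -"time", names_to = "output", values_to = "value"
  )
  meas$source <- "measured"
  tru <- tidyr::pivot_longer(
    x$truth[, c("time", .measured_outputs, "sigma_t")],
    -"time", names_to = "output", values_to = "value"
  )
  tru$source <- "truth"
  soft <- tibble::tibble(
    time = x$soft_tensile$time, output = "sigma_t",
    value = x$soft_tensile$sigma_t_soft, source = "soft_sensor"
  )
  out <- dplyr::bind_rows(meas, tru, soft)
  out <- dplyr::arrange(out, .data$output, .data$time)
  out <- dplyr::group_by(out, .data$output)
  out <- dplyr::mutate(out, setpoint = sp_of(.data$output[1], .data$time))
  dplyr::ungroup(out)[, c("time", "output", "source", "value", "setpoint")]
}

#' One-row summary of a closed-loop run
#'
#' @param x a `press_run`.
#' @param ... unused.
#' @return a one-row tibble: scenario, mode, seed, horizon, solver
#'   convergence fractions and per-output IAE.
#' @export
#' @exportS3Method generics::glance
glance.press_run <- function(x, ...) {
  m <- x$metrics
  wide <- stats::setNames(as.list(m$iae), paste0("iae_", m$output))
  tibble::tibble(
    scenario = x$scenario$name, mode = x$mode, seed = x$seed,
    horizon_end = x$scenario$horizon_end,
    mhe_converged = if (nrow(x$estimates)) mean(x$estimates$converged, na.rm = TRUE) else NA_real_,
    nmpc_converged = if (nrow(x$moves)) mean(x$moves$converged) else NA_real_,
    !!!wide
  )
}

#' Plot the controlled outputs of a run
#'
#' Faceted time series of the four controlled outputs: plant truth (line),
#' noisy measurements (points, where measured), soft-sensed tensile strength
#' (dotted) and the active setpoint (dashed).
#'
#' @param object a `press_run`.
#' @param ... unused.
#' @return a ggplot object.
#' @export
#' @exportS3Method ggplot2::autoplot
autoplot.press_run <- function(object, ...) {
  d <- tidy.press_run(object)
  d$output <- factor(d$output,
                     levels = c("weight", "f_pc", "f_mc", "rate", "sigma_t"),
                     labels = c("weight [mg]", "PCF [kN]", "MCF [kN]",
                                "rate [kg/h]", "tensile [MPa]"))
  ggplot2::ggplot(d, ggplot2::aes(x = .data$time)) +
    ggplot2::geom_point(
      data = d[d$source == "measured", ],
      ggplot2::aes(y = .data$value), alpha = 0.15, size = 0.3
    ) +
    ggplot2::geom_line(
      data = d[d$source == "truth", ],
      ggplot2::aes(y = .data$value), colour = "#1f78b4"
    ) +
    ggplot2::geom_line(
      data = d[d$source == "soft_sensor", ],
      ggplot2::aes(y = .data$value), colour = "#33a02c", linetype = "dotted"
    ) +
    ggplot2::geom_step(
      data = d[d$source == "truth" & !is.na(d$setpoint), ],
      ggplot2::aes(y = .data$setpoint), linetype = "dashed", colour = "grey30"
    ) +
    ggplot2::facet_wrap(~output, scales = "free_y", ncol = 2) +
    ggplot2::labs(x = "time [s]", y = NULL,
                  title = sprintf("%s (%s)", object$scenario$name, object$mode)) +
    ggplot2::theme_minimal()
}

#' Plot the estimated parameter traces of a run
#'
#' Estimated parameter trajectories with the plant's true values overlaid
#' (constant mismatch in case study 1, the scheduled silica steps in case
#' study 2).
#'
#' @param run a `press_run`.
#' @return a ggplot object.
#' @export
plot_estimates <- function(run) {
  est <- run$estimates
  th_cols <- grep("^theta_", names(est), value = TRUE)
  d <- tidyr::pivot_longer(est[, c("time", th_cols)], -"time",
                           names_to = "parameter", values_to = "estimate")
  d$parameter <- sub("^theta_", "", d$parameter)
  sc <- run$scenario
  truth <- dplyr::bind_rows(lapply(unique(d$parameter), function(p) {
    tt <- sort(unique(d$time))
    val <- if (p == "cl") {
      vapply(tt, function(t) plant_state_at(sc, t)$cl, numeric(1))
    } else {
      rep(sc$plant_params[[p]], length(tt))
    }
    tibble::tibble(time = tt, parameter = p, value = val)
  }))
  ggplot2::ggplot(d, ggplot2::aes(x = .data$time)) +
    ggplot2::geom_line(ggplot2::aes(y = .data$estimate), colour = "#1f78b4") +
    ggplot2::geom_line(data = truth, ggplot2::aes(y = .data$value),
                       linetype = "dashed", colour = "grey30") +
    ggplot2::facet_wrap(~parameter, scales = "free_y") +
    ggplot2::labs(x = "time [s]", y = "estimate (dashed: plant truth)") +
    ggplot2::theme_minimal()
}
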