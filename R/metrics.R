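# Control-performance metrics. Errors are normalized to percent of setpoint
# so that outputs with very different physical units are comparable; the
# settling (duration-to-reject) band is a configurable percent envelope.

#' Integral of absolute error (IAE)
#'
#' Sum of the setpoint-normalized absolute error over the 1 s grid inside
#' `(t_start, t_end]`, in units of percent-seconds: a constant 1 % error
#' held for 700 s gives 700.
#'
#' @param time sample times, s (1 s grid).
#' @param value output series.
#' @param setpoint setpoint, scalar or series aligned with `time`; must be
#'   nonzero.
#' @param t_start,t_end evaluation window, s.
#' @return IAE in %.s.
#' @export
iae <- function(time, value, setpoint, t_start, t_end) {
  if (t_start < min(time) - 1 || t_end > max(time)) {
    rlang::abort("evaluation window extends outside the series")
  }
  keep <- time > t_start & time <= t_end
  sp <- rep_len(setpoint, length(time))[keep]
  if (any(sp == 0)) rlang::abort("setpoint must be nonzero")
  sum(abs(value[keep] - sp) / abs(sp) * 100)
}

#' Maximum deviation from setpoint (M2P)
#'
#' Largest percent deviation of the output from its setpoint inside the
#' window.
#'
#' @inheritParams iae
#' @return maximum deviation in percent of setpoint.
#' @export
m2p <- function(time, value, setpoint, t_start, t_end) {
  keep <- time >= t_start & time <= t_end
  sp <- rep_len(setpoint, length(time))[keep]
  if (any(sp == 0)) rlang::abort("setpoint must be nonzero")
  max(abs(value[keep] - sp) / abs(sp) * 100)
}

#' Duration to reject (D2R)
#'
#' Time after a setpoint change or disturbance event until the output enters
#' a percent band around the setpoint and remains inside it for the rest of
#' the window. Returns `NA` (the unsettled sentinel) if the series never
#' settles.
#'
#' @inheritParams iae
#' @param event_time time of the setpoint change or disturbance, s.
#' @param band half-width of the settling envelope, percent of setpoint
#'   (> 0).
#' @param t_end end of the window, s (default: end of series).
#' @return settling duration in seconds, or `NA` if unsettled.
#' @export
d2r <- function(time, value, setpoint, event_time, band = 1,
                t_end = max(time)) {
  if (band <= 0) rlang::abort("settling band must be positive")
  if (event_time < min(time) || event_time > max(time)) {
    rlang::abort("event time outside the series")
  }
  keep <- time >= event_time & time <= t_end
  tt <- time[keep]
  sp <- rep_len(setpoint, length(time))[keep]
  if (any(sp == 0)) rlang::abort("setpoint must be nonzero")
  inside <- abs(value[keep] - sp) / abs(sp) * 100 <= band
  # last index outside the band; settled ever after
  if (all(inside)) return(0)
  last_out <- max(which(!inside))
  if (last_out == length(inside)) return(NA_real_)
  tt[last_out + 1] - event_time
}

#' Control-performance metrics of a closed-loop run
#'
#' Computes IAE, M2P and D2R per controlled output from the stored series of
#' a [run_closed_loop()] result. Metrics use the noise-free plant truth so
#' that scenario comparisons reflect control quality rather than sensor
#' noise; tensile strength has no real-time measurement in any case. D2R is
#' evaluated after each output's own setpoint event (case study 1) or after
#' the first disturbance event (case study 2).
#'
#' @param run a `press_run` from [run_closed_loop()], or a list with
#'   `truth` and `scenario` elements of the same shape.
#' @param band D2R settling band, percent of setpoint.
#' @param window numeric `c(t_start, t_end)`; default 300 s to the horizon
#'   end.
#' @return a tibble with one row per controlled output: `output`, `iae`,
#'   `m2p`, `d2r`, `t_start`, `t_end`.
#' @export
run_metrics <- function(run, band = 1, window = NULL) {
  sc <- run$scenario
  if (is.null(window)) {
    # the standard evaluation window opens at 300 s; shortened runs fall
    # back to the start of the closed-loop phase
    t0 <- if (sc$horizon_end > 300) 300 else min(sc$control_start, sc$horizon_end - 1)
    window <- c(t0, sc$horizon_end)
  }
  tr <- run$truth
  sp_series <- function(o) {
    vapply(tr$time, function(t) setpoints_at(sc, t)[[o]], numeric(1))
  }
  rows <- lapply(.controlled_outputs, function(o) {
    sp <- sp_series(o)
    ev <- sc$setpoint_schedule$time[sc$setpoint_schedule$output == o]
    if (!length(ev) && nrow(sc$disturbance_schedule)) {
      ev <- sc$disturbance_schedule$time[1]
    }
    tibble::tibble(
      output = o,
      iae = iae(tr$time, tr[[o]], sp, window[1], window[2]),
      m2p = m2p(tr$time, tr[[o]], sp, window[1], window[2]),
      d2r = if (length(ev)) d2r(tr$time, tr[[o]], sp, ev[length(ev)],
                                band = band, t_end = window[2]) else NA_real_,
      t_start = window[1], t_end = window[2]
    )
  })
  dplyr::bind_rows(rows)
}
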