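test_that("median disturbance is the componentwise robust summary", {
  expect_equal(median_disturbance(data.frame(a = c(0, 0, 0))), c(a = 0))
  expect_equal(median_disturbance(data.frame(a = rep(2.5, 7))), c(a = 2.5))
  # robust to the outlier, unlike the mean (34.33)
  expect_equal(median_disturbance(data.frame(a = c(1, 2, 100))), c(a = 2))
  # even length: midpoint of the central order statistics
  expect_equal(median_disturbance(data.frame(a = c(1, 2, 3, 10))), c(a = 2.5))
  expect_equal(median_disturbance(data.frame(a = c(1, 3), b = c(-2, -4))),
               c(a = 2, b = -3))
  expect_error(median_disturbance(data.frame(a = numeric())), "empty")
})

test_that("a zero-mismatch zero-noise window is a fixed point", {
  sc <- make_scenario("cs1_no_pmm", noise_sd = zero_noise)
  cfg <- default_estimator_config(sc)
  win <- make_window(sc$model_params)
  est <- mhe_update(win, cfg$theta_nominal, sc$model_params, sc$geometry, cfg)
  expect_identical(est$theta_hat, cfg$theta_nominal)
  expect_equal(unname(est$zeta), rep(0, 4), tolerance = 1e-9)
  expect_equal(est$objective_value, 0, tolerance = 1e-9)
})

test_that("single mismatched parameters are recovered from one window", {
  sc <- make_scenario("cs1_no_pmm", noise_sd = zero_noise)
  cfg <- default_estimator_config(sc)
  cases <- list(rho_b = 0.390, rho_c = 0.290, kaw_a = 0.77)
  for (nm in names(cases)) {
    plant <- sc$model_params
    plant[[nm]] <- cases[[nm]]
    win <- make_window(plant)
    est <- mhe_update(win, cfg$theta_nominal, sc$model_params, sc$geometry, cfg)
    expect_lt(abs(est$theta_hat[[nm]] - cases[[nm]]) / cases[[nm]], 1e-3,
              label = paste("relative error for", nm))
    expect_true(est$converged)
  }
  # silica concentration (case study 2): plant at the disturbed level
  cs2 <- make_scenario("cs2_silica_steps", noise_sd = zero_noise)
  cfg2 <- default_estimator_config(cs2)
  win2 <- make_window(cs2$plant_params, glidant_density = TRUE, cl = 0.35)
  est2 <- mhe_update(win2, cfg2$theta_nominal, cs2$model_params, cs2$geometry,
                     cfg2, glidant_density = TRUE)
  expect_lt(abs(est2$theta_hat[["cl"]] - 0.35) / 0.35, 1e-3)
})

test_that("estimates always respect the parameter bounds", {
  sc <- make_scenario("cs1_high_pmm")
  cfg <- default_estimator_config(sc)
  set.seed(5)
  recs <- dplyr::bind_rows(lapply(1:31, function(t)
    plant_step(sc, t, sc$u_nominal)$record))
  est <- mhe_update(recs, cfg$theta_nominal, sc$model_params, sc$geometry, cfg)
  expect_true(all(est$theta_hat >= cfg$theta_lower - 1e-12))
  expect_true(all(est$theta_hat <= cfg$theta_upper + 1e-12))
})

test_that("the optimizer never degrades the incumbent objective", {
  sc <- make_scenario("cs1_mild_pmm")
  cfg <- default_estimator_config(sc)
  set.seed(11)
  win <- dplyr::bind_rows(lapply(1:31, function(t)
    plant_step(sc, t, sc$u_nominal)$record))
  # independent computation of the objective at the incumbent
  obj_at <- function(theta) {
    pars <- sc$model_params
    for (nm in names(theta)) pars[[nm]] <- theta[[nm]]
    out <- evaluate_outputs(win[, c("h_fill", "h_pc", "h_in_die", "n_t", "cl")],
                            pars, sc$geometry)
    w_e <- cfg$w_e
    sum(w_e[["weight"]] * (win$weight - out$weight)^2) +
      sum(w_e[["f_pc"]] * (win$f_pc - out$f_pc)^2) +
      sum(w_e[["f_mc"]] * (win$f_mc - out$f_mc)^2) +
      sum(w_e[["rate"]] * (win$rate - out$rate)^2)
  }
  est <- mhe_update(win, cfg$theta_nominal, sc$model_params, sc$geometry, cfg)
  expect_lte(est$objective_value, obj_at(cfg$theta_nominal) + 1e-9)
  # and the reconstructed outputs fit the window better than the nominal model
  expect_lt(obj_at(est$theta_hat), obj_at(cfg$theta_nominal))
})

test_that("bulk-density estimate is robust to sensor noise across seeds", {
  sc <- make_scenario("cs1_mild_pmm")
  cfg <- default_estimator_config(sc)
  est_rho_b <- vapply(1:50, function(s) {
    set.seed(s)
    win <- dplyr::bind_rows(lapply(1:31, function(t)
      plant_step(sc, t, sc$u_nominal)$record))
    mhe_update(win, cfg$theta_nominal, sc$model_params, sc$geometry,
               cfg)$theta_hat[["rho_b"]]
  }, numeric(1))
  expect_lt(abs(stats::median(est_rho_b) - 0.390) / 0.390, 0.02)
})

test_that("under heavy mismatch the fit improves even if parameters are biased", {
  # six plant constants deviate but only three are tracked: the estimator is
  # allowed to land on biased values, as long as the window residual shrinks
  sc <- make_scenario("cs1_high_pmm", noise_sd = zero_noise)
  cfg <- default_estimator_config(sc)
  win <- make_window(sc$plant_params)
  est <- mhe_update(win, cfg$theta_nominal, sc$model_params, sc$geometry, cfg)
  expect_true(est$converged)
  pred0 <- evaluate_outputs(win[, c("h_fill", "h_pc", "h_in_die", "n_t", "cl")],
                            sc$model_params, sc$geometry)
  sse0 <- sum((win$weight - pred0$weight)^2) + sum((win$f_pc - pred0$f_pc)^2)
  sse1 <- sum((win$weight - est$y_hat_window$weight)^2) +
    sum((win$f_pc - est$y_hat_window$f_pc)^2)
  expect_lt(sse1, sse0 / 10)
})
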