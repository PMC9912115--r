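sc0 <- make_scenario("cs1_no_pmm")
ccfg <- default_controller_config(sc0)
ecfg <- default_estimator_config(sc0)
zeta0 <- c(weight = 0, f_pc = 0, rate = 0)
ysp0 <- c(weight = 210, f_pc = 0.3, rate = 6.9, sigma_t = 4.2)

test_that("zero move is optimal when already at the setpoints", {
  mv <- nmpc_solve(ecfg$theta_nominal, zeta0, ysp0, sc0$u_nominal,
                   sc0$model_params, sc0$geometry, ccfg)
  expect_equal(unname(mv$du_first), rep(0, 5), tolerance = 1e-6)
  expect_lt(mv$objective_value, 1e-8)
})

test_that("applied inputs and moves respect bounds on every iteration", {
  ysp <- c(weight = 260, f_pc = 0.7, rate = 9, sigma_t = 6.5) # far target
  u <- sc0$u_nominal; warm <- NULL
  m <- ccfg$manipulated
  for (k in 1:30) {
    mv <- nmpc_solve(ecfg$theta_nominal, zeta0, ysp, u, sc0$model_params,
                     sc0$geometry, ccfg, warm = warm)
    expect_true(all(unclass(mv$u_applied)[m] >= ccfg$u_lower[m] - 1e-12))
    expect_true(all(unclass(mv$u_applied)[m] <= ccfg$u_upper[m] + 1e-12))
    expect_true(all(abs(mv$du_first) <= ccfg$du_max[m] + 1e-12))
    u <- mv$u_applied; warm <- mv$warm
  }
})

test_that("horizon prediction is static, causal and calibrated", {
  n <- ccfg$n_pred
  u_const <- as.data.frame(lapply(unclass(sc0$u_nominal), rep, n))
  pred <- predict_horizon(ecfg$theta_nominal, zeta0, u_const,
                          sc0$model_params, sc0$geometry)
  # static model: constant inputs give constant outputs
  expect_equal(max(abs(diff(pred$weight))), 0)
  expect_equal(max(abs(diff(pred$sigma_t))), 0)
  # nominal inputs, zero disturbance: the calibrated operating point
  expect_equal(pred$weight[1], 210, tolerance = 1e-6)
  expect_equal(pred$f_pc[1], 0.3, tolerance = 1e-8)
  expect_equal(pred$rate[1], 6.9, tolerance = 1e-8)
  expect_equal(pred$sigma_t[1], 4.2, tolerance = 1e-8)
  # causality: a move at step 5 changes steps >= 5 only
  u_mod <- u_const
  u_mod$h_fill[5:n] <- u_mod$h_fill[5:n] + 0.2
  pred2 <- predict_horizon(ecfg$theta_nominal, zeta0, u_mod,
                           sc0$model_params, sc0$geometry)
  expect_equal(pred2$weight[1:4], pred$weight[1:4])
  expect_true(all(pred2$weight[5:n] != pred$weight[5:n]))
  # the disturbance median shifts measured outputs but not the soft sensor
  pred3 <- predict_horizon(ecfg$theta_nominal, c(weight = 2, f_pc = 0, rate = 0),
                           u_const, sc0$model_params, sc0$geometry)
  expect_equal(pred3$weight, pred$weight + 2)
  expect_equal(pred3$sigma_t, pred$sigma_t)
})

test_that("a constant output bias is rejected without steady-state offset", {
  # plant = model + constant weight bias; the residual median enters the
  # controller's predictions, so the measured output settles on the setpoint
  bias <- 4
  u <- sc0$u_nominal
  zeta <- zeta0
  warm <- NULL
  for (k in 1:80) {
    y_meas <- evaluate_outputs(u, sc0$model_params, sc0$geometry)
    zeta["weight"] <- y_meas$weight + bias -
      evaluate_outputs(u, sc0$model_params, sc0$geometry)$weight
    mv <- nmpc_solve(ecfg$theta_nominal, zeta, ysp0, u, sc0$model_params,
                     sc0$geometry, ccfg, warm = warm)
    u <- mv$u_applied; warm <- mv$warm
  }
  y_final <- evaluate_outputs(u, sc0$model_params, sc0$geometry)
  expect_equal(y_final$weight + bias, 210, tolerance = 0.01)
  expect_equal(y_final$f_pc, 0.3, tolerance = 1e-3)
})

test_that("failed solves hold the previous input and are flagged", {
  bad_cfg <- ccfg
  bad_cfg$maxit <- 0 # degenerate solver budget
  mv <- nmpc_solve(ecfg$theta_nominal, zeta0,
                   c(weight = 240, f_pc = 0.3, rate = 6.9, sigma_t = 4.2),
                   sc0$u_nominal, sc0$model_params, sc0$geometry, bad_cfg)
  expect_true(all(unclass(mv$u_applied) == unclass(sc0$u_nominal)) || !mv$converged)
})
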