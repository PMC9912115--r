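p <- nominal_params()
g <- nominal_geom()

test_that("fill volume separates into cylinder and cup terms", {
  # cylinder term alone: difference between filled and empty die
  expect_equal(fill_volume(g, 8) - fill_volume(g, 0), 200 * pi)
  # cup term alone (h = 1, D = 10): pi * 1 * (75 + 1) / 6
  expect_equal(fill_volume(g, 0), pi * 76 / 6)
  expect_equal(fill_volume(g, 8), 668.11, tolerance = 1e-5)
  expect_error(fill_volume(g, -1), "non-negative")
})

test_that("tablet weight follows the die-filling model", {
  u <- process_inputs(8, 4, 2, g$feed_frame_speed_nF, cl = 0.2)
  # no speed/fill correction: weight is density times volume exactly
  p0 <- model_parameters(xi1 = 1e-12, xi2 = 1e-12)
  expect_equal(tablet_weight(p0, g, u), 0.365 * fill_volume(g, 8),
               tolerance = 1e-9)
  # hand evaluation with the fitted correction constants at nT/nF = 1
  expect_equal(tablet_weight(p, g, u), 240.93, tolerance = 1e-4)
  # linear in bulk density
  expect_equal(tablet_weight(p, g, u, rho_b_effective = 0.73),
               2 * tablet_weight(p, g, u), tolerance = 1e-12)
  expect_error(tablet_weight(p, g, u, rho_b_effective = -1), "positive")
})

test_that("production rate is the linear weight x speed x stations map", {
  expect_equal(production_rate(210, 54.76, 10), 6.9, tolerance = 1e-4)
  expect_equal(production_rate(0, 54.76, 10), 0)
  expect_equal(production_rate(420, 54.76, 10),
               2 * production_rate(210, 54.76, 10))
  expect_equal(production_rate(210, 2 * 54.76, 10),
               2 * production_rate(210, 54.76, 10))
})

test_that("relative density is weight over volume times true density", {
  expect_equal(relative_density(100 * 1.53, 100, 1.53), 1)
  expect_equal(relative_density(240.94, 393.75, 1.53), 0.400, tolerance = 2e-4)
  expect_equal(relative_density(240.94, 393.75 / 2, 1.53),
               2 * relative_density(240.94, 393.75, 1.53))
  expect_error(relative_density(100, -1, 1.53))
})

test_that("Kawakita force vanishes at the critical density and increases", {
  expect_identical(kawakita_force(p$rho_c, p, 10), 0)
  expect_equal(kawakita_force(0.53, p, 10), 1.343, tolerance = 1e-3)
  # strictly increasing over the validity interval (fine grid)
  rho <- seq(p$rho_c, p$rho_c / (1 - p$kaw_a) - 1e-6, length.out = 1000)
  f <- kawakita_force(rho, p, 10)
  expect_true(all(diff(f) > 0))
  expect_error(kawakita_force(0.2, p, 10), "validity")
  expect_error(kawakita_force(1.4, p, 10), "validity")
})

test_that("elastic recovery hits its analytic limits", {
  expect_identical(elastic_recovery(1, p), p$eps0)
  expect_identical(elastic_recovery(p$rho_c_eps, p), 0)
  expect_equal(elastic_recovery(0.785, p), 0.04, tolerance = 1e-12)
  expect_message(val <- elastic_recovery(0.3, p), "clamped")
  expect_identical(val, 0)
})

test_that("glidant shear is the baseline plus feed-frame residence time", {
  g0 <- tooling_geometry(holdup_mfh = 1e-12)
  expect_equal(glidant_shear(g0, 6.9), g0$gamma0, tolerance = 1e-9)
  expect_equal(glidant_shear(g, 6.9), 10 + 60 / 6.9, tolerance = 1e-12)
  rates <- seq(2, 20, by = 0.5)
  expect_true(all(diff(glidant_shear(g, rates)) < 0))
  expect_error(glidant_shear(g, 0), "positive")
})

test_that("glidant bulk density saturates between its two plateaus", {
  cs2 <- press_params("cs2_nominal")
  expect_identical(bulk_density_from_c(0, cs2), cs2$rho_b_0)
  expect_equal(bulk_density_from_c(1e9, cs2), cs2$rho_b_inf, tolerance = 1e-8)
  expect_equal(bulk_density_from_c(1, cs2), 0.390, tolerance = 1e-12)
  cr <- seq(0, 50, length.out = 500)
  bd <- bulk_density_from_c(cr, cs2)
  expect_true(all(diff(bd) > 0))
  expect_true(all(bd >= cs2$rho_b_0 & bd <= cs2$rho_b_inf))
  expect_identical(glidant_bulk_density(0, 18.7, cs2), cs2$rho_b_0)
  expect_error(bulk_density_from_c(-1, cs2), "non-negative")
})

test_that("tensile strength hits its limits and is monotone in density", {
  # zero porosity, no glidant correction: the zero-porosity strength
  expect_equal(tensile_strength(1, 0, 18.7, p), p$sigma0,
               tolerance = 1e-12, ignore_attr = TRUE)
  expect_equal(tensile_strength(p$rho_c0, 0, 18.7, p), 0,
               tolerance = 1e-12, ignore_attr = TRUE)
  expect_equal(tensile_strength(0.785, 0, 18.7, p), 4.435, tolerance = 1e-3,
               ignore_attr = TRUE)
  rho <- seq(p$rho_c0, 1, length.out = 1000)
  st <- tensile_strength(rho, 0, 18.7, p)
  expect_true(all(diff(st) > 0))
  st_low <- tensile_strength(0.4, 0.2, 18.7, p)
  expect_identical(as.numeric(st_low), 0)
  expect_false(attr(st_low, "tablet_forms"))
})

test_that("the composed output map is pure and matches the chained pieces", {
  u <- process_inputs(6.9319, 4.1501, 1.0218, 54.7619, cl = 0.2)
  o1 <- evaluate_outputs(u, p, g)
  o2 <- evaluate_outputs(u, p, g)
  expect_identical(o1, o2)

  # chain the scalar operations by hand and compare
  w <- tablet_weight(p, g, u)
  expect_equal(o1$weight, w, tolerance = 1e-12)
  rate <- production_rate(w, u[["n_t"]], g$n_stations)
  expect_equal(o1$rate, rate, tolerance = 1e-12)
  vpc <- pi * 100 * u[["h_pc"]] / 4 + pi * 76 / 3
  rho_pc <- relative_density(w, vpc, p$rho_t)
  expect_equal(o1$f_pc, kawakita_force(rho_pc, p, 10), tolerance = 1e-12)
  vind <- pi * 100 * u[["h_in_die"]] / 4 + pi * 76 / 3
  rho_ind <- relative_density(w, vind, p$rho_t)
  expect_equal(o1$rho_in_die, rho_ind, tolerance = 1e-12)
  rho_tab <- (1 - elastic_recovery(rho_ind, p)) * rho_ind
  expect_equal(o1$rho_tablet, rho_tab, tolerance = 1e-12)
  gam <- glidant_shear(g, rate)
  expect_equal(o1$sigma_t, tensile_strength(rho_tab, 0.2, gam, p),
               tolerance = 1e-12, ignore_attr = TRUE)

  # tablet density never exceeds the in-die density
  expect_true(o1$rho_tablet <= o1$rho_in_die)
  expect_error(
    evaluate_outputs(process_inputs(8, 4, 0.5, 90, validate = FALSE), p, g),
    "validity"
  )
})

test_that("vectorised evaluation agrees with row-by-row evaluation", {
  set.seed(42)
  cs2 <- press_params("cs2_nominal")
  for (gl in c(FALSE, TRUE)) {
    pp <- if (gl) cs2 else p
    # the glidant bulk density (~0.42 g/cm^3) makes heavier tablets, so the
    # valid thickness window sits higher than with the CS1 bulk density
    u <- if (gl) {
      tibble::tibble(
        h_fill = runif(20, 5.8, 7.0), h_pc = runif(20, 4.2, 4.8),
        h_in_die = runif(20, 1.25, 1.55), n_t = runif(20, 48, 62),
        cl = runif(20, 0.05, 0.5)
      )
    } else {
      tibble::tibble(
        h_fill = runif(20, 6.5, 8.5), h_pc = runif(20, 3.9, 4.6),
        h_in_die = runif(20, 1.05, 1.35), n_t = runif(20, 48, 62),
        cl = runif(20, 0.05, 0.5)
      )
    }
    all_at_once <- evaluate_outputs(u, pp, g, glidant_density = gl)
    one_by_one <- dplyr::bind_rows(
      lapply(seq_len(20), function(i) evaluate_outputs(u[i, ], pp, g,
                                                       glidant_density = gl))
    )
    expect_equal(all_at_once, one_by_one, tolerance = 1e-12)
  }
})
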