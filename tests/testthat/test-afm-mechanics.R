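test_that("to_force_indentation applies the defining arithmetic", {
  # single post-contact point: z - z0 = 100 nm, d - d0 = 10 nm at k = 30
  z <- seq(0, 2100, length.out = 211)
  d <- numeric(211)
  d[211] <- 10
  fc <- force_curve(z, d, k = 30)
  fi <- to_force_indentation(fc, z0 = 2000)
  expect_equal(fi$delta[length(fi$delta)], 90)
  expect_equal(fi$force[length(fi$force)], 0.3)

  # flat curve -> empty contact
  flat <- force_curve(z, numeric(211), k = 30)
  expect_error(to_force_indentation(flat, 2000), class = "empty_contact")
})

test_that("contact point is found at sample precision and is translation-equivariant", {
  cfg <- afm_sim_config(E_true = 3000, noise_sd = 0, z0 = 2000)
  fc <- simulate_force_curve(cfg)
  spacing <- diff(fc$z_sensor[1:2])
  z0 <- find_contact_point(fc)
  expect_lt(abs(z0 - 2000), spacing)

  # shifting z shifts z0 identically
  fc2 <- fc
  fc2$z_sensor <- fc$z_sensor + 500
  expect_equal(find_contact_point(fc2), z0 + 500, tolerance = 1e-6)

  # pure-noise curve: no contact
  set.seed(8)
  noise <- force_curve(seq(0, 3000, length.out = 300), rnorm(300), k = 30)
  expect_error(find_contact_point(noise), class = "no_contact")
})

test_that("Hertz fit is exact on exact data and linear in force", {
  delta <- seq(100, 1000, length.out = 50)
  force <- hertz_force(delta, 2000, 0.5, 17.5 * pi / 180)
  fit <- fit_hertz_pyramid(delta, force)
  expect_equal(fit$E, 2000, tolerance = 1e-4)

  # doubling force doubles E
  fit2 <- fit_hertz_pyramid(delta, 2 * force)
  expect_equal(fit2$E, 2 * fit$E, tolerance = 1e-10)

  # degenerate indentation
  expect_error(fit_hertz_pyramid(rep(500, 20), rep(0.1, 20)),
               class = "singular_fit")
  expect_error(fit_hertz_pyramid(delta[1:5], force[1:5]),
               class = "invalid_input")
})

test_that("noiseless round trip recovers (z0, E) and matches the grid-search oracle", {
  for (E in c(900, 2900, 4400)) {
    cfg <- afm_sim_config(E_true = E, noise_sd = 0, z0 = 2000)
    fc <- simulate_force_curve(cfg)
    fit <- analyze_force_curve(fc)
    expect_lt(abs(fit$E - E) / E, 0.001)
    expect_lt(abs(fit$z0 - 2000), diff(fc$z_sensor[1:2]))
  }
  # oracle equivalence on a noisy curve: grid search lands within its grid
  # resolution of the analytic fit
  cfgn <- afm_sim_config(E_true = 2000, noise_sd = 1, z0 = 2000, seed = 7)
  fcn <- simulate_force_curve(cfgn)
  fit <- analyze_force_curve(fcn)
  or <- oracle_grid_hertz(fcn, E_grid = seq(1600, 2400, by = 10))
  expect_lt(abs(fit$E - or$E), 25)        # within one oracle grid step + eps
  expect_lt(abs(fit$z0 - or$z0), 2 * diff(fcn$z_sensor[1:2]))
  expect_lt(abs(fit$E - 2000) / 2000, 0.05)
})

test_that("fitted E scales with the spring constant at fixed deflections", {
  cfg <- afm_sim_config(E_true = 2000, noise_sd = 0, z0 = 2000)
  fc <- simulate_force_curve(cfg)
  fit1 <- analyze_force_curve(fc, F_max = NULL)
  fc2 <- fc
  fc2$k <- fc$k * 2
  fit2 <- analyze_force_curve(fc2, F_max = NULL)
  expect_equal(fit2$E / fit1$E, 2, tolerance = 1e-6)
})

test_that("median fitted E stays within 5% of truth at 1 nm noise", {
  for (E in c(500, 2000, 10000)) {
    Es <- vapply(1:40, function(i) {
      cfg <- afm_sim_config(E_true = E, noise_sd = 1, z0 = 2000,
                            seed = 1000 * E + i)
      analyze_force_curve(simulate_force_curve(cfg))$E
    }, numeric(1))
    expect_lt(abs(median(Es) - E) / E, 0.05)
  }
})

test_that("spring-constant calibration round-trips through the thermal method", {
  for (k in c(28, 31)) {
    th <- simulate_thermal_spectrum(k = k, T = 295, n_samples = 2^17,
                                    seed = k)
    k_est <- calibrate_spring_constant(th, T = 295)
    expect_lt(abs(k_est - k) / k, 0.05)
    expect_gt(k_est, 26); expect_lt(k_est, 33)
  }
  # doubling T doubles k for a fixed series
  th <- simulate_thermal_spectrum(k = 30, T = 295, n_samples = 2^15, seed = 1)
  expect_equal(calibrate_spring_constant(th, T = 590) /
                 calibrate_spring_constant(th, T = 295), 2, tolerance = 1e-10)
  expect_error(calibrate_spring_constant(numeric(100)), class = "invalid_input")
})

test_that("per-cell aggregation averages converged fits and counts exclusions", {
  mkfit <- function(E, conv = TRUE) structure(
    list(E = E, converged = conv), class = "hertz_fit")
  cs <- aggregate_cell(lapply(rep(4400, 10), mkfit), "c1")
  expect_equal(cs$E_mean, 4400)
  expect_equal(cs$n_points, 10)

  cs2 <- aggregate_cell(lapply(c(1000, 2000, 3000), mkfit), "c2")
  expect_equal(cs2$E_mean, 2000)

  fits <- c(lapply(rep(2000, 7), mkfit),
            lapply(rep(NA_real_, 3), mkfit, conv = FALSE))
  cs3 <- aggregate_cell(fits, "c3")
  expect_equal(cs3$E_mean, 2000)
  expect_equal(cs3$excluded_count, 3)

  expect_error(aggregate_cell(lapply(1:3, mkfit, conv = FALSE)),
               class = "empty_cell")
  expect_error(aggregate_cell(list()), class = "empty_cell")
})

test_that("force-curve files round-trip through the text format", {
  cfg <- afm_sim_config(E_true = 2500, noise_sd = 1, seed = 3)
  fc <- simulate_force_curve(cfg, id = "cellA_p1")
  path <- tempfile(fileext = ".txt")
  write_force_curve(fc, path)
  back <- read_force_curve(path)
  expect_equal(back$z_sensor, fc$z_sensor, tolerance = 1e-6)
  expect_equal(back$deflection, fc$deflection, tolerance = 1e-6)
  expect_equal(back$k, fc$k)
  expect_equal(back$id, "cellA_p1")
  unlink(path)
})
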