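test_that("oscillator_params links omega, mass and k consistently", {
  p <- oscillator_params(k = 12e-9, gamma = 3, omega = 6)
  expect_equal(p$mass, 12e-9 / (36 + 9))
  p2 <- oscillator_params(k = 12e-9, gamma = 3, omega = NULL, mass = p$mass)
  expect_equal(p2$omega, 6)
  expect_error(oscillator_params(k = -1e-9), "positive")
  expect_error(oscillator_params(omega = 6, mass = 1e-10), "exactly one")
  # overdamped mass in SDE convention is rejected with guidance
  expect_error(
    oscillator_params(k = 1e-9, gamma = 10, omega = NULL, mass = 1e-9),
    "simulate_gp"
  )
})

test_that("theoretical autocovariance evaluates the damped cosine exactly", {
  p <- oscillator_params(k = 12e-9, gamma = 2, omega = 5)
  C0 <- thermal_energy(298) / 12e-9 * 1e12
  th <- theoretical_acf(p, c(0, 1))
  expect_equal(th$C_um2[1], C0)          # cos(0) = exp(0) = 1
  expect_equal(th$C_um2[1], 0.3429, tolerance = 1e-3)
  expect_equal(th$C_um2[2] / th$C_um2[1], exp(-2) * cos(5))
  expect_error(theoretical_acf(p, -0.1), "non-negative")
})

test_that("GP generator is reproducible and seed-sensitive", {
  p <- control_params()
  sp <- sampling_spec(n_frames = 200, n_molecules = 2, seed = 42)
  s1 <- simulate_gp(p, sp)
  s2 <- simulate_gp(p, sp)
  expect_identical(s1, s2)
  s3 <- simulate_gp(p, sampling_spec(n_frames = 200, n_molecules = 2, seed = 43))
  expect_false(isTRUE(all.equal(s1$R_um, s3$R_um)))
  # evenly spaced at the frame interval, lengths positive at these params
  expect_equal(unique(round(diff(s1$time_s[1:200]), 10)), round(1 / 30, 10))
  expect_true(all(s1$R_um > 0))
})

test_that("GP generator satisfies equipartition and matches the model ACF", {
  p <- control_params()
  s <- simulate_gp(p, sampling_spec(n_frames = 1e5, n_molecules = 1, seed = 3))
  C0 <- thermal_energy(298) / p$k * 1e12
  v <- mean((s$R_um - mean(s$R_um))^2)
  expect_equal(v, C0, tolerance = 0.05)
  # empirical ACF tracks the damped cosine at the first 30 lags within
  # a few standard errors of the ACF estimator (~ sqrt(2/(gamma*T)))
  ac <- autocovariance(s, max_lag_s = 1)
  th <- theoretical_acf(p, ac$lag_s)
  se <- C0 * sqrt(2 / (p$gamma * max(s$time_s)))
  expect_lt(max(abs(ac$C_um2[1:30] - th$C_um2[1:30])), 4 * se)
})

test_that("a mean far below the fluctuation amplitude triggers the negative-length warning", {
  p <- oscillator_params(k = 1e-10, gamma = 3, omega = 6, mean_length_um = 1)
  expect_warning(
    simulate_gp(p, sampling_spec(n_frames = 100, n_molecules = 1, seed = 1)),
    "P\\(R < 0\\)"
  )
})

test_that("SDE integrator reproduces the closed-form zero-temperature decay", {
  p <- control_params()
  for (dt in c(0.01, 0.005)) {
    n <- round(2 / dt)
    num <- propagate_deterministic(p, x0_um = 0.5, n_steps = n, dt_internal = dt)
    ref <- relaxation_curve(p, 0.5, num$time_s)
    # exact propagator: no time-step bias at either resolution
    expect_lt(max(abs(num$x_um - ref$x_um)), 1e-10)
  }
})

test_that("SDE generator reaches the equipartition variance", {
  p <- control_params()
  s <- simulate_sde(p, sampling_spec(n_frames = 4e4, n_molecules = 1, seed = 4))
  C0 <- thermal_energy(298) / p$k * 1e12
  expect_equal(var(s$R_um), C0, tolerance = 0.05)
})

test_that("SDE mode refuses overdamped parameter sets", {
  p <- oscillator_params(k = 12e-9, gamma = 3, omega = 6)
  p$mass <- 10 * p$k / p$gamma^2   # force k/m < gamma^2
  expect_error(
    simulate_sde(p, sampling_spec(n_frames = 100, n_molecules = 1)),
    "simulate_gp"
  )
})

test_that("series CSV + sidecar round trip preserves data and ground truth", {
  p <- control_params()
  sp <- sampling_spec(n_frames = 60, n_molecules = 2, seed = 5)
  s <- simulate_gp(p, sp)
  path <- file.path(withr::local_tempdir(), "series.csv")
  write_series(s, path, params = p, sampling = sp)
  r <- read_series(path)
  expect_equal(r, s, tolerance = 1e-12, ignore_attr = TRUE)
  meta <- attr(r, "meta")
  expect_equal(meta$ground_truth$k, 12e-9)
  expect_equal(meta$sampling$seed, 5)
})
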