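test_that("autocovariance matches the brute-force double-loop oracle", {
  # frozen worked example for the oracle itself, unit spacing: [1, 2, 3, 2]
  expect_equal(brute_force_acov(c(1, 2, 3, 2), 2), c(0.5, 0, -0.25))

  # property: exact agreement with the oracle on random series
  set.seed(77)
  for (rep in 1:8) {
    n <- sample(50:200, 1)
    x <- rnorm(n, mean = 3, sd = 0.5)
    ser <- tibble::tibble(time_s = (seq_len(n) - 1) / 30, R_um = x)
    maxlag <- floor(n / 3)
    for (est in c("biased", "unbiased")) {
      got <- autocovariance(ser, max_lag_s = maxlag / 30, estimator = est)
      want <- brute_force_acov(x, maxlag, est)
      expect_equal(got$C_um2, want, tolerance = 1e-12)
    }
  }
})

test_that("C(0) equals the biased sample variance and bounds the curve", {
  set.seed(11)
  x <- rnorm(300, 3, 0.4)
  ser <- tibble::tibble(time_s = (0:299) / 30, R_um = x)
  ac <- autocovariance(ser, max_lag_s = 2)
  expect_equal(ac$C_um2[1], mean((x - mean(x))^2))
  expect_true(all(abs(ac$C_um2) <= ac$C_um2[1] + 1e-12))
  expect_equal(ac$n_pairs, 300 - 0:60)
})

test_that("degenerate and invalid series are handled", {
  const <- tibble::tibble(time_s = (0:99) / 30, R_um = rep(2, 100))
  ac <- autocovariance(const, max_lag_s = 1)
  expect_true(all(ac$C_um2 == 0))
  short <- tibble::tibble(time_s = (0:9) / 30, R_um = rnorm(10))
  expect_error(autocovariance(short), "at least 50")
  long <- tibble::tibble(time_s = (0:99) / 30, R_um = rnorm(100, 3, 0.1))
  expect_error(autocovariance(long, max_lag_s = 2), "third")
  flagged <- tibble::tibble(time_s = (0:99) / 30, R_um = rnorm(100, 3, 0.1),
                            flag = c(rep("ok", 99), "no-detection"))
  expect_error(autocovariance(flagged), "flagged")
})

test_that("a long cosine record converges to the closed-form autocovariance", {
  # R(t) = Rbar + a cos(w0 t)  =>  C(tau) -> (a^2/2) cos(w0 tau)
  dt <- 1 / 30; n <- 60000; a <- 0.3; w0 <- 5
  t <- (seq_len(n) - 1) * dt
  ser <- tibble::tibble(time_s = t, R_um = 3 + a * cos(w0 * t))
  ac <- autocovariance(ser, max_lag_s = 1)
  expect_equal(ac$C_um2, a^2 / 2 * cos(w0 * ac$lag_s), tolerance = 5e-3)
})

test_that("gap-aware autocovariance agrees with the full-record estimate", {
  p <- control_params()
  s <- simulate_gp(p, sampling_spec(n_frames = 3000, n_molecules = 1, seed = 21))
  full <- autocovariance(s, max_lag_s = 1)
  set.seed(22)
  holes <- sample(nrow(s), 30)
  gappy <- s[-holes, ]
  expect_error(autocovariance(gappy, max_lag_s = 1), "pairwise")
  ac <- autocovariance(gappy, max_lag_s = 1, gaps = "pairwise")
  expect_lt(max(abs(ac$C_um2 - full$C_um2)), 0.02 * full$C_um2[1])
  expect_true(all(ac$n_pairs <= full$n_pairs))
})

test_that("noiseless damped-cosine curves are recovered to 1e-6 relative", {
  dt <- 1 / 30
  lags <- seq(0, 2, by = dt)
  cases <- expand.grid(A = c(0.1, 0.3), g = c(1, 2, 6), w = c(3, 5, 10))
  for (i in seq_len(nrow(cases))) {
    A <- cases$A[i]; g <- cases$g[i]; w <- cases$w[i]
    curve <- tibble::tibble(lag_s = lags, C_um2 = A * exp(-g * lags) * cos(w * lags))
    fit <- fit_damped_cosine(curve, fit_window_s = 2)
    expect_true(fit$converged)
    expect_equal(fit$A_um2, A, tolerance = 1e-6)
    expect_equal(fit$gamma, g, tolerance = 1e-6)
    expect_equal(fit$omega, w, tolerance = 1e-6)
  }
})

test_that("the fit agrees with a deterministic grid-search oracle under noise", {
  dt <- 1 / 30
  lags <- seq(0, 2, by = dt)
  set.seed(33)
  y <- 0.30 * exp(-2 * lags) * cos(5 * lags) + rnorm(length(lags), 0, 0.01)
  curve <- tibble::tibble(lag_s = lags, C_um2 = y)
  fit <- suppressWarnings(fit_damped_cosine(curve, fit_window_s = 2))
  oracle <- grid_search_damped_cosine(
    lags, y, g_grid = seq(0.5, 4, by = 0.05), w_grid = seq(3, 7, by = 0.05)
  )
  expect_equal(fit$gamma, oracle$g, tolerance = 0.05)
  expect_equal(fit$omega, oracle$w, tolerance = 0.05)
  # and both stay near the generating parameters
  expect_equal(fit$gamma, 2, tolerance = 0.05)
  expect_equal(fit$omega, 5, tolerance = 0.05)
  expect_lte(sum((fit$curve$C_um2 - fit$curve$fitted_um2)^2), oracle$rss + 1e-10)
})

test_that("k is read from C(0) and flagged when the amplitude disagrees", {
  dt <- 1 / 30
  lags <- seq(0, 2, by = dt)
  # white measurement noise inflates C(0) only: A stays, C(0) jumps
  curve <- tibble::tibble(lag_s = lags, C_um2 = 0.30 * exp(-2 * lags) * cos(5 * lags))
  curve$C_um2[1] <- 0.40
  expect_warning(fit <- fit_damped_cosine(curve, fit_window_s = 2), "20%")
  expect_equal(fit$k, thermal_energy(298) / (0.40 * 1e-12))
  expect_equal(fit$k_amp, thermal_energy(298) / (fit$A_um2 * 1e-12))
  # inflated C(0) pulls k below the amplitude-based estimate
  expect_gt(fit$k_amp / fit$k, 1.2)
})

test_that("tidy, glance and autoplot work on a fit", {
  lags <- seq(0, 1.5, by = 1 / 30)
  curve <- tibble::tibble(lag_s = lags, C_um2 = 0.34 * exp(-3 * lags) * cos(6 * lags))
  fit <- fit_damped_cosine(curve)
  td <- tidy(fit)
  expect_equal(td$term, c("k", "gamma", "omega", "A"))
  gl <- glance(fit)
  expect_true(gl$converged)
  expect_s3_class(autoplot(fit), "ggplot")
})

test_that("k-omega^2 diagnostic recovers a linear law and rejects degenerate input", {
  # exact collinear synthetic points: omega^2 = k/m - gamma^2
  m <- 3e-10; g <- 1
  k <- c(5, 12, 25, 50) * 1e-9
  fits <- tibble::tibble(k_N_per_m = k, omega_rad_per_s = sqrt(k / m - g^2))
  # lm warns about the numerically perfect fit; that is the point here
  d <- suppressWarnings(k_omega_diagnostic(fits))
  expect_equal(d$r_squared, 1)
  expect_equal(d$slope, 1 / m, tolerance = 1e-9)
  expect_equal(d$intercept, -g^2, tolerance = 1e-6)
  expect_error(k_omega_diagnostic(fits[1:2, ]), "at least 3")
  same <- tibble::tibble(k_N_per_m = rep(1e-8, 4), omega_rad_per_s = rep(6, 4))
  expect_error(k_omega_diagnostic(same), "degenerate")
})

test_that("condition summaries report mean and SEM over molecules", {
  fits <- tibble::tibble(
    molecule_id = c("a", "b", "c"),
    k_N_per_m = c(1, 2, 3) * 1e-9, gamma_per_s = c(2, 2, 2),
    omega_rad_per_s = c(5, 6, 7), converged = TRUE
  )
  s <- summarize_condition(fits, "demo")
  expect_equal(s$mean_k_N_per_m, 2e-9)
  expect_equal(s$sem_k_N_per_m, 1e-9 / sqrt(3))
  expect_equal(s$sem_gamma_per_s, 0)
  # single molecule: mean reported, SEM absent
  s1 <- summarize_condition(fits[1, ], "solo")
  expect_equal(s1$mean_k_N_per_m, 1e-9)
  expect_true(is.na(s1$sem_k_N_per_m))
  # non-converged fits are excluded and counted
  fits$converged[2] <- FALSE
  s2 <- summarize_condition(fits, "demo")
  expect_equal(s2$n_molecules, 2)
  expect_equal(s2$n_excluded, 1)
  expect_error(summarize_condition(fits[fits$converged == FALSE, ], "x"),
               "no converged")
})

test_that("SEM shrinks as 1/sqrt(n) on resampled synthetic conditions", {
  p <- control_params()
  f4 <- fit_molecules(simulate_gp(p, sampling_spec(n_frames = 1500, n_molecules = 4, seed = 8)))
  f16 <- fit_molecules(simulate_gp(p, sampling_spec(n_frames = 1500, n_molecules = 16, seed = 8)))
  s4 <- summarize_condition(f4, "n4")
  s16 <- summarize_condition(f16, "n16")
  # ratio ~ sqrt(4/16) = 0.5 up to sampling noise in the sd estimates
  expect_lt(s16$sem_k_N_per_m / s4$sem_k_N_per_m, 1)
  expect_equal(s16$sem_k_N_per_m / s4$sem_k_N_per_m, 0.5, tolerance = 0.6)
})
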