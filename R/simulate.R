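#' Ground-truth oscillator parameters
#'
#' Physical parameters of the effective damped harmonic oscillator whose
#' thermal fluctuations the simulators realize: spring constant k [N/m],
#' damping constant gamma [1/s] (the decay rate of the autocovariance
#' envelope), angular frequency omega [rad/s], temperature, and the mean
#' long-axis length the fluctuation rides on.
#'
#' Exactly one of `omega` / `mass` is given; the other is derived through
#' the underdamped relation `mass = k / (omega^2 + gamma^2)` (equivalently
#' `omega = sqrt(k/mass - gamma^2)`, the oscillation frequency of the
#' autocovariance). Note the damping convention: `gamma` here is the
#' envelope rate e^(-gamma*tau) of the autocovariance, i.e. the equation of
#' motion reads `x'' = -(k/m) x - 2*gamma*x' + noise`. Some texts call
#' 2*gamma (or gamma*m) the damping constant; conventions differ by a
#' factor of two.
#'
#' @param k Spring constant in N/m (> 0).
#' @param gamma Damping constant in 1/s (>= 0).
#' @param omega Angular frequency in rad/s (>= 0), or `NULL` if `mass` given.
#' @param mass Effective mass in kg (> 0), or `NULL` if `omega` given.
#' @param temperature Absolute temperature in kelvin (> 0).
#' @param mean_length_um Mean long-axis length in um (> 0).
#' @return An object of class `oscillator_params` (a validated list).
#' @examples
#' oscillator_params(k = 12e-9, gamma = 3, omega = 6)
#' @export
oscillator_params <- function(k = 12e-9, gamma = 3, omega = 6, mass = NULL,
                              temperature = 298, mean_length_um = 3) {
  if (!is.numeric(k) || length(k) != 1L || !is.finite(k) || k <= 0) {
    abort("`k` must be a single positive spring constant in N/m.")
  }
  if (!is.numeric(gamma) || length(gamma) != 1L || !is.finite(gamma) || gamma < 0) {
    abort("`gamma` must be a single non-negative damping constant in 1/s.")
  }
  if (is.null(omega) == is.null(mass)) {
    abort("supply exactly one of `omega` or `mass`.")
  }
  if (!is.numeric(temperature) || temperature <= 0) {
    abort("`temperature` must be positive (kelvin).")
  }
  if (!is.numeric(mean_length_um) || mean_length_um <= 0) {
    abort("`mean_length_um` must be positive.")
  }
  if (is.null(omega)) {
    if (!is.finite(mass) || mass <= 0) abort("`mass` must be positive (kg).")
    om2 <- k / mass - gamma^2
    if (om2 < 0) {
      abort(paste0(
        "overdamped parameter set: k/mass = ", format(k / mass),
        " <= gamma^2 = ", format(gamma^2),
        ". The physical simulator handles the underdamped regime only; ",
        "use the Gaussian-process generator (`simulate_gp()`) for ",
        "arbitrary envelope/frequency combinations."
      ))
    }
    omega <- sqrt(om2)
  } else {
    if (!is.finite(omega) || omega < 0) abort("`omega` must be non-negative (rad/s).")
    mass <- k / (omega^2 + gamma^2)
  }
  structure(
    list(
      k = k, gamma = gamma, omega = omega, mass = mass,
      temperature = temperature, mean_length_um = mean_length_um
    ),
    class = "oscillator_params"
  )
}

#' @export
print.oscillator_params <- function(x, ...) {
  cat("<oscillator_params>\n")
  cat(sprintf("  k      = %.4g N/m\n", x$k))
  cat(sprintf("  gamma  = %.4g 1/s\n", x$gamma))
  cat(sprintf("  omega  = %.4g rad/s\n", x$omega))
  cat(sprintf("  mass   = %.4g kg\n", x$mass))
  cat(sprintf("  T      = %.4g K,  mean length = %.4g um\n",
              x$temperature, x$mean_length_um))
  cat(sprintf("  C(0)   = kBT/k = %.4g um^2\n",
              thermal_energy(x$temperature) / x$k * 1e12))
  invisible(x)
}

#' Sampling specification for simulated recordings
#'
#' @param frame_interval_s Time between frames in seconds (default 1/30,
#'   i.e. 30 frames per second video).
#' @param n_frames Number of frames per molecule (>= 2).
#' @param n_molecules Number of molecules (independent realizations).
#' @param seed Integer root seed. Per-molecule RNG streams are derived as
#'   `seed + molecule index`, so output is reproducible molecule by
#'   molecule.
#' @return An object of class `sampling_spec`.
#' @export
sampling_spec <- function(frame_interval_s = 1 / 30, n_frames = 3000,
                          n_molecules = 10, seed = 1) {
  if (!is.numeric(frame_interval_s) || frame_interval_s <= 0) {
    abort("`frame_interval_s` must be positive.")
  }
  if (!is.numeric(n_frames) || n_frames < 2) abort("`n_frames` must be >= 2.")
  if (!is.numeric(n_molecules) || n_molecules < 1) abort("`n_molecules` must be >= 1.")
  if (!is.numeric(seed) || !is.finite(seed)) abort("`seed` must be a finite integer.")
  structure(
    list(
      frame_interval_s = frame_interval_s, n_frames = as.integer(n_frames),
      n_molecules = as.integer(n_molecules), seed = as.integer(seed)
    ),
    class = "sampling_spec"
  )
}

#' Theoretical autocovariance of the long-axis fluctuation
#'
#' The fluctuation-dissipation model curve
#' C(tau) = (kBT/k) * exp(-gamma*tau) * cos(omega*tau), in um^2.
#' C(0) = kBT/k exactly (equipartition).
#'
#' @param params An [oscillator_params()] object.
#' @param lags_s Numeric vector of non-negative lags in seconds.
#' @return A tibble with columns `lag_s` and `C_um2`.
#' @examples
#' p <- oscillator_params(k = 12e-9, gamma = 2, omega = 5)
#' theoretical_acf(p, seq(0, 2, by = 1 / 30))
#' @export
theoretical_acf <- function(params, lags_s) {
  stopifnot(inherits(params, "oscillator_params"))
  if (!is.numeric(lags_s) || any(!is.finite(lags_s)) || any(lags_s < 0)) {
    abort("`lags_s` must be non-negative finite lags in seconds.")
  }
  C0 <- thermal_energy(params$temperature) / params$k * 1e12
  tibble(
    lag_s = lags_s,
    C_um2 = C0 * exp(-params$gamma * lags_s) * cos(params$omega * lags_s)
  )
}

# Circulant-embedding sample of a stationary Gaussian series with
# autocovariance cov_fun(j * dt), j = 0..n-1. Returns one realization of
# length n (zero mean). Doubles the embedding until the circulant spectrum
# is non-negative (up to a tiny clamp) or errors.
.circulant_sample <- function(n, dt, cov_fun, max_doublings = 6) {
  m <- 2^ceiling(log2(max(2 * (n - 1), 2)))
  for (i in seq_len(max_doublings + 1)) {
    j <- 0:(m - 1)
    r <- cov_fun(pmin(j, m - j) * dt)
    lam <- Re(fft(r))
    tol <- 1e-10 * max(lam)
    if (min(lam) >= -tol) {
      lam <- pmax(lam, 0)
      # complex normals with E|eps|^2 = 2: the real part of the
      # transformed vector then carries the full target covariance
      eps <- complex(real = rnorm(m), imaginary = rnorm(m))
      y <- fft(sqrt(lam) * eps) / sqrt(m)
      return(Re(y)[seq_len(n)])
    }
    m <- 2 * m
  }
  abort(paste0(
    "circulant embedding failed: the target covariance could not be ",
    "embedded in a non-negative circulant even after padding to length ",
    m, ". The requested grid is pathological for this covariance."
  ))
}

#' Simulate long-axis-length series with the exact target autocovariance
#'
#' Stationary Gaussian-process generator: draws series whose population
#' autocovariance is exactly the fluctuation-dissipation model curve
#' (kBT/k) e^(-gamma*tau) cos(omega*tau), by circulant embedding of the
#' covariance on the frame grid. This is the reference generator for
#' estimator-recovery work, since the analysis model is recoverable with
#' no discretization or model-mismatch bias. Mean level `mean_length_um`
#' is added to the zero-mean fluctuation.
#'
#' A warning is raised if the parameter set puts non-negligible
#' probability (> 1e-6) on negative lengths; excursions are never clipped,
#' so that the Gaussian statistics stay exact.
#'
#' @param params An [oscillator_params()] object (ground truth).
#' @param sampling A [sampling_spec()] object.
#' @return A tibble with columns `molecule_id`, `time_s`, `R_um`.
#' @examples
#' p <- oscillator_params(k = 12e-9, gamma = 3, omega = 6)
#' s <- simulate_gp(p, sampling_spec(n_frames = 300, n_molecules = 2, seed = 7))
#' @export
simulate_gp <- function(params, sampling) {
  stopifnot(inherits(params, "oscillator_params"), inherits(sampling, "sampling_spec"))
  C0 <- thermal_energy(params$temperature) / params$k * 1e12
  .warn_if_negative_lengths(params, C0)
  dt <- sampling$frame_interval_s
  n <- sampling$n_frames
  cov_fun <- function(tau) C0 * exp(-params$gamma * tau) * cos(params$omega * tau)
  times <- (seq_len(n) - 1L) * dt
  out <- purrr::map(seq_len(sampling$n_molecules), function(i) {
    set.seed(sampling$seed + i)
    x <- .circulant_sample(n, dt, cov_fun)
    tibble(
      molecule_id = sprintf("mol%02d", i),
      time_s = times,
      R_um = params$mean_length_um + x
    )
  })
  bind_rows(out)
}

.warn_if_negative_lengths <- function(params, C0_um2) {
  # P(R < 0) for N(mean, C0); tolerate up to 1e-6
  p_neg <- stats::pnorm(0, mean = params$mean_length_um, sd = sqrt(C0_um2))
  if (p_neg > 1e-6) {
    warn(sprintf(
      "P(R < 0) = %.2g exceeds 1e-6 for mean %.3g um, sd %.3g um; lengths are not clipped.",
      p_neg, params$mean_length_um, sqrt(C0_um2)
    ))
  }
  invisible(p_neg)
}

# Exact one-step propagator of the underdamped Langevin system
#   x' = v,  v' = -(k/m) x - 2 gamma v + sqrt(4 gamma kBT / m) eta(t)
# over a time step h: returns list(Phi = 2x2 transition matrix,
# L = Cholesky factor of the step-noise covariance). Positions in um,
# velocities in um/s.
.sde_propagator <- function(params, h) {
  g <- params$gamma
  om1 <- params$omega          # oscillation frequency sqrt(k/m - gamma^2)
  om0sq <- params$k / params$mass
  e <- exp(-g * h)
  if (om1 > 0) {
    cth <- cos(om1 * h); sth <- sin(om1 * h)
    Phi <- e * matrix(c(
      cth + g / om1 * sth,        sth / om1,
      -om0sq / om1 * sth,         cth - g / om1 * sth
    ), nrow = 2, byrow = TRUE)
  } else {
    # critically damped limit om1 -> 0
    Phi <- e * matrix(c(
      1 + g * h,  h,
      -om0sq * h, 1 - g * h
    ), nrow = 2, byrow = TRUE)
  }
  kT <- thermal_energy(params$temperature)
  S <- diag(c(kT / params$k * 1e12, kT / params$mass * 1e12))  # um^2, (um/s)^2
  Q <- S - Phi %*% S %*% t(Phi)
  Q <- (Q + t(Q)) / 2
  ev <- eigen(Q, symmetric = TRUE)
  vals <- pmax(ev$values, 0)
  L <- ev$vectors %*% diag(sqrt(vals), 2)
  list(Phi = Phi, L = L, S = S)
}

#' Simulate long-axis-length series by integrating the Langevin equation
#'
#' Physical second-order (underdamped) Langevin realization:
#' `x'' = -(k/m) x - 2 gamma x' + sqrt(4 gamma kBT / m) eta(t)` around the
#' mean length, integrated with the exact Gaussian transition density of
#' this linear system (closed-form propagator plus matched step noise), so
#' there is no time-step discretization bias; `dt_internal` only sets the
#' internal sampling used before subsampling to the frame grid. The state
#' is initialized from the stationary distribution.
#'
#' The position autocovariance of this process is
#' (kBT/k) e^(-gamma*tau) (cos(omega*tau) + (gamma/omega) sin(omega*tau)):
#' it carries a sine correction that the pure damped-cosine analysis model
#' omits, so fits to these series exhibit the (small, documented)
#' model-mismatch bias a real underdamped object would produce.
#'
#' @param params An [oscillator_params()] object; must be underdamped
#'   (`k/mass > gamma^2`), otherwise an error directs you to
#'   [simulate_gp()].
#' @param sampling A [sampling_spec()] object.
#' @param dt_internal Internal integration step in seconds (default: a
#'   tenth of the frame interval). Must divide the frame interval within
#'   rounding.
#' @return A tibble with columns `molecule_id`, `time_s`, `R_um`.
#' @export
simulate_sde <- function(params, sampling, dt_internal = sampling$frame_interval_s / 10) {
  stopifnot(inherits(params, "oscillator_params"), inherits(sampling, "sampling_spec"))
  if (params$k / params$mass <= params$gamma^2) {
    abort("overdamped parameter set in SDE mode; use `simulate_gp()` instead.")
  }
  if (dt_internal <= 0 || dt_internal > sampling$frame_interval_s) {
    abort("`dt_internal` must be in (0, frame_interval_s].")
  }
  sub <- round(sampling$frame_interval_s / dt_internal)
  if (abs(sub * dt_internal - sampling$frame_interval_s) > 1e-9 * sampling$frame_interval_s) {
    abort("`dt_internal` must divide the frame interval.")
  }
  prop <- .sde_propagator(params, dt_internal)
  n <- sampling$n_frames
  times <- (seq_len(n) - 1L) * sampling$frame_interval_s
  sdx <- sqrt(prop$S[1, 1]); sdv <- sqrt(prop$S[2, 2])
  out <- purrr::map(seq_len(sampling$n_molecules), function(i) {
    set.seed(sampling$seed + i)
    z <- c(rnorm(1, 0, sdx), rnorm(1, 0, sdv))
    x <- numeric(n)
    x[1] <- z[1]
    n_steps <- (n - 1L) * sub
    noise <- matrix(rnorm(2 * n_steps), nrow = 2)
    idx <- 0L
    for (f in 2:n) {
      for (s in seq_len(sub)) {
        idx <- idx + 1L
        z <- prop$Phi %*% z + prop$L %*% noise[, idx]
      }
      x[f] <- z[1]
    }
    tibble(
      molecule_id = sprintf("mol%02d", i),
      time_s = times,
      R_um = params$mean_length_um + x
    )
  })
  C0 <- thermal_energy(params$temperature) / params$k * 1e12
  .warn_if_negative_lengths(params, C0)
  bind_rows(out)
}

#' Deterministic relaxation of the noiseless oscillator
#'
#' Zero-temperature limit of the Langevin system: the closed-form decay
#' from an initial displacement `x0` at zero initial velocity,
#' `x(t) = x0 e^(-gamma t) (cos(omega1 t) + (gamma/omega1) sin(omega1 t))`.
#' Useful as an exactness check on the integrator's propagator.
#'
#' @param params An [oscillator_params()] object.
#' @param x0_um Initial displacement from the mean, in um.
#' @param times_s Times at which to evaluate, in seconds.
#' @return A tibble with `time_s` and displacement `x_um`.
#' @export
relaxation_curve <- function(params, x0_um, times_s) {
  stopifnot(inherits(params, "oscillator_params"))
  g <- params$gamma; om1 <- params$omega
  x <- if (om1 > 0) {
    x0_um * exp(-g * times_s) * (cos(om1 * times_s) + g / om1 * sin(om1 * times_s))
  } else {
    x0_um * exp(-g * times_s) * (1 + g * times_s)
  }
  tibble(time_s = times_s, x_um = x)
}

#' Propagate the noiseless oscillator numerically
#'
#' Applies the integrator's exact propagator with the noise switched off
#' (zero temperature), from displacement `x0_um` at rest. Matches
#' [relaxation_curve()] to machine precision for any `dt_internal`,
#' demonstrating that the stochastic integrator has no time-step bias.
#'
#' @inheritParams relaxation_curve
#' @param n_steps Number of steps of size `dt_internal`.
#' @param dt_internal Step size in seconds.
#' @return A tibble with `time_s` and `x_um`.
#' @export
propagate_deterministic <- function(params, x0_um, n_steps, dt_internal) {
  stopifnot(inherits(params, "oscillator_params"))
  prop <- .sde_propagator(params, dt_internal)
  z <- c(x0_um, 0)
  x <- numeric(n_steps + 1L)
  x[1] <- x0_um
  for (s in seq_len(n_steps)) {
    z <- prop$Phi %*% z
    x[s + 1L] <- z[1]
  }
  tibble(time_s = (0:n_steps) * dt_internal, x_um = x)
}

#' Write / read a long-axis-length series as CSV with a JSON sidecar
#'
#' The CSV has columns `molecule_id`, `time_s`, `R_um` (and `flag` when
#' present); the sidecar `<path>.json` records ground-truth parameters and
#' the seed when supplied, so simulated datasets stay self-describing.
#'
#' @param series A series tibble (from the simulators or the extractor).
#' @param path CSV output path.
#' @param params Optional [oscillator_params()] ground truth to record.
#' @param sampling Optional [sampling_spec()] to record.
#' @return `path`, invisibly.
#' @export
write_series <- function(series, path, params = NULL, sampling = NULL) {
  stopifnot(is.data.frame(series), all(c("molecule_id", "time_s", "R_um") %in% names(series)))
  write.csv(series, path, row.names = FALSE)
  meta <- list(format = "dnafluct-series-v1")
  if (!is.null(params)) meta$ground_truth <- unclass(params)
  if (!is.null(sampling)) meta$sampling <- unclass(sampling)
  jsonlite::write_json(meta, paste0(path, ".json"), auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname write_series
#' @return For `read_series()`: the series tibble; any sidecar metadata is
#'   attached as attribute `"meta"`.
#' @export
read_series <- function(path) {
  df <- as_tibble(read.csv(path, stringsAsFactors = FALSE))
  if (!all(c("molecule_id", "time_s", "R_um") %in% names(df))) {
    abort("series CSV must have columns molecule_id, time_s, R_um.")
  }
  sidecar <- paste0(path, ".json")
  if (file.exists(sidecar)) {
    attr(df, "meta") <- jsonlite::read_json(sidecar, simplifyVector = TRUE)
  }
  df
}
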