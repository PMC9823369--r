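#' Fit the damped-cosine fluctuation-dissipation model to an autocovariance
#'
#' Least-squares fit of `A * exp(-gamma * tau) * cos(omega * tau)` to the
#' estimated autocovariance over `0 <= tau <= fit_window_s`. The spring
#' constant is reported from the zero-lag value via `k = kBT / C(0)` (the
#' primary estimator; the amplitude-based `kBT / A` is stored as a
#' diagnostic, and a warning is raised when the two disagree by more than
#' 20%, the signature of measurement noise inflating `C(0)`). The damping
#' constant `gamma` and angular frequency `omega` come from the fit.
#'
#' Initialization is a deterministic multi-start grid,
#' gamma in {0.5, 2, 8} 1/s x omega in {2, 6, 12} rad/s with `A = C(0)`;
#' the start with the lowest residual sum of squares wins, ties broken by
#' the smallest fitted gamma. There is no randomness in the fit.
#'
#' @param acf_curve An autocovariance tibble from [autocovariance()] (or
#'   any data frame with `lag_s`, `C_um2`).
#' @param temperature Absolute temperature in kelvin used for the
#'   fluctuation-dissipation conversion (default 298).
#' @param fit_window_s Upper lag bound of the fit in seconds (default
#'   1.5, about 45 lags at 30 frames/s — covers at least one oscillation
#'   period for omega >= 4 rad/s). Must span at least 5 frame intervals.
#' @return An object of class `viscoelastic_fit`: a list with elements
#'   `k` (N/m, from C(0)), `gamma` (1/s), `omega` (rad/s), `A_um2`,
#'   `C0_um2`, `k_amp` (N/m, from A), `residual_rms_um2`, `converged`,
#'   `fit_window_s`, `temperature`, and the fitted curve. Supports
#'   [tidy()], [glance()] and [autoplot()].
#' @examples
#' p <- oscillator_params(k = 12e-9, gamma = 3, omega = 6)
#' s <- simulate_gp(p, sampling_spec(n_frames = 3000, n_molecules = 1, seed = 2))
#' fit <- fit_damped_cosine(autocovariance(s))
#' glance(fit)
#' @export
fit_damped_cosine <- function(acf_curve, temperature = 298, fit_window_s = 1.5) {
  stopifnot(is.data.frame(acf_curve))
  if (!all(c("lag_s", "C_um2") %in% names(acf_curve))) {
    abort("`acf_curve` needs columns `lag_s` and `C_um2`.")
  }
  lag <- acf_curve$lag_s
  dt <- median(diff(sort(unique(lag))))
  if (fit_window_s < 5 * dt) abort("`fit_window_s` must span at least 5 frame intervals.")
  if (max(lag) + 1e-9 < fit_window_s) {
    abort("autocovariance curve does not cover the requested fit window.")
  }
  C0 <- acf_curve$C_um2[which.min(lag)]
  if (min(lag) > 1e-12 || C0 <= 0) {
    abort("`acf_curve` must include lag 0 with C(0) > 0.")
  }
  keep <- lag <= fit_window_s + 1e-9
  tau <- lag[keep]
  y <- acf_curve$C_um2[keep]

  starts <- expand.grid(g = c(0.5, 2, 8), w = c(2, 6, 12))
  best <- NULL
  for (s in seq_len(nrow(starts))) {
    fit <- tryCatch(
      minpack.lm::nlsLM(
        y ~ A * exp(-g * tau) * cos(w * tau),
        start = list(A = C0, g = starts$g[s], w = starts$w[s]),
        lower = c(A = 0, g = 0, w = 0),
        control = minpack.lm::nls.lm.control(maxiter = 200, ftol = 1e-14, ptol = 1e-14)
      ),
      error = function(e) NULL
    )
    if (is.null(fit)) next
    rss <- sum(stats::residuals(fit)^2)
    g_hat <- coef(fit)[["g"]]
    if (is.null(best) || rss < best$rss * (1 - 1e-12) ||
        (abs(rss - best$rss) <= best$rss * 1e-12 && g_hat < best$g)) {
      best <- list(fit = fit, rss = rss, g = g_hat)
    }
  }

  kT <- thermal_energy(temperature)
  k_C0 <- kT / (C0 * 1e-12)
  if (is.null(best)) {
    res <- structure(
      list(
        k = k_C0, gamma = NA_real_, omega = NA_real_, A_um2 = NA_real_,
        C0_um2 = C0, k_amp = NA_real_, residual_rms_um2 = NA_real_,
        converged = FALSE, fit_window_s = fit_window_s,
        temperature = temperature,
        curve = tibble(lag_s = tau, C_um2 = y, fitted_um2 = NA_real_)
      ),
      class = "viscoelastic_fit"
    )
    return(res)
  }
  cf <- coef(best$fit)
  A <- cf[["A"]]; g <- cf[["g"]]; w <- cf[["w"]]
  k_amp <- if (A > 0) kT / (A * 1e-12) else NA_real_
  if (is.finite(k_amp) && abs(k_amp - k_C0) / k_C0 > 0.2) {
    warn(sprintf(
      paste0("amplitude-based k (%.3g N/m) and C(0)-based k (%.3g N/m) ",
             "differ by more than 20%%; C(0) may be inflated by ",
             "measurement noise."),
      k_amp, k_C0
    ))
  }
  fitted <- A * exp(-g * tau) * cos(w * tau)
  structure(
    list(
      k = k_C0, gamma = g, omega = w, A_um2 = A, C0_um2 = C0, k_amp = k_amp,
      residual_rms_um2 = sqrt(best$rss / length(tau)),
      converged = TRUE, fit_window_s = fit_window_s, temperature = temperature,
      curve = tibble(lag_s = tau, C_um2 = y, fitted_um2 = fitted)
    ),
    class = "viscoelastic_fit"
  )
}

#' @export
print.viscoelastic_fit <- function(x, ...) {
  cat("<viscoelastic_fit>\n")
  cat(sprintf("  k     = %.4g N/m   (kBT / C(0), C(0) = %.4g um^2)\n", x$k, x$C0_um2))
  cat(sprintf("  gamma = %.4g 1/s\n", x$gamma))
  cat(sprintf("  omega = %.4g rad/s\n", x$omega))
  cat(sprintf("  fit window %.3g s, residual rms %.3g um^2, converged: %s\n",
              x$fit_window_s, x$residual_rms_um2, x$converged))
  invisible(x)
}

#' @rdname fit_damped_cosine
#' @param x A `viscoelastic_fit` object.
#' @param ... Unused.
#' @export
tidy.viscoelastic_fit <- function(x, ...) {
  tibble(
    term = c("k", "gamma", "omega", "A"),
    estimate = c(x$k, x$gamma, x$omega, x$A_um2),
    unit = c("N/m", "1/s", "rad/s", "um^2")
  )
}

#' @rdname fit_damped_cosine
#' @export
glance.viscoelastic_fit <- function(x, ...) {
  tibble(
    k_N_per_m = x$k, gamma_per_s = x$gamma, omega_rad_per_s = x$omega,
    C0_um2 = x$C0_um2, A_um2 = x$A_um2, k_amp_N_per_m = x$k_amp,
    residual_rms_um2 = x$residual_rms_um2, fit_window_s = x$fit_window_s,
    converged = x$converged
  )
}

#' @rdname fit_damped_cosine
#' @param object A `viscoelastic_fit` object.
#' @export
autoplot.viscoelastic_fit <- function(object, ...) {
  ggplot(object$curve, aes(x = .data$lag_s)) +
    geom_point(aes(y = .data$C_um2), size = 0.8, colour = "grey30") +
    geom_line(aes(y = .data$fitted_um2), colour = "#d1495b", linewidth = 0.7) +
    labs(
      x = expression(tau ~ "(s)"), y = expression(C(tau) ~ (mu * m^2)),
      title = sprintf("k = %.3g N/m, gamma = %.3g 1/s, omega = %.3g rad/s",
                      object$k, object$gamma, object$omega)
    ) +
    theme_minimal()
}

#' Fit every molecule in a series table
#'
#' Convenience wrapper: estimates the autocovariance and fits the damped
#' cosine per molecule, returning one row per molecule. Frames flagged by
#' the extractor (if a `flag` column is present) cause an error in the
#' underlying estimator; filter beforehand.
#'
#' @param series A tibble with `molecule_id`, `time_s`, `R_um`.
#' @param temperature Kelvin (default 298).
#' @param max_lag_s Autocovariance lag range in seconds (default 2).
#' @param fit_window_s Fit window in seconds (default 1.5).
#' @param estimator Autocovariance estimator (see [autocovariance()]).
#' @param gaps Missing-frame handling passed to [autocovariance()]
#'   (`"error"` or `"pairwise"`).
#' @return A tibble with one row per molecule: `molecule_id`,
#'   `k_N_per_m`, `gamma_per_s`, `omega_rad_per_s`, `C0_um2`, `A_um2`,
#'   `k_amp_N_per_m`, `residual_rms_um2`, `converged`.
#' @export
fit_molecules <- function(series, temperature = 298, max_lag_s = 2,
                          fit_window_s = 1.5, estimator = "biased",
                          gaps = "error") {
  stopifnot(is.data.frame(series), "molecule_id" %in% names(series))
  series %>%
    group_by(.data$molecule_id) %>%
    dplyr::group_modify(function(df, key) {
      fit <- fit_damped_cosine(
        autocovariance(df, max_lag_s = max_lag_s, estimator = estimator,
                       gaps = gaps),
        temperature = temperature, fit_window_s = fit_window_s
      )
      glance(fit)
    }) %>%
    ungroup()
}

#' Linearity diagnostic between spring constant and squared frequency
#'
#' For a fixed effective mass the damped oscillator obeys
#' `omega^2 = k/m - gamma^2`, so fitted `omega^2` should regress almost
#' linearly on fitted `k` across conditions; the slope estimates `1/m`.
#' Agreement between the `C(0)`-based stiffness and the frequency-based
#' one is evidence the two parts of the fitted curve tell one consistent
#' mechanical story.
#'
#' @param fits A data frame of per-molecule fits with columns
#'   `k_N_per_m` and `omega_rad_per_s` (e.g. from [fit_molecules()]);
#'   at least 3 rows with distinct `k`.
#' @return A one-row tibble: `slope` (1/kg), `intercept` (rad^2/s^2),
#'   `r_squared`, `n`.
#' @export
k_omega_diagnostic <- function(fits) {
  stopifnot(is.data.frame(fits))
  if (!all(c("k_N_per_m", "omega_rad_per_s") %in% names(fits))) {
    abort("`fits` needs columns `k_N_per_m` and `omega_rad_per_s`.")
  }
  ok <- is.finite(fits$k_N_per_m) & is.finite(fits$omega_rad_per_s)
  k <- fits$k_N_per_m[ok]
  w2 <- fits$omega_rad_per_s[ok]^2
  if (length(k) < 3) abort("need at least 3 fits for the k-omega^2 regression.")
  if (sd(k) == 0) abort("degenerate regression: all spring constants identical.")
  m <- lm(w2 ~ k)
  tibble(
    slope = unname(coef(m)[2]),
    intercept = unname(coef(m)[1]),
    r_squared = summary(m)$r.squared,
    n = length(k)
  )
}

#' Per-condition summary of fitted viscoelastic parameters
#'
#' Mean and standard error of the mean (sample sd / sqrt(n)) of the
#' spring and damping constants over molecules of one condition.
#' Non-converged fits are excluded and counted; the SEM is reported as
#' `NA` for a single molecule.
#'
#' @param fits A data frame of per-molecule fits (see [fit_molecules()]).
#' @param label Condition label (e.g. `"control"`, `"ethanol 2%"`).
#' @return A one-row tibble: `condition`, `n_molecules`, `n_excluded`,
#'   `mean_k_N_per_m`, `sem_k_N_per_m`, `mean_gamma_per_s`,
#'   `sem_gamma_per_s`, `mean_omega_rad_per_s`, `sem_omega_rad_per_s`.
#' @export
summarize_condition <- function(fits, label) {
  stopifnot(is.data.frame(fits))
  conv <- fits[which(fits$converged), , drop = FALSE]
  n_excl <- nrow(fits) - nrow(conv)
  if (nrow(conv) == 0) abort("no converged fits in this condition.")
  sem <- function(v) if (length(v) > 1) sd(v) / sqrt(length(v)) else NA_real_
  tibble(
    condition = label,
    n_molecules = nrow(conv),
    n_excluded = n_excl,
    mean_k_N_per_m = mean(conv$k_N_per_m),
    sem_k_N_per_m = sem(conv$k_N_per_m),
    mean_gamma_per_s = mean(conv$gamma_per_s),
    sem_gamma_per_s = sem(conv$gamma_per_s),
    mean_omega_rad_per_s = mean(conv$omega_rad_per_s),
    sem_omega_rad_per_s = sem(conv$omega_rad_per_s)
  )
}
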