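#' Demonstration condition set
#'
#' Four synthetic parameter sets exercising the full pipeline the way a
#' small alcohol-series study would: a control at the aqueous-buffer
#' stiffness scale (k = 12 nN/m) and three alcohol-like conditions in
#' which spring and damping constants roughly double at "2%" and rise
#' further for the "4% 1-propanol"-like set. These are fixtures with
#' known ground truth for recovery checks, not claims about alcohol
#' chemistry.
#'
#' @param temperature Kelvin (default 298).
#' @return A named list of [oscillator_params()].
#' @export
demo_conditions <- function(temperature = 298) {
  list(
    control = oscillator_params(k = 12e-9, gamma = 3, omega = 6,
                                temperature = temperature),
    ethanol_2pct = oscillator_params(k = 24e-9, gamma = 6, omega = 8,
                                     temperature = temperature),
    ethanol_4pct = oscillator_params(k = 28e-9, gamma = 7, omega = 9,
                                     temperature = temperature),
    propan1ol_4pct = oscillator_params(k = 48e-9, gamma = 10, omega = 12,
                                       temperature = temperature)
  )
}

#' Run the fluctuation-analysis pipeline end to end
#'
#' Orchestrates simulate -> (render -> extract | passthrough) -> analyze
#' -> summarize over a set of conditions, with per-stage artifacts
#' persisted when `out_dir` is given and full determinism from the root
#' seed (per-condition, per-molecule RNG streams are derived from it).
#'
#' Passthrough: give `series` (a table with `molecule_id`, `time_s`,
#' `R_um`, and optionally `condition`) to skip the synthetic stages and
#' analyze measured data; the analysis stage is then byte-identical to
#' calling [fit_molecules()] + [summarize_condition()] yourself.
#'
#' With `render = TRUE` every simulated molecule is rendered to a
#' synthetic image stack and re-measured by [extract_series()], so the
#' estimates carry realistic segmentation noise; this multiplies runtime
#' roughly twentyfold.
#'
#' @param conditions Named list of [oscillator_params()] (default
#'   [demo_conditions()]). Ignored in passthrough mode.
#' @param sampling A [sampling_spec()]; its `seed` is the root seed.
#' @param series Optional measured series table (passthrough mode).
#' @param mode `"gp"` (default; exact-covariance generator) or `"sde"`
#'   (physical Langevin integrator).
#' @param render Render + extract stage toggle (default `FALSE`).
#' @param imaging An [imaging_config()] (used when `render = TRUE`).
#' @param extraction An [extraction_config()] (used when `render = TRUE`).
#' @param temperature Kelvin for the fluctuation-dissipation conversion
#'   (default 298).
#' @param max_lag_s,fit_window_s Analysis settings (see
#'   [fit_molecules()]).
#' @param out_dir Optional output directory; created if missing. Per
#'   condition, `series_<label>.csv` (+ sidecar) and `fits_<label>.csv`
#'   are written, plus `summary.csv`, `report.json` and `manifest.json`.
#' @return An object of class `study_report`: list with `summary`
#'   (per-condition tibble), `fits`, `recovery` (truth vs estimate, when
#'   ground truth is known), `theory_reference`, `manifest`.
#' @examples
#' \donttest{
#' rep <- run_pipeline(
#'   conditions = demo_conditions()[1],
#'   sampling = sampling_spec(n_frames = 1500, n_molecules = 3, seed = 11)
#' )
#' rep$summary
#' }
#' @export
run_pipeline <- function(conditions = demo_conditions(),
                         sampling = sampling_spec(),
                         series = NULL,
                         mode = c("gp", "sde"),
                         render = FALSE,
                         imaging = imaging_config(),
                         extraction = extraction_config(),
                         temperature = 298,
                         max_lag_s = 2, fit_window_s = 1.5,
                         out_dir = NULL) {
  mode <- match.arg(mode)
  if (!is.null(out_dir) && !dir.exists(out_dir)) {
    dir.create(out_dir, recursive = TRUE)
  }
  passthrough <- !is.null(series)

  if (passthrough) {
    stopifnot(is.data.frame(series))
    if (!"condition" %in% names(series)) series$condition <- "user"
    cond_series <- split(series, series$condition)
    truths <- NULL
  } else {
    stopifnot(is.list(conditions), length(conditions) >= 1,
              !is.null(names(conditions)))
    cond_series <- list()
    truths <- conditions
    for (i in seq_along(conditions)) {
      label <- names(conditions)[i]
      samp_i <- sampling
      samp_i$seed <- sampling$seed + 1000L * i
      sim <- if (mode == "gp") simulate_gp(conditions[[i]], samp_i)
             else simulate_sde(conditions[[i]], samp_i)
      if (render) {
        sim <- sim %>%
          group_by(.data$molecule_id) %>%
          dplyr::group_modify(function(df, key) {
            cfg <- imaging
            cfg$seed <- samp_i$seed + match(key$molecule_id[1],
                                            sort(unique(sim$molecule_id)))
            st <- render_stack(df, cfg)
            ex <- extract_series(st, extraction, molecule_id = key$molecule_id[1])
            ex %>% filter(.data$flag == "ok") %>%
              dplyr::select("time_s", "R_um")
          }) %>%
          ungroup()
      }
      sim$condition <- label
      cond_series[[label]] <- sim
      if (!is.null(out_dir)) {
        write_series(
          sim[, c("molecule_id", "time_s", "R_um")],
          file.path(out_dir, paste0("series_", label, ".csv")),
          params = conditions[[i]], sampling = samp_i
        )
      }
    }
  }

  fits <- purrr::imap(cond_series, function(s, label) {
    f <- fit_molecules(s, temperature = temperature,
                       max_lag_s = max_lag_s, fit_window_s = fit_window_s,
                       gaps = if (render && !passthrough) "pairwise" else "error")
    f$condition <- label
    if (!is.null(out_dir)) {
      write.csv(f, file.path(out_dir, paste0("fits_", label, ".csv")),
                row.names = FALSE)
    }
    f
  })
  summary <- purrr::imap(fits, function(f, label) summarize_condition(f, label)) %>%
    bind_rows()

  recovery <- NULL
  if (!is.null(truths)) {
    recovery <- purrr::imap(truths, function(p, label) {
      est <- summary[summary$condition == label, ]
      tibble(
        condition = label,
        k_true_N_per_m = p$k, k_hat_N_per_m = est$mean_k_N_per_m,
        k_rel_err = abs(est$mean_k_N_per_m - p$k) / p$k,
        gamma_true_per_s = p$gamma, gamma_hat_per_s = est$mean_gamma_per_s,
        gamma_rel_err = if (p$gamma > 0) abs(est$mean_gamma_per_s - p$gamma) / p$gamma else NA_real_,
        omega_true_rad_per_s = p$omega, omega_hat_rad_per_s = est$mean_omega_rad_per_s,
        omega_rel_err = if (p$omega > 0) abs(est$mean_omega_rad_per_s - p$omega) / p$omega else NA_real_
      )
    }) %>% bind_rows()
  }

  theory_reference <- tibble(
    kBT_pN_nm = thermal_energy(temperature, "pN.nm"),
    k_wlc_N_per_m = spring_constant_wlc(50, 57, temperature),
    manning_neutralized = manning_fractions()$neutralized_fraction,
    manning_dissociated = manning_fractions()$dissociated_fraction
  )

  manifest <- list(
    package_version = as.character(utils::packageVersion("dnafluct")),
    mode = if (passthrough) "passthrough" else mode,
    render = render && !passthrough,
    temperature = temperature,
    max_lag_s = max_lag_s, fit_window_s = fit_window_s,
    sampling = if (!passthrough) unclass(sampling) else NULL,
    conditions = if (!passthrough) lapply(conditions, unclass) else NULL
  )

  report <- structure(
    list(
      summary = summary,
      fits = bind_rows(fits),
      recovery = recovery,
      theory_reference = theory_reference,
      manifest = manifest
    ),
    class = "study_report"
  )

  if (!is.null(out_dir)) {
    write.csv(summary, file.path(out_dir, "summary.csv"), row.names = FALSE)
    jsonlite::write_json(
      list(
        summary = summary, recovery = recovery,
        theory_reference = theory_reference, manifest = manifest
      ),
      file.path(out_dir, "report.json"),
      auto_unbox = TRUE, digits = NA, null = "null"
    )
    files <- list.files(out_dir, full.names = TRUE)
    files <- files[basename(files) != "manifest.json"]
    manifest$file_md5 <- as.list(setNames(
      unname(tools::md5sum(sort(files))), basename(sort(files))
    ))
    jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                         auto_unbox = TRUE, digits = NA, null = "null")
    report$manifest <- manifest
  }
  report
}

#' @export
print.study_report <- function(x, ...) {
  cat("<study_report>\n")
  print(x$summary)
  if (!is.null(x$recovery)) {
    cat("\nRecovery (truth vs estimate):\n")
    print(x$recovery[, c("condition", "k_rel_err", "gamma_rel_err", "omega_rel_err")])
  }
  invisible(x)
}

#' Compare measured stiffness to the semiflexible-chain estimate
#'
#' Tabulates the ratio of each condition's mean fitted spring constant to
#' the closed-form semiflexible-polymer value kBT/(l_p L_c). For T4 GT7
#' DNA the measured control stiffness (~12 nN/m) is several times the
#' bending-only estimate (~1.4 nN/m), as twist and segment interactions
#' also stiffen the coil.
#'
#' @param report A `study_report`, or a summary tibble with `condition`
#'   and `mean_k_N_per_m`.
#' @param persistence_length_nm Persistence length in nm (default 50).
#' @param contour_length_um Contour length in um (default 57).
#' @param temperature Kelvin (default 298).
#' @return A tibble: `condition`, `k_hat_N_per_m`, `k_theory_N_per_m`,
#'   `ratio`.
#' @export
compare_to_theory <- function(report, persistence_length_nm = 50,
                              contour_length_um = 57, temperature = 298) {
  summary <- if (inherits(report, "study_report")) report$summary else report
  stopifnot(is.data.frame(summary),
            all(c("condition", "mean_k_N_per_m") %in% names(summary)))
  if (nrow(summary) < 1) abort("need at least one condition.")
  k_th <- spring_constant_wlc(persistence_length_nm, contour_length_um, temperature)
  tibble(
    condition = summary$condition,
    k_hat_N_per_m = summary$mean_k_N_per_m,
    k_theory_N_per_m = k_th,
    ratio = summary$mean_k_N_per_m / k_th
  )
}
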