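#' Plot a long-axis-length time trace
#'
#' One line per molecule, the raw input of the fluctuation analysis.
#'
#' @param series A series tibble (`molecule_id`, `time_s`, `R_um`).
#' @return A ggplot object.
#' @export
plot_series <- function(series) {
  stopifnot(is.data.frame(series))
  ggplot(series, aes(x = .data$time_s, y = .data$R_um,
                     colour = .data$molecule_id)) +
    geom_line(linewidth = 0.3, show.legend = length(unique(series$molecule_id)) <= 6) +
    labs(x = "time (s)", y = expression(R ~ (mu * m)), colour = NULL) +
    theme_minimal()
}

#' Plot per-condition viscoelastic summaries
#'
#' Bar charts of mean spring constant and damping constant with SEM
#' error bars, one panel per parameter.
#'
#' @param summary A summary tibble from [summarize_condition()] or a
#'   `study_report$summary`.
#' @return A ggplot object.
#' @export
plot_condition_summary <- function(summary) {
  stopifnot(is.data.frame(summary))
  long <- bind_rows(
    tibble(
      condition = summary$condition, parameter = "spring constant k (nN/m)",
      mean = summary$mean_k_N_per_m * 1e9, sem = summary$sem_k_N_per_m * 1e9
    ),
    tibble(
      condition = summary$condition, parameter = "damping constant gamma (1/s)",
      mean = summary$mean_gamma_per_s, sem = summary$sem_gamma_per_s
    )
  )
  long$condition <- factor(long$condition, levels = unique(summary$condition))
  ggplot(long, aes(x = .data$condition, y = .data$mean)) +
    geom_col(fill = "grey65", width = 0.7) +
    geom_errorbar(aes(ymin = .data$mean - .data$sem, ymax = .data$mean + .data$sem),
                  width = 0.2) +
    facet_wrap(~ .data$parameter, scales = "free_y") +
    labs(x = NULL, y = "mean ± SEM") +
    theme_minimal() +
    theme(axis.text.x = element_text(angle = 30, hjust = 1))
}

#' @export
autoplot.study_report <- function(object, ...) {
  plot_condition_summary(object$summary)
}
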