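#' Plot study metrics over time
#'
#' Weekly group means (one line per group) with per-session points, faceted
#' by metric — the usual way longitudinal recording quality is displayed.
#'
#' @param study_table output of [build_study_table()].
#' @param metrics which metrics to show.
#' @return A ggplot object.
#' @export
plot_study_metrics <- function(study_table,
                               metrics = c("pct_channels_with_units",
                                           "units_per_channel", "noise_level",
                                           "max_amplitude", "snr")) {
  long <- study_table |>
    tidyr::pivot_longer(dplyr::all_of(metrics), names_to = "metric",
                        values_to = "value") |>
    mutate(metric = factor(.data$metric, levels = metrics))
  wk <- long |>
    group_by(.data$group, .data$metric, .data$week) |>
    summarise(value = mean(.data$value, na.rm = TRUE), .groups = "drop")
  ggplot2::ggplot(long, ggplot2::aes(x = .data$week, y = .data$value,
                                     colour = .data$group)) +
    ggplot2::geom_point(alpha = 0.25, size = 0.8, na.rm = TRUE) +
    ggplot2::geom_line(data = wk, linewidth = 0.9) +
    ggplot2::facet_wrap(~metric, scales = "free_y") +
    ggplot2::labs(x = "week post-implant", y = NULL, colour = "group") +
    ggplot2::theme_minimal()
}

#' Plot normalized strain profiles
#'
#' Normalized von Mises strain versus lateral distance from the probe
#' surface, one panel per depth (brain top, probe mid-point, probe tip),
#' one line per species.
#'
#' @param profiles the `profiles` tibble from [run_strain_comparison()].
#' @return A ggplot object.
#' @export
plot_strain_profiles <- function(profiles) {
  profiles <- profiles |>
    mutate(location = factor(.data$location,
                             c("brain_top", "probe_mid", "probe_tip")))
  ggplot2::ggplot(profiles,
                  ggplot2::aes(x = .data$distance, y = .data$strain,
                               colour = .data$species)) +
    ggplot2::geom_line(linewidth = 0.9) +
    ggplot2::facet_wrap(~location) +
    ggplot2::labs(x = "distance from probe surface (µm)",
                  y = "normalized von Mises strain", colour = NULL) +
    ggplot2::theme_minimal()
}

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot

#' @export
autoplot.nested_glm <- function(object, ...) {
  d <- tibble(group = names(object$group_means),
              mean = unname(object$group_means))
  ggplot2::ggplot(d, ggplot2::aes(x = .data$group, y = .data$mean)) +
    ggplot2::geom_col(width = 0.6) +
    ggplot2::labs(y = "group mean (of animal means)",
                  subtitle = sprintf("F(%d, %d) = %.2f, p = %.3g",
                                     object$df_num, object$df_den,
                                     object$f_statistic, object$p_value)) +
    ggplot2::theme_minimal()
}
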