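#' Nested general linear model for a two-group longitudinal metric
#'
#' Fits `value = mean + group + animal(group) + residual` by least squares on
#' the non-missing session-level observations of one metric within one time
#' range. Because sessions are repeated measures on the same animals, the
#' group effect is F-tested against the animal-within-group mean square
#' (not the residual), which is the correct error stratum for a
#' between-animal factor.
#'
#' @param data tibble with columns `group`, `animal`, `value` (one metric,
#'   already restricted to the time range of interest).
#' @param alpha significance level (default 0.05).
#' @return An object of class `nested_glm` with the F statistic, degrees of
#'   freedom, p-value, per-group means and effect estimate. Degenerate
#'   designs (zero animal-stratum variance) are flagged rather than
#'   rejected.
#' @export
fit_nested_glm <- function(data, alpha = 0.05) {
  d <- data[!is.na(data$value), , drop = FALSE]
  if (nrow(d) == 0) stop_degenerate("all observations are missing")
  d$group <- factor(d$group)
  d$animal <- factor(d$animal)
  if (nlevels(d$group) != 2)
    stop_degenerate("exactly two groups are required")
  per_group <- tapply(d$animal, d$group, function(a) length(unique(a)))
  if (any(per_group < 2))
    stop_degenerate("each group needs >= 2 animals with observations")
  # animal means define the between-animal stratum
  am <- d |>
    group_by(.data$group, .data$animal) |>
    summarise(value = mean(.data$value), .groups = "drop")
  grand <- mean(d$value)
  g_means <- c(tapply(am$value, am$group, mean))  # unweighted over animals
  # sequential sums of squares: group first, then animal within group
  n_i <- table(d$animal)
  mu_a <- tapply(d$value, d$animal, mean)
  mu_g_w <- tapply(d$value, d$group, mean)      # observation-weighted
  grp_of <- tapply(as.character(d$group), d$animal, `[`, 1)
  ss_group <- sum(table(d$group) * (mu_g_w - grand)^2)
  ss_animal <- sum(n_i * (mu_a - mu_g_w[grp_of])^2)
  ss_resid <- sum((d$value - mu_a[as.character(d$animal)])^2)
  df_group <- nlevels(d$group) - 1L
  df_animal <- length(unique(d$animal)) - nlevels(d$group)
  df_resid <- nrow(d) - length(unique(d$animal))
  ms_animal <- ss_animal / df_animal
  degenerate <- ms_animal <= .Machine$double.eps * max(1, abs(grand))^2
  if (degenerate) {
    f <- NA_real_; p <- NA_real_
  } else {
    f <- (ss_group / df_group) / ms_animal
    p <- pf(f, df_group, df_animal, lower.tail = FALSE)
  }
  structure(list(
    f_statistic = f, df_num = df_group, df_den = df_animal,
    p_value = p, alpha = alpha,
    significant = isTRUE(!is.na(p) && p < alpha),
    group_means = g_means,
    effect = unname(diff(g_means)),
    n_obs = nrow(d), n_animals = length(unique(d$animal)),
    ss = c(group = ss_group, animal = ss_animal, residual = ss_resid),
    df = c(group = df_group, animal = df_animal, residual = df_resid),
    degenerate = degenerate), class = "nested_glm")
}

#' @export
print.nested_glm <- function(x, ...) {
  cat(sprintf("<nested_glm> F(%d, %d) = %s, p = %s%s\n", x$df_num, x$df_den,
              format(x$f_statistic, digits = 4),
              format(x$p_value, digits = 4),
              if (x$significant) " *" else ""))
  cat("  group means:", paste(names(x$group_means),
                              format(x$group_means, digits = 4),
                              sep = " = ", collapse = ", "), "\n")
  invisible(x)
}

#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' Tidy a nested GLM fit
#'
#' @param x a `nested_glm` object.
#' @param ... unused.
#' @return One row per model term with sums of squares, df, and (for the
#'   group term) the F statistic and p-value.
#' @export
tidy.nested_glm <- function(x, ...) {
  tibble(term = c("group", "animal(group)", "residual"),
         sumsq = unname(x$ss), df = unname(x$df),
         meansq = unname(x$ss / x$df),
         statistic = c(x$f_statistic, NA, NA),
         p.value = c(x$p_value, NA, NA))
}

#' @rdname tidy.nested_glm
#' @return `glance()`: a one-row model summary.
#' @export
glance.nested_glm <- function(x, ...) {
  tibble(f_statistic = x$f_statistic, df_num = x$df_num, df_den = x$df_den,
         p_value = x$p_value, significant = x$significant,
         effect = x$effect, n_obs = x$n_obs, n_animals = x$n_animals,
         degenerate = x$degenerate)
}

#' Run the full 5 x 3 group-comparison suite
#'
#' One nested GLM per metric (the five recording-quality metrics) per time
#' range (total weeks 1-8, acute 1-2, chronic 3-8): 15 results. Each
#' comparison is tested at the per-comparison `alpha` with no
#' multiple-testing correction by default, matching common practice for
#' these study designs; `fdr = TRUE` applies Benjamini-Hochberg across the
#' 15 p-values.
#'
#' @param study_table output of [build_study_table()].
#' @param alpha per-comparison significance level.
#' @param fdr apply Benjamini-Hochberg across the suite.
#' @param per_animal_mean average sessions to one value per animal per range
#'   before fitting (off by default: session-level observations).
#' @return A tibble with one row per (metric, time range): F, dfs, p,
#'   significance, group means, and an `error` column for cells whose fit
#'   failed.
#' @export
run_comparison_suite <- function(study_table, alpha = 0.05, fdr = FALSE,
                                 per_animal_mean = FALSE) {
  metrics <- c("pct_channels_with_units", "units_per_channel", "noise_level",
               "max_amplitude", "snr")
  ranges <- c("total", "acute", "chronic")
  groups <- sort(unique(study_table$group))
  rows <- list()
  for (m in metrics) for (r in ranges) {
    d <- study_table |>
      filter(.data$week %in% time_bin_weeks(r)) |>
      transmute(.data$group, .data$animal, value = .data[[m]])
    if (per_animal_mean)
      d <- d |> group_by(.data$group, .data$animal) |>
        summarise(value = mean(.data$value, na.rm = TRUE), .groups = "drop")
    fit <- tryCatch(fit_nested_glm(d, alpha = alpha), error = function(e) e)
    if (inherits(fit, "error")) {
      rows[[length(rows) + 1L]] <- tibble(
        metric = m, time_range = r, f_statistic = NA_real_,
        df_num = NA_integer_, df_den = NA_integer_, p_value = NA_real_,
        significant = FALSE, mean_1 = NA_real_, mean_2 = NA_real_,
        effect = NA_real_, error = conditionMessage(fit))
    } else {
      rows[[length(rows) + 1L]] <- tibble(
        metric = m, time_range = r, f_statistic = fit$f_statistic,
        df_num = fit$df_num, df_den = fit$df_den, p_value = fit$p_value,
        significant = fit$significant,
        mean_1 = unname(fit$group_means[groups[1]]),
        mean_2 = unname(fit$group_means[groups[2]]),
        effect = fit$effect, error = NA_character_)
    }
  }
  out <- list_rbind(rows)
  names(out)[names(out) == "mean_1"] <- paste0("mean_", groups[1])
  names(out)[names(out) == "mean_2"] <- paste0("mean_", groups[2])
  if (fdr) {
    out$p_adjusted <- stats::p.adjust(out$p_value, method = "BH")
    out$significant <- !is.na(out$p_adjusted) & out$p_adjusted < alpha
  }
  out
}
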