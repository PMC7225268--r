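#' Classify working channels from noise levels
#'
#' A channel is "working" when its noise level (2 x robust SD) lies inside a
#' plausible band for an intact connection: dead or shorted channels sit near
#' zero, broken connections ring far above the rest. The default band of
#' 2-60 uV is a configurable operating choice; an externally measured
#' impedance table can veto channels as well.
#'
#' @param session a [recording_session()].
#' @param noise_floor,noise_ceiling accepted noise-level band, uV.
#' @param impedance_ok optional logical vector (per channel) from an external
#'   impedance check; `FALSE` forces non-working.
#' @param robust use the robust SD estimate.
#' @return Logical working mask; also respects flags already cleared by
#'   [remove_artifacts()].
#' @export
classify_working_channels <- function(session, noise_floor = 2,
                                      noise_ceiling = 60,
                                      impedance_ok = NULL, robust = TRUE) {
  if (noise_floor > noise_ceiling)
    stop_invalid("`noise_floor` must not exceed `noise_ceiling`")
  n_ch <- n_channels(session)
  lvl <- vapply(seq_len(n_ch), function(ch)
    2 * estimate_noise_sd(session$traces[ch, ], session$excluded_windows[[ch]],
                          robust = robust), 1.0)
  ok <- lvl >= noise_floor & lvl <= noise_ceiling & session$working_mask
  if (!is.null(impedance_ok)) ok <- ok & impedance_ok
  ok
}

#' The five recording-quality metrics for one session
#'
#' Given a per-channel table (from [process_session()] or
#' [study_channel_truth()]), computes:
#' \enumerate{
#'   \item `pct_channels_with_units` — percent of working channels with at
#'     least one isolated unit;
#'   \item `units_per_channel` — mean unit count over working channels;
#'   \item `noise_level` — mean over working channels of 2 x robust SD of the
#'     background (uV);
#'   \item `max_amplitude` — mean over unit-bearing channels of the
#'     per-channel mean unit peak-to-peak amplitude (uV);
#'   \item `snr` — each unit's peak-to-peak amplitude divided by its own
#'     channel's noise level, averaged across units.
#' }
#' Metrics 4 and 5 are `NA` when the session holds no units.
#'
#' @param channels tibble with columns `channel`, `working`, `n_units`,
#'   `noise_level`, `amp` (list-column of per-unit amplitudes).
#' @return A one-row tibble with the five metrics and `n_working`.
#' @export
compute_session_metrics <- function(channels) {
  wk <- channels[channels$working %in% TRUE, , drop = FALSE]
  if (nrow(wk) == 0) stop_degenerate("no working channels in session")
  pct <- 100 * mean(wk$n_units > 0)
  upc <- mean(wk$n_units)
  noise <- mean(wk$noise_level)
  bearing <- wk[wk$n_units > 0, , drop = FALSE]
  if (nrow(bearing) > 0) {
    max_amp <- mean(vapply(bearing$amp, mean, 1.0))
    snr <- mean(unlist(Map(function(a, nl) a / nl, bearing$amp,
                           bearing$noise_level)))
  } else {
    max_amp <- NA_real_
    snr <- NA_real_
  }
  tibble(pct_channels_with_units = pct, units_per_channel = upc,
         noise_level = noise, max_amplitude = max_amp, snr = snr,
         n_working = nrow(wk))
}

#' Most-active consecutive-channel window
#'
#' Returns the starting index (1-based) of the contiguous window of
#' `window` channels maximizing the sum of per-channel average unit counts,
#' with ties broken toward the smallest start — the rule used to restrict
#' metrics to the contacts spanning the large pyramidal layers (10
#' consecutive channels for rat arrays, 8 for mouse).
#'
#' @param avg_units numeric vector of per-channel average unit counts over
#'   the study.
#' @param window window length in channels.
#' @return 1-based start index of the selected window.
#' @export
select_active_window <- function(avg_units, window) {
  n <- length(avg_units)
  if (window > n) stop_invalid("`window` exceeds the number of channels")
  cs <- cumsum(c(0, avg_units))
  sums <- cs[(window + 1):(n + 1)] - cs[1:(n - window + 1)]
  # round away float summation noise so mathematically tied windows resolve
  # to the smallest starting index
  which.max(round(sums, 9))
}

#' Acute / chronic time-bin membership of a study week
#'
#' Weeks 1-2 are acute, weeks 3-8 chronic; every week belongs to the total
#' range — the three ranges used to mirror phases of the neuroinflammatory
#' response.
#'
#' @param week integer in 1..8.
#' @return Character vector of bin labels.
#' @export
assign_time_bins <- function(week) {
  if (length(week) != 1 || is.na(week) || week < 1 || week > 8 ||
      week != round(week))
    stop_invalid("`week` must be an integer in 1..8")
  c("total", if (week <= 2) "acute" else "chronic")
}

time_bin_weeks <- function(label) {
  switch(label, total = 1:8, acute = 1:2, chronic = 3:8,
         stop_invalid("unknown time bin"))
}

#' Study-level metrics table restricted to the active channel window
#'
#' For each animal, averages unit counts per channel across the whole study,
#' selects the most-active consecutive window for its group (fixed per
#' animal), recomputes the five session metrics on that window only, and
#' emits one tidy row per recorded session.
#'
#' @param channel_tbl per-channel table with columns `group`, `animal`,
#'   `week`, `session`, `channel`, `working`, `n_units`, `noise_level`,
#'   `amp` — from [study_channel_truth()] or by row-binding
#'   [process_session()] channel tables.
#' @param windows named integer vector giving the window length per group,
#'   e.g. `c(rat = 10, mouse = 8)`.
#' @return A tibble with one row per (group, animal, week, session): the five
#'   metrics, `n_working` and `window_start`.
#' @export
build_study_table <- function(channel_tbl, windows = c(rat = 10L, mouse = 8L)) {
  missing_groups <- setdiff(unique(channel_tbl$group), names(windows))
  if (length(missing_groups))
    stop_invalid(paste("no window length for group(s):",
                       paste(missing_groups, collapse = ", ")))
  # fixed-per-animal window: average unit count per channel over the study
  sel_tbl <- list()
  for (an in unique(channel_tbl$animal)) {
    tb <- channel_tbl[channel_tbl$animal == an & channel_tbl$working %in% TRUE, ]
    g <- tb$group[1]
    all_ch <- sort(unique(channel_tbl$channel[channel_tbl$animal == an]))
    avg_full <- setNames(rep(0, length(all_ch)), all_ch)
    avg <- tapply(tb$n_units, tb$channel, mean)
    avg_full[names(avg)] <- avg
    w <- windows[[g]]
    start <- select_active_window(as.numeric(avg_full), w)
    sel_tbl[[an]] <- tibble(animal = an, channel = all_ch[start:(start + w - 1)],
                            window_start = start)
  }
  sel_tbl <- list_rbind(sel_tbl)
  d <- inner_join(channel_tbl, sel_tbl, by = c("animal", "channel")) |>
    filter(.data$working %in% TRUE)
  # per-row unit-amplitude summaries (list-column -> scalars)
  d$amp_mean <- vapply(d$amp, function(a) if (length(a)) mean(a) else NA_real_, 1.0)
  d$snr_sum <- vapply(d$amp, sum, 1.0) / d$noise_level
  out <- d |>
    group_by(.data$group, .data$animal, .data$week, .data$session,
             .data$window_start) |>
    summarise(
      pct_channels_with_units = 100 * mean(.data$n_units > 0),
      units_per_channel = mean(.data$n_units),
      noise_level = mean(.data$noise_level),
      max_amplitude = ifelse(any(.data$n_units > 0),
                             mean(.data$amp_mean[.data$n_units > 0]), NA_real_),
      snr = ifelse(sum(.data$n_units) > 0,
                   sum(.data$snr_sum) / sum(.data$n_units), NA_real_),
      n_working = dplyr::n(), .groups = "drop") |>
    relocate("window_start", .after = "n_working") |>
    arrange(.data$group, .data$animal, .data$week, .data$session)
  out
}
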