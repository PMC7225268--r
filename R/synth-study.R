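#' Specify a two-group longitudinal recording study
#'
#' Emulates a chronic implant study: two animal groups recorded twice a week
#' for eight weeks, with a multiplicative week-on-week decline in expected
#' unit yield and amplitude, and an optional additive group effect on one
#' metric restricted to a time range. With `group_effect = NULL` both groups
#' share identical generative parameters, which is the null configuration
#' used for statistical calibration.
#'
#' @param groups named integer vector of animals per group, e.g.
#'   `c(rat = 6, mouse = 14)`.
#' @param weeks number of study weeks (default 8).
#' @param sessions_per_week recordings per animal per week (default 2).
#' @param n_channels channels per array (default 16).
#' @param yield_decline per-week multiplicative decay in `(0, 1]` applied to
#'   expected unit count and amplitude.
#' @param baseline_units mean expected units per channel at week 1.
#' @param baseline_units_sd between-animal SD of that expectation.
#' @param baseline_amp,baseline_amp_sd mean and between-animal SD of unit
#'   peak-to-peak amplitude (uV) at week 1.
#' @param noise_sd background noise SD (uV) common to all channels.
#' @param group_effect `NULL`, or `list(group =, metric =, value =, weeks =)`
#'   adding `value` to the named metric's generative parameter for one group
#'   within `weeks` (`metric` is `"units_per_channel"` or `"max_amplitude"`).
#' @param seed integer master seed.
#' @return A `study_spec` list.
#' @export
study_spec <- function(groups = c(rat = 6L, mouse = 14L), weeks = 8L,
                       sessions_per_week = 2L, n_channels = 16L,
                       yield_decline = 0.9, baseline_units = 1.3,
                       baseline_units_sd = 0.35, baseline_amp = 110,
                       baseline_amp_sd = 15, noise_sd = 5,
                       group_effect = NULL, seed = 1L) {
  if (length(groups) < 1 || any(groups < 1) || is.null(names(groups)))
    stop_invalid("`groups` must be a named vector of positive animal counts")
  if (yield_decline <= 0 || yield_decline > 1)
    stop_invalid("`yield_decline` must lie in (0, 1]")
  if (!is.null(group_effect)) {
    stopifnot(all(c("group", "metric", "value", "weeks") %in% names(group_effect)))
    if (!group_effect$group %in% names(groups))
      stop_invalid("`group_effect$group` is not a study group")
    if (!group_effect$metric %in% c("units_per_channel", "max_amplitude"))
      stop_invalid("`group_effect$metric` must be units_per_channel or max_amplitude")
  }
  structure(list(groups = groups, weeks = as.integer(weeks),
                 sessions_per_week = as.integer(sessions_per_week),
                 n_channels = as.integer(n_channels),
                 yield_decline = yield_decline,
                 baseline_units = baseline_units,
                 baseline_units_sd = baseline_units_sd,
                 baseline_amp = baseline_amp, baseline_amp_sd = baseline_amp_sd,
                 noise_sd = noise_sd, group_effect = group_effect,
                 seed = as.integer(seed)),
            class = "study_spec")
}

#' Simulate a longitudinal two-group study
#'
#' Per-animal generative parameters (expected units per channel, unit
#' amplitude) are drawn once from the study spec; each session then draws
#' per-channel Poisson unit counts and unit amplitudes under the week's
#' decayed expectation. With `traces = TRUE` a full voltage recording is
#' synthesized for every session via [simulate_session()]; with the default
#' `traces = FALSE` only the ground-truth channel table is produced, which is
#' what metric-level and statistical studies need.
#'
#' @param spec a [study_spec()].
#' @param traces logical; also synthesize raw voltage traces.
#' @param duration session length in seconds when `traces = TRUE`.
#' @return A tibble with one row per session: `group`, `animal`, `week`,
#'   `session`, a `channels` list-column of per-channel ground truth
#'   (`channel`, `working`, `n_units`, `noise_level`, `amp`), and (when
#'   requested) a `recording` list-column of [recording_session()] objects.
#' @export
simulate_study <- function(spec, traces = FALSE, duration = 6) {
  stopifnot(inherits(spec, "study_spec"))
  n_sess <- sum(spec$groups) * spec$weeks * spec$sessions_per_week
  n_ch <- spec$n_channels
  g_v <- character(n_sess); an_v <- character(n_sess)
  wk_v <- integer(n_sess); se_v <- integer(n_sess)
  chans_l <- vector("list", n_sess); rec_l <- vector("list", n_sess)
  row <- 0L
  a_counter <- 0L
  for (g in names(spec$groups)) {
    for (a in seq_len(spec$groups[[g]])) {
      a_counter <- a_counter + 1L
      animal_id <- sprintf("%s_%02d", g, a)
      par_seed <- derive_seed(spec$seed, a_counter)
      pars <- with_seed(par_seed, {
        list(lambda = max(0.1, rnorm(1, spec$baseline_units, spec$baseline_units_sd)),
             amp = max(40, rnorm(1, spec$baseline_amp, spec$baseline_amp_sd)))
      })
      for (w in seq_len(spec$weeks)) {
        decay <- spec$yield_decline^(w - 1)
        lam <- pars$lambda * decay
        amp_mu <- pars$amp * decay
        fx <- spec$group_effect
        if (!is.null(fx) && g == fx$group && w %in% fx$weeks) {
          if (fx$metric == "units_per_channel") lam <- lam + fx$value
          if (fx$metric == "max_amplitude") amp_mu <- amp_mu + fx$value
        }
        for (s in seq_len(spec$sessions_per_week)) {
          sess_seed <- derive_seed(spec$seed,
                                   a_counter * 10000L + w * 100L + s)
          chans <- with_seed(sess_seed, {
            n_units <- rpois(n_ch, lam)
            amps <- lapply(n_units, function(k)
              if (k == 0) numeric(0) else pmax(30, rnorm(k, amp_mu, 12)))
            list(n_units = as.integer(n_units), amp = amps)
          })
          rec <- NULL
          if (isTRUE(traces)) {
            units <- list()
            ui <- 0L
            for (ch in seq_len(n_ch)) {
              for (amp in chans$amp[[ch]]) {
                ui <- ui + 1L
                units[[ui]] <- list(
                  template = make_template(
                    if (ui %% 2 == 0) "biphasic" else "triphasic",
                    amplitude_pp = amp, primary_channel = ch),
                  rate = 6 + 4 * ((ui * 7) %% 5) / 4)
              }
            }
            rec <- simulate_session(session_spec(
              duration = duration, n_channels = n_ch,
              noise_sd = spec$noise_sd, units = units,
              seed = derive_seed(sess_seed, 1L)))
          }
          row <- row + 1L
          g_v[row] <- g; an_v[row] <- animal_id
          wk_v[row] <- w; se_v[row] <- s
          chans_l[[row]] <- chans
          rec_l[[row]] <- rec
        }
      }
    }
  }
  out <- tibble(group = g_v, animal = an_v, week = wk_v, session = se_v,
                channels = chans_l)
  if (traces) out$recording <- rec_l
  attr(out, "study_spec") <- spec
  attr(out, "noise_level") <- 2 * spec$noise_sd
  attr(out, "n_channels") <- n_ch
  out
}

#' Flatten a simulated study to one row per channel
#'
#' @param study output of [simulate_study()].
#' @return A tibble with columns `group`, `animal`, `week`, `session`,
#'   `channel`, `working`, `n_units`, `noise_level`, `amp`.
#' @export
study_channel_truth <- function(study) {
  n_ch <- attr(study, "n_channels")
  n_sess <- nrow(study)
  tibble(
    group = rep(study$group, each = n_ch),
    animal = rep(study$animal, each = n_ch),
    week = rep(study$week, each = n_ch),
    session = rep(study$session, each = n_ch),
    channel = rep(seq_len(n_ch), n_sess),
    working = TRUE,
    n_units = unlist(lapply(study$channels, `[[`, "n_units")),
    noise_level = attr(study, "noise_level"),
    amp = unlist(lapply(study$channels, `[[`, "amp"), recursive = FALSE))
}
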