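#' Canonical single-unit waveform templates
#'
#' Builds a deterministic extracellular action-potential template on the
#' 37-sample snippet grid used by the detection pipeline (12 samples before
#' the alignment sample, the alignment sample, 24 after, at 24.4 kHz). The
#' negative trough falls exactly on the alignment sample so that inserted
#' spikes line up with threshold detections.
#'
#' @param shape `"biphasic"` (trough then rebound) or `"triphasic"` (small
#'   positive deflection, trough, rebound).
#' @param amplitude_pp peak-to-peak amplitude in uV; the waveform is scaled so
#'   that `max - min == amplitude_pp`.
#' @param primary_channel 1-based index of the channel carrying the full
#'   amplitude.
#' @param neighbor_attenuation fraction in `[0, 1)` of the amplitude seen one
#'   channel away; falls off geometrically with channel distance.
#' @param snippet_length number of samples (default 37).
#' @param align_sample 1-based index of the trough (default 13).
#' @return An object of class `unit_template` with fields `waveform`,
#'   `primary_channel`, `amplitude_pp`, `neighbor_attenuation`.
#' @examples
#' tpl <- make_template("biphasic", amplitude_pp = 100, primary_channel = 3)
#' max(tpl$waveform) - min(tpl$waveform)  # 100
#' @export
make_template <- function(shape = c("biphasic", "triphasic"),
                          amplitude_pp, primary_channel = 1L,
                          neighbor_attenuation = 0.1,
                          snippet_length = 37L, align_sample = 13L) {
  shape <- match.arg(shape)
  if (!is.numeric(amplitude_pp) || length(amplitude_pp) != 1 || amplitude_pp <= 0)
    stop_invalid("`amplitude_pp` must be a single positive number (uV)")
  if (primary_channel < 1) stop_invalid("`primary_channel` must be >= 1")
  if (neighbor_attenuation < 0 || neighbor_attenuation >= 1)
    stop_invalid("`neighbor_attenuation` must lie in [0, 1)")
  i <- seq_len(snippet_length) - align_sample   # 0 at the trough
  w <- switch(shape,
    biphasic  = -exp(-i^2 / (2 * 2.4^2)) + 0.45 * exp(-(i - 6)^2 / (2 * 4.5^2)),
    triphasic = 0.45 * exp(-(i + 5)^2 / (2 * 2.0^2)) -
                exp(-i^2 / (2 * 2.4^2)) + 0.35 * exp(-(i - 7)^2 / (2 * 5^2)))
  w <- w * amplitude_pp / (max(w) - min(w))
  structure(list(waveform = w, primary_channel = as.integer(primary_channel),
                 amplitude_pp = amplitude_pp,
                 neighbor_attenuation = neighbor_attenuation,
                 align_sample = as.integer(align_sample), shape = shape),
            class = "unit_template")
}

#' Specify a synthetic recording session
#'
#' @param duration session length in seconds.
#' @param n_channels number of channels (default 16).
#' @param sampling_rate Hz (default 24400).
#' @param noise_sd background noise SD in uV, scalar or per channel.
#' @param units list of `list(template = unit_template, rate = Hz)` entries.
#' @param artifact_rate broadband artifact events per minute.
#' @param pink_noise add a 1/f low-frequency component (off by default; the
#'   background model is white Gaussian).
#' @param seed integer; fully determines the simulated output.
#' @return A `synthetic_session_spec` list.
#' @export
session_spec <- function(duration, n_channels = 16L, sampling_rate = 24400,
                         noise_sd = 5, units = list(), artifact_rate = 0,
                         pink_noise = FALSE, seed = 1L) {
  if (n_channels < 1) stop_invalid("`n_channels` must be >= 1")
  if (any(noise_sd <= 0)) stop_invalid("`noise_sd` must be positive")
  if (duration <= 0) stop_invalid("`duration` must be positive")
  structure(list(duration = duration, n_channels = as.integer(n_channels),
                 sampling_rate = sampling_rate, noise_sd = noise_sd,
                 units = units, artifact_rate = artifact_rate,
                 pink_noise = pink_noise, seed = as.integer(seed)),
            class = "synthetic_session_spec")
}

# Homogeneous Poisson arrivals (in samples) with an absolute refractory period
poisson_spike_samples <- function(rate, duration, fs, refractory_s = 0.002) {
  n_exp <- rpois(1, rate * duration)
  if (n_exp == 0) return(integer(0))
  t <- sort(runif(n_exp, 0, duration))
  keep <- c(TRUE, diff(t) > refractory_s)
  # re-thin sequentially: diff-based thinning can readmit close pairs
  acc <- numeric(0); last <- -Inf
  for (ti in t) if (ti - last > refractory_s) { acc <- c(acc, ti); last <- ti }
  round(acc * fs)
}

#' Simulate a multi-channel extracellular recording with ground truth
#'
#' Gaussian background noise plus linear superposition of spike templates
#' inserted at Poisson times (2 ms refractory per unit), with optional
#' high-amplitude broadband artifact transients on all channels. Every
#' insertion is reported in the ground truth, so downstream detection,
#' sorting and metric stages can be scored exactly.
#'
#' @param spec a [session_spec()].
#' @return A list with elements `session` (a [recording_session()]) and
#'   `truth` (spike times per unit, per-channel true noise SD, artifact
#'   windows, per-channel unit counts).
#' @export
simulate_session <- function(spec) {
  stopifnot(inherits(spec, "synthetic_session_spec"))
  fs <- spec$sampling_rate
  ns <- round(spec$duration * fs)
  n_ch <- spec$n_channels
  sds <- rep(spec$noise_sd, length.out = n_ch)
  for (u in spec$units) {
    if (length(u$template$waveform) > ns)
      stop_invalid("template longer than the trace")
    if (u$template$primary_channel > n_ch)
      stop_invalid("unit primary_channel exceeds n_channels")
  }
  with_seed(spec$seed, {
    traces <- matrix(rnorm(n_ch * ns), nrow = n_ch) * sds
    if (isTRUE(spec$pink_noise)) {
      # slow random-walk drift, high-passed away by the pipeline
      for (ch in seq_len(n_ch)) {
        drift <- cumsum(rnorm(ns, 0, sds[ch] / sqrt(fs)))
        traces[ch, ] <- traces[ch, ] + drift - mean(drift)
      }
    }
    spikes <- list()
    for (ui in seq_along(spec$units)) {
      u <- spec$units[[ui]]
      tpl <- u$template
      wl <- length(tpl$waveform)
      pre <- tpl$align_sample - 1L
      post <- wl - tpl$align_sample
      s <- poisson_spike_samples(u$rate, spec$duration, fs)
      s <- s[s - pre >= 0 & s + post < ns]
      for (si in s) {
        idx <- (si - pre):(si + post) + 1L   # R indices
        for (dch in -2:2) {
          ch <- tpl$primary_channel + dch
          if (ch < 1 || ch > n_ch) next
          gain <- tpl$neighbor_attenuation^abs(dch)
          if (gain < 1e-3) next
          traces[ch, idx] <- traces[ch, idx] + gain * tpl$waveform
        }
      }
      spikes[[ui]] <- tibble(unit = ui, channel = tpl$primary_channel,
                             sample = as.integer(s))
    }
    art <- matrix(numeric(0), ncol = 2)
    n_art <- if (spec$artifact_rate > 0)
      rpois(1, spec$artifact_rate * spec$duration / 60) else 0L
    if (n_art > 0) {
      for (k in seq_len(n_art)) {
        dur <- round(runif(1, 0.005, 0.05) * fs)
        start <- sample.int(ns - dur, 1) - 1L
        amp <- runif(1, 10, 20) * mean(sds)
        tt <- seq_len(dur)
        burst <- amp * sin(pi * tt / dur) * sin(2 * pi * 400 * tt / fs)
        for (ch in seq_len(n_ch)) traces[ch, start + tt] <- traces[ch, start + tt] + burst
        art <- rbind(art, c(start, start + dur))
      }
      art <- merge_windows(art)
    }
    spikes <- if (length(spikes)) list_rbind(spikes) else
      tibble(unit = integer(0), channel = integer(0), sample = integer(0))
    counts <- integer(n_ch)
    if (nrow(spikes) > 0) {
      per_unit <- spikes |> distinct(.data$unit, .data$channel)
      tab <- table(factor(per_unit$channel, levels = seq_len(n_ch)))
      counts <- as.integer(tab)
    }
    list(session = recording_session(traces, fs),
         truth = list(spikes = spikes, noise_sd = sds,
                      artifact_windows = art, unit_counts = counts))
  })
}

#' Write simulation ground truth as JSON
#'
#' @param truth the `truth` element returned by [simulate_session()].
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_ground_truth <- function(truth, path) {
  by_unit <- split(truth$spikes$sample, truth$spikes$unit)
  jsonlite::write_json(
    list(spike_samples = by_unit,
         noise_sd = truth$noise_sd,
         artifact_windows = apply(truth$artifact_windows, 1,
                                  function(r) as.list(setNames(r, c("start", "end")))),
         unit_counts = truth$unit_counts),
    path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}
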