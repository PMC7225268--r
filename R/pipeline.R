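#' Detection-pipeline configuration
#'
#' Defaults follow common chronic-recording practice: a 300 Hz - 3 kHz
#' band-pass, a detection threshold of 3.5 noise SDs, snippets of 12 samples
#' before the threshold crossing through 24 samples after it (37 samples
#' including the crossing sample), negative-going detection, and a 1 ms
#' lockout to avoid double-counting a single waveform.
#'
#' @param band_low,band_high band-pass edges in Hz.
#' @param threshold_multiplier detection threshold in units of noise SD.
#' @param pre_samples,post_samples snippet extent around the crossing sample.
#' @param lockout_ms minimum separation between detections, ms.
#' @param polarity `"negative"`, `"positive"` or `"both"`.
#' @param robust_sd use the median-based robust SD estimate (default); plain
#'   sample SD when `FALSE`.
#' @return A `pipeline_config` list.
#' @export
pipeline_config <- function(band_low = 300, band_high = 3000,
                            threshold_multiplier = 3.5,
                            pre_samples = 12L, post_samples = 24L,
                            lockout_ms = 1,
                            polarity = c("negative", "positive", "both"),
                            robust_sd = TRUE) {
  polarity <- match.arg(polarity)
  if (band_low <= 0 || band_high <= band_low)
    stop_invalid("need 0 < band_low < band_high")
  if (threshold_multiplier <= 0) stop_invalid("`threshold_multiplier` must be > 0")
  if (pre_samples < 0 || post_samples < 0)
    stop_invalid("snippet extents must be non-negative")
  structure(list(band_low = band_low, band_high = band_high,
                 threshold_multiplier = threshold_multiplier,
                 pre_samples = as.integer(pre_samples),
                 post_samples = as.integer(post_samples),
                 lockout_ms = lockout_ms, polarity = polarity,
                 robust_sd = robust_sd),
            class = "pipeline_config")
}

snippet_length <- function(config) config$pre_samples + 1L + config$post_samples

#' Zero-phase band-pass filter
#'
#' 4th-order Butterworth applied forward and backward (`signal::filtfilt`),
#' per channel; output length is unchanged.
#'
#' @param session a [recording_session()].
#' @param config a [pipeline_config()].
#' @return The filtered session.
#' @export
bandpass_filter <- function(session, config = pipeline_config()) {
  nyq <- session$sampling_rate / 2
  if (config$band_high >= nyq)
    stop_invalid("band_high must be below the Nyquist frequency")
  bf <- signal::butter(4, c(config$band_low, config$band_high) / nyq,
                       type = "pass")
  out <- session
  for (ch in seq_len(n_channels(session)))
    out$traces[ch, ] <- signal::filtfilt(bf, session$traces[ch, ])
  out
}

#' Common average reference
#'
#' Subtracts, at every sample, the mean across working channels from each
#' working channel; non-working channels are untouched. Differences between
#' working channels are preserved exactly.
#'
#' @param session a [recording_session()].
#' @return The re-referenced session.
#' @export
common_average_reference <- function(session) {
  wk <- which(session$working_mask)
  if (length(wk) < 2)
    stop_degenerate("common average reference needs >= 2 working channels")
  avg <- colMeans(session$traces[wk, , drop = FALSE])
  out <- session
  out$traces[wk, ] <- sweep(session$traces[wk, , drop = FALSE], 2, avg)
  out
}

#' Rule-based artifact removal
#'
#' Replaces blinded human artifact review with deterministic rules: samples
#' where `|v|` exceeds `saturation_multiplier` x the channel's robust SD on
#' at least half of the working channels simultaneously are excluded, padded
#' by `pad_ms` on each side; channels whose robust SD exceeds
#' `channel_kill_multiplier` x the median channel SD are flagged
#' non-working. Idempotent: re-running adds nothing new.
#'
#' @param session a [recording_session()].
#' @param saturation_multiplier threshold, in robust SDs, for the
#'   cross-channel saturation rule.
#' @param channel_kill_multiplier ratio above the median channel SD at which
#'   a channel is declared broken.
#' @param pad_ms padding applied to each excluded window.
#' @return The session with updated `excluded_windows` and `working_mask`.
#' @export
remove_artifacts <- function(session, saturation_multiplier = 8,
                             channel_kill_multiplier = 5, pad_ms = 5) {
  ns <- n_samples(session)
  wk <- which(session$working_mask)
  sds <- vapply(wk, function(ch)
    median(abs(session$traces[ch, ])) / MAD_SCALE, 1.0)
  out <- session
  # dead/broken channel rule
  med_sd <- median(sds)
  if (med_sd > 0) {
    kill <- wk[sds > channel_kill_multiplier * med_sd]
    out$working_mask[kill] <- FALSE
  }
  wk2 <- which(out$working_mask)
  if (length(wk2) == 0) return(out)
  sds2 <- vapply(wk2, function(ch)
    median(abs(session$traces[ch, ])) / MAD_SCALE, 1.0)
  over <- matrix(FALSE, nrow = length(wk2), ncol = ns)
  for (i in seq_along(wk2))
    over[i, ] <- abs(session$traces[wk2[i], ]) > saturation_multiplier * sds2[i]
  hot <- colSums(over) >= length(wk2) / 2
  if (any(hot)) {
    pad <- round(pad_ms / 1000 * session$sampling_rate)
    idx <- which(hot) - 1L   # 0-based
    runs <- split(idx, cumsum(c(1, diff(idx) != 1)))
    win <- do.call(rbind, lapply(runs, function(r)
      c(max(0, min(r) - pad), min(ns, max(r) + 1 + pad))))
    for (ch in seq_len(n_channels(out)))
      out$excluded_windows[[ch]] <- merge_windows(
        rbind(out$excluded_windows[[ch]], win))
  }
  out
}

#' Robust noise SD of a single channel
#'
#' `median(|v|) / 0.6745` over retained (non-excluded) samples — the robust
#' Gaussian-consistent estimate that tolerates spikes and residual
#' artifacts. Set `robust = FALSE` for the plain sample SD.
#'
#' @param trace numeric vector of samples (uV).
#' @param excluded_windows two-column matrix of half-open sample intervals to
#'   drop, or NULL.
#' @param robust logical.
#' @param min_samples minimum retained samples required.
#' @return Noise SD in uV (not yet doubled; the x2 "noise level" metric lives
#'   in [compute_session_metrics()]).
#' @export
estimate_noise_sd <- function(trace, excluded_windows = NULL, robust = TRUE,
                              min_samples = 1000L) {
  keep <- !in_windows(seq_along(trace) - 1L, excluded_windows)
  v <- trace[keep]
  if (length(v) < min_samples)
    stop_degenerate("fewer than `min_samples` retained samples")
  if (robust) median(abs(v - median(v))) / MAD_SCALE else sd(v)
}

#' Threshold spike detection
#'
#' Finds first crossings of the mean-subtracted trace beyond
#' `threshold_multiplier x noise_sd` (negative-going by default), enforces
#' the lockout, and drops crossings inside excluded windows.
#'
#' @param trace single-channel samples (uV).
#' @param noise_sd noise SD in uV (from [estimate_noise_sd()]).
#' @param config a [pipeline_config()].
#' @param sampling_rate Hz.
#' @param excluded_windows half-open sample intervals to ignore.
#' @return Integer vector of 0-based crossing samples.
#' @export
detect_spikes <- function(trace, noise_sd, config = pipeline_config(),
                          sampling_rate = 24400, excluded_windows = NULL) {
  if (noise_sd <= 0) stop_invalid("`noise_sd` must be positive")
  v <- trace - mean(trace)
  thr <- config$threshold_multiplier * noise_sd
  below <- switch(config$polarity,
                  negative = v < -thr,
                  positive = v > thr,
                  both = abs(v) > thr)
  cross <- which(below & !c(FALSE, below[-length(below)])) - 1L  # 0-based
  cross <- cross[!in_windows(cross, excluded_windows)]
  if (length(cross) == 0) return(integer(0))
  lock <- config$lockout_ms / 1000 * sampling_rate
  keep <- integer(0); last <- -Inf
  for (cs in cross) if (cs - last >= lock) { keep <- c(keep, cs); last <- cs }
  keep
}

#' Extract fixed-length snippets around threshold crossings
#'
#' Each snippet spans `pre_samples` before the crossing through
#' `post_samples` after it (37 samples at the defaults). Crossings too close
#' to the trace edges are skipped and counted.
#'
#' @param trace single-channel samples (uV).
#' @param crossings sorted 0-based crossing samples.
#' @param config a [pipeline_config()].
#' @return A list with `waveforms` (n x 37 matrix), `crossings` (the retained
#'   0-based crossing samples) and `n_skipped`.
#' @export
extract_snippets <- function(trace, crossings, config = pipeline_config()) {
  ns <- length(trace)
  ok <- crossings - config$pre_samples >= 0 &
        crossings + config$post_samples < ns
  kept <- crossings[ok]
  wl <- snippet_length(config)
  wf <- matrix(0, nrow = length(kept), ncol = wl)
  for (i in seq_along(kept))
    wf[i, ] <- trace[(kept[i] - config$pre_samples):(kept[i] + config$post_samples) + 1L]
  list(waveforms = wf, crossings = kept, n_skipped = sum(!ok))
}

# shift each snippet so its trough (searched within +-max_shift of the
# nominal alignment sample) lands on the alignment sample; edges are padded
# with the boundary value
realign_on_trough <- function(waveforms, align_sample = 13L, max_shift = 8L) {
  wl <- ncol(waveforms)
  # the trough trails the threshold crossing, so the search is asymmetric
  lo <- max(1L, align_sample - 2L)
  hi <- min(wl, align_sample + max_shift)
  out <- waveforms
  for (i in seq_len(nrow(waveforms))) {
    w <- waveforms[i, ]
    trough <- lo + which.min(w[lo:hi]) - 1L
    d <- trough - align_sample
    if (d == 0) next
    if (d > 0) out[i, ] <- c(w[(d + 1):wl], rep(w[wl], d))
    else out[i, ] <- c(rep(w[1], -d), w[1:(wl + d)])
  }
  out
}

#' Cluster snippets into single units
#'
#' The sorting stage: snippets are projected onto their first three principal
#' components and fit with Gaussian mixtures for k = 1..`k_max`; k is chosen
#' by BIC. Clusters with fewer than `min_cluster_size` members, or whose mean
#' waveform peak-to-peak amplitude falls below
#' `accept_multiplier x (2 x noise_sd)`, are discarded — a rule-based stand-in
#' for manual curation that rejects threshold-crossing noise clusters.
#'
#' @param waveforms n x 37 snippet matrix for one channel.
#' @param noise_sd the channel's noise SD (uV).
#' @param channel channel index recorded in the output.
#' @param crossings optional 0-based crossing samples, carried per member.
#' @param k_max maximum number of mixture components.
#' @param min_cluster_size minimum members for an accepted unit.
#' @param accept_multiplier amplitude gate in units of the channel noise
#'   level (2 x noise SD); the default of 5 is a conservative curation
#'   cutoff that rejects common-average-reference leakage clusters.
#' @return A list of `unit_cluster` objects (fields `channel`,
#'   `member_index`, `crossings`, `mean_waveform`, `amplitude_pp`, `n`).
#' @export
cluster_snippets <- function(waveforms, noise_sd, channel = 1L,
                             crossings = NULL, k_max = 5L,
                             min_cluster_size = 15L, accept_multiplier = 5) {
  n <- nrow(waveforms)
  if (is.null(n) || n < min_cluster_size) return(list())
  # realign each snippet on its trough: threshold-crossing alignment jitters
  # by a sample or two, which smears one unit into several mixture modes
  aligned <- realign_on_trough(waveforms)
  pcs <- prcomp(aligned, center = TRUE, scale. = FALSE)
  d <- min(3L, ncol(pcs$x))
  x <- pcs$x[, seq_len(d), drop = FALSE]
  Gs <- seq_len(min(k_max, max(1L, n %/% min_cluster_size)))
  bic <- mclust::mclustBIC(x, G = Gs, verbose = FALSE)
  fit <- mclust::Mclust(x, x = bic, verbose = FALSE)
  cls <- if (is.null(fit)) rep(1L, n) else fit$classification
  out <- list()
  for (k in sort(unique(cls))) {
    idx <- which(cls == k)
    if (length(idx) < min_cluster_size) next
    mw <- colMeans(aligned[idx, , drop = FALSE])
    amp <- max(mw) - min(mw)
    if (amp < accept_multiplier * 2 * noise_sd) next
    out[[length(out) + 1L]] <- structure(
      list(channel = as.integer(channel), member_index = idx,
           crossings = if (!is.null(crossings)) crossings[idx],
           mean_waveform = mw, amplitude_pp = amp, n = length(idx)),
      class = "unit_cluster")
  }
  merge_similar_clusters(out, aligned, noise_sd)
}

# residual one-sample alignment dither can split one unit into two mixture
# modes with near-identical waveforms; merge accepted clusters whose mean
# waveforms agree, under a small shift, to within the sampling noise of the
# two means (RMS difference <= rms_mult x noise_sd x sqrt(1/na + 1/nb))
merge_similar_clusters <- function(clusters, aligned, noise_sd,
                                   max_shift = 4L, rms_mult = 3,
                                   max_amp_ratio = 1.25) {
  shifted_rms <- function(a, b) {
    wl <- length(a)
    best <- Inf
    for (s in -max_shift:max_shift) {
      ia <- max(1, 1 + s):min(wl, wl + s)
      ib <- ia - s
      r <- sqrt(mean((a[ia] - b[ib])^2))
      if (r < best) best <- r
    }
    best
  }
  repeat {
    if (length(clusters) < 2) break
    merged <- FALSE
    for (i in seq_along(clusters)) {
      for (j in seq_along(clusters)) {
        if (j <= i) next
        a <- clusters[[i]]; b <- clusters[[j]]
        ratio <- max(a$amplitude_pp, b$amplitude_pp) /
                 min(a$amplitude_pp, b$amplitude_pp)
        if (ratio > max_amp_ratio) next
        gate <- rms_mult * noise_sd * sqrt(1 / a$n + 1 / b$n)
        if (shifted_rms(a$mean_waveform, b$mean_waveform) > gate) next
        idx <- sort(c(a$member_index, b$member_index))
        mw <- colMeans(aligned[idx, , drop = FALSE])
        clusters[[i]] <- structure(
          list(channel = a$channel, member_index = idx,
               crossings = if (!is.null(a$crossings))
                 sort(c(a$crossings, b$crossings)),
               mean_waveform = mw, amplitude_pp = max(mw) - min(mw),
               n = length(idx)), class = "unit_cluster")
        clusters[[j]] <- NULL
        merged <- TRUE
        break
      }
      if (merged) break
    }
    if (!merged) break
  }
  clusters
}

#' Run the full per-session pipeline
#'
#' Band-pass filter, common average reference, rule-based artifact removal,
#' per-channel robust noise estimation, threshold detection, snippet
#' extraction and clustering, summarized as a per-channel table.
#'
#' @param session a [recording_session()].
#' @param config a [pipeline_config()].
#' @param ... passed to [cluster_snippets()].
#' @return A list with `channels` (tibble: `channel`, `working`, `n_units`,
#'   `noise_level` = 2 x robust SD, `amp` list-column of unit amplitudes,
#'   `n_detections`), `clusters` (list of accepted units) and `session`
#'   (the processed session).
#' @export
process_session <- function(session, config = pipeline_config(), ...) {
  s <- bandpass_filter(session, config)
  s <- common_average_reference(s)
  s <- remove_artifacts(s)
  n_ch <- n_channels(s)
  clusters <- list()
  rows <- vector("list", n_ch)
  for (ch in seq_len(n_ch)) {
    if (!s$working_mask[ch]) {
      rows[[ch]] <- tibble(channel = ch, working = FALSE, n_units = NA_integer_,
                           noise_level = NA_real_, amp = list(numeric(0)),
                           n_detections = NA_integer_,
                           detections = list(integer(0)))
      next
    }
    nsd <- estimate_noise_sd(s$traces[ch, ], s$excluded_windows[[ch]],
                             robust = config$robust_sd)
    cr <- detect_spikes(s$traces[ch, ], nsd, config, s$sampling_rate,
                        s$excluded_windows[[ch]])
    sn <- extract_snippets(s$traces[ch, ], cr, config)
    cl <- cluster_snippets(sn$waveforms, nsd, channel = ch,
                           crossings = sn$crossings, ...)
    clusters <- c(clusters, cl)
    rows[[ch]] <- tibble(channel = ch, working = TRUE,
                         n_units = length(cl), noise_level = 2 * nsd,
                         amp = list(vapply(cl, function(u) u$amplitude_pp, 1.0)),
                         n_detections = length(sn$crossings),
                         detections = list(sn$crossings))
  }
  list(channels = list_rbind(rows), clusters = clusters, session = s)
}
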