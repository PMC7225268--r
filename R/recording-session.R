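#' Construct a multi-channel recording session
#'
#' The basic container for extracellular data: a channels-by-samples voltage
#' matrix in microvolts plus acquisition metadata. All sample intervals used
#' throughout the package (excluded windows, artifact windows) are 0-based and
#' half-open `[start, end)`.
#'
#' @param traces numeric matrix, channels x samples, in uV.
#' @param sampling_rate sampling rate in Hz.
#' @param channel_ids optional channel identifiers (default `1:n_channels`).
#' @param working_mask logical vector, one flag per channel; `TRUE` marks a
#'   channel whose impedance/noise indicate an intact connection.
#' @param excluded_windows list (one element per channel) of two-column
#'   matrices of half-open sample intervals excluded from analysis.
#' @return An object of class `recording_session`.
#' @export
recording_session <- function(traces, sampling_rate,
                              channel_ids = NULL,
                              working_mask = NULL,
                              excluded_windows = NULL) {
  if (!is.matrix(traces)) traces <- matrix(traces, nrow = 1)
  n_ch <- nrow(traces)
  if (!is.numeric(sampling_rate) || sampling_rate <= 0)
    stop_invalid("`sampling_rate` must be a positive number")
  if (is.null(channel_ids)) channel_ids <- seq_len(n_ch)
  if (is.null(working_mask)) working_mask <- rep(TRUE, n_ch)
  if (length(working_mask) != n_ch)
    stop_invalid("`working_mask` must have one entry per channel")
  if (is.null(excluded_windows)) excluded_windows <- rep(list(NULL), n_ch)
  structure(
    list(traces = traces, sampling_rate = sampling_rate,
         channel_ids = channel_ids, working_mask = working_mask,
         excluded_windows = excluded_windows),
    class = "recording_session")
}

#' @export
print.recording_session <- function(x, ...) {
  cat(sprintf("<recording_session> %d channels x %d samples @ %.1f kHz (%.1f s)\n",
              nrow(x$traces), ncol(x$traces), x$sampling_rate / 1000,
              ncol(x$traces) / x$sampling_rate))
  cat(sprintf("  working channels: %d/%d; excluded windows: %d\n",
              sum(x$working_mask), length(x$working_mask),
              sum(vapply(x$excluded_windows, NROW, 1L))))
  invisible(x)
}

n_samples <- function(session) ncol(session$traces)
n_channels <- function(session) nrow(session$traces)

#' Write / read a recording in the flat binary + JSON sidecar format
#'
#' Traces are stored channel-major as little-endian 32-bit floats (uV); the
#' sidecar JSON carries channel count, sampling rate, channel ids and any
#' extra metadata supplied.
#'
#' @param session a `recording_session`.
#' @param path path of the binary file; the sidecar is written at
#'   `paste0(path, ".json")`.
#' @param meta optional named list echoed into the sidecar.
#' @return `write_recording()` returns `path` invisibly; `read_recording()`
#'   returns a `recording_session`.
#' @export
write_recording <- function(session, path, meta = list()) {
  con <- file(path, "wb")
  on.exit(close(con))
  # channel-major: all samples of channel 1, then channel 2, ...
  writeBin(as.numeric(t(session$traces))[seq_along(session$traces)],
           con, size = 4, endian = "little")
  sidecar <- c(list(n_channels = nrow(session$traces),
                    n_samples = ncol(session$traces),
                    sampling_rate = session$sampling_rate,
                    channel_ids = session$channel_ids,
                    unit = "uV",
                    working_mask = session$working_mask), meta)
  jsonlite::write_json(sidecar, paste0(path, ".json"), auto_unbox = TRUE,
                       digits = NA)
  invisible(path)
}

#' @rdname write_recording
#' @export
read_recording <- function(path) {
  meta <- jsonlite::read_json(paste0(path, ".json"), simplifyVector = TRUE)
  con <- file(path, "rb")
  on.exit(close(con))
  v <- readBin(con, "numeric", n = meta$n_channels * meta$n_samples,
               size = 4, endian = "little")
  traces <- matrix(v, nrow = meta$n_channels, byrow = TRUE)
  recording_session(traces, meta$sampling_rate, meta$channel_ids,
                    as.logical(meta$working_mask))
}
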