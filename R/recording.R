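#' Construct a vibrational recording
#'
#' A recording is the basic unit of analysis: a mono waveform sampled from a
#' piezoelectric probe inside a tree trunk, normalized to the open interval
#' \eqn{[-1, 1)}, together with its sampling rate and (optionally) capture
#' metadata parsed from the device's filename convention.
#'
#' @param samples Numeric vector of amplitudes, all finite and within
#'   \eqn{[-1, 1]}.
#' @param rate Sampling rate in Hz (samples per second), positive.
#' @param metadata Optional [recording_metadata] describing the capture
#'   time, file index and source name, or `NULL`.
#'
#' @return An object of class `"recording"`: a list with elements `samples`,
#'   `rate`, `length_samples` and `metadata`.
#' @seealso [read_recording()], [parse_filename()]
#' @export
#' @examples
#' rec <- recording(sin(2 * pi * 440 * seq(0, 0.1, by = 1 / 16000)) * 0.5, 16000)
#' rec$length_samples
recording <- function(samples, rate, metadata = NULL) {
  samples <- as.numeric(samples)
  if (length(samples) == 0L) {
    stop("recording must contain at least one sample", call. = FALSE)
  }
  if (!all(is.finite(samples))) {
    stop("recording samples must all be finite", call. = FALSE)
  }
  if (max(abs(samples)) > 1) {
    stop("recording samples must lie within [-1, 1] (normalized amplitude)",
         call. = FALSE)
  }
  if (!is.numeric(rate) || length(rate) != 1L || !is.finite(rate) || rate <= 0) {
    stop("rate must be a single positive number (Hz)", call. = FALSE)
  }
  if (!is.null(metadata) && !inherits(metadata, "recording_metadata")) {
    stop("metadata must be NULL or a recording_metadata object", call. = FALSE)
  }
  structure(
    list(samples = samples, rate = rate,
         length_samples = length(samples), metadata = metadata),
    class = "recording"
  )
}

#' @export
print.recording <- function(x, ...) {
  dur <- x$length_samples / x$rate
  cat(sprintf("<recording> %d samples @ %g Hz (%.2f s)\n",
              x$length_samples, x$rate, dur))
  if (!is.null(x$metadata)) {
    cat(sprintf("  captured %s (index %d, %s)\n",
                format(x$metadata$timestamp, "%Y-%m-%d %H:%M:%S"),
                x$metadata$index, x$metadata$source_name))
  }
  invisible(x)
}

#' Capture metadata for a recording
#'
#' @param timestamp `POSIXct` capture time (zone-naive local time; stored in
#'   UTC so no daylight-saving arithmetic is applied).
#' @param index Non-negative integer distinguishing consecutive recordings
#'   that share a timestamp.
#' @param source_name Original file name (or other source label).
#' @param ext File extension (`"wav"` or `"mp3"`), kept so that names
#'   round-trip through [format_filename()].
#'
#' @return An object of class `"recording_metadata"`.
#' @export
recording_metadata <- function(timestamp, index, source_name = "", ext = "wav") {
  if (!inherits(timestamp, "POSIXct")) {
    stop("timestamp must be POSIXct", call. = FALSE)
  }
  index <- as.integer(index)
  if (is.na(index) || index < 0L) {
    stop("index must be a non-negative integer", call. = FALSE)
  }
  structure(
    list(timestamp = timestamp, index = index,
         source_name = as.character(source_name), ext = as.character(ext)),
    class = "recording_metadata"
  )
}
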