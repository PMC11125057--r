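#' Parse a device filename into capture metadata
#'
#' Field recorders in this monitoring system name files
#' `F_YYYYMMDDhhmmss_<index>.<ext>`: a 14-digit local timestamp followed by
#' an integer distinguishing consecutive recordings. For example
#' `F_20230812193118_1.mp3` was captured on 12 August 2023 at 19:31:18.
#'
#' @param name File name (base name; any directory part is stripped).
#' @return A [recording_metadata] object.
#' @export
#' @examples
#' parse_filename("F_20230812193118_1.mp3")
parse_filename <- function(name) {
  base <- basename(name)
  m <- regmatches(base, regexec("^F_([0-9]{14})_([0-9]+)\\.([A-Za-z0-9]+)$", base))[[1]]
  if (length(m) == 0L) {
    # diagnose which component is malformed
    if (!grepl("^F_", base)) {
      stop(sprintf("cannot parse '%s': prefix must be 'F_'", base), call. = FALSE)
    }
    if (!grepl("^F_[0-9]{14}", base)) {
      stop(sprintf("cannot parse '%s': expected a 14-digit timestamp after 'F_'",
                   base), call. = FALSE)
    }
    stop(sprintf("cannot parse '%s': expected '_<index>.<ext>' after the timestamp",
                 base), call. = FALSE)
  }
  stamp <- m[2]
  ts <- as.POSIXct(stamp, format = "%Y%m%d%H%M%S", tz = "UTC")
  if (is.na(ts)) {
    stop(sprintf("cannot parse '%s': '%s' is not a valid calendar timestamp",
                 base, stamp), call. = FALSE)
  }
  recording_metadata(timestamp = ts, index = as.integer(m[3]),
                     source_name = base, ext = tolower(m[4]))
}

#' Format capture metadata back into a device filename
#'
#' Inverse of [parse_filename()]: `format_filename(parse_filename(x))`
#' reproduces `x` for conforming names.
#'
#' @param meta A [recording_metadata] object.
#' @return A file name string.
#' @export
format_filename <- function(meta) {
  stopifnot(inherits(meta, "recording_metadata"))
  sprintf("F_%s_%d.%s", format(meta$timestamp, "%Y%m%d%H%M%S", tz = "UTC"),
          meta$index, meta$ext)
}

#' Read a vibrational recording from disk
#'
#' Reads a WAV (RIFF, 16-bit PCM) file, averages multichannel audio to mono,
#' and normalizes integer samples to \eqn{[-1, 1)} by dividing by 32768.
#' When the file name follows the device convention
#' (`F_YYYYMMDDhhmmss_<index>.<ext>`, see [parse_filename()]) the capture
#' metadata is attached. mp3 input is not supported by this build (no decoder
#' backend); convert to WAV first.
#'
#' @param path Path to the audio file.
#' @param target_rate Optional sampling rate in Hz; if given and different
#'   from the file's rate, the waveform is resampled (polyphase FIR via
#'   \pkg{signal}).
#' @return A [recording].
#' @export
read_recording <- function(path, target_rate = NULL) {
  if (!file.exists(path)) {
    stop(sprintf("file not found: '%s'", path), call. = FALSE)
  }
  ext <- tolower(tools::file_ext(path))
  if (ext == "mp3") {
    stop("mp3 decoding is not available in this build; convert to WAV first",
         call. = FALSE)
  }
  if (ext != "wav") {
    stop(sprintf("unsupported audio format '.%s' (expected .wav)", ext),
         call. = FALSE)
  }
  wav <- read_wav_pcm16(path)
  samples <- wav$samples
  if (is.matrix(samples)) samples <- rowMeans(samples)
  if (length(samples) == 0L) {
    stop(sprintf("'%s' contains no audio samples", path), call. = FALSE)
  }
  rate <- wav$rate
  if (!is.null(target_rate) && target_rate != rate) {
    samples <- signal::resample(samples, p = target_rate, q = rate)
    # resampling filters can overshoot slightly; clamp to the contract
    samples <- pmin(pmax(samples, -1), 1 - 2^-15)
    rate <- target_rate
  }
  meta <- tryCatch(parse_filename(path), error = function(e) NULL)
  recording(samples, rate, metadata = meta)
}

# Minimal RIFF/WAVE PCM-16 reader. Walks the chunk list so files with extra
# chunks (LIST, fact, ...) still load. Returns samples as a vector (mono) or
# an n x channels matrix, already normalized by 1/32768.
read_wav_pcm16 <- function(path) {
  con <- file(path, "rb")
  on.exit(close(con))
  riff <- readChar(con, 4, useBytes = TRUE)
  if (!identical(riff, "RIFF")) stop(sprintf("'%s' is not a RIFF file", path), call. = FALSE)
  invisible(readBin(con, "integer", 1, size = 4, endian = "little"))
  wave <- readChar(con, 4, useBytes = TRUE)
  if (!identical(wave, "WAVE")) stop(sprintf("'%s' is not a WAVE file", path), call. = FALSE)

  fmt <- NULL
  data_raw <- NULL
  repeat {
    id <- readChar(con, 4, useBytes = TRUE)
    if (length(id) == 0L || nchar(id) < 4L) break
    size <- readBin(con, "integer", 1, size = 4, endian = "little")
    if (identical(id, "fmt ")) {
      body <- readBin(con, "raw", size)
      fmt <- list(
        audio_format = sum(as.integer(body[1:2]) * c(1L, 256L)),
        channels     = sum(as.integer(body[3:4]) * c(1L, 256L)),
        rate         = sum(as.integer(body[5:8]) * c(1, 256, 65536, 16777216)),
        bits         = sum(as.integer(body[15:16]) * c(1L, 256L))
      )
    } else if (identical(id, "data")) {
      data_raw <- readBin(con, "raw", size)
    } else {
      invisible(readBin(con, "raw", size))
    }
    if (size %% 2L == 1L) invisible(readBin(con, "raw", 1L))  # chunk padding
    if (!is.null(fmt) && !is.null(data_raw)) break
  }
  if (is.null(fmt) || is.null(data_raw)) {
    stop(sprintf("'%s': missing fmt or data chunk", path), call. = FALSE)
  }
  if (fmt$audio_format != 1L || fmt$bits != 16L) {
    stop(sprintf("'%s': only 16-bit PCM WAV is supported (format %d, %d bits)",
                 path, fmt$audio_format, fmt$bits), call. = FALSE)
  }
  ints <- readBin(data_raw, "integer", n = length(data_raw) %/% 2L,
                  size = 2, signed = TRUE, endian = "little")
  x <- ints / 32768
  if (fmt$channels > 1L) {
    n <- length(x) %/% fmt$channels
    x <- matrix(x[seq_len(n * fmt$channels)], ncol = fmt$channels, byrow = TRUE)
  }
  list(samples = x, rate = fmt$rate)
}

#' Write a recording as 16-bit PCM WAV
#'
#' Quantizes the normalized waveform with `round(x * 32768)` clamped to the
#' 16-bit range. Used to materialize synthetic fixtures; reading the file
#' back reproduces the samples to within one least-significant bit of the
#' 16-bit quantization.
#'
#' @param rec A [recording] (or bare numeric vector, in which case `rate`
#'   must be given).
#' @param path Output path.
#' @param rate Sampling rate in Hz, only needed for bare vectors.
#' @return `path`, invisibly.
#' @export
write_recording <- function(rec, path, rate = NULL) {
  if (inherits(rec, "recording")) {
    samples <- rec$samples
    rate <- rec$rate
  } else {
    samples <- as.numeric(rec)
    if (is.null(rate)) stop("rate must be given for bare sample vectors", call. = FALSE)
  }
  ints <- as.integer(pmin(pmax(round(samples * 32768), -32768), 32767))
  n_bytes <- length(ints) * 2L
  con <- file(path, "wb")
  on.exit(close(con))
  writeChar("RIFF", con, eos = NULL)
  writeBin(as.integer(36L + n_bytes), con, size = 4, endian = "little")
  writeChar("WAVE", con, eos = NULL)
  writeChar("fmt ", con, eos = NULL)
  writeBin(16L, con, size = 4, endian = "little")
  writeBin(1L, con, size = 2, endian = "little")             # PCM
  writeBin(1L, con, size = 2, endian = "little")             # mono
  writeBin(as.integer(rate), con, size = 4, endian = "little")
  writeBin(as.integer(rate) * 2L, con, size = 4, endian = "little")  # byte rate
  writeBin(2L, con, size = 2, endian = "little")             # block align
  writeBin(16L, con, size = 2, endian = "little")            # bits/sample
  writeChar("data", con, eos = NULL)
  writeBin(n_bytes, con, size = 4, endian = "little")
  writeBin(ints, con, size = 2, endian = "little")
  invisible(path)
}

#' Read a per-file annotation table
#'
#' Annotations pair each recording with the number of impulses a trained
#' observer counted in it and a free-text background-noise tag. The expected
#' dialect is comma-separated UTF-8 with a header row `file,count,noise`;
#' alternative column names can be mapped via the `columns` argument.
#'
#' @param path Path to the CSV file.
#' @param columns Named character vector mapping the roles `file`, `count`,
#'   `noise` to the actual header names.
#' @return A data frame with columns `file` (character), `true_count`
#'   (integer) and `noise_tag` (character), one row per input row in order.
#' @export
read_annotations <- function(path,
                             columns = c(file = "file", count = "count",
                                         noise = "noise")) {
  if (!file.exists(path)) {
    stop(sprintf("annotation file not found: '%s'", path), call. = FALSE)
  }
  tab <- utils::read.csv(path, stringsAsFactors = FALSE, encoding = "UTF-8")
  missing <- setdiff(unname(columns[c("file", "count")]), names(tab))
  if (length(missing) > 0L) {
    stop(sprintf("annotation table is missing required column(s): %s",
                 paste(missing, collapse = ", ")), call. = FALSE)
  }
  counts <- tab[[columns[["count"]]]]
  counts_int <- suppressWarnings(as.integer(counts))
  bad <- is.na(counts_int) | counts_int < 0L
  if (any(bad)) {
    stop(sprintf("annotation counts must be non-negative integers (bad rows: %s)",
                 paste(utils::head(which(bad), 5), collapse = ", ")), call. = FALSE)
  }
  noise_col <- columns[["noise"]]
  noise <- if (noise_col %in% names(tab)) as.character(tab[[noise_col]]) else ""
  data.frame(
    file = as.character(tab[[columns[["file"]]]]),
    true_count = counts_int,
    noise_tag = noise,
    stringsAsFactors = FALSE
  )
}
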