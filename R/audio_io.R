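# Audio input: RIFF/WAVE reading, validation, and analysis-segment selection.
#
# The analysis protocol expects mono recordings of a sustained vowel at
# 44100 Hz / 16 bit; other PCM dialects (24/32-bit integer, IEEE float) and
# sample rates are accepted and scaled to [-1, 1].

#' Construct a voice recording
#'
#' Container for a mono waveform plus its sampling metadata. Samples are
#' amplitudes on a full-scale \eqn{[-1, 1]} axis.
#'
#' @param samples numeric vector of amplitudes in \eqn{[-1, 1]}.
#' @param sample_rate sampling rate in Hz (positive).
#' @param bit_depth bits per sample of the source file (informational).
#' @return An object of class `voice_recording` with fields `samples`,
#'   `sample_rate`, `bit_depth` and `duration` (seconds).
#' @export
voice_recording <- function(samples, sample_rate, bit_depth = 16L) {
  if (length(samples) == 0L)
    vox_validation_error("recording contains no samples")
  if (!all(is.finite(samples)))
    vox_validation_error("recording contains non-finite samples")
  if (!is.numeric(sample_rate) || length(sample_rate) != 1L || sample_rate <= 0)
    vox_validation_error("sample_rate must be a positive scalar (Hz)")
  structure(
    list(samples = as.numeric(samples), sample_rate = sample_rate,
         bit_depth = as.integer(bit_depth),
         duration = length(samples) / sample_rate),
    class = "voice_recording")
}

#' @export
print.voice_recording <- function(x, ...) {
  cat(sprintf("<voice_recording> %.3f s @ %d Hz, %d bit\n",
              x$duration, as.integer(x$sample_rate), x$bit_depth))
  invisible(x)
}

read_chunk_id <- function(con) {
  id <- readChar(con, 4L, useBytes = TRUE)
  if (length(id) == 0L || nchar(id, type = "bytes") < 4L) return(NULL)
  id
}

decode_pcm <- function(raw_data, bits, fmt) {
  if (fmt == 3L) { # IEEE float
    size <- bits / 8L
    x <- readBin(raw_data, numeric(), n = length(raw_data) %/% size,
                 size = size, endian = "little")
    return(x)
  }
  if (bits == 16L) {
    readBin(raw_data, integer(), n = length(raw_data) %/% 2L, size = 2L,
            signed = TRUE, endian = "little") / 32768
  } else if (bits == 8L) {
    (as.integer(readBin(raw_data, integer(), n = length(raw_data), size = 1L,
                        signed = FALSE)) - 128) / 128
  } else if (bits == 24L) {
    n <- length(raw_data) %/% 3L
    b <- matrix(as.integer(raw_data[seq_len(n * 3L)]), nrow = 3L)
    v <- b[1, ] + 256 * b[2, ] + 65536 * b[3, ]
    v <- ifelse(v >= 8388608, v - 16777216, v)
    v / 8388608
  } else if (bits == 32L) {
    readBin(raw_data, integer(), n = length(raw_data) %/% 4L, size = 4L,
            signed = TRUE, endian = "little") / 2147483648
  } else {
    vox_io_error(sprintf("unsupported PCM bit depth: %d", bits))
  }
}

#' Read a WAV file
#'
#' Reads a RIFF/WAVE file (PCM 8/16/24/32-bit or IEEE float) and returns a
#' mono [voice_recording()] with samples scaled to \eqn{[-1, 1]}. Multi-channel
#' input is reduced to channel 1 with a warning: the recording protocol is
#' mono, and dropping the extra channels avoids silently averaging in
#' inter-channel artifacts.
#'
#' @param path path to a WAV file.
#' @return A [voice_recording()].
#' @export
read_wav <- function(path) {
  if (!file.exists(path))
    vox_io_error(sprintf("cannot read WAV file '%s': no such file", path))
  con <- file(path, "rb")
  on.exit(close(con))

  riff <- read_chunk_id(con)
  if (!identical(riff, "RIFF"))
    vox_io_error(sprintf("'%s' is not a RIFF/WAVE file (missing RIFF header)", path))
  readBin(con, integer(), 1L, size = 4L, endian = "little")
  wave <- read_chunk_id(con)
  if (!identical(wave, "WAVE"))
    vox_io_error(sprintf("'%s' is not a RIFF/WAVE file (missing WAVE tag)", path))

  fmt <- NULL
  raw_data <- NULL
  repeat {
    id <- read_chunk_id(con)
    if (is.null(id)) break
    sz <- readBin(con, integer(), 1L, size = 4L, endian = "little")
    if (length(sz) == 0L || is.na(sz) || sz < 0L)
      vox_io_error(sprintf("'%s' has a corrupt chunk header", path))
    if (id == "fmt ") {
      body <- readBin(con, raw(), n = sz)
      if (length(body) < 16L)
        vox_io_error(sprintf("'%s' has a truncated fmt chunk", path))
      fmt <- list(
        audio_format = readBin(body[1:2], integer(), 1L, size = 2L,
                               signed = FALSE, endian = "little"),
        channels = readBin(body[3:4], integer(), 1L, size = 2L,
                           signed = FALSE, endian = "little"),
        sample_rate = readBin(body[5:8], integer(), 1L, size = 4L,
                              endian = "little"),
        bits = readBin(body[15:16], integer(), 1L, size = 2L,
                       signed = FALSE, endian = "little"))
    } else if (id == "data") {
      raw_data <- readBin(con, raw(), n = sz)
      if (length(raw_data) < sz)
        vox_io_error(sprintf("'%s' has a truncated data chunk", path))
    } else {
      seek(con, sz, origin = "current")
    }
    if (sz %% 2L == 1L) seek(con, 1L, origin = "current")
  }

  if (is.null(fmt))
    vox_io_error(sprintf("'%s' has no fmt chunk (truncated or corrupt header)", path))
  if (is.null(raw_data))
    vox_io_error(sprintf("'%s' has no data chunk (truncated or corrupt file)", path))
  afmt <- fmt$audio_format
  if (afmt == 0xFFFE) afmt <- 1L # WAVE_FORMAT_EXTENSIBLE: assume PCM layout
  if (!afmt %in% c(1L, 3L))
    vox_io_error(sprintf("'%s': unsupported WAVE format code %d", path, afmt))

  x <- decode_pcm(raw_data, fmt$bits, afmt)
  if (fmt$channels > 1L) {
    warning(sprintf("multi-channel WAV (%d channels): using channel 1",
                    fmt$channels), call. = FALSE)
    x <- x[seq(1L, length(x), by = fmt$channels)]
  }
  if (length(x) == 0L)
    vox_validation_error(sprintf("'%s' contains zero-length audio", path))
  voice_recording(x, fmt$sample_rate, fmt$bits)
}

#' Write a 16-bit PCM WAV file
#'
#' @param samples numeric amplitudes in \eqn{[-1, 1]}.
#' @param sample_rate sampling rate in Hz.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_wav <- function(samples, sample_rate, path) {
  q <- as.integer(pmax(pmin(round(samples * 32768), 32767), -32768))
  n_bytes <- length(q) * 2L
  con <- file(path, "wb")
  on.exit(close(con))
  writeChar("RIFF", con, eos = NULL)
  writeBin(as.integer(36L + n_bytes), con, size = 4L, endian = "little")
  writeChar("WAVE", con, eos = NULL)
  writeChar("fmt ", con, eos = NULL)
  writeBin(16L, con, size = 4L, endian = "little")
  writeBin(1L, con, size = 2L, endian = "little")        # PCM
  writeBin(1L, con, size = 2L, endian = "little")        # mono
  writeBin(as.integer(sample_rate), con, size = 4L, endian = "little")
  writeBin(as.integer(sample_rate * 2L), con, size = 4L, endian = "little")
  writeBin(2L, con, size = 2L, endian = "little")        # block align
  writeBin(16L, con, size = 2L, endian = "little")       # bits
  writeChar("data", con, eos = NULL)
  writeBin(n_bytes, con, size = 4L, endian = "little")
  writeBin(q, con, size = 2L, endian = "little")
  invisible(path)
}

#' Select the analysis segment of a recording
#'
#' Applies the sustained-vowel segmentation protocol: recordings longer than
#' 3 s are analyzed on their 3 central seconds; recordings between 1 and 3 s
#' are analyzed whole; recordings under 1 s are rejected as too short for a
#' reliable analysis. The selected samples are a verbatim contiguous slice of
#' the source (no resampling or tapering).
#'
#' @param rec a [voice_recording()] (or an existing `analysis_segment`).
#' @param max_duration maximum analysis duration in seconds (default 3).
#' @param min_duration minimum feasible duration in seconds (default 1).
#' @return An object of class `analysis_segment` with fields `samples`,
#'   `sample_rate`, `start_offset` (seconds into the source) and `duration`.
#' @export
select_analysis_window <- function(rec, max_duration = 3, min_duration = 1) {
  x <- rec$samples
  fs <- rec$sample_rate
  dur <- length(x) / fs
  if (dur < min_duration)
    vox_duration_error(sprintf(
      "emission lasts %.3f s: signals lasting less than %g second cannot be feasibly assessed",
      dur, min_duration))
  if (dur > max_duration) {
    n_keep <- round(max_duration * fs)
    start0 <- floor((length(x) - n_keep) / 2)  # 0-based start index
    x <- x[(start0 + 1L):(start0 + n_keep)]
    start_offset <- start0 / fs
  } else {
    start_offset <- 0
  }
  prev <- if (!is.null(rec$start_offset)) rec$start_offset else 0
  structure(
    list(samples = x, sample_rate = fs,
         start_offset = prev + start_offset,
         duration = length(x) / fs),
    class = "analysis_segment")
}

#' @export
print.analysis_segment <- function(x, ...) {
  cat(sprintf("<analysis_segment> %.3f s @ %d Hz (offset %.3f s)\n",
              x$duration, as.integer(x$sample_rate), x$start_offset))
  invisible(x)
}

# coerce recordings/segments/synthetic voices to an analysis_segment without
# applying the duration rules (internal)
as_segment <- function(x) {
  if (inherits(x, "analysis_segment")) return(x)
  structure(list(samples = x$samples, sample_rate = x$sample_rate,
                 start_offset = 0, duration = length(x$samples) / x$sample_rate),
            class = "analysis_segment")
}
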