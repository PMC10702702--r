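# Shared fixture builders: everything is generated in code at test time.

# segment from a synthetic voice (duration rules applied)
seg_of <- function(voice) {
  select_analysis_window(voice_recording(voice$samples, voice$sample_rate))
}

make_sine <- function(f0, duration = 2, fs = 44100, amp = 0.8) {
  amp * sin(2 * pi * f0 * (0:(round(duration * fs) - 1)) / fs)
}

sine_segment <- function(f0, duration = 2, fs = 44100, amp = 0.8) {
  select_analysis_window(voice_recording(make_sine(f0, duration, fs, amp), fs))
}

# bare impulse train with per-cycle amplitudes (one impulse per period)
impulse_train <- function(period_s, amplitudes, fs = 44100) {
  lens <- round(period_s * fs)
  if (length(lens) == 1L) lens <- rep(lens, length(amplitudes))
  n <- sum(lens)
  x <- numeric(n)
  pos <- cumsum(c(1L, lens[-length(lens)]))
  x[pos] <- amplitudes
  x
}

# hand-built period_sequence for direct perturbation-formula tests
make_seq <- function(periods, amplitudes = rep(1, length(periods)),
                     run = rep(1L, length(periods))) {
  structure(list(cycle_onsets = cumsum(c(0, periods)), periods = periods,
                 amplitudes = amplitudes, run = run,
                 pitch_floor = 75, pitch_ceiling = 600),
            class = "period_sequence")
}

# hand-built pitch_track for statistics/auxiliary tests
make_track <- function(f0_values, voiced = !is.na(f0_values),
                       peak_autocorr = rep(0.95, length(f0_values)),
                       step = 0.01, floor = 75, ceiling = 600) {
  structure(list(frame_times = (seq_along(f0_values) - 1) * step,
                 f0_values = f0_values, voiced_flags = voiced,
                 peak_autocorr = peak_autocorr, pitch_floor = floor,
                 pitch_ceiling = ceiling, step = step),
            class = "pitch_track")
}

# hand-built long-term spectrum for ratio-measure tests
make_spectrum <- function(freqs, power, fs = 44100) {
  db <- 10 * log10(pmax(power / max(power), 1e-10))
  structure(list(freqs = freqs, power = power, magnitude_db = db,
                 sample_rate = fs, nyquist = fs / 2),
            class = "vox_spectrum")
}

# stereo/float WAV writers for exercising the reader's dialect support
write_stereo_wav16 <- function(left, right, fs, path) {
  inter <- as.vector(rbind(left, right))
  q <- as.integer(pmax(pmin(round(inter * 32767), 32767), -32768))
  con <- file(path, "wb")
  on.exit(close(con))
  writeChar("RIFF", con, eos = NULL)
  writeBin(as.integer(36L + length(q) * 2L), con, size = 4L, endian = "little")
  writeChar("WAVE", con, eos = NULL)
  writeChar("fmt ", con, eos = NULL)
  writeBin(16L, con, size = 4L, endian = "little")
  writeBin(1L, con, size = 2L, endian = "little")
  writeBin(2L, con, size = 2L, endian = "little")
  writeBin(as.integer(fs), con, size = 4L, endian = "little")
  writeBin(as.integer(fs * 4L), con, size = 4L, endian = "little")
  writeBin(4L, con, size = 2L, endian = "little")
  writeBin(16L, con, size = 2L, endian = "little")
  writeChar("data", con, eos = NULL)
  writeBin(length(q) * 2L, con, size = 4L, endian = "little")
  writeBin(q, con, size = 2L, endian = "little")
  path
}

write_float_wav <- function(x, fs, path) {
  con <- file(path, "wb")
  on.exit(close(con))
  nb <- length(x) * 4L
  writeChar("RIFF", con, eos = NULL)
  writeBin(as.integer(36L + nb), con, size = 4L, endian = "little")
  writeChar("WAVE", con, eos = NULL)
  writeChar("fmt ", con, eos = NULL)
  writeBin(16L, con, size = 4L, endian = "little")
  writeBin(3L, con, size = 2L, endian = "little")   # IEEE float
  writeBin(1L, con, size = 2L, endian = "little")
  writeBin(as.integer(fs), con, size = 4L, endian = "little")
  writeBin(as.integer(fs * 4L), con, size = 4L, endian = "little")
  writeBin(4L, con, size = 2L, endian = "little")
  writeBin(32L, con, size = 2L, endian = "little")
  writeChar("data", con, eos = NULL)
  writeBin(nb, con, size = 4L, endian = "little")
  writeBin(x, con, size = 4L, endian = "little")
  path
}
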