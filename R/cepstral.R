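# Quefrency-domain analysis: per-frame power cepstra, the cepstral peak
# prominence (CPP), its smoothed variant (CPPS), and the cepstrogram.
#
# Per frame: power cepstrum = |DFT of the log power spectrum|^2 in dB; a
# least-squares line is fitted to the cepstrum over quefrencies >= 1 ms
# (excluding the low-quefrency spectral-envelope bulge); the cepstral peak is
# searched within the pitch band so it cannot lock onto formant quefrencies;
# the prominence is peak minus regression line at the peak quefrency.
# CPPS applies a moving average across time (7 frames) and quefrency
# (11 bins) to the cepstrum matrix before peak picking.

# core engine shared by cepstrum_frame / cpps_series / cepstrogram
vox_cepstra <- function(seg, config = analysis_config()) {
  seg <- as_segment(seg)
  x <- seg$samples
  fs <- seg$sample_rate
  wlen <- round(config$cpps_window * fs)
  if (wlen < round(2 / config$pitch_floor * fs) / 2 || length(x) < wlen)
    vox_validation_error("segment too short for cepstral analysis")
  step_n <- max(1L, round(config$cpps_step * fs))
  starts <- seq(1L, length(x) - wlen + 1L, by = step_n)
  nfft <- next_pow2(wlen)
  w <- hann_window(wlen)

  idx <- outer(0:(wlen - 1L), starts, "+")
  frames <- matrix(x[idx], nrow = wlen) * w
  if (nfft > wlen)
    frames <- rbind(frames, matrix(0, nfft - wlen, ncol(frames)))
  X <- stats::mvfft(frames)
  log_spec <- 10 * log10(pmax(Mod(X)^2, 1e-250))
  C <- stats::mvfft(log_spec)
  half <- nfft %/% 2
  ceps_db <- 10 * log10(pmax(Mod(C[1:(half + 1L), , drop = FALSE])^2, 1e-250))
  quefrencies <- (0:half) / fs

  list(times = (starts - 1 + (wlen - 1) / 2) / fs,
       quefrencies = quefrencies,
       ceps_db = ceps_db,
       fs = fs, config = config)
}

# regression line + pitch-band peak for each column of a cepstrum matrix
ceps_peaks <- function(ceps_db, quefrencies, config) {
  reg <- quefrencies >= 0.001
  q <- quefrencies[reg]
  qc <- q - mean(q)
  denom <- sum(qc^2)
  m <- ceps_db[reg, , drop = FALSE]
  slopes <- colSums(qc * m) / denom
  intercepts <- colMeans(m) - slopes * mean(q)

  band <- quefrencies >= 1 / config$pitch_ceiling &
          quefrencies <= 1 / config$pitch_floor
  qb <- quefrencies[band]
  mb <- ceps_db[band, , drop = FALSE]
  ki <- apply(mb, 2, which.max)
  peak_q <- qb[ki]
  peak_db <- mb[cbind(ki, seq_len(ncol(mb)))]
  line_db <- intercepts + slopes * peak_q
  list(slope = slopes, intercept = intercepts, peak_quefrency = peak_q,
       peak_db = peak_db, line_db = line_db, prominence = peak_db - line_db)
}

#' Cepstral analysis of a single frame
#'
#' @param samples a windowed signal frame (at least two pitch-floor periods
#'   long).
#' @param sample_rate sampling rate in Hz.
#' @param config an [analysis_config()].
#' @return An object of class `cepstrum_frame`: `quefrencies` (s),
#'   `cepstrum_db`, `regression_intercept` (dB), `regression_slope` (dB/s),
#'   `peak_quefrency` (s), `peak_prominence` (dB, the CPP).
#' @export
cepstrum_frame <- function(samples, sample_rate, config = analysis_config()) {
  if (length(samples) < round(2 / config$pitch_floor * sample_rate))
    vox_validation_error("frame shorter than two pitch-floor periods")
  if (all(samples == 0)) {
    n <- next_pow2(length(samples))
    return(structure(list(quefrencies = (0:(n %/% 2)) / sample_rate,
                          cepstrum_db = rep(NA_real_, n %/% 2 + 1L),
                          regression_intercept = NA_real_,
                          regression_slope = NA_real_,
                          peak_quefrency = NA_real_,
                          peak_prominence = NA_real_),
                     class = "cepstrum_frame"))
  }
  n <- length(samples)
  nfft <- next_pow2(n)
  w <- hann_window(n)
  X <- stats::fft(c(samples * w, rep(0, nfft - n)))
  log_spec <- 10 * log10(pmax(Mod(X)^2, 1e-250))
  C <- stats::fft(log_spec)
  half <- nfft %/% 2
  ceps_db <- matrix(10 * log10(pmax(Mod(C[1:(half + 1L)])^2, 1e-250)), ncol = 1)
  quefrencies <- (0:half) / sample_rate
  pk <- ceps_peaks(ceps_db, quefrencies, config)
  structure(list(quefrencies = quefrencies, cepstrum_db = ceps_db[, 1],
                 regression_intercept = pk$intercept,
                 regression_slope = pk$slope,
                 peak_quefrency = pk$peak_quefrency,
                 peak_prominence = pk$prominence),
            class = "cepstrum_frame")
}

#' CPP/CPPS series and statistics
#'
#' Computes per-frame cepstral peak prominences (CPP) and their smoothed
#' counterpart (CPPS: the cepstrum matrix is moving-averaged across time and
#' quefrency before peak picking), with summary statistics over frames and
#' the "CPPS f0" (here read as the frequency equivalent of the median
#' smoothed peak quefrency, `1 / median(peak quefrency)`).
#'
#' @param seg an `analysis_segment` of at least 1 s.
#' @param config an [analysis_config()].
#' @return An object of class `cepstral_series`: `frame_times`, `cpp_values`,
#'   `cpps_values` (dB), unsmoothed and smoothed peak/line levels, `stats`
#'   (mean, sd, q1, median, q3, min, max in dB, cv in percent over the CPPS
#'   values), and `cpps_f0` (Hz).
#' @export
cpps_series <- function(seg, config = analysis_config()) {
  seg <- as_segment(seg)
  if (seg$duration < 1)
    vox_validation_error("CPPS needs at least 1 s of signal")
  ce <- vox_cepstra(seg, config)
  if (ncol(ce$ceps_db) < 11L)
    vox_validation_error("too few cepstral frames (< 11)")

  raw_pk <- ceps_peaks(ce$ceps_db, ce$quefrencies, config)
  sm <- moving_average_mat(ce$ceps_db, config$cpps_time_smooth, margin = 2L)
  sm <- moving_average_mat(sm, config$cpps_quefrency_smooth, margin = 1L)
  sm_pk <- ceps_peaks(sm, ce$quefrencies, config)

  v <- sm_pk$prominence
  q <- stats::quantile(v, c(0.25, 0.5, 0.75), names = FALSE, type = 7)
  m <- mean(v)
  s <- stats::sd(v)
  structure(list(
    frame_times = ce$times,
    cpp_values = raw_pk$prominence,
    cpp_peak_db = raw_pk$peak_db, cpp_line_db = raw_pk$line_db,
    cpps_values = v,
    cpps_peak_db = sm_pk$peak_db, cpps_line_db = sm_pk$line_db,
    peak_quefrency = sm_pk$peak_quefrency,
    stats = list(mean = m, sd = s, q1 = q[1], median = q[2], q3 = q[3],
                 min = min(v), max = max(v),
                 cv = if (m != 0) 100 * s / m else NA_real_),
    cpps_f0 = 1 / stats::median(sm_pk$peak_quefrency)),
    class = "cepstral_series")
}

#' @export
print.cepstral_series <- function(x, ...) {
  cat(sprintf("<cepstral_series> %d frames, CPPS mean %.2f dB (sd %.2f), CPPS f0 %.1f Hz\n",
              length(x$frame_times), x$stats$mean, x$stats$sd, x$cpps_f0))
  invisible(x)
}

#' Cepstrogram
#'
#' Matrix of per-frame (pre-smoothing) power cepstra with both axes in
#' seconds; the quefrency axis is limited to `1 / pitch_floor`.
#'
#' @param seg an `analysis_segment`.
#' @param config an [analysis_config()].
#' @return An object of class `vox_cepstrogram`: `times` (s), `quefrencies`
#'   (s), `cepstrum_db` (quefrency x time matrix).
#' @export
cepstrogram <- function(seg, config = analysis_config()) {
  ce <- vox_cepstra(seg, config)
  keep <- ce$quefrencies <= 1 / config$pitch_floor
  structure(list(times = ce$times, quefrencies = ce$quefrencies[keep],
                 cepstrum_db = ce$ceps_db[keep, , drop = FALSE]),
            class = "vox_cepstrogram")
}
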