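# Frame-wise f0 and voicing, glottal-cycle extraction, intensity trace, and
# the auxiliary voicing statistics (mean correlation, voice breaks, unvoiced
# frames).

#' Estimate a pitch track by normalized autocorrelation
#'
#' Classic short-term autocorrelation pitch analysis: each frame (window
#' length `3 / pitch_floor`) is mean-subtracted, Hann-windowed, and its
#' autocorrelation is normalized by lag 0 and divided by the window's own
#' autocorrelation to undo the taper bias. Candidate lags span the pitch band;
#' a small per-octave bonus on shorter lags prevents locking one octave down.
#' The best lag is refined by parabolic interpolation. A frame is voiced when
#' its normalized autocorrelation peak reaches the voicing threshold and its
#' amplitude clears the silence threshold.
#'
#' @param seg an `analysis_segment` (or any object with `samples` and
#'   `sample_rate`).
#' @param config an [analysis_config()] supplying the pitch band, frame step
#'   and thresholds.
#' @return An object of class `pitch_track`: `frame_times` (s), `f0_values`
#'   (Hz, `NA` on unvoiced frames), `voiced_flags`, `peak_autocorr` (in
#'   \eqn{[0, 1]} on voiced frames), `pitch_floor`, `pitch_ceiling`, `step`.
#' @export
estimate_pitch <- function(seg, config = analysis_config()) {
  seg <- as_segment(seg)
  x <- seg$samples
  fs <- seg$sample_rate
  floor_hz <- config$pitch_floor
  ceil_hz <- config$pitch_ceiling
  if (!(floor_hz > 0 && floor_hz < ceil_hz && ceil_hz < fs / 2))
    vox_config_error("need 0 < pitch_floor < pitch_ceiling < sample_rate/2")

  wlen <- round(3 / floor_hz * fs)
  if (wlen > length(x))
    vox_validation_error(sprintf(
      "segment (%.3f s) is shorter than one pitch analysis window (%.3f s)",
      length(x) / fs, wlen / fs))
  step_n <- max(1L, round(config$pitch_step * fs))
  starts <- seq(1L, length(x) - wlen + 1L, by = step_n)
  frame_times <- (starts - 1 + (wlen - 1) / 2) / fs

  w <- hann_window(wlen)
  nfft <- next_pow2(2L * wlen)
  rw <- Re(stats::fft(Mod(stats::fft(c(w, rep(0, nfft - wlen))))^2,
                      inverse = TRUE))
  rw <- rw / rw[1]

  lag_min <- max(2L, floor(fs / ceil_hz))
  lag_max <- min(wlen - 1L, ceiling(fs / floor_hz))
  lags <- lag_min:lag_max
  global_peak <- max(abs(x))

  n_f <- length(starts)
  f0 <- rep(NA_real_, n_f)
  voiced <- logical(n_f)
  rpeak <- rep(NA_real_, n_f)
  candidates <- vector("list", n_f)

  # per-frame pitch candidates: local maxima of the corrected autocorrelation,
  # each refined by parabolic interpolation
  for (j in seq_len(n_f)) {
    fr <- x[starts[j]:(starts[j] + wlen - 1L)]
    if (global_peak <= 0 ||
        max(abs(fr)) < config$silence_threshold * global_peak) next
    fr <- (fr - mean(fr)) * w
    acf_fr <- Re(stats::fft(Mod(stats::fft(c(fr, rep(0, nfft - wlen))))^2,
                            inverse = TRUE))
    if (acf_fr[1] <= .Machine$double.eps) next
    r <- (acf_fr / acf_fr[1]) / rw
    rr <- r[lags + 1L]
    nr <- length(rr)
    ks <- which(rr[2:(nr - 1L)] >= rr[1:(nr - 2L)] &
                rr[2:(nr - 1L)] >= rr[3:nr]) + 1L
    if (length(ks) == 0L) next
    cand_lag <- cand_r <- numeric(length(ks))
    for (i in seq_along(ks)) {
      k <- ks[i]
      denom <- rr[k - 1L] - 2 * rr[k] + rr[k + 1L]
      delta <- 0
      peak <- rr[k]
      if (is.finite(denom) && abs(denom) > .Machine$double.eps) {
        delta <- max(min(0.5 * (rr[k - 1L] - rr[k + 1L]) / denom, 0.5), -0.5)
        peak <- rr[k] - 0.25 * (rr[k - 1L] - rr[k + 1L]) * delta
      }
      cand_lag[i] <- lags[k] + delta
      cand_r[i] <- max(0, min(1, peak))
    }
    keep <- fs / cand_lag >= floor_hz & fs / cand_lag <= ceil_hz
    if (!any(keep)) next
    ord <- order(cand_r[keep], decreasing = TRUE)[seq_len(min(5L, sum(keep)))]
    candidates[[j]] <- list(lag = cand_lag[keep][ord], r = cand_r[keep][ord])
  }

  # first pass: octave-cost-penalized best candidate per frame
  choose <- function(extra_penalty) {
    for (j in seq_len(n_f)) {
      cand <- candidates[[j]]
      if (is.null(cand)) next
      score <- cand$r - config$octave_cost * log2(floor_hz * cand$lag / fs) -
        extra_penalty(fs / cand$lag)
      b <- which.max(score)
      rpeak[j] <<- cand$r[b]
      if (cand$r[b] >= config$voicing_threshold) {
        voiced[j] <<- TRUE
        f0[j] <<- fs / cand$lag[b]
      } else {
        voiced[j] <<- FALSE
        f0[j] <<- NA_real_
      }
    }
  }
  choose(function(f) 0)
  # second pass: on a sustained vowel the f0 is near-stationary, so penalize
  # candidates far (in octaves) from the first-pass median; this suppresses
  # occasional sub-harmonic locking when the corrected autocorrelation
  # saturates at both the true and the doubled lag
  if (sum(voiced) >= 5L) {
    med <- stats::median(f0[voiced])
    choose(function(f) 0.2 * abs(log2(f / med)))
  }

  structure(list(frame_times = frame_times, f0_values = f0,
                 voiced_flags = voiced, peak_autocorr = rpeak,
                 pitch_floor = floor_hz, pitch_ceiling = ceil_hz,
                 step = step_n / fs),
            class = "pitch_track")
}

#' @export
print.pitch_track <- function(x, ...) {
  nv <- sum(x$voiced_flags)
  cat(sprintf("<pitch_track> %d frames (%d voiced), band %g-%g Hz, mean f0 %s Hz\n",
              length(x$frame_times), nv, x$pitch_floor, x$pitch_ceiling,
              if (nv > 0) sprintf("%.1f", mean(x$f0_values[x$voiced_flags]))
              else "--"))
  invisible(x)
}

#' Extract glottal cycles from a segment
#'
#' Marks one cycle onset per glottal period by waveform matching: starting
#' from a dominant extremum in the first voiced window (whose polarity is
#' fixed once and applied globally), the next onset is predicted as the lag
#' in \eqn{[0.75, 1.25] / f_0} that maximizes the normalized
#' cross-correlation between the current cycle's waveform and its shifted
#' copy, then snapped to the nearest local extremum of the chosen polarity
#' (within 0.35 ms). Matching whole cycle shapes is robust to additive
#' noise, which can otherwise flip the choice between neighbouring formant
#' ringing peaks; the local-extremum snap pins the mark to a consistent
#' waveform landmark. No cycle ever spans an unvoiced gap, and cycles whose
#' period falls outside the pitch band are dropped (breaking the run so no
#' perturbation difference is formed across them).
#'
#' @param seg an `analysis_segment`.
#' @param track a `pitch_track` from [estimate_pitch()].
#' @return An object of class `period_sequence`: `cycle_onsets` (s),
#'   `periods` (s), `amplitudes` (per-cycle peak absolute amplitude), and
#'   `run` (integer label; perturbation differences are only taken within a
#'   run).
#' @export
extract_periods <- function(seg, track) {
  seg <- as_segment(seg)
  x <- seg$samples
  fs <- seg$sample_rate
  n <- length(x)
  runs <- voiced_runs(track$voiced_flags)
  if (nrow(runs) == 0L || max(runs$end - runs$start + 1L) < 3L)
    vox_validation_error("insufficient voiced cycles: need >= 3 consecutive voiced frames")

  # cycle-marking polarity from the first voiced window, applied globally
  j0 <- runs$start[which.max(runs$end - runs$start)[1]]
  c0 <- round(track$frame_times[j0] * fs) + 1L
  T_med <- 1 / stats::median(track$f0_values[track$voiced_flags])
  i_hi <- min(n, c0 + round(3 * T_med * fs))
  pol <- if (abs(max(x[c0:i_hi])) >= abs(min(x[c0:i_hi]))) 1 else -1
  snap <- max(3L, round(0.00035 * fs))  # local-extremum snap radius

  onsets_all <- numeric(0)
  periods <- numeric(0)
  amplitudes <- numeric(0)
  run_id <- integer(0)
  cur_run <- 0L

  for (ri in seq_len(nrow(runs))) {
    idx <- runs$start[ri]:runs$end[ri]
    if (length(idx) < 2L) next
    tt <- track$frame_times[idx]
    ff <- track$f0_values[idx]
    t_a <- tt[1]
    t_b <- tt[length(tt)]
    T0 <- 1 / ff[1]
    s_lo <- max(1L, round(t_a * fs) + 1L)
    s_hi <- min(n, s_lo + round(1.5 * T0 * fs))
    if (s_hi - s_lo < 3L) next
    pos <- s_lo - 1L + which.max(pol * x[s_lo:s_hi])
    onsets <- pos
    t_cur <- T0 * fs  # running period estimate in samples
    repeat {
      L <- round(0.8 * t_cur)
      lags <- floor(0.75 * t_cur):ceiling(1.25 * t_cur)
      if ((pos + max(lags) + L + snap) / fs > t_b + track$step / 2 ||
          pos + max(lags) + L + snap > n) break
      a <- x[pos:(pos + L - 1L)]
      m <- matrix(x[outer(0:(L - 1L), pos + lags, "+")], nrow = L)
      cc <- as.vector(crossprod(a, m)) /
        sqrt(sum(a^2) * colSums(m^2) + .Machine$double.xmin)
      pred <- pos + lags[which.max(cc)]
      w <- pol * x[(pred - snap):(pred + snap)]
      locmax <- which(diff(sign(diff(w))) < 0) + 1L
      if (length(locmax) > 1L)  # collapse plateau edges to one landmark
        locmax <- locmax[c(TRUE, diff(locmax) > 2L)]
      nxt <- if (length(locmax) > 0L)
        (pred - snap - 1L) + locmax[which.min(abs(locmax - (snap + 1L)))]
      else pred
      onsets <- c(onsets, nxt)
      t_cur <- 0.9 * t_cur + 0.1 * (nxt - pos)
      pos <- nxt
    }
    if (length(onsets) < 2L) next
    onsets <- (onsets - 1L) / fs
    t_min <- 1 / track$pitch_ceiling
    t_max <- 1 / track$pitch_floor
    cur_run <- cur_run + 1L
    onsets_all <- c(onsets_all, onsets)
    for (i in seq_len(length(onsets) - 1L)) {
      p <- onsets[i + 1L] - onsets[i]
      if (p < t_min || p > t_max) {
        cur_run <- cur_run + 1L  # dropped cycle: never difference across it
        next
      }
      # per-cycle peak amplitude from a window centered on the cycle mark:
      # wide enough to hold the excitation peak, narrow enough to exclude
      # the neighbouring cycles' peaks
      half <- round(0.35 * p * fs)
      c_i <- round(onsets[i] * fs) + 1L
      i1 <- max(1L, c_i - half)
      i2 <- min(length(x), c_i + half)
      periods <- c(periods, p)
      amplitudes <- c(amplitudes, max(abs(x[i1:i2])))
      run_id <- c(run_id, cur_run)
    }
  }

  if (length(periods) < 3L)
    vox_validation_error("insufficient voiced cycles: fewer than 3 periods extracted")
  structure(list(cycle_onsets = onsets_all, periods = periods,
                 amplitudes = amplitudes, run = run_id,
                 pitch_floor = track$pitch_floor,
                 pitch_ceiling = track$pitch_ceiling),
            class = "period_sequence")
}

#' @export
print.period_sequence <- function(x, ...) {
  cat(sprintf("<period_sequence> %d cycles in %d voiced run(s), mean period %.4f ms\n",
              length(x$periods), length(unique(x$run)),
              1000 * mean(x$periods)))
  invisible(x)
}

#' Auxiliary voicing measures
#'
#' Summarizes a pitch track the way voice reports do: the mean normalized
#' autocorrelation peak over voiced frames ("mean correlation", akin to a
#' Pearson r of the signal with itself one period later), the percentage of
#' unvoiced frames, and voice breaks. A voice break is a maximal unvoiced
#' run, interior to the segment (runs touching either edge do not count),
#' lasting longer than `voice_break_factor / pitch_floor` seconds.
#'
#' @param track a `pitch_track`.
#' @param config an [analysis_config()].
#' @return A list: `mean_correlation` (`NA` if no voiced frame),
#'   `unvoiced_fraction` (percent), `n_voice_breaks`, and
#'   `voice_break_fraction` (percent of total time).
#' @export
auxiliary_measures <- function(track, config = analysis_config()) {
  n <- length(track$voiced_flags)
  if (n == 0L) vox_validation_error("empty pitch track")
  voiced <- track$voiced_flags
  mean_corr <- if (any(voiced)) mean(track$peak_autocorr[voiced]) else NA_real_
  unvoiced_fraction <- 100 * sum(!voiced) / n

  thr <- config$voice_break_factor / track$pitch_floor
  r <- rle(voiced)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1L
  interior <- !r$values & starts > 1L & ends < n
  durations <- r$lengths * track$step
  is_break <- interior & durations > thr
  total_time <- n * track$step
  list(mean_correlation = mean_corr,
       unvoiced_fraction = unvoiced_fraction,
       n_voice_breaks = sum(is_break),
       voice_break_fraction = 100 * sum(durations[is_break]) / total_time)
}

#' Intensity trace
#'
#' Per-frame RMS level in dB, `20 log10(RMS / 2e-5)`, treating digital full
#' scale 1.0 as nominal. This mirrors the uncalibrated convention of common
#' voice-analysis software: it is not SPL-calibrated. Digital-zero frames are
#' clamped to the -100 dB floor.
#'
#' @param seg an `analysis_segment`.
#' @param config an [analysis_config()] (frame step `pitch_step`, window
#'   `intensity_window`).
#' @return An object of class `intensity_track`: `frame_times`,
#'   `intensity_db`.
#' @export
intensity_trace <- function(seg, config = analysis_config()) {
  seg <- as_segment(seg)
  x <- seg$samples
  fs <- seg$sample_rate
  if (length(x) == 0L) vox_validation_error("empty segment")
  wlen <- min(length(x), max(2L, round(config$intensity_window * fs)))
  step_n <- max(1L, round(config$pitch_step * fs))
  starts <- seq(1L, length(x) - wlen + 1L, by = step_n)
  rms <- vapply(starts, function(s) sqrt(mean(x[s:(s + wlen - 1L)]^2)),
                numeric(1))
  db <- ifelse(rms > 0, 20 * log10(rms / 2e-5), -Inf)
  structure(list(frame_times = (starts - 1 + (wlen - 1) / 2) / fs,
                 intensity_db = pmax(db, VOX_DB_FLOOR)),
            class = "intensity_track")
}

#' Export a trace as a tab-separated table
#'
#' Writes `(time, value)` pairs of a pitch or intensity track for external
#' inspection.
#'
#' @param track a `pitch_track` or `intensity_track`.
#' @param path output TSV path.
#' @return `path`, invisibly.
#' @export
export_trace <- function(track, path) {
  if (inherits(track, "pitch_track")) {
    df <- data.frame(time = track$frame_times, f0 = track$f0_values)
  } else if (inherits(track, "intensity_track")) {
    df <- data.frame(time = track$frame_times, intensity_db = track$intensity_db)
  } else {
    vox_validation_error("export_trace expects a pitch_track or intensity_track")
  }
  utils::write.table(df, path, sep = "\t", row.names = FALSE, quote = FALSE)
  invisible(path)
}
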