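# Time-domain scalar measures: f0 statistics, period statistics, and the
# jitter and shimmer perturbation families (MDVP-style formulas).
#
# All differences and moving averages are computed within voiced runs only
# and then pooled, so no perturbation term ever spans an unvoiced gap.
# Quartiles use linear interpolation between order statistics (quantile
# type 7); standard deviations are sample (n-1) SDs throughout.

#' f0 distribution statistics
#'
#' @param track a `pitch_track`.
#' @return A list of class `f0_stats`: `mean`, `sd`, `q1`, `median`, `q3`,
#'   `min`, `max` (Hz) and `cv` (percent, `100 * sd / mean`).
#' @export
f0_statistics <- function(track) {
  f0 <- track$f0_values[track$voiced_flags]
  if (length(f0) < 2L)
    vox_validation_error("f0 statistics need at least 2 voiced frames")
  q <- stats::quantile(f0, c(0.25, 0.5, 0.75), names = FALSE, type = 7)
  m <- mean(f0)
  s <- stats::sd(f0)
  structure(list(mean = m, sd = s, q1 = q[1], median = q[2], q3 = q[3],
                 min = min(f0), max = max(f0), cv = 100 * s / m),
            class = "f0_stats")
}

#' Period statistics
#'
#' Mean period, its sample standard deviation (PSD, seconds), and the
#' natural logarithm of that standard deviation (NLPSD, dimensionless).
#' A perfectly periodic sequence has PSD 0, for which NLPSD is reported as
#' `-Inf` and flagged downstream.
#'
#' @param seq a `period_sequence`.
#' @return A list of class `period_stats`: `mean_period`, `psd`, `nlpsd`.
#' @export
period_statistics <- function(seq) {
  t <- seq$periods
  if (length(t) < 2L)
    vox_validation_error("period statistics need at least 2 periods")
  psd <- stats::sd(t)
  structure(list(mean_period = mean(t), psd = psd,
                 nlpsd = if (psd > 0) log(psd) else -Inf),
            class = "period_stats")
}

# pooled first differences within runs
run_diffs <- function(values, run) {
  unlist(lapply(split(values, run), function(v)
    if (length(v) >= 2L) diff(v) else numeric(0)), use.names = FALSE)
}

# pooled |value - centered moving average of width k| within runs
run_apq_devs <- function(values, run, k) {
  h <- (k - 1L) %/% 2L
  unlist(lapply(split(values, run), function(v) {
    n <- length(v)
    if (n < k) return(numeric(0))
    vapply((h + 1L):(n - h), function(i) abs(v[i] - mean(v[(i - h):(i + h)])),
           numeric(1))
  }), use.names = FALSE)
}

#' Jitter measures
#'
#' The MDVP/voice-report jitter family on extracted glottal periods
#' \eqn{T_i}:
#' \itemize{
#'   \item local, absolute: mean absolute consecutive period difference (s);
#'   \item local: the same, as a percentage of the mean period;
#'   \item RAP: mean absolute deviation from the 3-point moving average,
#'     percent of mean period;
#'   \item PPQ5: as RAP with a 5-point moving average;
#'   \item DDP: mean absolute difference of consecutive period differences,
#'     percent of mean period (identically `3 * RAP`).
#' }
#' Measures whose minimum cycle count is not met are returned as `NA`; the
#' remaining measures are still computed.
#'
#' @param seq a `period_sequence`.
#' @return A list of class `jitter_measures`: `local` (%),
#'   `local_absolute` (s), `rap` (%), `ppq5` (%), `ddp` (%).
#' @export
jitter_measures <- function(seq) {
  t <- seq$periods
  run <- seq$run
  mt <- mean(t)
  d1 <- run_diffs(t, run)
  local_abs <- if (length(d1) >= 1L) mean(abs(d1)) else NA_real_
  local <- if (is.na(local_abs)) NA_real_ else 100 * local_abs / mt
  rap_dev <- run_apq_devs(t, run, 3L)
  rap <- if (length(rap_dev) >= 1L) 100 * mean(rap_dev) / mt else NA_real_
  ppq_dev <- run_apq_devs(t, run, 5L)
  ppq5 <- if (length(ppq_dev) >= 1L) 100 * mean(ppq_dev) / mt else NA_real_
  # second differences within runs, pooled
  d2 <- unlist(lapply(split(t, run), function(v)
    if (length(v) >= 3L) diff(diff(v)) else numeric(0)), use.names = FALSE)
  ddp <- if (length(d2) >= 1L) 100 * mean(abs(d2)) / mt else NA_real_
  structure(list(local = local, local_absolute = local_abs, rap = rap,
                 ppq5 = ppq5, ddp = ddp),
            class = "jitter_measures")
}

#' Shimmer measures
#'
#' The MDVP/voice-report shimmer family on per-cycle peak amplitudes
#' \eqn{A_i}: local (%), local in dB (mean `|20 log10(A_{i+1}/A_i)|`), APQ3,
#' APQ5 and APQ11 (mean absolute deviation from the 3/5/11-point moving
#' average, percent of mean amplitude), and DDA (identically `3 * APQ3`).
#' Cycles with non-positive amplitude are excluded from the dB computation
#' with a warning. Measures with too few cycles are `NA`.
#'
#' @param seq a `period_sequence`.
#' @return A list of class `shimmer_measures`: `local` (%), `local_db` (dB),
#'   `apq3`, `apq5`, `apq11`, `dda` (%).
#' @export
shimmer_measures <- function(seq) {
  a <- seq$amplitudes
  run <- seq$run
  ma <- mean(a)
  d1 <- run_diffs(a, run)
  local <- if (length(d1) >= 1L) 100 * mean(abs(d1)) / ma else NA_real_

  db_ratios <- unlist(lapply(split(a, run), function(v) {
    if (length(v) < 2L) return(numeric(0))
    ok <- v > 0
    if (!all(ok)) {
      warning("non-positive cycle amplitude excluded from shimmer (dB)",
              call. = FALSE)
      v <- v[ok]
      if (length(v) < 2L) return(numeric(0))
    }
    abs(20 * log10(v[-1] / v[-length(v)]))
  }), use.names = FALSE)
  local_db <- if (length(db_ratios) >= 1L) mean(db_ratios) else NA_real_

  apq <- function(k) {
    dev <- run_apq_devs(a, run, k)
    if (length(dev) >= 1L) 100 * mean(dev) / ma else NA_real_
  }
  apq3 <- apq(3L)
  structure(list(local = local, local_db = local_db, apq3 = apq3,
                 apq5 = apq(5L), apq11 = apq(11L),
                 dda = if (is.na(apq3)) NA_real_ else 3 * apq3),
            class = "shimmer_measures")
}
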