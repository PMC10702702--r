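# Glottal-to-noise excitation ratio (GNE).
#
# Construction: downsample to 10 kHz; approximate the glottal excitation by
# frame-wise LPC inverse filtering (order 13, 30 ms frames); compute Hilbert
# envelopes of the excitation band-passed at centers stepping 100 Hz across
# the 0-5 kHz range with the requested bandwidth; GNE is the maximum
# cross-correlation, over lags up to 0.3 ms, between envelope pairs whose
# centers are at least half a bandwidth apart. Pulse-like excitation excites
# all bands synchronously (GNE near 1); turbulent noise decorrelates the
# envelopes.

GNE_RATE <- 10000
GNE_LPC_ORDER <- 13L
GNE_FRAME_S <- 0.030
GNE_CENTER_STEP <- 100
GNE_MAX_LAG_S <- 0.0003

# frame-wise LPC inverse filter: returns the prediction residual
gne_residual <- function(x, fs, order = GNE_LPC_ORDER, frame_s = GNE_FRAME_S) {
  flen <- round(frame_s * fs)
  n <- length(x)
  if (n < flen)
    vox_validation_error("segment too short for one 30 ms GNE frame")
  res <- numeric(n)
  starts <- seq(1L, n - flen + 1L, by = flen)
  for (s in starts) {
    e <- min(n, s + flen - 1L)
    fr <- x[s:e]
    a <- tryCatch(
      stats::ar(fr, aic = FALSE, order.max = order, method = "yule-walker",
                demean = TRUE)$ar,
      error = function(e) numeric(0))
    if (length(a) == 0L) {
      res[s:e] <- fr - mean(fr)
    } else {
      fr0 <- fr - mean(fr)
      pred <- as.numeric(stats::filter(fr0, a, method = "convolution",
                                       sides = 1))
      pred <- c(0, pred[-length(pred)])
      pred[is.na(pred)] <- 0
      res[s:e] <- fr0 - pred
    }
  }
  # trailing partial frame: keep residual of last full frame's model region
  if (max(starts) + flen - 1L < n) {
    s <- max(starts) + flen
    res[s:n] <- x[s:n] - mean(x[s:n])
  }
  res
}

# Hilbert envelopes of Hann-shaped bands centered at `centers`, bandwidth bw
gne_band_envelopes <- function(res, fs, centers, bw) {
  n <- length(res)
  X <- stats::fft(res)
  f <- (0:(n - 1)) * fs / n
  env <- matrix(0, n, length(centers))
  for (j in seq_along(centers)) {
    fc <- centers[j]
    h <- numeric(n)
    pos <- f <= fs / 2
    d <- abs(f - fc)
    sel <- pos & d <= bw / 2
    h[sel] <- 0.5 * (1 + cos(pi * d[sel] / (bw / 2))) # Hann-shaped band
    Y <- X * h
    # analytic signal: zero negative frequencies, double positive ones
    Y[!pos] <- 0
    keep <- f > 0 & f < fs / 2
    Y[keep] <- 2 * Y[keep]
    env[, j] <- Mod(stats::fft(Y, inverse = TRUE) / n)
  }
  env
}

#' Glottal-to-noise excitation ratio
#'
#' @param seg an `analysis_segment`.
#' @param bandwidth analysis bandwidth in Hz; one of 1000, 2000 or 3000.
#' @return GNE, dimensionless in \eqn{[0, 1]}.
#' @export
gne <- function(seg, bandwidth) {
  if (!bandwidth %in% c(1000, 2000, 3000))
    vox_config_error("unsupported GNE bandwidth: must be 1000, 2000 or 3000 Hz")
  seg <- as_segment(seg)
  x <- seg$samples
  fs <- seg$sample_rate
  if (fs != GNE_RATE)
    x <- as.numeric(signal::resample(x, p = GNE_RATE, q = round(fs)))
  res <- gne_residual(x, GNE_RATE)

  centers <- seq(bandwidth / 2, GNE_RATE / 2 - bandwidth / 2,
                 by = GNE_CENTER_STEP)
  env <- gne_band_envelopes(res, GNE_RATE, centers, bandwidth)
  env <- sweep(env, 2, colMeans(env))
  sds <- apply(env, 2, stats::sd)
  ok <- sds > 0
  env <- env[, ok, drop = FALSE]
  centers <- centers[ok]
  if (ncol(env) < 2L) return(NA_real_)

  sep <- abs(outer(centers, centers, "-"))
  pair_mask <- sep >= bandwidth / 2
  if (!any(pair_mask)) return(NA_real_)
  max_lag <- round(GNE_MAX_LAG_S * GNE_RATE)
  n <- nrow(env)
  best <- -1
  for (lag in 0:max_lag) {
    if (lag == 0L) {
      cc <- stats::cor(env)
      cand <- max(cc[pair_mask])
    } else {
      a <- env[(1 + lag):n, , drop = FALSE]
      b <- env[1:(n - lag), , drop = FALSE]
      cc1 <- stats::cor(a, b)  # envelope i delayed vs j
      cand <- max(pmax(cc1, t(cc1))[pair_mask])
    }
    if (cand > best) best <- cand
  }
  max(0, min(1, best))
}
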