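# Frequency-domain analysis: long-term Fourier spectrum, LPC envelope,
# narrowband spectrogram, and the spectral noise/shape measures (HNR, HNRD,
# HFNO, H1-H2, decline, tilt).
#
# HNRD, HFNO, decline and tilt are reported under declared conventions (comb
# harmonic/noise split below 5 kHz; 6-10 kHz relative noise level; harmonic
# peak regressions against frequency and log2-frequency); each lives behind
# its own function so an alternative convention can be swapped in.

#' Long-term Fourier spectrum
#'
#' Single Hann-windowed DFT of the whole analysis segment. The one-sided
#' power is window-compensated so that total spectral power equals the
#' windowed time-domain mean power; dB magnitudes are relative to the
#' spectral maximum with a -100 dB floor. Band-limited report panels are
#' slices of this one spectrum.
#'
#' @param seg an `analysis_segment`.
#' @return An object of class `vox_spectrum`: `freqs` (Hz, 0..Nyquist),
#'   `power` (linear, one-sided), `magnitude_db`, `sample_rate`, `nyquist`.
#' @export
fourier_spectrum <- function(seg) {
  seg <- as_segment(seg)
  x <- seg$samples
  fs <- seg$sample_rate
  n <- length(x)
  if (n == 0L) vox_validation_error("empty segment")
  w <- hann_window(n)
  X <- stats::fft(x * w)
  half <- floor(n / 2)
  k <- 0:half
  p <- Mod(X[k + 1])^2
  mult <- rep(2, length(k))
  mult[1] <- 1
  if (n %% 2 == 0) mult[length(k)] <- 1
  power <- mult * p / (n * sum(w^2))
  pmax_ <- max(power)
  db <- if (pmax_ > 0) power_db(power, pmax_) else rep(VOX_DB_FLOOR, length(power))
  structure(list(freqs = k * fs / n, power = power, magnitude_db = db,
                 sample_rate = fs, nyquist = fs / 2),
            class = "vox_spectrum")
}

#' @export
print.vox_spectrum <- function(x, ...) {
  cat(sprintf("<vox_spectrum> %d bins, 0-%.0f Hz, df = %.3f Hz\n",
              length(x$freqs), x$nyquist, x$freqs[2] - x$freqs[1]))
  invisible(x)
}

#' LPC spectral envelope
#'
#' Downsamples the segment to `lpc_rate` (default 11025 Hz) and fits an
#' autocorrelation-method (Yule-Walker) linear predictor, rendering the
#' all-pole envelope up to `lpc_rate / 2` (5.5 kHz at the default), gain
#' matched so its mean equals the Fourier spectrum's mean level over the
#' same band.
#'
#' @param seg an `analysis_segment`.
#' @param order predictor order; default `round(rate_kHz) + 5` (16 at
#'   11025 Hz).
#' @param config an [analysis_config()].
#' @return An object of class `lpc_envelope`: `freqs` (Hz), `envelope_db`,
#'   `order`.
#' @export
lpc_envelope <- function(seg, order = NULL, config = analysis_config()) {
  seg <- as_segment(seg)
  fs <- seg$sample_rate
  rate <- config$lpc_rate
  order <- order %||% default_lpc_order(config)
  if (order < 1L) vox_config_error("LPC order must be a positive integer")
  x <- seg$samples
  if (fs > rate) {
    x <- as.numeric(signal::resample(x, p = round(rate), q = round(fs)))
  } else {
    rate <- fs
  }
  # first-order pre-emphasis flattens the glottal-source tilt so the poles
  # model the vocal-tract resonances rather than the low-frequency bulk;
  # the moderate coefficient keeps the zero well inside what the all-pole
  # fit can absorb, and its response is divided back out below
  alpha <- 0.8
  x <- c(x[1], x[-1] - alpha * x[-length(x)])
  fit <- stats::ar(x, aic = FALSE, order.max = order, method = "yule-walker",
                   demean = TRUE)
  a <- fit$ar
  # roots of 1 - sum a_j x^j are the reciprocals of the predictor poles:
  # stability requires them all outside the unit circle
  roots <- polyroot(c(1, -a))
  if (any(Mod(roots) <= 1 + 1e-12))
    vox_error(sprintf(
      "unstable LPC filter (pole modulus %.6f); try a lower order than %d",
      max(1 / Mod(roots)), order), "vox_validation_error")

  freqs <- seq(0, rate / 2, length.out = 512L)
  om <- 2 * pi * freqs / rate
  # A(e^{i om}) = 1 - sum_j a_j e^{-i om j}
  A <- rep(1 + 0i, length(om))
  for (j in seq_along(a)) A <- A - a[j] * exp(-1i * om * j)
  env_db <- 10 * log10(pmax(fit$var.pred, 1e-300)) - 20 * log10(pmax(Mod(A), 1e-150))
  # undo the pre-emphasis response so the envelope overlays the raw spectrum
  env_db <- env_db - 20 * log10(pmax(Mod(1 - alpha * exp(-1i * om)), 1e-6))

  spec <- fourier_spectrum(seg)
  band <- spec$freqs <= rate / 2
  env_db <- env_db - mean(env_db) + mean(spec$magnitude_db[band])
  structure(list(freqs = freqs, envelope_db = env_db, order = as.integer(order)),
            class = "lpc_envelope")
}

#' Narrowband spectrogram
#'
#' Gaussian-windowed STFT with a long (default 30 ms) window and 2 ms hop:
#' the frequency resolution is finer than a typical f0, so individual
#' harmonics resolve as horizontal stripes. Power is in dB relative to the
#' spectrogram maximum, floored at -100 dB; the frequency axis is kept up to
#' 5 kHz, the conventional narrowband viewing range.
#'
#' @param seg an `analysis_segment`.
#' @param config an [analysis_config()].
#' @return An object of class `vox_spectrogram`: `times` (s), `freqs` (Hz),
#'   `power_db` (frequency x time matrix), `window_length` (s).
#' @export
narrowband_spectrogram <- function(seg, config = analysis_config()) {
  seg <- as_segment(seg)
  x <- seg$samples
  fs <- seg$sample_rate
  wlen <- round(config$spectrogram_window * fs)
  if (length(x) < wlen)
    vox_validation_error("segment shorter than one spectrogram window")
  step_n <- max(1L, round(config$spectrogram_step * fs))
  w <- gaussian_window(wlen)
  nfft <- next_pow2(wlen)
  st <- vox_stft(x, fs, wlen, step_n, w, nfft)
  keep <- st$freqs <= 5000
  p <- st$power[keep, , drop = FALSE]
  pm <- max(p)
  db <- if (pm > 0) matrix(power_db(p, pm), nrow = nrow(p))
        else matrix(VOX_DB_FLOOR, nrow(p), ncol(p))
  structure(list(times = st$times, freqs = st$freqs[keep], power_db = db,
                 window_length = wlen / fs),
            class = "vox_spectrogram")
}

# shared STFT: returns linear one-sided power matrix (freq x time)
vox_stft <- function(x, fs, wlen, step_n, w, nfft) {
  starts <- seq(1L, length(x) - wlen + 1L, by = step_n)
  idx <- outer(0:(wlen - 1L), starts, "+")
  frames <- matrix(x[idx], nrow = wlen) * w
  if (nfft > wlen)
    frames <- rbind(frames, matrix(0, nfft - wlen, ncol(frames)))
  X <- stats::mvfft(frames)
  half <- nfft %/% 2
  power <- Mod(X[1:(half + 1L), , drop = FALSE])^2
  list(times = (starts - 1 + (wlen - 1) / 2) / fs,
       freqs = (0:half) * fs / nfft,
       power = power)
}

#' Harmonics-to-noise ratio
#'
#' Autocorrelation-domain HNR: on each voiced frame the normalized
#' autocorrelation peak \eqn{r} estimates the periodic fraction of the frame
#' energy, so the frame HNR is \eqn{10 \log_{10}(r / (1 - r))} dB. The
#' segment HNR is the mean over voiced frames.
#'
#' @param seg an `analysis_segment` (unused beyond its pairing with `track`;
#'   kept for a uniform operation surface).
#' @param track a `pitch_track`.
#' @return HNR in dB.
#' @export
hnr <- function(seg, track) {
  r <- track$peak_autocorr[track$voiced_flags]
  if (length(r) < 1L)
    vox_validation_error("HNR needs at least one voiced frame")
  r <- pmin(pmax(r, 1e-9), 1 - 1e-9)
  mean(10 * log10(r / (1 - r)))
}

#' Dejonckere-style spectrum-based harmonics-to-noise ratio
#'
#' Comb decomposition of the long-term spectrum below 5 kHz: energy within
#' \eqn{\pm f_0 / 8} of each harmonic \eqn{k f_0} counts as harmonic, the
#' remaining sub-5 kHz energy as noise; HNRD is 10 log10 of their ratio.
#'
#' @param spectrum a `vox_spectrum`.
#' @param mean_f0 mean fundamental frequency in Hz.
#' @return HNRD in dB (`NA` if no harmonic lies below 5 kHz).
#' @export
hnrd <- function(spectrum, mean_f0) {
  if (!is.finite(mean_f0) || mean_f0 <= 0) return(NA_real_)
  f <- spectrum$freqs
  p <- spectrum$power
  in_band <- f > 0 & f < 5000
  ks <- seq_len(floor(5000 / mean_f0 - 1e-9))
  if (length(ks) == 0L) return(NA_real_)
  harmonic <- rep(FALSE, length(f))
  for (k in ks)
    harmonic <- harmonic | abs(f - k * mean_f0) <= mean_f0 / 8
  e_h <- sum(p[in_band & harmonic])
  e_n <- sum(p[in_band & !harmonic])
  if (e_n <= 0) return(-VOX_DB_FLOOR)
  if (e_h <= 0) return(VOX_DB_FLOOR)
  10 * log10(e_h / e_n)
}

#' Relative high-frequency noise level
#'
#' Power in the 6-10 kHz band relative to the total 0-10 kHz power, in dB.
#' Harmonic-dominated voices concentrate energy below 6 kHz, making HFNO
#' strongly negative; broadband noise pulls it toward
#' \eqn{10 \log_{10}(4/10) \approx -4} dB. If the Nyquist frequency is below
#' 10 kHz the band is truncated at Nyquist with a warning.
#'
#' @param spectrum a `vox_spectrum`.
#' @return HFNO in dB.
#' @export
hfno <- function(spectrum) {
  nyq <- spectrum$nyquist
  if (nyq <= 6000)
    vox_validation_error("HFNO needs a Nyquist frequency above 6 kHz")
  top <- 10000
  if (nyq < 10000) {
    warning(sprintf("Nyquist %.0f Hz < 10 kHz: HFNO uses the 6 kHz-Nyquist band",
                    nyq), call. = FALSE)
    top <- nyq
  }
  f <- spectrum$freqs
  hi <- sum(spectrum$power[f >= 6000 & f <= top])
  tot <- sum(spectrum$power[f <= top])
  if (tot <= 0 || hi <= 0) return(VOX_DB_FLOOR)
  max(10 * log10(hi / tot), VOX_DB_FLOOR)
}

# dB level of the strongest bin within [f_lo, f_hi]; NA if band empty
band_peak_db <- function(spectrum, f_lo, f_hi) {
  sel <- spectrum$freqs >= f_lo & spectrum$freqs <= f_hi
  if (!any(sel)) return(list(db = NA_real_, freq = NA_real_))
  i <- which(sel)[which.max(spectrum$magnitude_db[sel])]
  list(db = spectrum$magnitude_db[i], freq = spectrum$freqs[i])
}

#' First-to-second harmonic amplitude difference (H1-H2)
#'
#' Peak level within \eqn{\pm f_0/4} of \eqn{f_0} minus the peak level
#' within \eqn{\pm f_0/4} of \eqn{2 f_0}, in dB. Positive when the
#' fundamental dominates (a breathy-voice correlate).
#'
#' @param spectrum a `vox_spectrum`.
#' @param mean_f0 mean fundamental frequency in Hz.
#' @return H1-H2 in dB (`NA` when either peak is missing).
#' @export
h1h2 <- function(spectrum, mean_f0) {
  if (!is.finite(mean_f0) || mean_f0 <= 0) return(NA_real_)
  h1 <- band_peak_db(spectrum, mean_f0 * 0.75, mean_f0 * 1.25)
  h2 <- band_peak_db(spectrum, 2 * mean_f0 - mean_f0 / 4,
                     2 * mean_f0 + mean_f0 / 4)
  if (is.na(h1$db) || is.na(h2$db)) return(NA_real_)
  h1$db - h2$db
}

#' Spectral decline and tilt from harmonic peaks
#'
#' Locates the harmonic peak (strongest bin within \eqn{\pm f_0/4} of each
#' \eqn{k f_0}) for all harmonics up to 5.5 kHz, then fits two least-squares
#' lines to peak level versus frequency: tilt is the slope against frequency
#' in kHz (dB/kHz), decline the slope against log2 frequency (dB/octave).
#' Both are gain-invariant. Fewer than 4 located peaks yields `NA`s.
#'
#' @param spectrum a `vox_spectrum`.
#' @param mean_f0 mean fundamental frequency in Hz.
#' @return A list: `decline` (dB/octave), `tilt` (dB/kHz).
#' @export
spectral_decline_tilt <- function(spectrum, mean_f0) {
  na <- list(decline = NA_real_, tilt = NA_real_)
  if (!is.finite(mean_f0) || mean_f0 <= 0) return(na)
  ks <- seq_len(floor(5500 / mean_f0))
  pk_db <- pk_f <- numeric(0)
  for (k in ks) {
    pk <- band_peak_db(spectrum, k * mean_f0 - mean_f0 / 4,
                       min(k * mean_f0 + mean_f0 / 4, 5500))
    if (!is.na(pk$db) && pk$db > VOX_DB_FLOOR + 1e-9) {
      pk_db <- c(pk_db, pk$db)
      pk_f <- c(pk_f, pk$freq)
    }
  }
  if (length(pk_db) < 4L) return(na)
  slope <- function(xx, yy) {
    xc <- xx - mean(xx)
    sum(xc * (yy - mean(yy))) / sum(xc^2)
  }
  list(decline = slope(log2(pk_f), pk_db),
       tilt = slope(pk_f / 1000, pk_db))
}
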