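# Synthetic sustained vowels with known ground truth.
#
# Source-filter synthesis: a Rosenberg-type glottal pulse train with
# i.i.d. Gaussian cycle-length (jitter) and cycle-amplitude (shimmer)
# perturbations, filtered through cascaded second-order formant resonators,
# plus white Gaussian noise scaled to an exact harmonics-to-noise energy
# ratio. Realized per-cycle periods and amplitudes are stored so perturbation
# analyzers can be checked against the exact generated values.

#' Specification of a synthetic sustained vowel
#'
#' @param f0 target fundamental frequency, Hz.
#' @param jitter_pct SD of the Gaussian cycle-length perturbation, percent of
#'   the mean period.
#' @param shimmer_pct SD of the Gaussian cycle-amplitude perturbation,
#'   percent of the mean amplitude.
#' @param hnr_db target harmonics-to-noise energy ratio in dB; `Inf` means
#'   no additive noise.
#' @param formants list of `c(center_hz, bandwidth_hz)` resonators; the
#'   default triple (500/80, 1500/120, 2500/160 Hz) approximates an open
#'   front vowel.
#' @param duration seconds (at least 1).
#' @param sample_rate Hz.
#' @param seed integer seed making the voice reproducible.
#' @return A list of class `synth_spec`.
#' @export
synth_spec <- function(f0 = 200, jitter_pct = 1, shimmer_pct = 3, hnr_db = 20,
                       formants = list(c(500, 80), c(1500, 120), c(2500, 160)),
                       duration = 3, sample_rate = 44100, seed = 1L) {
  if (f0 <= 0) vox_config_error("f0 must be positive")
  if (jitter_pct < 0 || shimmer_pct < 0)
    vox_config_error("jitter_pct and shimmer_pct must be non-negative")
  if (duration < 1) vox_config_error("duration must be at least 1 second")
  if (sample_rate <= 0) vox_config_error("sample_rate must be positive")
  structure(list(f0 = f0, jitter_pct = jitter_pct, shimmer_pct = shimmer_pct,
                 hnr_db = hnr_db, formants = formants, duration = duration,
                 sample_rate = sample_rate, seed = as.integer(seed)),
            class = "synth_spec")
}

# one Rosenberg-C glottal pulse occupying pulse_len samples (opening 40% and
# closing 16% of the nominal period), zero-padded to the cycle length. The
# pulse shape is fixed across cycles (computed from the nominal period):
# jitter stretches the closed phase only, so cycle onsets stay well-defined.
rosenberg_pulse <- function(len, pulse_len) {
  pulse_len <- min(pulse_len, len)
  n_open <- max(2L, round(0.40 / 0.56 * pulse_len))
  n_close <- max(1L, pulse_len - n_open)
  g <- numeric(len)
  g[seq_len(n_open)] <- 0.5 * (1 - cos(pi * seq_len(n_open) / n_open))
  g[n_open + seq_len(n_close)] <- cos(pi * (seq_len(n_close) - 1) / (2 * n_close))
  g
}

apply_formants <- function(x, formants, fs) {
  for (f in formants) {
    r <- exp(-pi * f[2] / fs)
    th <- 2 * pi * f[1] / fs
    # resonator 1 / (1 - 2 r cos(th) z^-1 + r^2 z^-2), unit DC-ish gain factor
    x <- as.numeric(stats::filter(x, c(2 * r * cos(th), -r^2),
                                  method = "recursive"))
    x <- x * (1 - r) # keep magnitudes bounded through the cascade
  }
  x
}

#' Synthesize a sustained vowel with known ground truth
#'
#' @param spec a [synth_spec()].
#' @return A list of class `synth_voice` with `samples`, `sample_rate` and a
#'   `truth` list holding the spec, the realized per-cycle periods `T_i`
#'   (seconds) and amplitudes `A_i`, the separate harmonic and noise
#'   components, and the count of truncation resamples applied to keep all
#'   cycle lengths positive.
#' @export
synthesize <- function(spec) {
  stopifnot(inherits(spec, "synth_spec"))
  fs <- spec$sample_rate
  n_total <- round(spec$duration * fs)
  t0 <- 1 / spec$f0
  sj <- spec$jitter_pct / 100
  ss <- spec$shimmer_pct / 100

  with_seed(spec$seed, {
    periods <- numeric(0)
    amps <- numeric(0)
    lens <- integer(0)
    n_resampled <- 0L
    total <- 0L
    while (total < n_total) {
      eps <- if (sj > 0) rnorm(1L, 0, sj) else 0
      while (1 + eps <= 0.05) { # truncate: cycle length must stay positive
        eps <- rnorm(1L, 0, sj)
        n_resampled <- n_resampled + 1L
      }
      del <- if (ss > 0) rnorm(1L, 0, ss) else 0
      a <- max(1 + del, 0.05)
      len <- max(4L, as.integer(round(t0 * (1 + eps) * fs)))
      lens <- c(lens, len)
      periods <- c(periods, len / fs)  # realized period after rounding
      amps <- c(amps, a)
      total <- total + len
    }
    pulse_len <- max(3L, round(0.56 * t0 * fs))
    src <- unlist(lapply(seq_along(lens),
                         function(i) amps[i] * rosenberg_pulse(lens[i], pulse_len)))
    src <- src[seq_len(n_total)]
    harm <- apply_formants(src, spec$formants, fs)
    peak <- max(abs(harm))
    if (peak > 0) harm <- harm * (0.7 / peak)

    e_h <- sum(harm^2)
    if (is.finite(spec$hnr_db)) {
      noise <- rnorm(n_total)
      noise <- noise * sqrt(e_h * 10^(-spec$hnr_db / 10) / sum(noise^2))
    } else {
      noise <- numeric(n_total)
    }
    samples <- harm + noise
    scale <- 1
    if (max(abs(samples)) > 0.99) {
      scale <- 0.99 / max(abs(samples))
      samples <- samples * scale
      harm <- harm * scale
      noise <- noise * scale
    }
    structure(
      list(samples = samples, sample_rate = fs,
           truth = list(spec = spec, T_i = periods, A_i = amps,
                        harmonic = harm, noise = noise,
                        n_resampled = n_resampled, scale = scale)),
      class = "synth_voice")
  })
}

#' @export
print.synth_voice <- function(x, ...) {
  s <- x$truth$spec
  cat(sprintf(
    "<synth_voice> %.2f s @ %d Hz: f0 %g Hz, jitter %g%%, shimmer %g%%, HNR %g dB, %d cycles\n",
    length(x$samples) / x$sample_rate, as.integer(x$sample_rate), s$f0,
    s$jitter_pct, s$shimmer_pct, s$hnr_db, length(x$truth$T_i)))
  invisible(x)
}

#' Write a synthetic voice to disk as a test fixture
#'
#' Writes a 16-bit PCM WAV plus a JSON sidecar (`<path minus .wav>.json`)
#' holding the generating parameters and the realized per-cycle ground truth.
#' If the waveform clips, it is peak-normalized with a warning and the factor
#' recorded in the sidecar.
#'
#' @param voice a `synth_voice` from [synthesize()].
#' @param path output WAV path.
#' @return Invisibly, a list with `wav` and `sidecar` paths.
#' @export
write_fixture <- function(voice, path) {
  stopifnot(inherits(voice, "synth_voice"))
  x <- voice$samples
  norm_factor <- 1
  if (max(abs(x)) > 1) {
    norm_factor <- 1 / max(abs(x))
    warning(sprintf("waveform clips: peak-normalizing by %.4f", norm_factor),
            call. = FALSE)
    x <- x * norm_factor
  }
  ok <- tryCatch({ write_wav(x, voice$sample_rate, path); TRUE },
                 error = function(e) FALSE, warning = function(w) FALSE)
  if (!ok || !file.exists(path))
    vox_io_error(sprintf("cannot write fixture to '%s'", path))
  s <- voice$truth$spec
  sidecar <- paste0(tools::file_path_sans_ext(path), ".json")
  jsonlite::write_json(
    list(spec = list(f0 = s$f0, jitter_pct = s$jitter_pct,
                     shimmer_pct = s$shimmer_pct, hnr_db = s$hnr_db,
                     duration = s$duration, sample_rate = s$sample_rate,
                     seed = s$seed,
                     formants = lapply(s$formants, function(f)
                       list(center_hz = f[1], bandwidth_hz = f[2]))),
         T_i = voice$truth$T_i, A_i = voice$truth$A_i,
         n_cycles = length(voice$truth$T_i),
         n_resampled = voice$truth$n_resampled,
         normalization_factor = norm_factor),
    sidecar, auto_unbox = TRUE, digits = NA)
  invisible(list(wav = path, sidecar = sidecar))
}
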