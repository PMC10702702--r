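# Analysis configuration: every tunable threshold of the pipeline in one
# validated object, so reports can echo the exact settings used.

#' Analysis configuration
#'
#' Collects all tunable parameters of the analysis pipeline. Defaults follow
#' widely used conventions from autocorrelation pitch analysis and smoothed
#' cepstral-peak work: pitch search band 75--600 Hz, 10 ms pitch frames,
#' voicing decided at 0.45 normalized autocorrelation, CPPS with 40 ms
#' windows stepped at 2 ms and 7-frame x 11-bin smoothing.
#'
#' @param pitch_floor,pitch_ceiling pitch search band in Hz.
#' @param pitch_step pitch (and intensity) frame step in seconds.
#' @param voicing_threshold minimum normalized autocorrelation peak for a
#'   frame to count as voiced.
#' @param octave_cost small per-octave bonus favouring shorter candidate lags,
#'   preventing sub-harmonic (octave-down) locking.
#' @param silence_threshold frames whose peak amplitude falls below this
#'   fraction of the segment's global peak are unvoiced.
#' @param intensity_window intensity RMS window length in seconds.
#' @param spectrogram_window,spectrogram_step narrowband spectrogram Gaussian
#'   window length and hop, seconds.
#' @param cpps_window,cpps_step cepstral analysis window length and hop,
#'   seconds.
#' @param cpps_time_smooth,cpps_quefrency_smooth CPPS moving-average spans:
#'   frames across time, bins across quefrency.
#' @param lpc_rate working sample rate (Hz) for the LPC spectral envelope;
#'   the envelope is rendered up to `lpc_rate / 2`.
#' @param lpc_order LPC order at `lpc_rate`; `NULL` uses
#'   round(rate in kHz) + 5 (16 at 11025 Hz), enough poles to render all
#'   resonances below 5.5 kHz after pre-emphasis.
#' @param gne_bandwidths GNE analysis bandwidths in Hz.
#' @param voice_break_factor an unvoiced run counts as a voice break when it
#'   is longer than `voice_break_factor / pitch_floor` seconds.
#' @param format report output format: `"auto"` (PNG on Windows, PDF
#'   elsewhere), `"png"` or `"pdf"`.
#' @param resample_to optional target rate in Hz; the recording is polyphase
#'   resampled to it before analysis (e.g. 44100 to force the protocol rate).
#' @return A validated list of class `vox_config`.
#' @export
analysis_config <- function(pitch_floor = 75, pitch_ceiling = 600,
                            pitch_step = 0.010, voicing_threshold = 0.45,
                            octave_cost = 0.01, silence_threshold = 0.03,
                            intensity_window = 0.040,
                            spectrogram_window = 0.030, spectrogram_step = 0.002,
                            cpps_window = 0.040, cpps_step = 0.002,
                            cpps_time_smooth = 7L, cpps_quefrency_smooth = 11L,
                            lpc_rate = 11025, lpc_order = NULL,
                            gne_bandwidths = c(1000, 2000, 3000),
                            voice_break_factor = 1.25,
                            format = c("auto", "png", "pdf"),
                            resample_to = NULL) {
  format <- match.arg(format)
  cfg <- list(pitch_floor = pitch_floor, pitch_ceiling = pitch_ceiling,
              pitch_step = pitch_step, voicing_threshold = voicing_threshold,
              octave_cost = octave_cost, silence_threshold = silence_threshold,
              intensity_window = intensity_window,
              spectrogram_window = spectrogram_window,
              spectrogram_step = spectrogram_step,
              cpps_window = cpps_window, cpps_step = cpps_step,
              cpps_time_smooth = as.integer(cpps_time_smooth),
              cpps_quefrency_smooth = as.integer(cpps_quefrency_smooth),
              lpc_rate = lpc_rate,
              lpc_order = if (is.null(lpc_order)) NULL else as.integer(lpc_order),
              gne_bandwidths = gne_bandwidths,
              voice_break_factor = voice_break_factor,
              format = format, resample_to = resample_to)

  if (!(pitch_floor > 0 && pitch_floor < pitch_ceiling))
    vox_config_error("need 0 < pitch_floor < pitch_ceiling")
  if (pitch_step <= 0 || cpps_step <= 0 || spectrogram_step <= 0)
    vox_config_error("frame steps must be positive")
  if (voicing_threshold <= 0 || voicing_threshold >= 1)
    vox_config_error("voicing_threshold must lie in (0, 1)")
  if (cfg$cpps_time_smooth < 1L || cfg$cpps_quefrency_smooth < 1L)
    vox_config_error("CPPS smoothing spans must be >= 1")
  if (!all(gne_bandwidths %in% c(1000, 2000, 3000)))
    vox_config_error("GNE bandwidths must be drawn from {1000, 2000, 3000} Hz")
  if (!is.null(cfg$lpc_order) && cfg$lpc_order < 1L)
    vox_config_error("lpc_order must be a positive integer")
  if (!is.null(resample_to) && resample_to <= 0)
    vox_config_error("resample_to must be a positive rate in Hz")
  structure(cfg, class = "vox_config")
}

#' @export
print.vox_config <- function(x, ...) {
  cat("<vox_config>\n")
  for (nm in names(x)) {
    v <- x[[nm]]
    cat(sprintf("  %-22s %s\n", nm,
                if (is.null(v)) "NULL" else paste(format(v), collapse = ", ")))
  }
  invisible(x)
}

default_lpc_order <- function(cfg) {
  cfg$lpc_order %||% as.integer(round(cfg$lpc_rate / 1000) + 5L)
}
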