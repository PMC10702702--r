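# Assembly of the complete named measure collection, grouped by the report
# taxonomy: f0, period, period perturbation (jitter), amplitude perturbation
# (shimmer), spectral, glottal noise (GNE), cepstral (CPPS), and the
# auxiliary voicing measures. Every scalar is always present; measures that
# cannot be computed carry an explicit NA sentinel, never a missing entry.

measure_group_titles <- c(
  f0 = "f0 measures",
  period = "Period measures",
  jitter = "f0 period perturbation measures",
  shimmer = "f0 amplitude perturbation measures",
  spectral = "Spectral measures",
  gne = "Glottal noise measures",
  cepstral = "CPPS cepstral measures",
  auxiliary = "Auxiliary measures")

measure_layout <- list(
  f0 = c("mean", "sd", "q1", "median", "q3", "min", "max", "cv"),
  period = c("mean_period", "psd", "nlpsd"),
  jitter = c("local", "local_absolute", "rap", "ppq5", "ddp"),
  shimmer = c("local", "local_db", "apq3", "apq5", "apq11", "dda"),
  spectral = c("hnr", "hnrd", "hfno", "h1h2", "decline", "tilt"),
  gne = c("gne_1000", "gne_2000", "gne_3000"),
  cepstral = c("mean", "sd", "q1", "median", "q3", "min", "max", "cv",
               "cpps_f0"),
  auxiliary = c("intensity_mean_db", "mean_correlation", "unvoiced_fraction",
                "n_voice_breaks", "voice_break_fraction"))

measure_units <- list(
  f0 = c(mean = "Hz", sd = "Hz", q1 = "Hz", median = "Hz", q3 = "Hz",
         min = "Hz", max = "Hz", cv = "%"),
  period = c(mean_period = "s", psd = "s", nlpsd = ""),
  jitter = c(local = "%", local_absolute = "s", rap = "%", ppq5 = "%",
             ddp = "%"),
  shimmer = c(local = "%", local_db = "dB", apq3 = "%", apq5 = "%",
              apq11 = "%", dda = "%"),
  spectral = c(hnr = "dB", hnrd = "dB", hfno = "dB", h1h2 = "dB",
               decline = "dB/oct", tilt = "dB/kHz"),
  gne = c(gne_1000 = "", gne_2000 = "", gne_3000 = ""),
  cepstral = c(mean = "dB", sd = "dB", q1 = "dB", median = "dB", q3 = "dB",
               min = "dB", max = "dB", cv = "%", cpps_f0 = "Hz"),
  auxiliary = c(intensity_mean_db = "dB", mean_correlation = "",
                unvoiced_fraction = "%", n_voice_breaks = "count",
                voice_break_fraction = "%"))

na_group <- function(group) {
  v <- as.list(rep(NA_real_, length(measure_layout[[group]])))
  names(v) <- measure_layout[[group]]
  v
}

#' Compute the complete measure set of a recording
#'
#' Runs the full analysis pipeline (segmentation, pitch tracking, cycle
#' extraction, perturbation, spectral, GNE, cepstral and auxiliary measures)
#' and returns every scalar measure grouped by the report taxonomy. Groups
#' whose substrate cannot be extracted (e.g. no voiced cycles) are filled
#' with `NA` sentinels rather than dropped.
#'
#' @param rec a [voice_recording()] or an `analysis_segment`.
#' @param config an [analysis_config()].
#' @return A nested list of class `measure_set` with elements `f0`, `period`,
#'   `jitter`, `shimmer`, `spectral`, `gne`, `cepstral`, `auxiliary`.
#' @export
compute_measures <- function(rec, config = analysis_config()) {
  seg <- if (inherits(rec, "analysis_segment")) rec
         else select_analysis_window(rec)
  an <- analyze_segment(seg, config)
  an$measures
}

# full pipeline on a segment; returns measures plus intermediate objects so
# the report renderer does not recompute anything
analyze_segment <- function(seg, config = analysis_config()) {
  track <- estimate_pitch(seg, config)
  intensity <- intensity_trace(seg, config)
  spectrum <- fourier_spectrum(seg)

  periods <- tryCatch(extract_periods(seg, track),
                      error = function(e) NULL)
  f0s <- tryCatch(unclass(f0_statistics(track)),
                  error = function(e) na_group("f0"))
  per <- if (!is.null(periods))
    tryCatch(unclass(period_statistics(periods)),
             error = function(e) na_group("period"))
    else na_group("period")
  jit <- if (!is.null(periods)) unclass(jitter_measures(periods))
         else na_group("jitter")
  shim <- if (!is.null(periods)) unclass(shimmer_measures(periods))
          else na_group("shimmer")

  mean_f0 <- if (is.na(f0s$mean)) NA_real_ else f0s$mean
  dt <- spectral_decline_tilt(spectrum, mean_f0)
  spectral <- list(
    hnr = tryCatch(hnr(seg, track), error = function(e) NA_real_),
    hnrd = hnrd(spectrum, mean_f0),
    hfno = tryCatch(hfno(spectrum), error = function(e) NA_real_),
    h1h2 = h1h2(spectrum, mean_f0),
    decline = dt$decline, tilt = dt$tilt)

  gnes <- lapply(c(1000, 2000, 3000), function(bw)
    tryCatch(gne(seg, bw), error = function(e) NA_real_))
  names(gnes) <- c("gne_1000", "gne_2000", "gne_3000")

  ceps <- tryCatch(cpps_series(seg, config), error = function(e) NULL)
  cep_meas <- if (!is.null(ceps)) c(ceps$stats, list(cpps_f0 = ceps$cpps_f0))
              else na_group("cepstral")

  aux_raw <- tryCatch(auxiliary_measures(track, config),
                      error = function(e) list(mean_correlation = NA_real_,
                                               unvoiced_fraction = NA_real_,
                                               n_voice_breaks = NA_real_,
                                               voice_break_fraction = NA_real_))
  aux <- c(list(intensity_mean_db = mean(intensity$intensity_db)), aux_raw)

  measures <- structure(list(f0 = f0s, period = per, jitter = jit,
                             shimmer = shim, spectral = spectral, gne = gnes,
                             cepstral = cep_meas, auxiliary = aux),
                        class = "measure_set")
  list(segment = seg, track = track, intensity = intensity,
       spectrum = spectrum, periods = periods, cepstral = ceps,
       measures = measures)
}

#' Flatten a measure set to a data frame
#'
#' @param x a `measure_set`.
#' @param row.names,optional,... ignored (S3 conformance).
#' @return A data frame with columns `group`, `measure`, `value`, `unit`, in
#'   the report's fixed listing order.
#' @export
as.data.frame.measure_set <- function(x, row.names = NULL, optional = FALSE,
                                      ...) {
  rows <- do.call(rbind, lapply(names(measure_layout), function(g) {
    keys <- measure_layout[[g]]
    data.frame(group = measure_group_titles[[g]], measure = keys,
               value = vapply(keys, function(k) {
                 v <- x[[g]][[k]]
                 if (is.null(v)) NA_real_ else as.numeric(v)
               }, numeric(1)),
               unit = unname(measure_units[[g]][keys]),
               stringsAsFactors = FALSE)
  }))
  rownames(rows) <- NULL
  rows
}

#' @export
print.measure_set <- function(x, ...) {
  df <- as.data.frame(x)
  cat("<measure_set>\n")
  for (g in unique(df$group)) {
    cat(" ", g, "\n")
    sub <- df[df$group == g, ]
    for (i in seq_len(nrow(sub)))
      cat(sprintf("    %-18s %s %s\n", sub$measure[i],
                  format_measure(sub$value[i]), sub$unit[i]))
  }
  invisible(x)
}

format_measure <- function(v) {
  if (is.na(v)) return("--")
  if (!is.finite(v)) return(if (v > 0) "Inf" else "-Inf")
  formatC(v, format = "fg", digits = 6)
}

#' Export a measure set
#'
#' Writes the flat measure table as TSV and/or JSON.
#'
#' @param measures a `measure_set`.
#' @param path output path without extension, or with `.tsv`/`.json`.
#' @param formats subset of `c("tsv", "json")`.
#' @return Character vector of written paths, invisibly.
#' @export
write_measures <- function(measures, path, formats = c("tsv", "json")) {
  base <- tools::file_path_sans_ext(path)
  written <- character(0)
  df <- as.data.frame(measures)
  if ("tsv" %in% formats) {
    p <- paste0(base, ".tsv")
    out <- df
    out$value <- vapply(out$value, format_measure, character(1))
    utils::write.table(out, p, sep = "\t", row.names = FALSE, quote = FALSE)
    written <- c(written, p)
  }
  if ("json" %in% formats) {
    p <- paste0(base, ".json")
    jsonlite::write_json(lapply(unclass(measures), function(g)
      lapply(g, function(v) if (is.na(v) || !is.finite(v)) NULL else v)),
      p, auto_unbox = TRUE, digits = NA, null = "null")
    written <- c(written, p)
  }
  invisible(written)
}
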