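# The four-file acoustic report: oscillograms with f0/intensity traces
# (file 1), Fourier/LPC spectra with a narrowband spectrogram (file 2),
# cepstral-peak panels with the cepstrogram (file 3), and the numeric tables
# with vertical bar charts under the patient header (file 4).

#' Patient header for the acoustic report
#'
#' All identification fields are optional pass-through text; the report date
#' is filled automatically at generation time.
#'
#' @param name,sex,age,occupation,grbas,cape_v,examiner free-text fields
#'   (GRBAS and CAPE-V are carried verbatim; no scoring is performed).
#' @return A list of class `patient_header` with an auto-filled
#'   `report_date`.
#' @export
patient_header <- function(name = "", sex = "", age = "", occupation = "",
                           grbas = "", cape_v = "", examiner = "") {
  structure(list(name = as.character(name %||% ""),
                 sex = as.character(sex %||% ""),
                 age = as.character(age %||% ""),
                 occupation = as.character(occupation %||% ""),
                 grbas = as.character(grbas %||% ""),
                 cape_v = as.character(cape_v %||% ""),
                 examiner = as.character(examiner %||% ""),
                 report_date = format(Sys.Date())),
            class = "patient_header")
}

#' Read a patient header from a JSON sidecar form
#'
#' @param path JSON file with any of the keys `name`, `sex`, `age`,
#'   `occupation`, `grbas`, `cape_v`, `examiner`.
#' @return A [patient_header()].
#' @export
read_patient_header <- function(path) {
  if (!file.exists(path))
    vox_io_error(sprintf("cannot read patient form '%s': no such file", path))
  d <- jsonlite::read_json(path, simplifyVector = TRUE)
  patient_header(name = d$name %||% "", sex = d$sex %||% "",
                 age = d$age %||% "", occupation = d$occupation %||% "",
                 grbas = d$grbas %||% "", cape_v = d$cape_v %||% "",
                 examiner = d$examiner %||% "")
}

resolve_format <- function(format) {
  if (format == "auto")
    format <- if (.Platform$OS.type == "windows") "png" else "pdf"
  format
}

vox_device <- function(path, format, width, height) {
  if (format == "png") {
    grDevices::png(path, width = width, height = height, units = "in",
                   res = 110, type = "cairo")
  } else {
    grDevices::pdf(path, width = width, height = height)
  }
}

plot_empty <- function(label) {
  plot(0, 0, type = "n", axes = FALSE, xlab = "", ylab = "")
  text(0, 0, paste0(label, "\n(undefined)"), cex = 0.9)
}

plot_oscillogram <- function(seg, t_from, t_to, title_txt) {
  fs <- seg$sample_rate
  i1 <- max(1L, round(t_from * fs) + 1L)
  i2 <- min(length(seg$samples), round(t_to * fs))
  tt <- (i1:i2 - 1) / fs
  plot(tt, seg$samples[i1:i2], type = "l", xlab = "Time (s)",
       ylab = "Amplitude", main = title_txt, cex.main = 0.95, col = "navy")
}

#' Render report file 1: oscillograms and f0/intensity traces
#'
#' Six panels: the complete signal (up to 3 s), the initial, central and
#' final 50 ms oscillograms, the f0 trace and the intensity trace against
#' total time.
#'
#' @param seg an `analysis_segment`.
#' @param track a `pitch_track`.
#' @param intensity an `intensity_track`.
#' @param path output file path.
#' @param format `"png"` or `"pdf"`.
#' @return Invisibly, a `vox_report_page` with the file path and panel
#'   descriptors.
#' @export
render_file1 <- function(seg, track, intensity, path, format = "pdf") {
  dur <- seg$duration
  zoom <- 0.050
  c0 <- (dur - zoom) / 2
  panels <- list(
    list(type = "oscillogram", span = c(0, dur)),
    list(type = "oscillogram", span = c(0, zoom)),
    list(type = "oscillogram", span = c(c0, c0 + zoom)),
    list(type = "oscillogram", span = c(dur - zoom, dur)),
    list(type = "f0_trace", span = c(0, dur)),
    list(type = "intensity_trace", span = c(0, dur)))

  vox_device(path, format, 10, 8)
  on.exit(grDevices::dev.off())
  par(mfrow = c(3, 2), mar = c(4, 4, 2.5, 1))
  plot_oscillogram(seg, 0, dur, sprintf("Complete signal (%.2f s)", dur))
  plot_oscillogram(seg, 0, zoom, "Initial 50 ms")
  plot_oscillogram(seg, c0, c0 + zoom, "Central 50 ms")
  plot_oscillogram(seg, dur - zoom, dur, "Final 50 ms")
  if (any(track$voiced_flags)) {
    plot(track$frame_times, track$f0_values, type = "p", pch = 16, cex = 0.35,
         col = "darkred", xlim = c(0, dur),
         ylim = c(track$pitch_floor, track$pitch_ceiling),
         xlab = "Time (s)", ylab = "f0 (Hz)", main = "f0 trace",
         cex.main = 0.95)
  } else plot_empty("f0 trace")
  plot(intensity$frame_times, intensity$intensity_db, type = "l",
       col = "darkgreen", xlim = c(0, dur), xlab = "Time (s)",
       ylab = "Intensity (dB)", main = "Intensity trace", cex.main = 0.95)
  invisible(structure(list(file = path, panels = panels),
                      class = "vox_report_page"))
}

#' Render report file 2: Fourier/LPC spectra and spectrogram
#'
#' Seven panels: the long-term Fourier spectrum viewed up to 22.05 kHz (or
#' Nyquist if lower, annotated), 11 kHz, 5.5 kHz with the LPC envelope
#' overlay, 2.75 kHz, 1.38 kHz and 690 Hz, plus the narrowband spectrogram.
#'
#' @param spectrum a `vox_spectrum`.
#' @param lpc an `lpc_envelope`.
#' @param sgram a `vox_spectrogram`.
#' @param path output file path.
#' @param format `"png"` or `"pdf"`.
#' @return Invisibly, a `vox_report_page`.
#' @export
render_file2 <- function(spectrum, lpc, sgram, path, format = "pdf") {
  bounds <- c(22050, 11000, 5500, 2750, 1380, 690)
  nyq <- spectrum$nyquist
  eff <- pmin(bounds, nyq)
  panels <- c(lapply(seq_along(bounds), function(i)
    list(type = if (i == 3) "spectrum_lpc" else "spectrum",
         upper_bound = eff[i])),
    list(list(type = "spectrogram", span = range(sgram$times))))

  vox_device(path, format, 10, 10)
  on.exit(grDevices::dev.off())
  par(mfrow = c(4, 2), mar = c(4, 4, 2.5, 1))
  for (i in seq_along(bounds)) {
    sel <- spectrum$freqs <= eff[i]
    main <- sprintf("Fourier spectrum to %.5g kHz", eff[i] / 1000)
    if (i == 3) main <- paste(main, "+ LPC")
    plot(spectrum$freqs[sel], spectrum$magnitude_db[sel], type = "l",
         col = "grey25", xlab = "Frequency (Hz)", ylab = "Level (dB)",
         main = main, cex.main = 0.95)
    if (i == 1 && eff[i] < bounds[i])
      mtext(sprintf("limited to Nyquist (%.0f Hz)", nyq), side = 3,
            cex = 0.6, col = "red3")
    if (i == 3 && !is.null(lpc)) {
      sel_l <- lpc$freqs <= eff[i]
      lines(lpc$freqs[sel_l], lpc$envelope_db[sel_l], col = "red3", lwd = 2)
    }
  }
  image(sgram$times, sgram$freqs, t(pmax(sgram$power_db, -70)),
        col = gray(seq(1, 0, length.out = 64)), xlab = "Time (s)",
        ylab = "Frequency (Hz)", main = "Narrowband spectrogram",
        cex.main = 0.95, useRaster = TRUE)
  invisible(structure(list(file = path, panels = panels),
                      class = "vox_report_page"))
}

#' Render report file 3: cepstral analysis
#'
#' Five panels: cepstral peak level with its regression-line level over time,
#' the peak minus the line (the CPP series), the same pair for the smoothed
#' cepstra (CPPS), and the cepstrogram with both axes in seconds.
#'
#' @param series a `cepstral_series`.
#' @param cgram a `vox_cepstrogram`.
#' @param path output file path.
#' @param format `"png"` or `"pdf"`.
#' @return Invisibly, a `vox_report_page`.
#' @export
render_file3 <- function(series, cgram, path, format = "pdf") {
  panels <- list(list(type = "cpp_with_line"),
                 list(type = "cpp_minus_line", baseline = 0),
                 list(type = "cpps_with_line"),
                 list(type = "cpps_minus_line", baseline = 0),
                 list(type = "cepstrogram", axes_unit = "seconds"))
  vox_device(path, format, 10, 10)
  on.exit(grDevices::dev.off())
  par(mfrow = c(3, 2), mar = c(4, 4, 2.5, 1))
  pk_line <- function(peak, line, main) {
    ylim <- range(c(peak, line), finite = TRUE)
    plot(series$frame_times, peak, type = "l", col = "navy", ylim = ylim,
         xlab = "Time (s)", ylab = "Level (dB)", main = main, cex.main = 0.95)
    lines(series$frame_times, line, col = "red3")
  }
  prom <- function(v, main) {
    plot(series$frame_times, v, type = "l", col = "navy", xlab = "Time (s)",
         ylab = "Prominence (dB)", main = main, cex.main = 0.95)
    abline(h = 0, col = "grey60", lty = 2)
  }
  pk_line(series$cpp_peak_db, series$cpp_line_db,
          "Cepstral peaks and regression line (CPP)")
  prom(series$cpp_values, "Cepstral peaks minus regression line (CPP)")
  pk_line(series$cpps_peak_db, series$cpps_line_db,
          "Smoothed cepstral peaks and regression line (CPPS)")
  prom(series$cpps_values, "Smoothed cepstral peaks minus regression line (CPPS)")
  image(cgram$times, cgram$quefrencies,
        t(pmax(cgram$cepstrum_db, max(cgram$cepstrum_db) - 60)),
        col = gray(seq(1, 0, length.out = 64)), xlab = "Time (s)",
        ylab = "Quefrency (s)", main = "Cepstrogram", cex.main = 0.95,
        useRaster = TRUE)
  invisible(structure(list(file = path, panels = panels),
                      class = "vox_report_page"))
}

#' Render report file 4: numeric results and bar charts
#'
#' The patient header block (with the auto-inserted report date), the full
#' numeric measure table grouped by the report taxonomy, and one vertical
#' bar chart per measure group. Undefined measures are printed as `--` with
#' a footnote.
#'
#' @param measures a `measure_set`.
#' @param header a [patient_header()].
#' @param path output file path.
#' @param format `"png"` or `"pdf"`.
#' @return Invisibly, a `vox_report_page`.
#' @export
render_file4 <- function(measures, header, path, format = "pdf") {
  df <- as.data.frame(measures)
  groups <- names(measure_layout)
  panels <- c(list(list(type = "header"), list(type = "table", rows = nrow(df))),
              lapply(groups, function(g) list(type = "bar_chart", group = g)))

  vox_device(path, format, 11, 14)
  on.exit(grDevices::dev.off())
  lay <- rbind(c(1, 1),
               cbind(rep(2, length(groups)), 2 + seq_along(groups)))
  layout(lay, heights = c(1.1, rep(1, length(groups))),
         widths = c(1.15, 1))

  # header block
  par(mar = c(0.5, 1, 1, 1))
  plot(0, 0, type = "n", axes = FALSE, xlab = "", ylab = "",
       xlim = c(0, 1), ylim = c(0, 1))
  text(0.5, 0.92, "Acoustic report", font = 2, cex = 1.5)
  hdr <- sprintf(
    "Name: %s    Sex: %s    Age: %s    Occupation: %s\nGRBAS: %s    CAPE-V: %s    Examiner: %s    Date: %s",
    header$name, header$sex, header$age, header$occupation, header$grbas,
    header$cape_v, header$examiner, header$report_date)
  text(0.5, 0.45, hdr, cex = 0.95)

  # numeric table
  par(mar = c(0.5, 0.5, 0.5, 0.5))
  plot(0, 0, type = "n", axes = FALSE, xlab = "", ylab = "",
       xlim = c(0, 1), ylim = c(0, 1))
  n_lines <- nrow(df) + length(groups) + 1L
  y <- 1
  dy <- 1 / (n_lines + 1)
  any_na <- FALSE
  for (g in groups) {
    y <- y - dy
    text(0.02, y, measure_group_titles[[g]], font = 2, adj = 0, cex = 0.85)
    sub <- df[df$group == measure_group_titles[[g]], ]
    for (i in seq_len(nrow(sub))) {
      y <- y - dy
      val <- format_measure(sub$value[i])
      if (val == "--") any_na <- TRUE
      text(0.07, y, sub$measure[i], adj = 0, cex = 0.78)
      text(0.72, y, val, adj = 1, cex = 0.78)
      text(0.75, y, sub$unit[i], adj = 0, cex = 0.78)
    }
  }
  if (any_na)
    text(0.02, y - dy, "-- : measure undefined on this signal", adj = 0,
         cex = 0.7, col = "grey40")

  # one vertical bar chart per group, measures in listing order
  par(mar = c(5, 4, 2, 1))
  for (g in groups) {
    sub <- df[df$group == measure_group_titles[[g]], ]
    vals <- sub$value
    vals[!is.finite(vals)] <- 0
    barplot(vals, names.arg = sub$measure, las = 2, col = "steelblue",
            main = measure_group_titles[[g]], cex.main = 0.9,
            cex.names = 0.65, ylab = "")
  }
  invisible(structure(list(file = path, panels = panels),
                      class = "vox_report_page"))
}

#' Generate the complete four-file acoustic report
#'
#' Validates the recording, runs the full analysis pipeline, and writes
#' exactly four report files plus numeric sidecars
#' (`<basename>_measures.tsv/.json`) to the output folder. Files are first
#' rendered into a temporary folder and moved into place on success, so a
#' failed run leaves no partial report.
#'
#' @param rec a [voice_recording()].
#' @param header a [patient_header()].
#' @param config an [analysis_config()].
#' @param output_dir destination folder (must exist and be writable).
#' @param basename stem for the output file names
#'   (`<basename>_report_{1,2,3,4}.<ext>`).
#' @param format `"auto"` (PNG on Windows, PDF on Linux/macOS), `"png"` or
#'   `"pdf"`; default taken from `config`.
#' @return An object of class `acoustic_report`: `header`, `files` (4 paths),
#'   `sidecars`, `measures`, `format`, `pages` (panel metadata).
#' @export
generate_report <- function(rec, header = patient_header(),
                            config = analysis_config(), output_dir = ".",
                            basename = "voice", format = config$format) {
  format <- resolve_format(format)
  if (!dir.exists(output_dir))
    vox_io_error(sprintf("output folder '%s' does not exist", output_dir))
  if (file.access(output_dir, 2L) != 0L)
    vox_io_error(sprintf("output folder '%s' is not writable", output_dir))

  if (!is.null(config$resample_to) &&
      rec$sample_rate != config$resample_to) {
    rec <- voice_recording(
      as.numeric(signal::resample(rec$samples, p = round(config$resample_to),
                                  q = round(rec$sample_rate))),
      config$resample_to, rec$bit_depth)
  }
  seg <- select_analysis_window(rec)

  an <- analyze_segment(seg, config)
  lpc <- tryCatch(lpc_envelope(seg, config = config), error = function(e) NULL)
  sgram <- narrowband_spectrogram(seg, config)
  cgram <- cepstrogram(seg, config)

  tmp <- file.path(output_dir,
                   sprintf(".vox_tmp_%s_%d", basename, Sys.getpid()))
  dir.create(tmp, showWarnings = FALSE)
  on.exit(unlink(tmp, recursive = TRUE), add = TRUE)

  ext <- format
  tmp_files <- file.path(tmp, sprintf("%s_report_%d.%s", basename, 1:4, ext))
  pages <- list(
    render_file1(seg, an$track, an$intensity, tmp_files[1], format),
    render_file2(an$spectrum, lpc, sgram, tmp_files[2], format),
    render_file3(an$cepstral, cgram, tmp_files[3], format),
    render_file4(an$measures, header, tmp_files[4], format))
  side_tmp <- write_measures(an$measures,
                             file.path(tmp, paste0(basename, "_measures")))

  final_files <- file.path(output_dir, base::basename(tmp_files))
  final_side <- file.path(output_dir, base::basename(side_tmp))
  ok <- file.rename(c(tmp_files, side_tmp), c(final_files, final_side))
  if (!all(ok)) vox_io_error(sprintf("cannot move report files into '%s'",
                                     output_dir))

  structure(list(header = header, files = final_files,
                 sidecars = final_side, measures = an$measures,
                 format = format, pages = pages),
            class = "acoustic_report")
}

#' @export
print.acoustic_report <- function(x, ...) {
  cat(sprintf("<acoustic_report> %d files (%s)\n", length(x$files), x$format))
  for (f in x$files) cat("  ", f, "\n")
  invisible(x)
}
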