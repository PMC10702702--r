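test_that("the measure set enumerates every measure exactly once", {
  v <- synthesize(synth_spec(duration = 2, seed = 10))
  ms <- compute_measures(voice_recording(v$samples, v$sample_rate))
  df <- as.data.frame(ms)
  expect_equal(nrow(df), 45)  # 40 taxonomy measures + 5 auxiliaries
  expect_false(any(duplicated(paste(df$group, df$measure))))
  expect_equal(length(unique(df$group)), 8)
  # every entry is present: numeric value or explicit NA sentinel
  expect_true(all(vapply(df$value, function(v) is.numeric(v), logical(1))))
})

test_that("an unvoiced recording still yields a complete measure set with sentinels", {
  set.seed(2)
  x <- stats::rnorm(round(1.5 * 44100))
  ms <- compute_measures(voice_recording(x / max(abs(x)), 44100))
  df <- as.data.frame(ms)
  expect_equal(nrow(df), 45)
  expect_true(any(is.na(df$value)))           # jitter etc. undefined
  expect_equal(ms$auxiliary$unvoiced_fraction, 100, tolerance = 10)
})

test_that("measure export writes matching TSV and JSON sidecars", {
  v <- synthesize(synth_spec(duration = 1.5, seed = 11))
  ms <- compute_measures(voice_recording(v$samples, v$sample_rate))
  base <- withr::local_tempfile()
  paths <- write_measures(ms, base)
  expect_true(all(file.exists(paste0(base, c(".tsv", ".json")))))
  df <- utils::read.delim(paste0(base, ".tsv"))
  expect_equal(nrow(df), 45)
  js <- jsonlite::read_json(paste0(base, ".json"))
  expect_equal(js$jitter$local, ms$jitter$local, tolerance = 1e-9)
})

test_that("the full report produces exactly four files with the protocol panels", {
  v <- synthesize(synth_spec(duration = 3, seed = 12))
  rec <- voice_recording(v$samples, v$sample_rate)
  out <- withr::local_tempdir()
  rep <- generate_report(rec, patient_header(name = "A B", sex = "F"),
                         output_dir = out, basename = "case1", format = "pdf")
  expect_length(rep$files, 4)
  expect_true(all(file.exists(rep$files)))
  expect_identical(base::basename(rep$files),
                   paste0("case1_report_", 1:4, ".pdf"))

  counts <- vapply(rep$pages, function(p) length(p$panels), integer(1))
  expect_identical(counts[1:3], c(6L, 7L, 5L))

  p1 <- rep$pages[[1]]$panels
  osc <- Filter(function(p) p$type == "oscillogram", p1)
  expect_length(osc, 4)
  spans <- vapply(osc[-1], function(p) diff(p$span), numeric(1))
  expect_true(all(abs(spans - 0.050) < 1e-9))
  expect_equal(sum(vapply(p1, function(p)
    p$type %in% c("f0_trace", "intensity_trace"), logical(1))), 2)

  p2 <- rep$pages[[2]]$panels
  bounds <- vapply(Filter(function(p) grepl("spectrum", p$type), p2),
                   function(p) p$upper_bound, numeric(1))
  expect_identical(bounds, c(22050, 11000, 5500, 2750, 1380, 690))
  expect_identical(p2[[3]]$type, "spectrum_lpc")  # LPC only in the 5.5 kHz panel
  expect_equal(sum(vapply(p2, function(p) p$type == "spectrogram",
                          logical(1))), 1)

  types3 <- vapply(rep$pages[[3]]$panels, function(p) p$type, character(1))
  expect_identical(types3, c("cpp_with_line", "cpp_minus_line",
                             "cpps_with_line", "cpps_minus_line",
                             "cepstrogram"))
  expect_identical(rep$pages[[3]]$panels[[5]]$axes_unit, "seconds")

  expect_true(all(file.exists(rep$sidecars)))
  expect_equal(rep$header$report_date, format(Sys.Date()))
})

test_that("a shorter-than-3-s recording spans its own duration in file 1", {
  v <- synthesize(synth_spec(duration = 1.5, seed = 13))
  out <- withr::local_tempdir()
  rep <- generate_report(voice_recording(v$samples, v$sample_rate),
                         output_dir = out, basename = "short", format = "pdf")
  expect_equal(rep$pages[[1]]$panels[[1]]$span, c(0, 1.5))
})

test_that("report numeric content is deterministic for the same input", {
  v <- synthesize(synth_spec(duration = 2, seed = 14))
  rec <- voice_recording(v$samples, v$sample_rate)
  o1 <- withr::local_tempdir()
  o2 <- withr::local_tempdir()
  r1 <- generate_report(rec, output_dir = o1, basename = "x", format = "pdf")
  r2 <- generate_report(rec, output_dir = o2, basename = "x", format = "pdf")
  t1 <- readLines(grep("tsv$", r1$sidecars, value = TRUE))
  t2 <- readLines(grep("tsv$", r2$sidecars, value = TRUE))
  expect_identical(t1, t2)
})

test_that("PNG output is supported", {
  v <- synthesize(synth_spec(duration = 1.5, seed = 15))
  out <- withr::local_tempdir()
  rep <- generate_report(voice_recording(v$samples, v$sample_rate),
                         output_dir = out, basename = "p", format = "png")
  expect_true(all(grepl("png$", rep$files)))
  expect_true(all(file.exists(rep$files)))
})

test_that("failures leave no partial report files", {
  short <- voice_recording(make_sine(200, duration = 0.5), 44100)
  out <- withr::local_tempdir()
  expect_error(generate_report(short, output_dir = out, basename = "bad"),
               class = "vox_duration_error")
  expect_length(list.files(out), 0)
  expect_error(generate_report(short, output_dir = file.path(out, "nope")),
               class = "vox_io_error")
})

test_that("an empty patient form still renders with the auto date", {
  hdr <- patient_header()
  expect_identical(hdr$name, "")
  expect_identical(hdr$report_date, format(Sys.Date()))
  p <- withr::local_tempfile(fileext = ".json")
  jsonlite::write_json(list(name = "X", grbas = "G1R1B0A0S0"), p,
                       auto_unbox = TRUE)
  h2 <- read_patient_header(p)
  expect_identical(h2$name, "X")
  expect_identical(h2$grbas, "G1R1B0A0S0")
  expect_identical(h2$sex, "")
})
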