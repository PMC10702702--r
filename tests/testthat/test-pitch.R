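test_that("a pure sine is fully voiced at its frequency", {
  seg <- sine_segment(200, duration = 2)
  tr <- estimate_pitch(seg)
  expect_true(all(tr$voiced_flags))
  expect_lt(abs(mean(tr$f0_values) - 200), 1)
  expect_true(all(tr$peak_autocorr >= 0 & tr$peak_autocorr <= 1))
  expect_true(all(diff(tr$frame_times) > 0))
  expect_equal(stats::sd(diff(tr$frame_times)), 0, tolerance = 1e-9)
})

test_that("white Gaussian noise is at least 90% unvoiced across seeds", {
  rates <- vapply(1:20, function(s) {
    set.seed(s)
    rec <- voice_recording(stats::rnorm(44100) / 5, 44100)
    tr <- estimate_pitch(select_analysis_window(rec))
    mean(!tr$voiced_flags)
  }, numeric(1))
  expect_true(all(rates >= 0.9))
})

test_that("mean f0 of a jittered pulse train is recovered within 1%", {
  v <- synthesize(synth_spec(f0 = 150, jitter_pct = 1, duration = 2, seed = 4))
  tr <- estimate_pitch(seg_of(v))
  expect_lt(abs(mean(tr$f0_values[tr$voiced_flags]) - 150) / 150, 0.01)
})

test_that("a segment shorter than one analysis window errors", {
  rec <- voice_recording(make_sine(200, duration = 0.02), 44100)
  expect_error(estimate_pitch(structure(
    list(samples = rec$samples, sample_rate = 44100, start_offset = 0,
         duration = rec$duration), class = "analysis_segment")),
    class = "vox_validation_error")
})

test_that("periods of a perfect pulse train are exact to one sample", {
  fs <- 44100
  x <- impulse_train(0.005, rep(1, 400), fs)
  seg <- select_analysis_window(voice_recording(x, fs))
  ps <- extract_periods(seg, estimate_pitch(seg))
  expect_gt(length(ps$periods), 300)
  expect_true(all(abs(ps$periods - 0.005) <= 1.01 / fs))
})

test_that("alternating pulse amplitudes are recovered in order", {
  fs <- 44100
  amps <- rep(c(1.0, 0.9), 200)
  x <- impulse_train(0.005, amps, fs)
  seg <- select_analysis_window(voice_recording(x, fs))
  ps <- extract_periods(seg, estimate_pitch(seg))
  a <- ps$amplitudes
  # consecutive extracted amplitudes alternate between the two levels
  expect_true(all(abs(diff(a)) > 0.05))
  expect_equal(sort(unique(round(a, 2))), c(0.9, 1.0))
})

test_that("no period crosses an unvoiced gap, and the gap counts as a voice break", {
  fs <- 44100
  v1 <- make_sine(200, duration = 1.2, fs = fs)
  v2 <- make_sine(200, duration = 1.2, fs = fs)
  x <- c(v1, numeric(round(0.3 * fs)), v2)
  seg <- select_analysis_window(voice_recording(x, fs))
  tr <- estimate_pitch(seg)
  ps <- extract_periods(seg, tr)
  expect_gt(length(unique(ps$run)), 1)
  expect_true(all(ps$periods <= 1 / tr$pitch_floor))
  # no cycle onset inside the silent gap
  gap <- c(1.21, 1.49)
  expect_false(any(ps$cycle_onsets > gap[1] & ps$cycle_onsets < gap[2]))
  aux <- auxiliary_measures(tr)
  expect_equal(aux$n_voice_breaks, 1)
  expect_gt(aux$voice_break_fraction, 0)
})

test_that("auxiliary measures follow their definitions on constructed tracks", {
  tr <- make_track(rep(200, 50), peak_autocorr = rep(0.99, 50))
  aux <- auxiliary_measures(tr)
  expect_equal(aux$mean_correlation, 0.99)
  expect_equal(aux$unvoiced_fraction, 0)
  expect_equal(aux$n_voice_breaks, 0)

  f0 <- rep(200, 100)
  f0[31:60] <- NA
  aux2 <- auxiliary_measures(make_track(f0))
  expect_equal(aux2$unvoiced_fraction, 30)

  # interior 200 ms unvoiced run exceeds the 1.25/75 = 16.7 ms threshold
  f0b <- rep(150, 100)
  f0b[41:60] <- NA
  aux3 <- auxiliary_measures(make_track(f0b))
  expect_equal(aux3$n_voice_breaks, 1)
  expect_equal(aux3$voice_break_fraction, 20)

  # unvoiced runs touching the segment edges are not breaks
  f0c <- rep(150, 100)
  f0c[1:30] <- NA
  expect_equal(auxiliary_measures(make_track(f0c))$n_voice_breaks, 0)

  aux_empty <- auxiliary_measures(make_track(rep(NA_real_, 20)))
  expect_true(is.na(aux_empty$mean_correlation))
  expect_equal(aux_empty$unvoiced_fraction, 100)
})

test_that("voiced and unvoiced fractions always sum to exactly 100%", {
  for (s in 1:5) {
    set.seed(s)
    f0 <- ifelse(stats::runif(80) < 0.6, 200, NA)
    aux <- auxiliary_measures(make_track(f0))
    voiced_frac <- 100 * mean(!is.na(f0))
    expect_identical(aux$unvoiced_fraction + voiced_frac, 100)
  }
})

test_that("intensity follows amplitude in dB and clamps on silence", {
  seg <- sine_segment(200, duration = 1, amp = 0.5)
  it <- intensity_trace(seg)
  expect_lt(diff(range(it$intensity_db)), 0.1)

  seg2 <- sine_segment(200, duration = 1, amp = 0.25)
  it2 <- intensity_trace(seg2)
  expect_equal(mean(it$intensity_db) - mean(it2$intensity_db), 20 * log10(2),
               tolerance = 1e-3)

  silent <- select_analysis_window(voice_recording(numeric(44100), 44100))
  expect_true(all(intensity_trace(silent)$intensity_db == -100))
})

test_that("extracted periods agree with the frame-wise f0", {
  v <- synthesize(synth_spec(f0 = 180, duration = 2, seed = 6))
  seg <- seg_of(v)
  tr <- estimate_pitch(seg)
  ps <- extract_periods(seg, tr)
  expect_lt(abs(stats::median(1 / ps$periods) -
                stats::median(tr$f0_values[tr$voiced_flags])) /
            stats::median(tr$f0_values[tr$voiced_flags]), 0.02)
})

test_that("mean correlation declines as additive noise increases", {
  levels <- c(30, 15, 5)
  mc <- sapply(levels, function(h) {
    mean(vapply(1:10, function(s) {
      v <- synthesize(synth_spec(hnr_db = h, duration = 1.5, seed = s))
      tr <- estimate_pitch(seg_of(v))
      mean(tr$peak_autocorr[tr$voiced_flags])
    }, numeric(1)))
  })
  expect_true(all(diff(mc) < 0))
})

test_that("traces export as two-column TSV tables", {
  seg <- sine_segment(200, duration = 1)
  p <- withr::local_tempfile(fileext = ".tsv")
  export_trace(estimate_pitch(seg), p)
  df <- utils::read.delim(p)
  expect_named(df, c("time", "f0"))
  expect_gt(nrow(df), 50)
})
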