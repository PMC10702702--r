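test_that("the long-term spectrum localizes tones and harmonics", {
  seg <- sine_segment(1000, duration = 1)
  sp <- fourier_spectrum(seg)
  df <- sp$freqs[2] - sp$freqs[1]
  expect_lt(abs(sp$freqs[which.max(sp$power)] - 1000), df + 1e-9)

  fs <- 44100
  t <- (0:(fs - 1)) / fs
  x <- 0.4 * sin(2 * pi * 200 * t) + 0.4 * sin(2 * pi * 400 * t)
  sp2 <- fourier_spectrum(select_analysis_window(voice_recording(x, fs)))
  p1 <- sp2$magnitude_db[which.min(abs(sp2$freqs - 200))]
  p2 <- sp2$magnitude_db[which.min(abs(sp2$freqs - 400))]
  expect_lt(abs(p1 - p2), 1)

  x3 <- impulse_train(220 / fs, rep(1, 250), fs)
  f0_true <- fs / 220  # exact integer-sample period
  sp3 <- fourier_spectrum(select_analysis_window(voice_recording(x3, fs)))
  df3 <- sp3$freqs[2] - sp3$freqs[1]
  for (k in 1:5) {
    sel <- abs(sp3$freqs - k * f0_true) < 50
    pk <- sp3$freqs[sel][which.max(sp3$power[sel])]
    expect_lt(abs(pk - k * f0_true), df3 + 1e-9)
  }
})

test_that("spectral power obeys the window-compensated Parseval identity", {
  set.seed(1)
  x <- stats::rnorm(round(1.7 * 44100)) / 4
  seg <- select_analysis_window(voice_recording(x / max(abs(x)), 44100))
  sp <- fourier_spectrum(seg)
  n <- length(seg$samples)
  w <- 0.5 - 0.5 * cos(2 * pi * (0:(n - 1)) / (n - 1))
  expect_equal(sum(sp$power), sum((seg$samples * w)^2) / sum(w^2),
               tolerance = 1e-6)
})

test_that("H1-H2 reproduces closed-form two-tone differences", {
  fs <- 44100
  t <- (0:(2 * fs - 1)) / fs
  mk <- function(a1, a2) {
    x <- a1 * sin(2 * pi * 200 * t) + a2 * sin(2 * pi * 400 * t)
    fourier_spectrum(select_analysis_window(voice_recording(x / 2, fs)))
  }
  expect_equal(h1h2(mk(1.0, 0.5), 200), 20 * log10(2), tolerance = 0.05)
  expect_equal(h1h2(mk(0.7, 0.7), 200), 0, tolerance = 0.05)
  expect_equal(h1h2(mk(0.5, 0.5 * 10^(3 / 20)), 200), -3, tolerance = 0.05)
})

test_that("autocorrelation HNR matches its closed form on constructed tracks", {
  tr1 <- make_track(rep(200, 10), peak_autocorr = rep(0.5, 10))
  expect_equal(hnr(NULL, tr1), 0)
  tr2 <- make_track(rep(200, 10), peak_autocorr = rep(0.99, 10))
  expect_equal(hnr(NULL, tr2), 10 * log10(99), tolerance = 1e-9)
  expect_equal(hnr(NULL, tr2), 19.96, tolerance = 1e-2)
  # r numerically 1 is clamped, not infinite
  tr3 <- make_track(rep(200, 10), peak_autocorr = rep(1, 10))
  expect_true(is.finite(hnr(NULL, tr3)))
})

test_that("HNR recovers a programmed 20 dB noise level within 3 dB", {
  est <- vapply(1:5, function(s) {
    v <- synthesize(synth_spec(jitter_pct = 0, shimmer_pct = 0, hnr_db = 20,
                               duration = 2, seed = s))
    seg <- seg_of(v)
    hnr(seg, estimate_pitch(seg))
  }, numeric(1))
  expect_lt(abs(mean(est) - 20), 3)
})

test_that("the comb-based HNRD separates harmonic from noise spectra", {
  fs <- 44100
  x <- impulse_train(0.005, rep(1, 400), fs)
  sp <- fourier_spectrum(select_analysis_window(voice_recording(x, fs)))
  expect_gt(hnrd(sp, 200), 20)

  # white noise with a forced f0: analytic flat-PSD comb fraction
  vals <- vapply(1:10, function(s) {
    set.seed(s)
    xn <- stats::rnorm(2 * fs)
    hnrd(fourier_spectrum(select_analysis_window(
      voice_recording(xn / max(abs(xn)), fs))), 200)
  }, numeric(1))
  p <- (24 * 50) / 5000  # 24 harmonics below 5 kHz, 50 Hz comb band each
  expect_equal(mean(vals), 10 * log10(p / (1 - p)), tolerance = 0.1)

  # equal harmonic and inter-harmonic power: 0 dB by symmetry
  freqs <- seq(0, 10000, by = 12.5)
  harm <- logical(length(freqs))
  for (k in 1:24) harm <- harm | abs(freqs - k * 200) <= 25
  pw <- numeric(length(freqs))
  pw[harm & freqs > 0 & freqs < 5000] <- 1
  n_h <- sum(pw)
  noise_bins <- !harm & freqs > 0 & freqs < 5000
  pw[noise_bins] <- n_h / sum(noise_bins)
  expect_equal(hnrd(make_spectrum(freqs, pw), 200), 0, tolerance = 1e-9)
})

test_that("HFNO measures the relative 6-10 kHz noise level", {
  vals <- vapply(1:10, function(s) {
    set.seed(s)
    x <- stats::rnorm(44100)
    hfno(fourier_spectrum(select_analysis_window(
      voice_recording(x / max(abs(x)), 44100))))
  }, numeric(1))
  expect_equal(mean(vals), 10 * log10(4000 / 10000), tolerance = 0.2)

  freqs <- seq(0, 22050, by = 50)
  hi_only <- ifelse(freqs >= 6000 & freqs <= 10000, 1, 0)
  expect_equal(hfno(make_spectrum(freqs, hi_only)), 0, tolerance = 1e-9)
  lo_only <- ifelse(freqs > 0 & freqs < 5500, 1, 1e-12)
  expect_lt(hfno(make_spectrum(freqs, lo_only)), -80)
})

test_that("decline and tilt recover a crafted -6 dB/octave harmonic rolloff", {
  fs <- 44100
  t <- (0:(2 * fs - 1)) / fs
  f0 <- 200
  ks <- 1:25
  x <- rowSums(sapply(ks, function(k) (1 / k) * sin(2 * pi * k * f0 * t)))
  sp <- fourier_spectrum(select_analysis_window(voice_recording(x / max(abs(x)), fs)))
  dt <- spectral_decline_tilt(sp, f0)
  expect_equal(dt$decline, -20 * log10(2), tolerance = 0.5)
  expect_lt(dt$tilt, 0)

  xf <- rowSums(sapply(ks, function(k) sin(2 * pi * k * f0 * t)))
  dtf <- spectral_decline_tilt(fourier_spectrum(select_analysis_window(
    voice_recording(xf / max(abs(xf)), fs))), f0)
  expect_equal(dtf$decline, 0, tolerance = 0.2)
  expect_equal(dtf$tilt, 0, tolerance = 0.05)
})

test_that("ratio measures are invariant to waveform gain", {
  v <- synthesize(synth_spec(duration = 2, seed = 8))
  seg1 <- seg_of(v)
  v2 <- v
  v2$samples <- v$samples * 0.2
  seg2 <- seg_of(v2)
  sp1 <- fourier_spectrum(seg1)
  sp2 <- fourier_spectrum(seg2)
  expect_equal(h1h2(sp1, 200), h1h2(sp2, 200), tolerance = 1e-9)
  expect_equal(hnrd(sp1, 200), hnrd(sp2, 200), tolerance = 1e-9)
  expect_equal(hfno(sp1), hfno(sp2), tolerance = 1e-9)
  expect_equal(spectral_decline_tilt(sp1, 200)$decline,
               spectral_decline_tilt(sp2, 200)$decline, tolerance = 1e-9)
  expect_equal(gne(seg1, 2000), gne(seg2, 2000), tolerance = 1e-6)
})

test_that("the LPC envelope is flat on white noise and peaks at formants", {
  envs <- sapply(1:10, function(s) {
    set.seed(s)
    x <- stats::rnorm(44100)
    lpc_envelope(select_analysis_window(
      voice_recording(x / max(abs(x)), 44100)))$envelope_db
  })
  lp <- lpc_envelope(sine_segment(200, 1))  # for the frequency grid
  avg <- rowMeans(envs)
  band <- lp$freqs >= 500 & lp$freqs <= 5000
  expect_lt(diff(range(avg[band])), 3)

  # low-f0 vowel: dense harmonics sample the envelope finely enough that
  # every resonance, including the weak third formant, is localizable
  v <- synthesize(synth_spec(f0 = 100, jitter_pct = 0, shimmer_pct = 0,
                             hnr_db = Inf, duration = 2, seed = 2))
  env <- lpc_envelope(seg_of(v))
  e <- env$envelope_db
  peaks <- which(diff(sign(diff(e))) < 0) + 1
  pf <- env$freqs[peaks]
  for (target in c(500, 1500, 2500))
    expect_lt(min(abs(pf - target)) / target, 0.10)

  expect_error(lpc_envelope(seg_of(v), order = 0), class = "vox_config_error")
})

test_that("the narrowband spectrogram resolves stationary harmonics", {
  fs <- 44100
  x <- impulse_train(0.005, rep(1, 400), fs)
  sg <- narrowband_spectrogram(select_analysis_window(voice_recording(x, fs)))
  row200 <- which.min(abs(sg$freqs - 200))
  expect_lt(stats::sd(sg$power_db[row200, ]), 1)
  # frequency resolution below a typical f0
  expect_lt(sg$freqs[2] - sg$freqs[1], 100)

  silent <- narrowband_spectrogram(select_analysis_window(
    voice_recording(numeric(2 * fs), fs)))
  expect_true(all(silent$power_db == -100))
})

test_that("a rising glide moves the spectrogram fundamental upward", {
  fs <- 44100
  dur <- 2
  t <- (0:(dur * fs - 1)) / fs
  x <- sin(2 * pi * (150 * t + 25 * t^2))  # linear sweep 150 -> 250 Hz
  sg <- narrowband_spectrogram(select_analysis_window(voice_recording(x, fs)))
  band <- sg$freqs >= 100 & sg$freqs <= 350
  peak_f <- apply(sg$power_db[band, ], 2, function(col)
    sg$freqs[band][which.max(col)])
  expect_gt(stats::cor(seq_along(peak_f), peak_f, method = "spearman"), 0.95)
})
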