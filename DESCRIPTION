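Package: voxcore
Title: Sustained-Vowel Acoustic Analysis and Clinical Voice Reports
Version: 1.0.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Acoustic analysis of sustained-vowel recordings for clinical
    voice assessment and teaching. From a WAV recording the package computes
    fundamental-frequency and period statistics, the jitter and shimmer
    perturbation families, spectral and glottal-noise measures (HNR, HNRD,
    HFNO, H1-H2, spectral tilt and decline, and the glottal-to-noise
    excitation ratio at 1, 2 and 3 kHz bandwidths), and cepstral peak
    prominence (CPP/CPPS) with a cepstrogram. Results are rendered as a
    four-file multi-domain acoustic report (oscillograms with f0 and
    intensity traces; Fourier and LPC spectra with a narrowband spectrogram;
    cepstral-peak panels; numeric tables with bar charts) in PNG or PDF. A
    seeded synthetic-voice generator with known per-cycle ground truth makes
    every measure testable without recorded data, and a command-line script
    exposes the pipeline.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    signal,
    jsonlite,
    stats,
    graphics,
    grDevices,
    utils,
    tools
Suggests:
    testthat (>= 3.0.0),
    withr,
    optparse,
    yaml
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
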