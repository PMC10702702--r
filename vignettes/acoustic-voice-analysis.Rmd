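---
title: "Sustained-vowel acoustic analysis with voxcore"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Sustained-vowel acoustic analysis with voxcore}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

voxcore computes the standard clinical taxonomy of acoustic voice measures
from a single sustained-vowel recording and renders them as a four-file
acoustic report. This vignette explains the models and conventions behind
each measure group, the tunable parameters, what the synthetic-voice
generator does and does not emulate, and the numerical choices made where
the literature leaves the design open.

## The analysis protocol

The input is a mono PCM WAV of a sustained vowel (the reference recording
protocol is 44100 Hz, 16 bit). Analysis is restricted to at most 3 seconds:
recordings longer than 3 s are analyzed on their 3 central seconds,
recordings between 1 and 3 s are analyzed whole, and recordings under 1 s
are rejected — too little signal for stable perturbation statistics. The
selected segment is a verbatim slice: no resampling, tapering or
silence-stripping happens at this stage, and "central" is computed on the
raw file rather than on a voiced-region detection (with sustained vowels
the two coincide in practice). When the number of trimmed samples is odd,
the extra sample goes to the trailing margin (the start index is floored),
making selection deterministic.

```{r, eval = FALSE}
library(voxcore)
rec <- read_wav("vowel.wav")
report <- generate_report(rec, patient_header(name = "..."),
                          output_dir = "out")
```

## Pitch and voicing

f0 is tracked by short-term normalized autocorrelation. Each frame (window
length `3 / pitch_floor`, i.e. 40 ms at the default 75 Hz floor; hop 10 ms)
is mean-subtracted and Hann-windowed; the frame autocorrelation is divided
by the window's own autocorrelation to undo the taper bias. Candidate lags
are the local maxima of this corrected function inside the pitch band
(75–600 Hz by default), each refined by parabolic interpolation. A frame is
voiced when its best peak reaches the voicing threshold (0.45) and the
frame clears a silence gate (3% of the segment's global peak, so the
decision is gain-invariant).

Two details matter on real and synthetic voices alike:

* a small per-octave bonus on shorter lags (`octave_cost`, 0.01) breaks
  ties between a period and its double;
* because the taper correction saturates both the true lag and the doubled
  lag near 1, a *second pass* re-scores candidates with a penalty of
  `0.2 |log2(f / median f0)|`, where the median comes from the first pass.
  On a sustained vowel f0 is near-stationary, so this prior suppresses
  occasional sub-harmonic locking without constraining genuine f0
  variation within the band. Without it, mean f0 on noisy synthetic
  voices biased several percent low; with it, recovery errors are below
  0.1%.

## Glottal-cycle extraction

All jitter and shimmer measures need per-cycle periods \(T_i\) and peak
amplitudes \(A_i\). Cycle marks are found by waveform matching: from an
initial dominant extremum (polarity fixed once, from the first voiced
window), the next mark is predicted as the lag in \([0.75, 1.25]/f_0\)
maximizing the normalized cross-correlation between the current cycle's
waveform and its shifted copy, then snapped to the nearest local extremum
of the chosen polarity within 0.35 ms. The combination is deliberate:

* pure peak-picking is precise on clean signals but fragile under additive
  noise — neighbouring formant-ringing peaks of similar height are ~0.4 ms
  apart, and noise flips which one is the maximum, inflating jitter by
  several hundred percent;
* pure cross-correlation is noise-robust but slightly smooths
  cycle-to-cycle differences (the correlation window carries overlapping
  resonator ringing from adjacent cycles);
* prediction by correlation plus a local-extremum snap keeps both
  properties: on noise-free pulse trains the recovered jitter and shimmer
  agree with the generator's stored per-cycle truth to about 1%, and under
  20 dB additive noise recovery of a 0.5/1/2% jitter grid stays strictly
  monotone.

Adjacent plateau samples (a waveform maximum two samples wide) are
collapsed to their leftmost index before snapping; otherwise the tie-break
follows the prediction parity and injects a correlated ±1-sample timing
noise. Amplitudes are measured as the peak absolute sample in a window of
±0.35 periods centered on each mark — wide enough to hold the excitation
peak, narrow enough to exclude the neighbours', whose inclusion would
low-pass the amplitude sequence and bias shimmer down by a third. No cycle
spans an unvoiced gap; cycles whose period leaves the pitch band are
dropped and break the run, so no perturbation difference is ever formed
across either.

## Perturbation measures

With \(T_i\) and \(A_i\) in hand the jitter family is the usual MDVP set:
local absolute (mean \(|T_{i+1}-T_i|\)), local (the same relative to the
mean period), RAP and PPQ5 (mean absolute deviation from 3- and 5-point
moving averages), and DDP (mean absolute second difference, identically
\(3 \times\) RAP). Shimmer is analogous on amplitudes: local, local in dB,
APQ3/5/11 and DDA (\(3 \times\) APQ3). Conventions fixed across the
package: sample (n−1) standard deviations, quantile type 7 (linear
interpolation) for quartiles, coefficients of variation in percent, and
differences/moving averages pooled over voiced runs only. Praat's
MDVP-style period-validity screens (maximum period factor) are not
applied; out-of-band cycles are dropped instead, which is simpler and
directly testable. Measures whose minimum cycle count is not met are
explicit `NA` sentinels — a report never silently omits a measure.

## Spectral and noise measures

A single Hann-windowed DFT of the whole segment serves HNRD, HFNO, H1–H2,
decline and tilt, matching the single-image spectrum panels of the report
(rather than frame-averaged spectra). Its one-sided power is
window-compensated so total spectral power equals windowed time-domain
power exactly; dB values are relative to the spectral maximum with a
−100 dB floor, making every ratio measure gain-invariant by construction.

Four of these measures are named in the clinical literature without a
printed formula, so voxcore declares explicit conventions, each isolated
behind its own function so an alternative can be swapped in:

* **HNRD** — comb decomposition below 5 kHz: energy within \(\pm f_0/8\)
  of each harmonic \(k f_0\) is harmonic, the rest is noise;
  \(10\log_{10}\) of the ratio.
* **HFNO** — power in 6–10 kHz relative to total power 0–10 kHz, in dB.
* **H1–H2** — peak level within \(\pm f_0/4\) of \(f_0\) minus the peak
  within \(\pm f_0/4\) of \(2f_0\).
* **decline / tilt** — least-squares slopes of harmonic-peak level against
  log2 frequency (dB/octave) and against frequency in kHz (dB/kHz), over
  harmonics up to 5.5 kHz; at least 4 located peaks are required.

The frame-wise HNR is autocorrelation-based: with \(r\) the normalized
autocorrelation peak of a voiced frame, the frame HNR is
\(10\log_{10}(r/(1-r))\), averaged over voiced frames; \(r\) is clamped to
\([10^{-9}, 1-10^{-9}]\). Note that jitter and shimmer also reduce \(r\),
so on strongly perturbed voices the estimate saturates below the
programmed additive-noise ratio — the estimate is monotone in the true
noise level, which is the property clinical comparisons rely on.

The **LPC envelope** is rendered at 11025 Hz (polyphase downsampling) with
a Yule-Walker (autocorrelation-method) fit. The signal is pre-emphasized
with a first-order zero (coefficient 0.8) so the poles model vocal-tract
resonances rather than the glottal spectral bulk, and the pre-emphasis
response is divided back out of the rendered envelope so it overlays the
raw spectrum. The default order is `round(rate_kHz) + 5` (16 at 11025 Hz):
with the classic `+2` heuristic the weak third formant of the test vowel
is absorbed into the source tilt, while 16 poles after moderate
pre-emphasis locate 500/1500/2500 Hz resonances within a few percent and
still render white noise flat within 3 dB over 0.5–5 kHz. A stronger
pre-emphasis (e.g. the common 50 Hz time-constant, coefficient ≈ 0.97)
was rejected because an all-pole model of that near-unit zero ripples
visibly on flat spectra.

**GNE** follows the Hilbert-envelope construction: downsample to 10 kHz,
inverse-filter 30 ms frames by order-13 LPC to approximate the excitation,
band-pass the residual at centers every 100 Hz with the requested
bandwidth (1000/2000/3000 Hz, Hann-shaped bands), and take the maximum
cross-correlation, over lags up to 0.3 ms, between envelope pairs whose
centers differ by at least half a bandwidth. Pulse-driven excitation
synchronizes all bands (GNE near 1); turbulence decorrelates them.

The **narrowband spectrogram** uses a 30 ms Gaussian window and 2 ms hop —
a frequency resolution well under a typical f0, so harmonics resolve as
stripes — displayed up to 5 kHz.

## Cepstral measures

Per 40 ms frame (2 ms hop), the power cepstrum is the squared-magnitude
DFT of the log power spectrum, in dB. A regression line is fitted over
quefrencies ≥ 1 ms (excluding the low-quefrency envelope bulge), the peak
is searched within the pitch band only (so CPP cannot lock onto formant
quefrencies), and CPP is the peak height above the line at the peak
quefrency. CPPS smooths the cepstrum matrix with moving averages across
time (7 frames) and quefrency (11 bins) before peak-picking — the
conventional smoothing spans. Both are gain-invariant because a gain
change only shifts the log spectrum, affecting the quefrency-zero bin that
neither the regression region nor the peak band contains. Summary
statistics (mean, SD, quartiles, CV) are computed over the per-frame CPPS
values. "CPPS f0" is read as the frequency equivalent of the median
smoothed peak quefrency, `1 / median(peak quefrency)` — an interpretation,
isolated in one place, since the measure name does not define itself. The
cepstrogram is the pre-smoothing cepstrum matrix, both axes in seconds,
quefrency limited to `1 / pitch_floor`.

## The synthetic-voice generator

Every analyzer is validated against `synthesize()`, a source-filter
generator with exact stored ground truth: a Rosenberg-C glottal pulse
train with cycle lengths \(T_i = (1/f_0)(1+\varepsilon_i)\),
\(\varepsilon_i \sim N(0, \text{jitter}/100)\) (resampled if a draw would
make a cycle non-positive), amplitudes \(A_i = 1+\delta_i\),
\(\delta_i \sim N(0, \text{shimmer}/100)\), cascaded second-order
resonators at (500, 80), (1500, 120), (2500, 160) Hz — an open-vowel
approximation — and white Gaussian noise scaled *after* filtering so the
harmonic-to-noise energy ratio equals the requested HNR exactly. Defaults
(f0 200 Hz, jitter 1%, shimmer 3%, HNR 20 dB, 3 s, 44100 Hz) describe a
mildly dysphonic sustained vowel. Perturbations are i.i.d. rather than
drifting, which keeps analytic expectations computable
(\(E|\Delta T| = 2\sigma/\sqrt{\pi}\) for i.i.d. Gaussian cycle noise); the
pulse *shape* is fixed at the nominal period (jitter stretches the closed
phase), so cycle onsets are well-defined landmarks. Randomness uses
Mersenne-Twister with inversion sampling under the spec's seed, restoring
the caller's RNG state afterwards.

What the generator does *not* emulate — and what passing recovery tests
therefore do not certify on real voices: amplitude/frequency drift and
tremor, period-doubling and sub-harmonic regimes, nonlinear source-tract
interaction, aspiration noise modulated within the glottal cycle (noise is
added post-tract), room acoustics and microphone coloration. Measures on
real dysphonic voices should be compared against normative data, not
against the generator's recovery accuracy.

## The report

Four files per analysis (`<basename>_report_{1..4}.<ext>`), PNG or PDF
(`auto` follows the host platform: PNG on Windows, PDF elsewhere):
oscillograms (full signal plus initial/central/final 50 ms) with f0 and
intensity traces; six Fourier-spectrum views with upper bounds 22.05, 11,
5.5 (with the LPC overlay), 2.75, 1.38 and 0.69 kHz plus the narrowband
spectrogram; the CPP and CPPS series each shown with its regression-line
level and as the line-subtracted prominence, plus the cepstrogram; and the
numeric table of all 45 scalar measures grouped by the report taxonomy
with one vertical bar chart per group, under a patient header whose date
is auto-filled. Undefined measures print as `--` with a footnote. Files
are rendered into a temporary folder and moved into place, so a failed run
leaves no partial report; numeric sidecars (`_measures.tsv/.json`) mirror
the table. Intensity is reported on an uncalibrated dB scale
(`20 log10(RMS / 2e-5)` with digital full scale as nominal reference) — it
is not SPL.

## Numerical and degenerate-input conventions

* dB floor −100 throughout; digital-zero frames clamp there.
* `NLPSD = ln(PSD)` is `-Inf` when the period SD is exactly zero; reported
  as a sentinel.
* An all-unvoiced recording yields a complete measure set of `NA`
  sentinels with `unvoiced_fraction = 100`.
* A voice break is a maximal unvoiced run, interior to the segment,
  longer than `1.25 / pitch_floor` seconds; edge-touching runs do not
  count.
* 16-bit WAV quantization uses full-scale 32768 on write and read, so a
  round trip is exact to within half an LSB.

## Problem sizes in the test suite

The suite validates recovery on 10 seeds per grid point with 2–3 s voices
(the generator's default duration) for f0, jitter, shimmer and HNR grids,
and 10 seeded clean/noisy pairs for CPPS and GNE; module-level tests use
1–2 s voices. These sizes give seed-averaged estimates stable to well
under the tolerances tested while keeping the full suite around two
minutes on a single core.

## Known limitations

* The HNRD/HFNO/decline/tilt conventions are declared, not normative; other
  implementations of the same names may differ in detail.
* The autocorrelation HNR conflates all aperiodicity (jitter, shimmer,
  noise); it is monotone in, but not equal to, the additive-noise ratio.
* Formant tracking is out of scope: the LPC envelope is rendered, not
  parameterized into formant frequencies.
* GRBAS/CAPE-V fields are pass-through text; no perceptual scoring is
  performed.
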