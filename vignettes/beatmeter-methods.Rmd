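---
title: "Methods: frequency-tagged beat/meter entrainment and HRV coupling"
author: "beatmeter"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: frequency-tagged beat/meter entrainment and HRV coupling}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(beatmeter)
```

## The problem

When listeners hear an isochronous tone stream whose tones are accented in
groups of two (duple meter, strong-weak) or three (triple meter,
strong-weak-weak), neural activity entrains both to the *beat* — the tone
rate itself — and to the *meter* — the accent cycle. With a 300 ms
inter-onset interval the beat frequency is 3.33 Hz and the meter frequency
is 1.67 Hz (duple) or 1.11 Hz (triple). Frequency tagging quantifies each as
a spectral peak in the evoked response, and their quotient,

$$\mathrm{ratio} = \frac{P_{\mathrm{beat}}}{P_{\mathrm{meter}}},$$

the **beat-to-meter ratio**, summarises how strongly an individual's brain
tracks the beat level relative to the meter level. In parallel, heart rate
variability — here the RMSSD,
$\sqrt{\tfrac{1}{n-1}\sum_k (\mathrm{IBI}_{k+1}-\mathrm{IBI}_k)^2}$ over the
inter-beat intervals of the same recording block — indexes parasympathetic
influence on the heart. The package implements the full chain linking the
two: stimulus synthesis, the sensor-level frequency-tagging analysis, the
cardiac analysis, and the group/individual statistics, together with a
synthetic-cohort generator whose known ground truth makes every stage
testable by parameter recovery.

The individual-level coupling model is linear on double-log axes:

$$\log_{10}(\mathrm{RMSSD}) = \beta_0 + \beta_1 \log_{10}(\mathrm{ratio}) + \varepsilon .$$

## Stimulus model

`accent_pattern()` builds the per-beat gain sequence: weak beats have gain
1, strong beats (every 2nd or 3rd beat, starting at beat 1) are amplified by
`accent_db` decibels interpreted on amplitude, i.e. gain
$10^{\mathrm{dB}/20}$ (so +10 dB is a factor 3.162) — the convention audio
editors apply when a clip is "amplified by 10 dB". The stream must contain
whole measures only, so the "about 10 s" stimulus is realised as 32 beats
(9.6 s) in duple and 33 beats (9.9 s) in triple; whole measures keep the
meter periodicity exact when the stimulus is tiled or repeated.

The tone placed on each beat is a deterministic stand-in for an instrument
sample: a harmonic complex on 220 Hz (A3) with eight partials at $1/k$
amplitudes, a 40 ms exponential decay and a 5 ms raised-cosine onset ramp,
100 ms long at 22,050 Hz by default. The *locations* of the rhythm-band
spectral peaks depend only on the accent timing, not on the tone's spectrum
or decay — a property the test-suite asserts by swapping tone models — so
any timbre supports the peak-frequency analyses. The *relative powers* at
beat and meter frequencies, by contrast, do depend on timbre: the
stimulus-level beat-to-meter ratios reported for the original instrument
recordings of this paradigm (0.39 duple, 1.04 triple) are properties of
unpublished waveforms and are therefore documented but never asserted; the
synthetic timbre used here gives stimulus-level ratios near 3.

Rhythm-band energy is read from the **amplitude envelope**, not the raw
waveform: `stimulus_envelope()` takes the magnitude of the analytic signal
(FFT-based Hilbert transform) and low-passes it below 30 Hz with a
zero-phase 4th-order Butterworth — comfortably above the 3.33 Hz beat rate
and below the 220 Hz carrier. `spectrum_of()` then computes a one-sided
power spectrum on a lattice of exact multiples of `resolution_hz` (default
0.01 Hz): the segment length is `fs / resolution_hz` samples, longer
signals are cut into consecutive non-overlapping segments whose
periodograms are averaged, and a short signal may be zero-padded on
request. Tiling the ~10 s stimulus beyond 100 s before the 0.01 Hz spectrum
keeps the metrical periodicity exact and places the peaks at 3.33 and
1.67 Hz (duple) / 1.11 Hz (triple) on the lattice.

## The sensor-level frequency-tagging chain

`analyze_block()` applies, in order:

1. **Band-pass 0.1–40 Hz** (`bandpass()`): 4th-order Butterworth low-pass
   and high-pass, each run forward-backward (`signal::filtfilt`), hence
   zero-phase. Passband gain is within 1% over 1–10 Hz; 60 Hz is attenuated
   by about 29 dB; DC is removed. The filter order and type are a package
   choice; a zero-phase Butterworth is the common default in evoked-response
   work.
2. **Epoching and averaging** (`epoch_and_average()`): one epoch per
   stimulus onset over the half-open window $[-1, 11)$ s in samples; epochs
   extending outside the recording are dropped and counted. Averaging the
   ~30 phase-locked repetitions suppresses the non-phase-locked noise
   variance by roughly the epoch count, which the tests verify directly.
3. **Welch PSD on a 0.05 Hz lattice** (`welch_psd()`). A 12 s evoked trace
   cannot natively yield 0.05 Hz spacing (its Fourier spacing is
   1/12 ≈ 0.083 Hz). The package therefore analyses the evoked trace as a
   **single Hann-windowed segment zero-padded to `fs/0.05` samples**
   (a 20 s equivalent), so the grid consists of exact multiples of 0.05 Hz.
   This reproduces the characteristic lattice bins: the bin nearest
   3.333 Hz is **3.35 Hz** and the bin nearest 1.667 Hz is **1.65 Hz**.
   Multi-segment averaging would coarsen the resolution below the reported
   grid; it is used only when a trace is *longer* than one segment. Per-
   channel PSDs are averaged arithmetically across channels before peak
   extraction.
4. **Peak extraction** (`extract_ratio()`): the peak is the maximum bin in
   the closed band — 3.2–3.5 Hz for beat, 1.6–1.9 Hz (duple) or 1.0–1.4 Hz
   (triple) for meter — with ties broken toward the lower frequency and no
   interpolation. The beat-to-meter ratio is the quotient of the two peak
   powers, and is invariant to any overall sensor scale.

One lattice quirk is worth flagging: the bin nearest the triple meter
frequency 1.111 Hz on a fixed 0.05 Hz lattice is **1.10 Hz**, whereas
sensor-level analyses of this paradigm report a mean triple meter peak of
1.11 Hz (SD 0.02) — consistent with per-subject grids that were not a fixed
0.05 lattice. The package keeps the
fixed lattice (it reproduces the 3.35/1.65 Hz bins exactly) and documents,
rather than asserts, the triple meter bin.

## The cardiac chain

`detect_r_peaks()` is a Pan–Tompkins-style detector: zero-phase 5–15 Hz
band-pass, derivative, squaring, 150 ms moving-window integration, adaptive
thresholding with running signal/noise peak estimates (threshold at the
noise estimate plus 25% of the signal-noise gap), a 250 ms refractory
period, and refinement of each detection to the raw-trace maximum within
±80 ms. Because detection is offline, the running estimates are initialised
from global quantiles of the integrated signal; initialising from the first
few local maxima (as in the on-line original) lets a silent lead-in produce
a spurious first detection. The interactive peak editing a human operator
would do is replaced by `correct_r_peaks()`, which applies explicit
add/remove corrections after detection.

`ibis_from_peaks()` converts peak times to intervals in ms; an optional
physiological filter drops intervals outside 300–2000 ms with a logged
count, and it is **off by default** since whether any such exclusion was
applied in the source analysis is unstated. `rmssd()` implements the RMSSD
definition above over the full condition block with no detrending and no
ectopic interpolation.

## The synthetic cohort

`cohort_config()` describes the emulated study conditions: 15 subjects;
rest, duple and triple conditions; 1000 Hz sampling; blocks of a ~10 s
stimulus repeated 30 times with 2 s gaps (~6 min); a 5 min resting ECG;
mean inter-beat interval 850 ms. Per subject and task condition the
generator draws the true ratio and sets RMSSD through the log-log coupling
(parameters above); it renders

- a **sensor block**: per repetition, two sinusoids phase-locked to the
  stimulus onset, one at 3.33 Hz and one at the meter frequency, with
  squared amplitude ratio $10^{\mathrm{true\ log_{10}\ ratio}}$, plus
  independent $1/f$ noise (exponent 1, white floor) per channel with RMS
  `noise_sd` (default 1, i.e. equal to the meter-component amplitude);
- an **ECG trace** from an IBI series whose successive-difference SD equals
  the target RMSSD (stationary Gaussian fluctuation, optional AR(1)), with
  a stereotyped QRS transient per beat, 0.25 Hz baseline wander, and white
  noise at 20 dB SNR by default.

Two named profiles set the coupling to the duple-condition estimates
(`paper_duple`: slope −0.56, intercept 1.83) or the triple-condition
estimates (`paper_triple`: slope −0.29, intercept 1.74). With the cohort
spread of true $\log_{10}$ ratios fixed at SD 0.2 — chosen once as a
realistic spread (ratios roughly 0.6–10, consistent with the width of
published group intervals at n = 15) — the residual coupling noise is
calibrated analytically to the corresponding design $R^2$ through
$\sigma^2_\varepsilon = \beta_1^2\,\sigma_x^2\,(1-R^2)/R^2$, giving
σ ≈ 0.116 (duple, $R^2 = 0.481$) and σ ≈ 0.106 (triple, $R^2 = 0.23$).
Resting RMSSD is modelled as the subject's mean task RMSSD plus a fixed
positive offset (default 6.3 ms, echoing the published group ordering
55.18 ms rest vs 48.9 ms duple); no generative model for the rest-task
difference is given in the source, so this is a declared choice.

Reproducibility: a single root seed drives everything; per-subject,
per-condition substreams are derived deterministically from it, so a cohort
is bit-identical given `(config, seed)`, and `cohort_truth()` reproduces the
latent draws without rendering any signal.

**What the generator does *not* emulate.** Sensor channels are homogeneous
(no gradiometer/magnetometer mix, no forward physics, no artifacts needing
tSSS/SSP), the evoked component is sinusoidal rather than a realistic
auditory waveform, the ECG has no P/T waves and no respiratory sinus
arrhythmia, and the rest-task RMSSD offset is deterministic — which makes
the rest-vs-task contrast in a synthetic cohort *stronger* than real data
would be. Passing tests therefore demonstrate that the analysis chain is
correct and unbiased where its assumptions hold, not that it is robust to
real MEG artifacts; real-data entry points (`read_evoked_csv()`,
`read_ibi_csv()`) bypass the simulator entirely.

## Statistics

- `rm_anova_gg()`: classical one-way within-subject ANOVA; the
  Greenhouse-Geisser ε comes from the double-centered covariance of the
  condition scores, $\varepsilon = (\mathrm{tr}\,C)^2 / ((k-1)\,
  \mathrm{tr}\,C^2)$, clamped to $[1/(k-1), 1]$, and the corrected p uses
  $F$ with both degrees of freedom multiplied by ε. Partial η² is
  $SS_{\mathrm{cond}}/(SS_{\mathrm{cond}}+SS_{\mathrm{err}})$. The tests
  verify exact agreement with `car::Anova` and a 5,000-run null calibration
  of the corrected test (rejection rate ≈ 0.04 at α = .05 — the correction
  is mildly conservative). Note that for $F < 1$ the ε-corrected p can be
  *smaller* than the uncorrected p; that is a property of the correction
  itself, not an implementation artifact. Post hocs are paired t-tests with
  Bonferroni multiply-and-cap.
- `bootstrap_mean()`: subjects resampled with replacement, percentile
  2.5/97.5 interval, seed recorded in the result.
- `loglog_regression()`: OLS of $\log_{10}$ RMSSD on $\log_{10}$ ratio
  (base 10 so the intercept is interpretable in $\log_{10}$ ms), returning
  the **signed** Pearson r with a two-sided p. Reported estimates for this
  paradigm pair a positive r with a negative slope for the same fit; such
  an r is evidently a magnitude, and this package always reports the sign.
- `pearson_cor()` and `signed_rank()` cover the exploratory correlations
  and the generic paired signed-rank comparison.

Degenerate inputs are signalled explicitly everywhere: constant columns
give $F = 0$ with all post hoc p = 1; a constant regression response gives
slope 0 with `NA` correlation and a warning; zero-variance correlation
inputs warn and return `NA`; an empty R-peak search warns and returns a
zero-length result rather than silently producing no intervals.

## Problem sizes used in tests and the acceptance script

Peak frequencies and the ratio statistic are invariant to the sampling rate
(once comfortably above the 40 Hz analysis band) and to the channel count
(channels are homogeneous), so the package's own verification runs at desk
scale: synthesis tests at 4,410 Hz audio rate, sensor simulations at 250 Hz
with 2–4 channels, and the end-to-end coupling-recovery run at 200 subjects
(duple condition, 30 repetitions per block) — large enough that the fitted
slope's sampling error (≈ 0.02) sits well inside the ±0.05 recovery
tolerance. The generator's defaults remain the full study conditions
(1000 Hz, 20 channels, three conditions, 15 subjects).

## Known limitations

- Source-space analyses (forward modelling, dSPM, hemisphere-wise ratios)
  are out of scope; the package stops at sensor-level statistics.
- Frequency-domain HRV (LF/HF) and other time-domain indices are not
  implemented; RMSSD is the single HRV endpoint.
- The fixed 0.05 Hz lattice yields a 1.10 Hz triple meter bin (see above).
- Group-level numbers from the original 15-subject recordings (bootstrap
  means, ANOVA F, regression r) cannot be reproduced without those
  recordings; the package instead demonstrates correctness by parameter
  recovery on synthetic cohorts with known ground truth.
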