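# beatmeter

Frequency-tagged neural entrainment to musical beat and meter, heart rate
variability, and the statistics that link them — with a synthetic-cohort
generator that makes the whole pipeline verifiable by parameter recovery.

## What it does

Listeners entrain neurally both to the **beat** of an isochronous tone
stream (300 ms inter-onset interval → 3.33 Hz) and to its **meter**, the
accent cycle imposed by amplifying every 2nd tone (duple, 1.67 Hz) or every
3rd tone (triple, 1.11 Hz) by +10 dB. The package quantifies the relative
strength of the two as the **beat-to-meter ratio**

    ratio = P_beat / P_meter

where `P_beat` is the peak of the channel-averaged Welch PSD of the evoked
response in 3.2–3.5 Hz and `P_meter` the peak in the condition's meter band
(1.6–1.9 Hz duple, 1.0–1.4 Hz triple), on a frequency lattice of exact
multiples of 0.05 Hz. Cardiac parasympathetic tone is measured as the
**RMSSD** of the inter-beat intervals, `sqrt(mean(diff(IBI)^2))` in ms,
after automatic R-peak detection. The two are linked per subject by the
log-log coupling model

    log10(RMSSD) = intercept + slope * log10(ratio) + e

estimated by OLS, alongside a repeated-measures ANOVA of RMSSD across
rest/duple/triple (Greenhouse–Geisser corrected, Bonferroni post hocs) and
a subject-level bootstrap of the ratio (1,000 repetitions, percentile 95%
CI).

Modules: stimulus synthesis (`accent_pattern`, `synthesize_stimulus`,
`stimulus_envelope`, `spectrum_of`, `find_peak`), entrainment analysis
(`bandpass`, `epoch_and_average`, `welch_psd`, `extract_ratio`,
`analyze_block`), cardiac analysis (`detect_r_peaks`, `ibis_from_peaks`,
`rmssd`), synthetic cohort (`cohort_config`, `cohort_profile`,
`simulate_evoked_block`, `simulate_ibi_series`, `render_ecg`,
`generate_cohort`), statistics (`rm_anova_gg`, `bootstrap_mean`,
`loglog_regression`, `pearson_cor`), and the orchestrating `run_pipeline`.
See the methods vignette (`vignettes/beatmeter-methods.Rmd`) for the model
details and design choices.

## Worked example

Simulate a 15-subject cohort under the duple coupling profile (slope −0.56,
intercept 1.83 on log10 axes) with rest, duple and triple conditions, and
run the full chain:

```r
library(beatmeter)

cfg <- cohort_profile("paper_duple",
                      conditions = c("rest", "duple", "triple"),
                      n_subjects = 15, n_channels = 4,
                      fs_neural_hz = 250, fs_ecg_hz = 250, seed = 42)
rep <- run_pipeline(cfg, n_boot = 1000)
print(rep)
#> bm_report: 15 subjects, conditions {rest, duple, triple}
#>   duple: bootstrap ratio mean 2.92 [2.47, 3.52]; coupling slope -0.390, r -0.476 (p 0.0732)
#>   triple: bootstrap ratio mean 3.08 [2.47, 3.75]; coupling slope -0.773, r -0.731 (p 0.00194)
#>   RMSSD ANOVA: F(2, 28) = 1.446, p_GG = 0.2499, eta2 = 0.094

print(rep$coupling$duple)
#> log10(RMSSD) = 1.775 -0.390 * log10(ratio)   (n = 15)
#> Pearson r = -0.476, R-squared = 0.226, p = 0.07322
```

Each bootstrap line is the resampled group mean of the per-subject
beat-to-meter ratios with its percentile 95% CI; the coupling line is the
fitted log-log regression of RMSSD on ratio within that condition. At
n = 15 the fitted slopes scatter widely around the generating value −0.56 —
exactly the sampling behaviour a 15-subject study implies; at n = 200 the
pipeline recovers the slope within ±0.05 (see below). `plot(rep)` draws the
coupling scatter with the fitted line, and
`run_pipeline(..., out_dir = "out")` writes the per-subject measures,
bootstrap distributions, a JSON report and the serialized configuration.

Single stages work standalone, e.g. the stimulus-level spectrum:

```r
stim <- synthesize_stimulus(accent_pattern("duple", 32, accent_db = 10))
sp   <- spectrum_of(stimulus_envelope(tile_stimulus(stim, 100)),
                    resolution_hz = 0.01)
find_peak(sp, c(2.5, 4.5))$freq_hz   # 3.33  (beat)
find_peak(sp, c(1.4, 2.0))$freq_hz   # 1.67  (duple meter)
```

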