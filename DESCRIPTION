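Package: beatmeter
Title: Frequency-Tagged Beat and Meter Entrainment and Heart Rate Variability
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for studying neural entrainment to musical beat and meter
    and its relation to cardiac parasympathetic tone. Synthesizes accented
    isochronous tone streams in duple and triple meter, quantifies
    frequency-tagged responses in multichannel sensor recordings as a
    beat-to-meter spectral power ratio (band-pass filtering, epoching, evoked
    averaging, Welch power spectral density on a fixed frequency lattice,
    band-limited peak extraction), computes time-domain heart rate
    variability (RMSSD) from ECG-like traces via R-peak detection, and links
    the two with repeated-measures ANOVA (Greenhouse-Geisser corrected),
    subject-level bootstrap, and log-log regression. A synthetic-cohort
    generator with a controllable log-log coupling between the beat-to-meter
    ratio and RMSSD makes every stage verifiable by parameter recovery.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    signal,
    jsonlite,
    stats,
    utils,
    graphics,
    grDevices
Suggests:
    testthat (>= 3.0.0),
    car
Config/testthat/edition: 3
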