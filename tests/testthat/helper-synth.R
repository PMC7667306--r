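# shared fixtures: everything is generated in code at test time

# fast tone model for spectral tests: lower sample rate, same rhythm content
test_tone <- function(fs_hz = 4410) tone_model(fs_hz = fs_hz)

# envelope spectrum of a tiled stimulus at a 0.01 Hz lattice
tiled_envelope_spectrum <- function(meter, n_beats, accent_db = 10,
                                    fs_hz = 4410, min_s = 100) {
  stim <- synthesize_stimulus(accent_pattern(meter, n_beats, accent_db),
                              test_tone(fs_hz))
  spectrum_of(stimulus_envelope(tile_stimulus(stim, min_s)),
              resolution_hz = 0.01)
}

# small cohort configuration that keeps simulation cheap
tiny_config <- function(...) {
  args <- utils::modifyList(
    list(n_subjects = 3, n_channels = 2, fs_neural_hz = 250,
         fs_ecg_hz = 250, n_reps = 3, rest_duration_s = 60),
    list(...))
  do.call(cohort_profile, c(list("paper_duple"), args))
}

# detector scoring against simulator ground truth
peak_scores <- function(detected_s, truth_s, tol_s = 0.010) {
  recall <- mean(vapply(truth_s, function(p) min(abs(detected_s - p)),
                        numeric(1)) <= tol_s)
  precision <- mean(vapply(detected_s, function(p) min(abs(truth_s - p)),
                           numeric(1)) <= tol_s)
  list(recall = recall, precision = precision)
}
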