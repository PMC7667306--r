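test_that("accent patterns encode the metrical hierarchy", {
  p <- accent_pattern("duple", 4, accent_db = 10)
  expect_equal(p$accent_gains, c(10^0.5, 1, 10^0.5, 1), tolerance = 1e-12)
  expect_equal(round(p$accent_gains[1], 3), 3.162)

  expect_equal(accent_pattern("triple", 3, accent_db = 0)$accent_gains,
               c(1, 1, 1))

  p6 <- accent_pattern("triple", 6, accent_db = 6)
  expect_equal(p6$accent_gains, c(10^0.3, 1, 1, 10^0.3, 1, 1),
               tolerance = 1e-12)
  expect_equal(round(p6$accent_gains[1], 3), 1.995)

  expect_error(accent_pattern("duple", 5), "multiple")
  expect_error(accent_pattern("triple", 8), "multiple")
  expect_error(accent_pattern("duple", 4, accent_db = -1))
})

test_that("stimulus synthesis respects duration, RMS reference and linearity", {
  tone <- test_tone()
  stim <- synthesize_stimulus(accent_pattern("duple", 32), tone)
  expect_equal(length(stim$samples) / stim$fs_hz, 9.6)
  expect_equal(stim$rms, 0.01, tolerance = 1e-9)

  s3 <- synthesize_stimulus(accent_pattern("triple", 33), tone)
  expect_equal(length(s3$samples) / s3$fs_hz, 9.9)

  # linearity: scaling the single beat's gain scales the waveform
  p1 <- accent_pattern("duple", 2, accent_db = 0)
  p2 <- p1
  p2$accent_gains <- p2$accent_gains * 2
  u1 <- synthesize_stimulus(p1, tone, normalize_rms = FALSE)
  u2 <- synthesize_stimulus(p2, tone, normalize_rms = FALSE)
  expect_equal(u2$samples, 2 * u1$samples, tolerance = 1e-12)

  bad_tone <- tone_model(duration_s = 0.4, fs_hz = 4410)
  expect_error(synthesize_stimulus(accent_pattern("duple", 4), bad_tone),
               "overlap")
})

test_that("envelope tracks tone amplitudes", {
  # pure constant-amplitude tone: envelope flat at the amplitude
  fs <- 4410
  x <- 0.3 * sin(2 * pi * 220 * seq(0, 2, by = 1 / fs))
  env <- stimulus_envelope(list(samples = x, fs_hz = fs))
  mid <- env$samples[round(0.3 * fs):round(1.7 * fs)]
  expect_lt(max(abs(mid - 0.3)) / 0.3, 0.02)

  # silence stays silent
  env0 <- stimulus_envelope(list(samples = numeric(2 * fs), fs_hz = fs))
  expect_true(all(env0$samples == 0))

  # accented vs unaccented tone: envelope peak ratio matches the +10 dB gain
  stim <- synthesize_stimulus(accent_pattern("duple", 2), test_tone(),
                              normalize_rms = FALSE)
  env <- stimulus_envelope(stim)
  n_half <- length(env$samples) %/% 2
  pk_strong <- max(env$samples[seq_len(n_half)])
  pk_weak <- max(env$samples[(n_half + 1):length(env$samples)])
  expect_equal(pk_strong / pk_weak, 10^0.5, tolerance = 0.02)
})

test_that("power spectra land tones on the expected bins", {
  fs <- 200
  t <- seq(0, 100 - 1 / fs, by = 1 / fs)
  sp <- spectrum_of(sin(2 * pi * 2 * t), fs_hz = fs, resolution_hz = 0.01)
  expect_equal(sp$freqs_hz[which.max(sp$power)], 2.00)

  # Parseval on pure on-grid tones: amplitudes (2a, a) give power ratio 4
  x <- 2 * sin(2 * pi * 2 * t) + sin(2 * pi * 5 * t)
  sp2 <- spectrum_of(x, fs_hz = fs, resolution_hz = 0.01)
  p2 <- sp2$power[which.min(abs(sp2$freqs_hz - 2))]
  p5 <- sp2$power[which.min(abs(sp2$freqs_hz - 5))]
  expect_equal(p2 / p5, 4, tolerance = 0.01)

  # too-short signal is rejected unless padding is requested
  expect_error(spectrum_of(sin(2 * pi * 2 * t[1:fs]), fs_hz = fs,
                           resolution_hz = 0.01), "pad")
  expect_silent(spectrum_of(sin(2 * pi * 2 * t[1:fs]), fs_hz = fs,
                            resolution_hz = 0.01, pad = TRUE))
})

test_that("metrical envelope spectra peak at beat and meter frequencies", {
  spd <- tiled_envelope_spectrum("duple", 32)
  expect_equal(find_peak(spd, c(2.5, 4.5))$freq_hz, 3.33)
  expect_equal(find_peak(spd, c(1.4, 2.0))$freq_hz, 1.67)

  spt <- tiled_envelope_spectrum("triple", 33)
  expect_equal(find_peak(spt, c(2.5, 4.5))$freq_hz, 3.33)
  expect_equal(find_peak(spt, c(0.9, 1.4))$freq_hz, 1.11)

  # ratio of the band peaks is strictly positive and finite
  r <- stimulus_beat_meter_ratio(spd, "duple")
  expect_true(is.finite(r) && r > 0)
})

test_that("peak frequencies are invariant to the tone timbre", {
  for (tone in list(tone_model(fs_hz = 4410),
                    tone_model(f0_hz = 330, n_harmonics = 4,
                               decay_tau_s = 0.02, fs_hz = 4410))) {
    stim <- synthesize_stimulus(accent_pattern("duple", 32), tone)
    sp <- spectrum_of(stimulus_envelope(tile_stimulus(stim, 100)),
                      resolution_hz = 0.01)
    expect_equal(find_peak(sp, c(2.5, 4.5))$freq_hz, 3.33)
    expect_equal(find_peak(sp, c(1.4, 2.0))$freq_hz, 1.67)
  }
})

test_that("an unaccented isochronous stream carries no meter component", {
  sp <- tiled_envelope_spectrum("duple", 32, accent_db = 0)
  p_beat <- find_peak(sp, c(3.2, 3.5))$power
  p_meter <- find_peak(sp, c(1.6, 1.9))$power
  expect_lt(p_meter / p_beat, 0.01)
})

test_that("doubling all accent gains multiplies spectral power by four", {
  tone <- test_tone()
  p1 <- accent_pattern("duple", 32)
  p2 <- p1
  p2$accent_gains <- 2 * p2$accent_gains
  s1 <- spectrum_of(tile_stimulus(synthesize_stimulus(p1, tone,
                                                      normalize_rms = FALSE), 50),
                    resolution_hz = 0.02)
  s2 <- spectrum_of(tile_stimulus(synthesize_stimulus(p2, tone,
                                                      normalize_rms = FALSE), 50),
                    resolution_hz = 0.02)
  expect_equal(s2$power, 4 * s1$power, tolerance = 1e-10)
})

test_that("find_peak matches a brute-force band maximum and breaks ties low", {
  set.seed(42)
  for (i in 1:20) {
    f <- seq(0, 10, by = 0.05)
    pw <- stats::runif(length(f))
    spec <- structure(list(freqs_hz = f, power = pw, resolution_hz = 0.05),
                      class = "power_spectrum")
    band <- sort(stats::runif(2, 0, 10))
    sel <- which(f >= band[1] & f <= band[2])
    if (length(sel) == 0) next
    pk <- find_peak(spec, band)
    expect_equal(pk$power, max(pw[sel]))
    expect_equal(pk$freq_hz, f[sel[which.max(pw[sel])]])
  }

  # explicit tie rule: all-equal power returns the lowest band frequency
  spec <- structure(list(freqs_hz = seq(0, 5, 0.05),
                         power = rep(1, 101), resolution_hz = 0.05),
                    class = "power_spectrum")
  expect_equal(find_peak(spec, c(3.2, 3.5))$freq_hz, 3.2)

  # single nonzero bin dominates its band
  pw <- rep(0, 101)
  pw[which.min(abs(seq(0, 5, 0.05) - 3.35))] <- 7
  spec$power <- pw
  pk <- find_peak(spec, c(3.2, 3.5))
  expect_equal(pk$freq_hz, 3.35)
  expect_equal(pk$power, 7)

  expect_error(find_peak(spec, c(5.4, 5.9)), "no frequency bins")
})

test_that("stimulus WAV export writes a valid RIFF header and sidecar", {
  stim <- synthesize_stimulus(accent_pattern("duple", 4), test_tone())
  path <- tempfile(fileext = ".wav")
  write_wav(stim, path, gain = 50)
  bytes <- readBin(path, "raw", 64)
  expect_identical(rawToChar(bytes[1:4]), "RIFF")
  expect_identical(rawToChar(bytes[9:16]), "WAVEfmt ")
  expect_equal(file.size(path), 44 + 2 * length(stim$samples))
  meta <- jsonlite::read_json(paste0(path, ".json"))
  expect_equal(meta$meter, "duple")
  expect_equal(meta$ioi_s, 0.3)
  unlink(c(path, paste0(path, ".json")))
})
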