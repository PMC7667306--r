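test_that("the band-pass preserves the rhythm band and rejects DC and 60 Hz", {
  fs <- 500
  t <- seq(0, 40, by = 1 / fs)
  mid <- seq(10 * fs, 30 * fs)

  y <- bandpass(sin(2 * pi * 3.33 * t), fs)
  amp <- (max(y[mid]) - min(y[mid])) / 2
  expect_equal(amp, 1, tolerance = 0.01)

  y0 <- bandpass(rep(2, length(t)), fs)
  expect_lt(abs(mean(y0[mid])), 0.02)
  expect_lt(max(abs(y0[mid])), 0.05)

  y60 <- bandpass(sin(2 * pi * 60 * t), fs)
  amp60 <- (max(y60[mid]) - min(y60[mid])) / 2
  expect_lt(20 * log10(amp60), -20)

  expect_error(bandpass(t, fs, lo_hz = 50, hi_hz = 40), "corner")
  expect_error(bandpass(t, fs, lo_hz = 0.1, hi_hz = 300), "corner")

  # matrix input filters each channel independently
  m <- rbind(sin(2 * pi * 3.33 * t), rep(1, length(t)))
  fm <- bandpass(m, fs)
  expect_equal(dim(fm), dim(m))
  expect_equal(fm[1, ], bandpass(m[1, ], fs))
})

test_that("epoching and averaging behaves like an arithmetic mean", {
  fs <- 100
  sig <- sin(2 * pi * 2 * seq(0, 12 - 1 / fs, by = 1 / fs))
  # identical noise-free repetitions: evoked equals one repetition
  nrep <- 4
  rec <- rep(sig, nrep)
  events <- 1 + (0:(nrep - 1)) * 12  # tmin = -1 maps epoch onto each copy
  ev <- epoch_and_average(rec, fs, events, tmin_s = -1, tmax_s = 11)
  expect_equal(ev$n_epochs_averaged, nrep)
  expect_equal(as.numeric(ev$data), sig, tolerance = 1e-12)

  # single event returns that epoch
  ev1 <- epoch_and_average(rec, fs, events[2], tmin_s = -1, tmax_s = 11)
  expect_equal(as.numeric(ev1$data), sig, tolerance = 1e-12)
  expect_equal(ev1$n_epochs_averaged, 1L)

  # epochs outside the recording are dropped with a logged count
  expect_message(
    ev2 <- epoch_and_average(rec, fs, c(events, 47.5), tmin_s = -1,
                             tmax_s = 11),
    "dropped 1")
  expect_equal(ev2$n_dropped, 1L)
  expect_error(epoch_and_average(rec, fs, 200, tmin_s = -1, tmax_s = 11),
               "no epoch")
})

test_that("averaging N epochs suppresses noise variance about N-fold", {
  fs <- 100
  n_ep <- 30
  sig <- sin(2 * pi * 2 * seq(0, 12 - 1 / fs, by = 1 / fs))
  set.seed(55)
  ratios <- replicate(8, {
    rec <- rep(sig, n_ep) + stats::rnorm(length(sig) * n_ep)
    events <- 1 + (0:(n_ep - 1)) * 12
    ev <- epoch_and_average(rec, fs, events, tmin_s = -1, tmax_s = 11)
    stats::var(as.numeric(ev$data) - sig)
  })
  expect_equal(mean(ratios), 1 / n_ep, tolerance = 0.2)
})

test_that("the PSD lattice is exact and holds the printed peak bins", {
  fs <- 500
  t <- seq(-1, 11 - 1 / fs, by = 1 / fs)
  x <- sin(2 * pi * (10 / 3) * t) + 0.5 * sin(2 * pi * (10 / 6) * t)
  psd <- welch_psd(matrix(x, 1), resolution_hz = 0.05, fs_hz = fs)

  expect_equal(psd$freqs_hz, (seq_along(psd$freqs_hz) - 1) * 0.05)
  # the lattice bin nearest 3.333 Hz is 3.35; nearest 1.667 Hz is 1.65
  expect_equal(psd$freqs_hz[which.min(abs(psd$freqs_hz - 10 / 3))], 3.35)
  expect_equal(psd$freqs_hz[which.min(abs(psd$freqs_hz - 10 / 6))], 1.65)
  # and the band maxima land there
  expect_equal(find_peak(psd, c(3.2, 3.5))$freq_hz, 3.35)
  expect_equal(find_peak(psd, c(1.6, 1.9))$freq_hz, 1.65)

  expect_error(welch_psd(matrix(x, 1), resolution_hz = 0, fs_hz = fs))
  expect_error(welch_psd(matrix(x, 1), resolution_hz = -1, fs_hz = fs))
})

test_that("on-grid sinusoid amplitudes (2a, a) give peak power ratio 4", {
  fs <- 500
  t <- seq(0, 20 - 1 / fs, by = 1 / fs)
  x <- 2 * sin(2 * pi * 3.35 * t) + sin(2 * pi * 1.65 * t)
  psd <- welch_psd(matrix(x, 1), resolution_hz = 0.05, fs_hz = fs)
  p1 <- find_peak(psd, c(3.2, 3.5))
  p2 <- find_peak(psd, c(1.6, 1.9))
  expect_equal(p1$power / p2$power, 4, tolerance = 0.05 * 4)
})

test_that("coarser-than-native resolution falls back to segment averaging", {
  fs <- 200
  t <- seq(0, 30 - 1 / fs, by = 1 / fs)
  psd <- welch_psd(matrix(sin(2 * pi * 2 * t), 1), resolution_hz = 0.2,
                   fs_hz = fs)
  expect_equal(psd$freqs_hz[which.max(psd$power_avg)], 2)
})

test_that("ratio extraction divides the printed band peak powers", {
  # construct a PSD holding the study's printed duple mean peak powers
  f <- seq(0, 5, by = 0.05)
  pw <- rep(0, length(f))
  pw[which.min(abs(f - 3.35))] <- 3.94e-25
  pw[which.min(abs(f - 1.65))] <- 2.05e-25
  psd <- structure(list(freqs_hz = f, power_per_channel = matrix(pw, 1),
                        power_avg = pw, resolution_hz = 0.05),
                   class = "psd_result")
  r <- extract_ratio(psd, "duple")
  expect_equal(r$ratio, 3.94 / 2.05, tolerance = 1e-12)
  expect_equal(round(r$ratio, 3), 1.922)
  expect_equal(r$f_beat_hz, 3.35)
  expect_equal(r$f_meter_hz, 1.65)

  # equal peak powers give ratio 1; zero meter power is rejected
  pw2 <- pw; pw2[which.min(abs(f - 1.65))] <- 3.94e-25
  psd$power_avg <- pw2
  expect_equal(extract_ratio(psd, "duple")$ratio, 1)
  psd$power_avg <- rep(0, length(f))
  expect_error(extract_ratio(psd, "duple"), "zero")

  # triple condition searches the 1.0-1.4 Hz meter band
  pw3 <- rep(0, length(f))
  pw3[which.min(abs(f - 3.35))] <- 2
  pw3[which.min(abs(f - 1.10))] <- 1
  psd$power_avg <- pw3
  r3 <- extract_ratio(psd, "triple")
  expect_equal(r3$f_meter_hz, 1.10)
  expect_equal(r3$ratio, 2)
})

test_that("the ratio is invariant to overall sensor scale", {
  cfg <- tiny_config(noise_sd = 0.5, n_reps = 3)
  set.seed(77)
  blk <- simulate_evoked_block(0.3, "duple", cfg)
  r1 <- analyze_block(blk$data, blk$fs_hz, blk$event_times_s, "duple")
  r2 <- analyze_block(blk$data * 3.7, blk$fs_hz, blk$event_times_s, "duple")
  expect_equal(r2$ratio, r1$ratio, tolerance = 1e-9)
  expect_equal(r2$p_beat, 3.7^2 * r1$p_beat, tolerance = 1e-6)
})

test_that("channel-averaged power equals the brute-force channel mean", {
  set.seed(12)
  dat <- matrix(stats::rnorm(3 * 3000), 3)
  psd <- welch_psd(dat, resolution_hz = 0.5, fs_hz = 250)
  expect_equal(psd$power_avg, colMeans(psd$power_per_channel),
               tolerance = 1e-12)
})

test_that("pre-averaged evoked CSV input round-trips", {
  fs <- 100
  tm <- seq(-1, 2 - 1 / fs, by = 1 / fs)
  d <- data.frame(time_s = tm, ch1 = sin(tm), ch2 = cos(tm))
  path <- tempfile(fileext = ".csv")
  utils::write.csv(d, path, row.names = FALSE)
  ev <- read_evoked_csv(path)
  expect_s3_class(ev, "evoked_response")
  expect_equal(ev$fs_hz, fs, tolerance = 1e-6)
  expect_equal(nrow(ev$data), 2)
  expect_equal(as.numeric(ev$data[1, ]), d$ch1)
  unlink(path)
})
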