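#' Metrical accent pattern
#'
#' Builds the sequence of per-beat amplitude multipliers that defines a duple
#' (strong-weak) or triple (strong-weak-weak) metrical tone stream. Beats are
#' isochronous with inter-onset interval `ioi_s`; the first beat of every
#' measure is the strong beat, amplified by `accent_db` decibels (amplitude
#' convention: gain = 10^(dB/20)).
#'
#' @param meter "duple" (period 2) or "triple" (period 3).
#' @param n_beats total number of beats; must be a positive multiple of the
#'   meter period so the stream contains whole measures only.
#' @param accent_db accent size in dB applied to strong beats (>= 0).
#' @param ioi_s inter-onset interval in seconds (default 0.3, i.e. a 3.33 Hz
#'   beat rate).
#' @return An object of class `accent_pattern`: list with `meter_label`,
#'   `accent_gains` (weak gain 1, strong gain 10^(accent_db/20)), `ioi_s`,
#'   `period`.
#' @examples
#' accent_pattern("duple", 4, accent_db = 10)$accent_gains
#' @export
accent_pattern <- function(meter = c("duple", "triple"), n_beats,
                           accent_db = 10, ioi_s = 0.3) {
  meter <- match.arg(meter)
  period <- if (meter == "duple") 2L else 3L
  if (!is.numeric(n_beats) || length(n_beats) != 1L || n_beats < 1 ||
      n_beats != round(n_beats)) {
    stop("'n_beats' must be a single positive integer")
  }
  if (n_beats %% period != 0) {
    stop(sprintf("'n_beats' (%d) must be a multiple of the %s meter period (%d)",
                 as.integer(n_beats), meter, period))
  }
  if (!is.numeric(accent_db) || accent_db < 0) {
    stop("'accent_db' must be >= 0")
  }
  if (!is.numeric(ioi_s) || ioi_s <= 0) stop("'ioi_s' must be positive")
  gains <- rep(1, n_beats)
  gains[seq(1L, n_beats, by = period)] <- 10^(accent_db / 20)
  structure(list(meter_label = meter, accent_gains = gains,
                 ioi_s = ioi_s, period = period),
            class = "accent_pattern")
}

#' Deterministic damped harmonic tone model
#'
#' Parameters of the complex tone placed on every beat: a harmonic complex
#' with fundamental `f0_hz`, `n_harmonics` partials with 1/k amplitudes, an
#' exponential amplitude decay with time constant `decay_tau_s`, and a short
#' raised-cosine onset ramp. The tone is fully deterministic given its
#' parameters.
#'
#' @param f0_hz fundamental frequency in Hz (default 220, A3).
#' @param duration_s tone duration in seconds (default 0.1); must be shorter
#'   than the inter-onset interval so successive tones never overlap.
#' @param n_harmonics number of partials (default 8).
#' @param decay_tau_s exponential decay constant in seconds (default 0.04).
#' @param ramp_s raised-cosine onset ramp in seconds (default 0.005).
#' @param fs_hz sample rate in Hz (default 22050).
#' @return An object of class `tone_model`.
#' @export
tone_model <- function(f0_hz = 220, duration_s = 0.1, n_harmonics = 8,
                       decay_tau_s = 0.04, ramp_s = 0.005, fs_hz = 22050) {
  stopifnot(f0_hz > 0, duration_s > 0, n_harmonics >= 1, decay_tau_s > 0,
            ramp_s >= 0, fs_hz > 2 * f0_hz * n_harmonics)
  structure(list(f0_hz = f0_hz, duration_s = duration_s,
                 n_harmonics = n_harmonics, decay_tau_s = decay_tau_s,
                 ramp_s = ramp_s, fs_hz = fs_hz),
            class = "tone_model")
}

# render one tone as a numeric vector (unit peak-gain complex, deterministic)
render_tone <- function(tone) {
  n <- round(tone$duration_s * tone$fs_hz)
  t <- (seq_len(n) - 1) / tone$fs_hz
  x <- numeric(n)
  for (k in seq_len(tone$n_harmonics)) {
    x <- x + sin(2 * pi * k * tone$f0_hz * t) / k
  }
  x <- x * exp(-t / tone$decay_tau_s)
  nr <- round(tone$ramp_s * tone$fs_hz)
  if (nr > 1) {
    ramp <- 0.5 - 0.5 * cos(pi * (seq_len(nr) - 1) / (nr - 1))
    x[seq_len(nr)] <- x[seq_len(nr)] * ramp
  }
  x / max(abs(x))
}

#' Synthesize a metrical tone stream
#'
#' Places one tone at each beat onset `k * ioi_s`, scaled by the pattern's
#' accent gain for that beat. Total duration is `n_beats * ioi_s`. When
#' `normalize_rms` is `TRUE` the waveform is scaled so its root-mean-square
#' amplitude equals `target_rms` (default 0.01), equalising overall intensity
#' across stimuli.
#'
#' @param pattern an [accent_pattern()].
#' @param tone a [tone_model()]; its duration must not exceed the pattern's
#'   inter-onset interval.
#' @param normalize_rms scale output RMS to `target_rms`?
#' @param target_rms reference RMS after normalization (default 0.01).
#' @return An object of class `audio_stimulus`: list with `samples`, `fs_hz`,
#'   `rms`, plus the generating `pattern` and `tone`.
#' @examples
#' stim <- synthesize_stimulus(accent_pattern("duple", 32))
#' length(stim$samples) / stim$fs_hz  # 9.6 s
#' @export
synthesize_stimulus <- function(pattern, tone = tone_model(),
                                normalize_rms = TRUE, target_rms = 0.01) {
  stopifnot(inherits(pattern, "accent_pattern"), inherits(tone, "tone_model"))
  if (tone$duration_s > pattern$ioi_s) {
    stop("tone duration exceeds the inter-onset interval: tones would overlap")
  }
  fs <- tone$fs_hz
  n_beats <- length(pattern$accent_gains)
  n_total <- round(n_beats * pattern$ioi_s * fs)
  w <- render_tone(tone)
  x <- numeric(n_total)
  for (b in seq_len(n_beats)) {
    i0 <- round((b - 1) * pattern$ioi_s * fs)
    idx <- i0 + seq_along(w)
    idx <- idx[idx <= n_total]
    x[idx] <- x[idx] + pattern$accent_gains[b] * w[seq_along(idx)]
  }
  if (normalize_rms) {
    r <- sqrt(mean(x^2))
    if (r == 0) stop("cannot normalize an all-zero stimulus")
    x <- x * (target_rms / r)
  }
  structure(list(samples = x, fs_hz = fs, rms = sqrt(mean(x^2)),
                 pattern = pattern, tone = tone),
            class = "audio_stimulus")
}

#' @export
print.audio_stimulus <- function(x, ...) {
  cat(sprintf("audio_stimulus: %.3f s at %g Hz, rms %.4g (%s, %d beats)\n",
              length(x$samples) / x$fs_hz, x$fs_hz, x$rms,
              x$pattern$meter_label, length(x$pattern$accent_gains)))
  invisible(x)
}

#' Tile a stimulus end-to-end
#'
#' Repeats the waveform back-to-back until it lasts at least
#' `min_duration_s`. Used to reach fine spectral resolution on a short
#' stimulus while keeping its metrical periodicity exact.
#'
#' @param stim an `audio_stimulus`.
#' @param min_duration_s minimum total duration in seconds.
#' @return An `audio_stimulus` with the tiled samples.
#' @export
tile_stimulus <- function(stim, min_duration_s) {
  stopifnot(inherits(stim, "audio_stimulus"), min_duration_s > 0)
  n_rep <- ceiling(min_duration_s * stim$fs_hz / length(stim$samples))
  out <- stim
  out$samples <- rep(stim$samples, n_rep)
  out
}

# analytic-signal magnitude via FFT (Hilbert-transform envelope)
analytic_magnitude <- function(x) {
  n <- length(x)
  X <- stats::fft(x)
  h <- numeric(n)
  if (n %% 2 == 0) {
    h[1] <- 1; h[n / 2 + 1] <- 1
    h[2:(n / 2)] <- 2
  } else {
    h[1] <- 1
    h[2:((n + 1) / 2)] <- 2
  }
  Mod(stats::fft(X * h, inverse = TRUE)) / n
}

#' Amplitude envelope of a stimulus
#'
#' Extracts the slow amplitude envelope that carries the rhythm-band
#' information: magnitude of the analytic signal (FFT-based Hilbert
#' transform), then zero-phase low-pass filtering below `lp_hz`. The envelope
#' has the same length and sample rate as the input and is clamped at zero.
#'
#' @param stim an `audio_stimulus` (or any list with `samples` and `fs_hz`).
#' @param lp_hz envelope low-pass corner in Hz (default 30; well above the
#'   3.33 Hz beat rate, well below the 220 Hz carrier).
#' @return An `audio_stimulus` whose samples are the envelope.
#' @export
stimulus_envelope <- function(stim, lp_hz = 30) {
  stopifnot(length(stim$samples) > 0)
  env <- analytic_magnitude(stim$samples)
  bf <- signal::butter(4, lp_hz / (stim$fs_hz / 2), type = "low")
  env <- signal::filtfilt(bf, env)
  env[env < 0] <- 0
  out <- stim
  out$samples <- env
  out$rms <- sqrt(mean(env^2))
  out
}

#' One-sided power spectrum on a fixed frequency lattice
#'
#' Computes a one-sided power spectrum whose frequency grid consists of
#' integer multiples of `resolution_hz`. The segment length is
#' `fs / resolution_hz` samples: a longer signal is split into consecutive
#' non-overlapping segments whose periodograms are averaged (partial trailing
#' segments are dropped); a shorter signal is zero-padded to one segment when
#' `pad = TRUE` and rejected otherwise.
#'
#' @param x numeric signal, or an `audio_stimulus`.
#' @param fs_hz sample rate; taken from `x` if it is an `audio_stimulus`.
#' @param resolution_hz frequency grid step (default 0.01).
#' @param pad allow zero-padding when the signal is shorter than one segment.
#' @return An object of class `power_spectrum`: list with `freqs_hz`,
#'   `power`, `resolution_hz`, `n_segments`.
#' @export
spectrum_of <- function(x, fs_hz = NULL, resolution_hz = 0.01, pad = FALSE) {
  if (inherits(x, "audio_stimulus")) {
    fs_hz <- x$fs_hz
    x <- x$samples
  }
  stopifnot(is.numeric(x), length(x) > 0, !is.null(fs_hz), fs_hz > 0,
            resolution_hz > 0)
  nseg <- round(fs_hz / resolution_hz)
  if (length(x) < nseg && !pad) {
    stop(sprintf(paste0("signal too short for %.3g Hz resolution ",
                        "(need %.3g s); set pad = TRUE to zero-pad"),
                 resolution_hz, nseg / fs_hz))
  }
  n_segments <- max(1L, floor(length(x) / nseg))
  acc <- numeric(nseg %/% 2 + 1)
  for (s in seq_len(n_segments)) {
    seg <- x[((s - 1) * nseg + 1):min(s * nseg, length(x))]
    if (length(seg) < nseg) seg <- c(seg, numeric(nseg - length(seg)))
    X <- stats::fft(seg)
    acc <- acc + Mod(X[seq_along(acc)])^2 / nseg^2
  }
  pw <- acc / n_segments
  # fold negative frequencies into the one-sided spectrum
  if (length(pw) > 2) {
    interior <- 2:(length(pw) - if (nseg %% 2 == 0) 1 else 0)
    pw[interior] <- 2 * pw[interior]
  }
  structure(list(freqs_hz = (seq_along(pw) - 1) * resolution_hz,
                 power = pw, resolution_hz = resolution_hz,
                 n_segments = n_segments),
            class = "power_spectrum")
}

#' @export
print.power_spectrum <- function(x, ...) {
  cat(sprintf("power_spectrum: %d bins, 0-%.4g Hz at %.4g Hz resolution (%d segment%s)\n",
              length(x$freqs_hz), max(x$freqs_hz), x$resolution_hz,
              x$n_segments, if (x$n_segments == 1) "" else "s"))
  invisible(x)
}

# core band-peak search shared by the stimulus and sensor chains;
# ties break toward the lower frequency (which.max returns the first max)
peak_in_band <- function(freqs, power, band) {
  stopifnot(length(band) == 2, band[1] <= band[2])
  sel <- which(freqs >= band[1] & freqs <= band[2])
  if (length(sel) == 0) {
    stop(sprintf("band [%g, %g] Hz contains no frequency bins", band[1], band[2]))
  }
  i <- sel[which.max(power[sel])]
  structure(list(freq_hz = freqs[i], power = power[i], band_hz = band),
            class = "spectral_peak")
}

#' Maximum-power bin within a closed frequency band
#'
#' Returns the bin of maximum power with `band[1] <= f <= band[2]`; ties are
#' broken toward the lower frequency. No interpolation is performed.
#'
#' @param spec a `power_spectrum` (or a `psd_result`, in which case the
#'   channel-averaged power is searched).
#' @param band_hz numeric length-2 closed interval in Hz.
#' @return An object of class `spectral_peak`: `freq_hz`, `power`, `band_hz`.
#' @export
find_peak <- function(spec, band_hz) {
  if (inherits(spec, "psd_result")) {
    return(peak_in_band(spec$freqs_hz, spec$power_avg, band_hz))
  }
  peak_in_band(spec$freqs_hz, spec$power, band_hz)
}

#' Stimulus-level beat-to-meter power ratio
#'
#' Ratio of the beat-band peak power to the meter-band peak power of a
#' stimulus (envelope) spectrum. The beat band is fixed at 3.2-3.5 Hz; the
#' meter band follows the metrical condition: 1.6-1.9 Hz for duple (600 ms
#' strong-beat period), 1.0-1.4 Hz for triple (900 ms).
#'
#' @param spec a `power_spectrum`.
#' @param meter "duple" or "triple".
#' @param beat_band,meter_band optional band overrides (Hz).
#' @return Scalar ratio (> 0), with the two `spectral_peak`s as attributes
#'   `beat_peak` and `meter_peak`.
#' @export
stimulus_beat_meter_ratio <- function(spec, meter = c("duple", "triple"),
                                      beat_band = c(3.2, 3.5),
                                      meter_band = NULL) {
  meter <- match.arg(meter)
  if (is.null(meter_band)) {
    meter_band <- if (meter == "duple") c(1.6, 1.9) else c(1.0, 1.4)
  }
  pb <- find_peak(spec, beat_band)
  pm <- find_peak(spec, meter_band)
  if (pm$power <= 0) stop("meter-band peak power is zero; ratio undefined")
  structure(pb$power / pm$power, beat_peak = pb, meter_peak = pm)
}

#' Write a mono waveform as a 16-bit PCM WAV file
#'
#' Minimal RIFF/WAVE writer for exporting synthesized stimuli. Samples are
#' scaled by `gain` and clipped to \[-1, 1\] before quantization. A JSON
#' sidecar with the synthesis parameters is written alongside when the
#' stimulus carries them.
#'
#' @param stim an `audio_stimulus`.
#' @param path output file path (".wav").
#' @param gain linear scale applied before quantization (default 1).
#' @param sidecar write `<path>.json` with synthesis parameters?
#' @return `path`, invisibly.
#' @export
write_wav <- function(stim, path, gain = 1, sidecar = TRUE) {
  x <- pmax(-1, pmin(1, stim$samples * gain))
  pcm <- as.integer(round(x * 32767))
  fs <- as.integer(round(stim$fs_hz))
  con <- file(path, "wb")
  on.exit(close(con))
  data_bytes <- 2L * length(pcm)
  writeChar("RIFF", con, eos = NULL)
  writeBin(as.integer(36L + data_bytes), con, size = 4, endian = "little")
  writeChar("WAVEfmt ", con, eos = NULL)
  writeBin(16L, con, size = 4, endian = "little")
  writeBin(1L, con, size = 2, endian = "little")   # PCM
  writeBin(1L, con, size = 2, endian = "little")   # mono
  writeBin(fs, con, size = 4, endian = "little")
  writeBin(fs * 2L, con, size = 4, endian = "little")  # byte rate
  writeBin(2L, con, size = 2, endian = "little")   # block align
  writeBin(16L, con, size = 2, endian = "little")  # bits per sample
  writeChar("data", con, eos = NULL)
  writeBin(data_bytes, con, size = 4, endian = "little")
  writeBin(pcm, con, size = 2, endian = "little")
  if (sidecar && !is.null(stim$pattern)) {
    meta <- list(meter = stim$pattern$meter_label,
                 n_beats = length(stim$pattern$accent_gains),
                 ioi_s = stim$pattern$ioi_s,
                 accent_gains = stim$pattern$accent_gains,
                 tone = unclass(stim$tone),
                 fs_hz = stim$fs_hz, rms = stim$rms)
    jsonlite::write_json(meta, paste0(path, ".json"),
                         auto_unbox = TRUE, digits = NA)
  }
  invisible(path)
}

#' Write a spectrum as a two-column CSV
#'
#' @param spec a `power_spectrum`.
#' @param path output path; columns `freq_hz`, `power`.
#' @return `path`, invisibly.
#' @export
write_spectrum_csv <- function(spec, path) {
  utils::write.csv(data.frame(freq_hz = spec$freqs_hz, power = spec$power),
                   path, row.names = FALSE)
  invisible(path)
}
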