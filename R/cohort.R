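#' Synthetic cohort configuration
#'
#' Collects every parameter of the synthetic-cohort generator: cohort size
#' and conditions, the cohort distribution of the true (log10) beat-to-meter
#' ratio, the log-log coupling between ratio and RMSSD, cardiac parameters,
#' sensor geometry and noise, and block timing. Defaults describe the study
#' conditions emulated by the generator: 15 subjects, rest/duple/triple
#' conditions, 1000 Hz sampling, ~6 min blocks of a ~10 s stimulus repeated
#' 30 times with 2 s gaps, mean inter-beat interval 850 ms, and the duple
#' coupling profile (slope -0.56, intercept 1.83 on the log10 scale, with
#' residual noise calibrated so the design R-squared is 0.481).
#'
#' The coupling model is
#' `log10(RMSSD_ms) = intercept + slope * log10(ratio) + e`,
#' `e ~ N(0, coupling_noise_sd)`. Rest-condition RMSSD is the subject's mean
#' task RMSSD plus `rest_rmssd_offset_ms`.
#'
#' @param n_subjects number of subjects (>= 2).
#' @param conditions subset of `c("rest", "duple", "triple")`.
#' @param mu_log10_ratio,sd_log10_ratio cohort mean and SD of the true log10
#'   beat-to-meter ratio.
#' @param coupling_slope,coupling_intercept,coupling_noise_sd log-log
#'   coupling parameters (see Details).
#' @param rest_rmssd_offset_ms amount by which resting RMSSD exceeds the
#'   subject's mean task RMSSD (ms).
#' @param mean_ibi_ms mean inter-beat interval in ms.
#' @param ibi_ar lag-1 autocorrelation of the IBI fluctuation process
#'   (default 0 = white).
#' @param n_channels number of sensor channels.
#' @param block_s block duration in seconds, or `NULL` to fit
#'   `n_reps` repetitions plus lead-in/lead-out automatically.
#' @param n_reps stimulus repetitions per block.
#' @param gap_s silent gap between repetitions (s).
#' @param ioi_s stimulus inter-onset interval (s).
#' @param noise_exponent spectral exponent of the 1/f^a sensor noise.
#' @param noise_sd RMS amplitude of the sensor noise per channel, in the
#'   same arbitrary units as the unit-amplitude meter component.
#' @param ecg_snr_db white-noise SNR of the rendered ECG relative to the R
#'   wave (dB); `Inf` = clean.
#' @param rest_duration_s length of the resting ECG recording (s).
#' @param fs_neural_hz,fs_ecg_hz sampling rates (Hz).
#' @param seed root RNG seed; all per-subject, per-condition substreams are
#'   derived from it deterministically.
#' @return An object of class `cohort_config`.
#' @seealso [cohort_profile()] for the named duple/triple coupling profiles.
#' @export
cohort_config <- function(n_subjects = 15,
                          conditions = c("rest", "duple", "triple"),
                          mu_log10_ratio = 0.394,
                          sd_log10_ratio = 0.2,
                          coupling_slope = -0.56,
                          coupling_intercept = 1.83,
                          coupling_noise_sd = 0.116,
                          rest_rmssd_offset_ms = 6.3,
                          mean_ibi_ms = 850,
                          ibi_ar = 0,
                          n_channels = 20,
                          block_s = NULL,
                          n_reps = 30,
                          gap_s = 2,
                          ioi_s = 0.3,
                          noise_exponent = 1,
                          noise_sd = 1,
                          ecg_snr_db = 20,
                          rest_duration_s = 300,
                          fs_neural_hz = 1000,
                          fs_ecg_hz = 1000,
                          seed = 1) {
  chk <- function(ok, field, msg) {
    if (!ok) stop(sprintf("invalid cohort_config field '%s': %s", field, msg))
  }
  chk(is.numeric(n_subjects) && n_subjects >= 2, "n_subjects", "must be >= 2")
  chk(all(conditions %in% c("rest", "duple", "triple")) &&
        length(conditions) >= 1, "conditions",
      "must be a subset of rest/duple/triple")
  chk(sd_log10_ratio >= 0, "sd_log10_ratio", "must be >= 0")
  chk(coupling_noise_sd >= 0, "coupling_noise_sd", "must be >= 0")
  chk(mean_ibi_ms > 0, "mean_ibi_ms", "must be positive")
  chk(ibi_ar >= 0 && ibi_ar < 1, "ibi_ar", "must be in [0, 1)")
  chk(n_channels >= 1, "n_channels", "must be >= 1")
  chk(n_reps >= 1, "n_reps", "must be >= 1")
  chk(gap_s >= 0, "gap_s", "must be >= 0")
  chk(ioi_s > 0, "ioi_s", "must be positive")
  chk(noise_sd >= 0, "noise_sd", "must be >= 0")
  chk(fs_neural_hz > 0, "fs_neural_hz", "must be positive")
  chk(fs_ecg_hz > 0, "fs_ecg_hz", "must be positive")
  chk(rest_duration_s > 0, "rest_duration_s", "must be positive")
  if (!is.null(block_s)) {
    # longest condition: triple, 33 beats
    need <- n_reps * (33 * ioi_s + gap_s)
    chk(block_s >= need * 0.95, "block_s",
        sprintf("too short for %d repetitions (need about %.0f s)",
                n_reps, need))
  }
  structure(list(n_subjects = as.integer(n_subjects), conditions = conditions,
                 mu_log10_ratio = mu_log10_ratio,
                 sd_log10_ratio = sd_log10_ratio,
                 coupling_slope = coupling_slope,
                 coupling_intercept = coupling_intercept,
                 coupling_noise_sd = coupling_noise_sd,
                 rest_rmssd_offset_ms = rest_rmssd_offset_ms,
                 mean_ibi_ms = mean_ibi_ms, ibi_ar = ibi_ar,
                 n_channels = as.integer(n_channels), block_s = block_s,
                 n_reps = as.integer(n_reps), gap_s = gap_s, ioi_s = ioi_s,
                 noise_exponent = noise_exponent, noise_sd = noise_sd,
                 ecg_snr_db = ecg_snr_db, rest_duration_s = rest_duration_s,
                 fs_neural_hz = fs_neural_hz, fs_ecg_hz = fs_ecg_hz,
                 seed = as.integer(seed)),
            class = "cohort_config")
}

#' Named coupling profiles
#'
#' Returns a [cohort_config()] whose ratio distribution and ratio-RMSSD
#' coupling are set to the duple-condition or triple-condition regression
#' estimates (slope/intercept on the log10 scale), with residual noise
#' calibrated analytically so the design R-squared equals the corresponding
#' condition's value (0.481 duple, 0.23 triple) at the default ratio spread.
#'
#' @param name `"paper_duple"` or `"paper_triple"`.
#' @param ... overrides passed on to [cohort_config()].
#' @return A `cohort_config`.
#' @export
cohort_profile <- function(name = c("paper_duple", "paper_triple"), ...) {
  name <- match.arg(name)
  base <- if (name == "paper_duple") {
    list(mu_log10_ratio = 0.394, coupling_slope = -0.56,
         coupling_intercept = 1.83, coupling_noise_sd = 0.116,
         conditions = c("rest", "duple"))
  } else {
    list(mu_log10_ratio = 0.401, coupling_slope = -0.29,
         coupling_intercept = 1.74, coupling_noise_sd = 0.106,
         conditions = c("rest", "triple"))
  }
  args <- utils::modifyList(base, list(...))
  do.call(cohort_config, args)
}

# deterministic substream seed below 2^31
derive_seed <- function(root, subject, stream) {
  as.integer((as.numeric(root) * 1000003 + subject * 7919 + stream * 104729) %%
               2147483629) + 1L
}

# 1/f^a Gaussian noise with a white floor, unit RMS, via FFT shaping
colored_noise <- function(n, fs_hz, exponent = 1, floor_frac = 0.1) {
  w <- stats::rnorm(n)
  if (exponent == 0) return(w / stats::sd(w))
  k <- 0:(n - 1)
  k <- pmin(k, n - k)              # two-sided |frequency| index
  f <- k * fs_hz / n
  g <- sqrt(1 / pmax(f, fs_hz / n)^exponent + floor_frac)
  x <- Re(stats::fft(stats::fft(w) * g, inverse = TRUE)) / n
  x / sqrt(mean(x^2))
}

# per-condition stimulus length in beats: whole measures, ~10 s
beats_for_meter <- function(meter) if (meter == "duple") 32L else 33L

#' Simulate one frequency-tagged sensor block
#'
#' Renders a multichannel sensor block in which every stimulus repetition
#' contributes two phase-locked sinusoidal components: one at the 3.33 Hz
#' beat frequency and one at the meter frequency (1.67 Hz duple, 1.11 Hz
#' triple), with squared amplitude ratio `10^true_log10_ratio` (the meter
#' component has unit amplitude). Additive 1/f^a noise is drawn
#' independently per channel. Repetition onsets are spaced by the stimulus
#' duration plus `gap_s`, after a 2 s lead-in.
#'
#' Uses the current RNG state; seed beforehand for reproducibility.
#'
#' @param true_log10_ratio true log10 beat-to-meter power ratio.
#' @param meter "duple" or "triple".
#' @param config a [cohort_config()].
#' @return List with `data` (channels x samples), `event_times_s`, `fs_hz`,
#'   `stim_duration_s`, `meter`.
#' @export
simulate_evoked_block <- function(true_log10_ratio,
                                  meter = c("duple", "triple"),
                                  config = cohort_config()) {
  meter <- match.arg(meter)
  stopifnot(is.finite(true_log10_ratio))
  fs <- config$fs_neural_hz
  dur <- beats_for_meter(meter) * config$ioi_s
  events <- 2 + (seq_len(config$n_reps) - 1) * (dur + config$gap_s)
  block_s <- if (is.null(config$block_s)) {
    2 + config$n_reps * (dur + config$gap_s) + 10
  } else {
    config$block_s
  }
  n <- round(block_s * fs)
  f_beat <- 1 / config$ioi_s  # 3.333... Hz for ioi 0.3
  f_meter <- if (meter == "duple") f_beat / 2 else f_beat / 3
  a_beat <- sqrt(10^true_log10_ratio)  # meter amplitude is 1

  sig <- numeric(n)
  for (t0 in events) {
    i0 <- round(t0 * fs)
    idx <- i0 + seq_len(round(dur * fs))
    idx <- idx[idx >= 1 & idx <= n]
    tt <- (idx - 1) / fs - t0
    sig[idx] <- sig[idx] + a_beat * sin(2 * pi * f_beat * tt) +
      sin(2 * pi * f_meter * tt)
  }
  dat <- matrix(0, config$n_channels, n)
  for (ch in seq_len(config$n_channels)) {
    noise <- if (config$noise_sd > 0) {
      config$noise_sd * colored_noise(n, fs, config$noise_exponent)
    } else 0
    dat[ch, ] <- sig + noise
  }
  list(data = dat, event_times_s = events, fs_hz = fs,
       stim_duration_s = dur, meter = meter)
}

#' Simulate an inter-beat-interval series with a target RMSSD
#'
#' IBIs are the mean plus a stationary Gaussian fluctuation (optionally
#' AR(1)) whose successive-difference standard deviation equals the target
#' RMSSD: for lag-1 autocorrelation `ar`, the fluctuation SD is
#' `rmssd / sqrt(2 * (1 - ar))`. The realized RMSSD converges to the target
#' as the series lengthens (within ~5% for a 5 min series).
#'
#' Uses the current RNG state; seed beforehand for reproducibility.
#'
#' @param true_rmssd_ms target RMSSD in ms (>= 0; 0 gives constant IBIs).
#' @param duration_s series duration in seconds (> 10 mean IBIs).
#' @param mean_ibi_ms mean inter-beat interval in ms.
#' @param ar lag-1 autocorrelation of the fluctuation (default 0).
#' @return An `ibi_series` with attribute `true_rmssd_ms`.
#' @export
simulate_ibi_series <- function(true_rmssd_ms, duration_s, mean_ibi_ms = 850,
                                ar = 0) {
  stopifnot(true_rmssd_ms >= 0, mean_ibi_ms > 0, ar >= 0, ar < 1)
  if (duration_s <= 10 * mean_ibi_ms / 1000) {
    stop("'duration_s' must exceed 10 mean inter-beat intervals")
  }
  sd_x <- true_rmssd_ms / sqrt(2 * (1 - ar))
  if (mean_ibi_ms - 5 * sd_x <= 0) {
    stop("target RMSSD too large relative to the mean IBI: intervals would go negative")
  }
  n <- round(duration_s * 1000 / mean_ibi_ms)
  x <- if (true_rmssd_ms == 0) {
    numeric(n)
  } else if (ar == 0) {
    stats::rnorm(n, 0, sd_x)
  } else {
    burn <- 50L
    innov <- stats::rnorm(n + burn, 0, sd_x * sqrt(1 - ar^2))
    as.numeric(stats::filter(innov, ar, method = "recursive"))[-seq_len(burn)]
  }
  ibis <- mean_ibi_ms + x
  ibis <- pmax(ibis, 1)  # guard; unreachable under the 5-sigma check above
  structure(list(ibis_ms = ibis, n_removed = 0L),
            class = "ibi_series", true_rmssd_ms = true_rmssd_ms)
}

#' Render an ECG-like trace from an IBI series
#'
#' Places one stereotyped QRS-like transient (Q and S dips flanking a sharp
#' R peak of unit amplitude) at each cumulative beat time, over slow
#' sinusoidal baseline wander and white noise at a configurable SNR. The
#' ground-truth R-peak times are returned alongside, so the detector can be
#' scored exactly. A zero-length IBI series yields an empty trace.
#'
#' Uses the current RNG state (for the noise); seed beforehand for
#' reproducibility.
#'
#' @param ibis an `ibi_series` (or numeric vector of IBIs in ms).
#' @param fs_hz sampling rate (default 1000).
#' @param snr_db white-noise SNR re the unit R amplitude in dB
#'   (default `Inf` = clean).
#' @param wander_amp amplitude of the 0.25 Hz baseline wander (default 0.05).
#' @return An object of class `ecg_trace`: `trace`, `fs_hz`,
#'   `peak_times_s` (ground truth).
#' @export
render_ecg <- function(ibis, fs_hz = 1000, snr_db = Inf, wander_amp = 0.05) {
  v <- if (inherits(ibis, "ibi_series")) ibis$ibis_ms else ibis
  if (length(v) == 0) {
    return(structure(list(trace = numeric(0), fs_hz = fs_hz,
                          peak_times_s = numeric(0)),
                     class = "ecg_trace"))
  }
  stopifnot(all(v > 300))
  peaks_s <- 0.5 + cumsum(c(0, v)) / 1000
  n <- round((peaks_s[length(peaks_s)] + 0.5) * fs_hz)
  # stereotyped QRS template on a +/- 60 ms support
  tt <- seq(-0.06, 0.06, by = 1 / fs_hz)
  template <- exp(-0.5 * (tt / 0.008)^2) -
    0.15 * exp(-0.5 * ((tt + 0.025) / 0.010)^2) -
    0.25 * exp(-0.5 * ((tt - 0.025) / 0.010)^2)
  half <- (length(template) - 1L) %/% 2L
  x <- numeric(n)
  for (p in peaks_s) {
    c0 <- round(p * fs_hz) + 1L
    idx <- (c0 - half):(c0 + half)
    ok <- idx >= 1L & idx <= n
    x[idx[ok]] <- x[idx[ok]] + template[ok]
  }
  t <- (seq_len(n) - 1) / fs_hz
  x <- x + wander_amp * sin(2 * pi * 0.25 * t)
  if (is.finite(snr_db)) {
    x <- x + stats::rnorm(n, 0, 10^(-snr_db / 20))
  }
  structure(list(trace = x, fs_hz = fs_hz, peak_times_s = peaks_s),
            class = "ecg_trace")
}

# draw the latent per-subject truths (ratios and RMSSDs) for one subject
draw_subject_truth <- function(config, i) {
  task <- setdiff(config$conditions, "rest")
  set.seed(derive_seed(config$seed, i, 0L))
  truth <- list()
  for (cond in task) {
    lr <- stats::rnorm(1, config$mu_log10_ratio, config$sd_log10_ratio)
    lrm <- config$coupling_intercept + config$coupling_slope * lr +
      stats::rnorm(1, 0, config$coupling_noise_sd)
    truth[[cond]] <- list(true_log10_ratio = lr, true_rmssd_ms = 10^lrm)
  }
  if ("rest" %in% config$conditions) {
    task_rmssd <- if (length(task)) {
      mean(vapply(truth, function(z) z$true_rmssd_ms, numeric(1)))
    } else 10^config$coupling_intercept
    truth$rest <- list(true_log10_ratio = NA_real_,
                       true_rmssd_ms = task_rmssd + config$rest_rmssd_offset_ms)
  }
  truth
}

#' Ground-truth manifest without rendering any data
#'
#' Draws only the latent per-subject quantities (true log10 beat-to-meter
#' ratio and true RMSSD per condition) under the same substream scheme as
#' [generate_cohort()], skipping sensor/ECG rendering entirely. Useful for
#' checking the generator's coupling calibration over many seeds.
#'
#' @param config a [cohort_config()].
#' @return Data frame with `subject`, `condition`, `true_log10_ratio`,
#'   `true_rmssd_ms`.
#' @export
cohort_truth <- function(config = cohort_config()) {
  rows <- list()
  for (i in seq_len(config$n_subjects)) {
    truth <- draw_subject_truth(config, i)
    for (cond in names(truth)) {
      rows[[length(rows) + 1L]] <- data.frame(
        subject = i, condition = cond,
        true_log10_ratio = truth[[cond]]$true_log10_ratio,
        true_rmssd_ms = truth[[cond]]$true_rmssd_ms)
    }
  }
  do.call(rbind, rows)
}

# render all blocks for one subject (internal; used by generate_cohort and
# the streaming pipeline)
generate_subject <- function(config, i) {
  truth <- draw_subject_truth(config, i)
  rec <- list(subject_id = i, conditions = list())
  for (j in seq_along(config$conditions)) {
    cond <- config$conditions[j]
    set.seed(derive_seed(config$seed, i, j))
    tr <- truth[[cond]]
    if (cond == "rest") {
      dur <- config$rest_duration_s
      block <- NULL
    } else {
      block <- simulate_evoked_block(tr$true_log10_ratio, cond, config)
      dur <- ncol(block$data) / block$fs_hz
    }
    ibis <- simulate_ibi_series(tr$true_rmssd_ms, dur, config$mean_ibi_ms,
                                config$ibi_ar)
    ecg <- render_ecg(ibis, config$fs_ecg_hz, config$ecg_snr_db)
    rec$conditions[[cond]] <- list(
      sensor_block = block, ecg = ecg, ibi_series = ibis,
      true_log10_ratio = tr$true_log10_ratio,
      true_rmssd_ms = tr$true_rmssd_ms)
  }
  rec
}

#' Generate a synthetic cohort
#'
#' Draws each subject's true log10 beat-to-meter ratio from
#' `N(mu_log10_ratio, sd_log10_ratio)` per task condition, sets
#' `log10(RMSSD)` through the configured log-log coupling, renders the
#' corresponding sensor blocks and ECG traces, and returns the records plus
#' a ground-truth manifest. Fully reproducible: identical `(config, seed)`
#' give identical output.
#'
#' @param config a [cohort_config()].
#' @param keep_data keep the rendered sensor/ECG data in each record? Set
#'   `FALSE` to return ground truth only (the blocks can always be
#'   regenerated from the config and subject id).
#' @return An object of class `bm_cohort`: list with `subjects` (list of
#'   per-subject records), `manifest` (data frame of ground truths), and
#'   `config`.
#' @export
generate_cohort <- function(config = cohort_config(), keep_data = TRUE) {
  stopifnot(inherits(config, "cohort_config"))
  subjects <- vector("list", config$n_subjects)
  rows <- list()
  for (i in seq_len(config$n_subjects)) {
    rec <- generate_subject(config, i)
    for (cond in names(rec$conditions)) {
      cc <- rec$conditions[[cond]]
      rows[[length(rows) + 1L]] <- data.frame(
        subject = i, condition = cond,
        true_log10_ratio = cc$true_log10_ratio,
        true_rmssd_ms = cc$true_rmssd_ms)
    }
    if (!keep_data) {
      for (cond in names(rec$conditions)) {
        rec$conditions[[cond]]$sensor_block <- NULL
        rec$conditions[[cond]]$ecg <- NULL
      }
    }
    subjects[[i]] <- rec
  }
  structure(list(subjects = subjects, manifest = do.call(rbind, rows),
                 config = config),
            class = "bm_cohort")
}

#' @export
print.bm_cohort <- function(x, ...) {
  cat(sprintf("bm_cohort: %d subjects x {%s} (seed %d)\n",
              x$config$n_subjects, paste(x$config$conditions, collapse = ", "),
              x$config$seed))
  invisible(x)
}
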