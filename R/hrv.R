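#' Detect R peaks in an ECG-like trace
#'
#' Pan-Tompkins-style detector: zero-phase 5-15 Hz band-pass, derivative,
#' squaring, 150 ms moving-window integration, then peak picking with an
#' adaptive threshold (running signal/noise peak estimates, threshold at
#' noise + `threshold_frac` of the signal-noise gap) and a 250 ms refractory
#' period. Each detection is refined to the local maximum of the raw trace
#' within +/- 80 ms.
#'
#' @param x numeric ECG trace.
#' @param fs_hz sampling rate in Hz.
#' @param threshold_frac fraction of the running signal-noise gap used for
#'   the detection threshold (default 0.25).
#' @param refractory_s minimum separation between peaks in seconds
#'   (default 0.25).
#' @return An object of class `r_peaks`: list with `times_s` (strictly
#'   increasing) and `fs_hz`. When nothing is detected, a zero-length result
#'   is returned with a warning.
#' @export
detect_r_peaks <- function(x, fs_hz, threshold_frac = 0.25,
                           refractory_s = 0.25) {
  stopifnot(is.numeric(x), fs_hz > 0)
  if (length(x) < 10 * fs_hz) stop("trace shorter than 10 s")
  bp <- signal::butter(2, c(5, 15) / (fs_hz / 2), type = "pass")
  y <- signal::filtfilt(bp, x)
  d <- c(diff(y), 0)
  sq <- d^2
  nw <- max(1L, round(0.150 * fs_hz))
  integ <- stats::filter(sq, rep(1 / nw, nw), sides = 2)
  integ[is.na(integ)] <- 0
  integ <- as.numeric(integ)

  # candidate local maxima of the integrated signal
  cand <- which(diff(sign(diff(integ))) < 0) + 1L
  if (length(cand) == 0) {
    warning("no R peaks detected")
    return(structure(list(times_s = numeric(0), fs_hz = fs_hz),
                     class = "r_peaks"))
  }
  # offline initialization: seed the running signal/noise peak estimates
  # from global statistics so a silent lead-in cannot trigger detections
  spki <- unname(stats::quantile(integ[cand], 0.99))
  npki <- unname(stats::median(integ[cand]))
  keep <- integer(0)
  last_t <- -Inf
  refr <- round(refractory_s * fs_hz)
  for (i in cand) {
    thr <- npki + threshold_frac * (spki - npki)
    if (integ[i] >= thr) {
      if (i - last_t >= refr) {
        keep <- c(keep, i)
        last_t <- i
      } else if (length(keep) && integ[i] > integ[keep[length(keep)]]) {
        keep[length(keep)] <- i  # stronger peak inside the refractory window
        last_t <- i
      }
      spki <- 0.125 * integ[i] + 0.875 * spki
    } else {
      npki <- 0.125 * integ[i] + 0.875 * npki
    }
  }
  if (length(keep) == 0) {
    warning("no R peaks detected")
    return(structure(list(times_s = numeric(0), fs_hz = fs_hz),
                     class = "r_peaks"))
  }
  # refine to the raw-trace maximum within +/- 80 ms
  half <- round(0.080 * fs_hz)
  refined <- vapply(keep, function(i) {
    lo <- max(1L, as.integer(i - half))
    hi <- min(length(x), as.integer(i + half))
    lo + which.max(x[lo:hi]) - 1L
  }, integer(1))
  refined <- sort(unique(refined))
  # enforce the refractory period on refined times, keeping larger peaks
  if (length(refined) > 1) {
    out <- refined[1]
    for (i in refined[-1]) {
      if (i - out[length(out)] >= refr) {
        out <- c(out, i)
      } else if (x[i] > x[out[length(out)]]) {
        out[length(out)] <- i
      }
    }
    refined <- out
  }
  structure(list(times_s = (refined - 1) / fs_hz, fs_hz = fs_hz),
            class = "r_peaks")
}

#' @export
print.r_peaks <- function(x, ...) {
  cat(sprintf("r_peaks: %d peaks", length(x$times_s)))
  if (length(x$times_s) > 1) {
    cat(sprintf(", mean rate %.1f bpm",
                60 * (length(x$times_s) - 1) /
                  (max(x$times_s) - min(x$times_s))))
  }
  cat("\n")
  invisible(x)
}

#' Apply manual peak corrections
#'
#' Replaces interactive peak editing: adds and/or removes peak times after
#' automatic detection. Removal matches the nearest detected peak within
#' `tol_s`.
#'
#' @param peaks an `r_peaks` object.
#' @param add numeric vector of peak times (s) to insert.
#' @param remove numeric vector of peak times (s) to delete.
#' @param tol_s matching tolerance for removals (default 0.05 s).
#' @return A corrected `r_peaks` object.
#' @export
correct_r_peaks <- function(peaks, add = numeric(0), remove = numeric(0),
                            tol_s = 0.05) {
  t <- peaks$times_s
  for (r in remove) {
    if (length(t) == 0) break
    i <- which.min(abs(t - r))
    if (abs(t[i] - r) <= tol_s) t <- t[-i]
  }
  t <- sort(unique(c(t, add)))
  structure(list(times_s = t, fs_hz = peaks$fs_hz), class = "r_peaks")
}

#' Inter-beat intervals from R peaks
#'
#' Successive peak-time differences in milliseconds. Optionally applies a
#' physiological plausibility filter removing intervals outside
#' `range_ms` (off by default), reporting how many were removed.
#'
#' @param peaks an `r_peaks` object (or numeric vector of peak times in s).
#' @param physio_filter drop IBIs outside `range_ms`?
#' @param range_ms plausibility window in ms (default c(300, 2000)).
#' @return An object of class `ibi_series`: list with `ibis_ms` and
#'   `n_removed`.
#' @export
ibis_from_peaks <- function(peaks, physio_filter = FALSE,
                            range_ms = c(300, 2000)) {
  t <- if (inherits(peaks, "r_peaks")) peaks$times_s else peaks
  if (length(t) < 2) stop("need at least 2 peaks to form inter-beat intervals")
  ibis <- diff(t) * 1000
  removed <- 0L
  if (physio_filter) {
    bad <- ibis < range_ms[1] | ibis > range_ms[2]
    removed <- sum(bad)
    if (removed > 0) {
      message(sprintf("ibis_from_peaks: removed %d implausible IBI(s)", removed))
      ibis <- ibis[!bad]
    }
  }
  structure(list(ibis_ms = ibis, n_removed = removed), class = "ibi_series")
}

#' @export
print.ibi_series <- function(x, ...) {
  cat(sprintf("ibi_series: %d intervals, mean %.1f ms\n",
              length(x$ibis_ms), mean(x$ibis_ms)))
  invisible(x)
}

#' Root mean square of successive differences (RMSSD)
#'
#' The square root of the mean of the squared differences between adjacent
#' inter-beat intervals, in milliseconds — the time-domain heart rate
#' variability index of parasympathetic (vagal) influence.
#'
#' @param ibis an `ibi_series` or numeric vector of IBIs in ms (>= 2 values).
#' @param condition optional condition label carried into the result.
#' @return An object of class `hrv_result`: `rmssd_ms`, `n_ibis`,
#'   `condition`.
#' @examples
#' rmssd(c(800, 810, 790, 805))$rmssd_ms  # 15.55
#' @export
rmssd <- function(ibis, condition = NA_character_) {
  v <- if (inherits(ibis, "ibi_series")) ibis$ibis_ms else ibis
  if (!is.numeric(v) || length(v) < 2) {
    stop("RMSSD requires at least 2 inter-beat intervals")
  }
  if (any(v <= 0)) stop("inter-beat intervals must be positive")
  structure(list(rmssd_ms = sqrt(mean(diff(v)^2)),
                 n_ibis = length(v), condition = condition),
            class = "hrv_result")
}

#' @export
print.hrv_result <- function(x, ...) {
  cat(sprintf("hrv_result: RMSSD %.2f ms over %d IBIs%s\n", x$rmssd_ms,
              x$n_ibis,
              if (is.na(x$condition)) "" else paste0(" (", x$condition, ")")))
  invisible(x)
}

#' Read an IBI series from a two-column CSV
#'
#' Expects columns `beat` (index) and `ibi_ms`.
#'
#' @param path CSV file path.
#' @return An `ibi_series`.
#' @export
read_ibi_csv <- function(path) {
  d <- utils::read.csv(path)
  stopifnot(all(c("beat", "ibi_ms") %in% names(d)))
  structure(list(ibis_ms = d$ibi_ms[order(d$beat)], n_removed = 0L),
            class = "ibi_series")
}

#' Write an IBI series as a two-column CSV
#'
#' @param ibis an `ibi_series`.
#' @param path output path; columns `beat`, `ibi_ms`.
#' @return `path`, invisibly.
#' @export
write_ibi_csv <- function(ibis, path) {
  utils::write.csv(data.frame(beat = seq_along(ibis$ibis_ms),
                              ibi_ms = ibis$ibis_ms),
                   path, row.names = FALSE)
  invisible(path)
}
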