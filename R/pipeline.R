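#' Run the full simulation-analysis-statistics pipeline
#'
#' Generates (or streams) a synthetic cohort from `config`, runs the
#' frequency-tagging chain on every task block (band-pass, epoch/average,
#' Welch PSD on the 0.05 Hz lattice, beat/meter peak extraction), the
#' cardiac chain on every ECG trace (R-peak detection, inter-beat intervals,
#' RMSSD), and the inference layer: repeated-measures ANOVA of RMSSD across
#' conditions (when three conditions are present), subject-level bootstrap
#' of the beat-to-meter ratio per condition, the log-log ratio-RMSSD
#' regression per task condition, and the exploratory correlation of resting
#' RMSSD with each task condition's ratio. Subjects are simulated and
#' analysed one at a time, so memory stays flat in cohort size.
#'
#' @param config a [cohort_config()] (or [cohort_profile()]).
#' @param out_dir optional directory; when given, tidy CSVs (per-subject
#'   measures), a JSON report, and a serialized copy of the configuration
#'   are written into it.
#' @param n_boot bootstrap repetitions (default 1000).
#' @param boot_seed seed for the bootstrap resampling (default derived from
#'   the cohort seed).
#' @param resolution_hz PSD grid step (default 0.05).
#' @param use_detector derive RMSSD from the rendered ECG via the R-peak
#'   detector (`TRUE`, the full chain) or directly from the simulated IBI
#'   series (`FALSE`, faster; skips ECG rendering checks).
#' @param verbose print a line per subject?
#' @return An object of class `bm_report`: `measures` (per subject/condition
#'   data frame with ratios, peak locations, RMSSD and ground truth),
#'   `anova` (or NULL), `bootstrap` (list per condition), `coupling` (list
#'   of `bm_loglog` per task condition), `rest_correlations`, `config`.
#' @export
run_pipeline <- function(config = cohort_profile("paper_duple"),
                         out_dir = NULL, n_boot = 1000, boot_seed = NULL,
                         resolution_hz = 0.05, use_detector = TRUE,
                         verbose = FALSE) {
  stopifnot(inherits(config, "cohort_config"))
  if (is.null(boot_seed)) boot_seed <- derive_seed(config$seed, 0L, 999L)
  rows <- vector("list", config$n_subjects)
  for (i in seq_len(config$n_subjects)) {
    rec <- generate_subject(config, i)
    out <- list()
    for (cond in names(rec$conditions)) {
      cc <- rec$conditions[[cond]]
      f_beat <- p_beat <- f_meter <- p_meter <- ratio <- NA_real_
      if (!is.null(cc$sensor_block)) {
        bm <- analyze_block(cc$sensor_block$data, cc$sensor_block$fs_hz,
                            cc$sensor_block$event_times_s, cond,
                            resolution_hz = resolution_hz)
        f_beat <- bm$f_beat_hz; p_beat <- bm$p_beat
        f_meter <- bm$f_meter_hz; p_meter <- bm$p_meter
        ratio <- bm$ratio
      }
      if (use_detector) {
        pk <- detect_r_peaks(cc$ecg$trace, cc$ecg$fs_hz)
        ib <- ibis_from_peaks(pk)
      } else {
        ib <- cc$ibi_series
      }
      hr <- rmssd(ib, condition = cond)
      out[[cond]] <- data.frame(
        subject = i, condition = cond, f_beat_hz = f_beat, p_beat = p_beat,
        f_meter_hz = f_meter, p_meter = p_meter, ratio = ratio,
        rmssd_ms = hr$rmssd_ms, n_ibis = hr$n_ibis,
        true_log10_ratio = cc$true_log10_ratio,
        true_rmssd_ms = cc$true_rmssd_ms)
    }
    rows[[i]] <- do.call(rbind, out)
    if (verbose) {
      message(sprintf("subject %d/%d done", i, config$n_subjects))
    }
  }
  measures <- do.call(rbind, rows)
  rownames(measures) <- NULL

  task <- setdiff(config$conditions, "rest")
  wide_rmssd <- stats::reshape(
    measures[, c("subject", "condition", "rmssd_ms")],
    idvar = "subject", timevar = "condition", direction = "wide")
  colnames(wide_rmssd) <- sub("^rmssd_ms\\.", "", colnames(wide_rmssd))

  anova <- NULL
  if (length(config$conditions) >= 2) {
    anova <- rm_anova_gg(as.matrix(wide_rmssd[, config$conditions,
                                              drop = FALSE]))
  }

  bootstrap <- list()
  coupling <- list()
  rest_cor <- list()
  for (cond in task) {
    sel <- measures$condition == cond
    bootstrap[[cond]] <- bootstrap_mean(measures$ratio[sel], n_boot,
                                        seed = boot_seed)
    coupling[[cond]] <- loglog_regression(measures$ratio[sel],
                                          measures$rmssd_ms[sel])
    if ("rest" %in% config$conditions) {
      rest <- measures$rmssd_ms[measures$condition == "rest"]
      rest_cor[[cond]] <- pearson_cor(log10(measures$ratio[sel]), log10(rest))
    }
  }

  report <- structure(list(measures = measures, anova = anova,
                           bootstrap = bootstrap, coupling = coupling,
                           rest_correlations = rest_cor, config = config),
                      class = "bm_report")
  if (!is.null(out_dir)) write_report(report, out_dir)
  report
}

#' @export
print.bm_report <- function(x, ...) {
  task <- setdiff(x$config$conditions, "rest")
  cat(sprintf("bm_report: %d subjects, conditions {%s}\n",
              x$config$n_subjects,
              paste(x$config$conditions, collapse = ", ")))
  for (cond in task) {
    b <- x$bootstrap[[cond]]
    cp <- x$coupling[[cond]]
    cat(sprintf("  %s: bootstrap ratio mean %.2f [%.2f, %.2f]; coupling slope %.3f, r %.3f (p %.3g)\n",
                cond, b$mean, b$ci_lo, b$ci_hi, cp$slope, cp$r, cp$p))
  }
  if (!is.null(x$anova)) {
    cat(sprintf("  RMSSD ANOVA: F(%d, %d) = %.3f, p_GG = %.4g, eta2 = %.3f\n",
                x$anova$df1, x$anova$df2, x$anova$F, x$anova$p_gg,
                x$anova$eta2))
  }
  invisible(x)
}

#' @export
summary.bm_report <- function(object, ...) {
  print(object)
  cat("\nPer-condition measured means:\n")
  agg <- stats::aggregate(cbind(ratio, rmssd_ms) ~ condition,
                          data = object$measures, FUN = mean, na.action = NULL,
                          na.rm = TRUE)
  print(agg, row.names = FALSE)
  invisible(agg)
}

#' @export
plot.bm_report <- function(x, condition = NULL, ...) {
  task <- setdiff(x$config$conditions, "rest")
  if (is.null(condition)) condition <- task[1]
  plot(x$coupling[[condition]],
       main = sprintf("%s condition (n = %d)", condition,
                      x$config$n_subjects), ...)
  invisible(x)
}

#' Write a pipeline report bundle to disk
#'
#' Writes `measures.csv` (per subject/condition), `bootstrap_<cond>.csv`
#' (resample means), `report.json` (ANOVA, bootstrap, coupling, correlation
#' estimates and the seeds/parameters needed to reproduce them), and
#' `config.json`.
#'
#' @param report a `bm_report`.
#' @param out_dir output directory (created if needed).
#' @return `out_dir`, invisibly.
#' @export
write_report <- function(report, out_dir) {
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  utils::write.csv(report$measures, file.path(out_dir, "measures.csv"),
                   row.names = FALSE)
  for (cond in names(report$bootstrap)) {
    utils::write.csv(
      data.frame(boot_mean = report$bootstrap[[cond]]$boot_means),
      file.path(out_dir, sprintf("bootstrap_%s.csv", cond)),
      row.names = FALSE)
  }
  js <- list(
    anova = if (is.null(report$anova)) NULL else {
      a <- unclass(report$anova)
      a$posthoc <- NULL
      a$means <- as.list(a$means)
      a
    },
    bootstrap = lapply(report$bootstrap, function(b) {
      list(mean = b$mean, ci_lo = b$ci_lo, ci_hi = b$ci_hi,
           n_reps = b$n_reps, seed = b$seed)
    }),
    coupling = lapply(report$coupling, function(cp) {
      list(slope = cp$slope, intercept = cp$intercept, r = cp$r,
           r2 = cp$r2, p = cp$p, n = cp$n)
    }),
    rest_correlations = report$rest_correlations)
  jsonlite::write_json(js, file.path(out_dir, "report.json"),
                       auto_unbox = TRUE, digits = NA, null = "null")
  jsonlite::write_json(unclass(report$config),
                       file.path(out_dir, "config.json"),
                       auto_unbox = TRUE, digits = NA, null = "null")
  invisible(out_dir)
}

#' Read the tidy measures table written by [write_report()]
#'
#' @param path path to `measures.csv`.
#' @return Data frame of per subject/condition measures.
#' @export
read_measures_csv <- function(path) {
  utils::read.csv(path)
}
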