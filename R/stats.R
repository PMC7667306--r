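#' One-way repeated-measures ANOVA with Greenhouse-Geisser correction
#'
#' Classical within-subject one-way ANOVA on a subjects-by-conditions table:
#' the condition effect is tested against the subject-by-condition
#' interaction, and the p-value is corrected for non-sphericity with the
#' Greenhouse-Geisser epsilon computed from the double-centered covariance
#' of the condition scores. Pairwise Bonferroni-corrected paired t-tests are
#' returned as post hocs (p multiplied by the number of pairs, capped at 1).
#'
#' @param values numeric matrix or data frame, one row per subject, one
#'   column per condition; no missing cells.
#' @return An object of class `bm_anova`: `F`, `df1`, `df2` (uncorrected),
#'   `epsilon`, `p_uncorrected`, `p_gg`, `eta2` (partial eta-squared),
#'   `means`, and `posthoc` (data frame of pairwise comparisons).
#' @examples
#' set.seed(1)
#' rm_anova_gg(matrix(rnorm(45), 15, 3))
#' @export
rm_anova_gg <- function(values) {
  x <- as.matrix(values)
  if (any(!is.finite(x))) stop("missing or non-finite cells are not allowed")
  n <- nrow(x)
  k <- ncol(x)
  if (n < 2 || k < 2) stop("need at least 2 subjects and 2 conditions")
  if (is.null(colnames(x))) colnames(x) <- paste0("cond", seq_len(k))

  gm <- mean(x)
  subj_m <- rowMeans(x)
  cond_m <- colMeans(x)
  ss_cond <- n * sum((cond_m - gm)^2)
  resid <- x - outer(subj_m, cond_m, "+") + gm
  ss_err <- sum(resid^2)
  df1 <- k - 1
  df2 <- (n - 1) * (k - 1)

  if (ss_cond + ss_err == 0 || ss_err == 0) {
    # degenerate: no within-subject variability around the additive model
    Fv <- if (ss_cond == 0) 0 else Inf
    eps <- 1
    p <- if (ss_cond == 0) 1 else 0
    eta2 <- if (ss_cond == 0) 0 else 1
  } else {
    Fv <- (ss_cond / df1) / (ss_err / df2)
    # Greenhouse-Geisser epsilon from the double-centered covariance
    S <- stats::cov(x)
    C <- S - outer(rowMeans(S), colMeans(S), "+") + mean(S)
    tr <- sum(diag(C))
    eps <- if (sum(C^2) == 0) 1 else tr^2 / (df1 * sum(C^2))
    eps <- min(1, max(1 / df1, eps))
    p <- stats::pf(Fv, eps * df1, eps * df2, lower.tail = FALSE)
    eta2 <- ss_cond / (ss_cond + ss_err)
  }
  p_unc <- if (is.infinite(Fv)) 0 else
    stats::pf(Fv, df1, df2, lower.tail = FALSE)

  pairs <- utils::combn(k, 2)
  n_pairs <- ncol(pairs)
  posthoc <- do.call(rbind, lapply(seq_len(n_pairs), function(j) {
    a <- pairs[1, j]; b <- pairs[2, j]
    d <- x[, a] - x[, b]
    praw <- if (stats::sd(d) == 0) 1 else stats::t.test(d)$p.value
    data.frame(a = colnames(x)[a], b = colnames(x)[b],
               mean_diff = mean(d), p_bonferroni = min(1, praw * n_pairs))
  }))

  structure(list(F = Fv, df1 = df1, df2 = df2, epsilon = eps,
                 p_uncorrected = p_unc, p_gg = p, eta2 = eta2,
                 means = cond_m, n = n, posthoc = posthoc),
            class = "bm_anova")
}

#' @export
print.bm_anova <- function(x, ...) {
  cat(sprintf("Repeated-measures ANOVA: F(%d, %d) = %.3f, p = %.4g (Greenhouse-Geisser, eps = %.3f), eta2 = %.3f\n",
              x$df1, x$df2, x$F, x$p_gg, x$epsilon, x$eta2))
  cat("Condition means:", paste(sprintf("%s = %.3g", names(x$means), x$means),
                                collapse = ", "), "\n")
  cat("Post hoc (Bonferroni):\n")
  print(x$posthoc, row.names = FALSE)
  invisible(x)
}

#' Bootstrap mean and percentile confidence interval
#'
#' Resamples subjects with replacement `n_reps` times, computes the mean of
#' each resample, and reports the mean of the resample means with the 2.5%
#' and 97.5% percentiles of their distribution as the 95% interval.
#'
#' @param values numeric vector (>= 2 values), one per subject.
#' @param n_reps number of bootstrap repetitions (default 1000).
#' @param seed optional seed for reproducibility (recorded in the result).
#' @return An object of class `bm_boot`: `mean`, `ci_lo`, `ci_hi`,
#'   `n_reps`, `seed`, and `boot_means` (the resample means).
#' @export
bootstrap_mean <- function(values, n_reps = 1000, seed = NULL) {
  if (length(values) < 2) stop("need at least 2 values to bootstrap")
  if (!is.null(seed)) set.seed(seed)
  n <- length(values)
  bm <- vapply(seq_len(n_reps),
               function(i) mean(values[sample.int(n, n, replace = TRUE)]),
               numeric(1))
  ci <- unname(stats::quantile(bm, c(0.025, 0.975)))
  structure(list(mean = mean(bm), ci_lo = ci[1], ci_hi = ci[2],
                 n_reps = n_reps, seed = seed, boot_means = bm),
            class = "bm_boot")
}

#' @export
print.bm_boot <- function(x, ...) {
  cat(sprintf("Bootstrap mean %.3f, 95%% CI [%.3f, %.3f] (%d repetitions)\n",
              x$mean, x$ci_lo, x$ci_hi, x$n_reps))
  invisible(x)
}

#' Log-log regression between beat-to-meter ratio and RMSSD
#'
#' Ordinary least squares of `log10(rmssd)` on `log10(ratio)`, the
#' individual-level coupling model between the neural beat-to-meter ratio
#' and heart rate variability. Returns the signed Pearson correlation with
#' its two-sided p-value alongside the fitted slope and intercept.
#'
#' @param ratio positive beat-to-meter ratios.
#' @param rmssd positive RMSSD values (ms), same length.
#' @return An object of class `bm_loglog`: `slope`, `intercept`, `r`, `r2`,
#'   `p`, `n`, plus the log10-transformed data and the underlying [lm] fit.
#'   With zero variance in `log10(rmssd)` the slope is 0 and `r`/`p` are
#'   `NA` with a warning (degenerate fit).
#' @export
loglog_regression <- function(ratio, rmssd) {
  if (length(ratio) != length(rmssd)) stop("inputs must have equal length")
  if (length(ratio) < 3) stop("need at least 3 subjects")
  bad <- which(!(is.finite(ratio) & ratio > 0))
  if (length(bad)) {
    stop(sprintf("non-positive or non-finite ratio at index %d", bad[1]))
  }
  bad <- which(!(is.finite(rmssd) & rmssd > 0))
  if (length(bad)) {
    stop(sprintf("non-positive or non-finite rmssd at index %d", bad[1]))
  }
  lx <- log10(ratio)
  ly <- log10(rmssd)
  if (stats::sd(lx) == 0) stop("log10(ratio) has zero variance")
  fit <- stats::lm(ly ~ lx)
  slope <- unname(stats::coef(fit)[2])
  intercept <- unname(stats::coef(fit)[1])
  if (stats::sd(ly) == 0) {
    warning("log10(rmssd) has zero variance: correlation undefined")
    r <- NA_real_; p <- NA_real_
  } else {
    ct <- stats::cor.test(lx, ly)
    r <- unname(ct$estimate)
    p <- ct$p.value
  }
  structure(list(slope = slope, intercept = intercept, r = r, r2 = r^2,
                 p = p, n = length(lx), log10_ratio = lx, log10_rmssd = ly,
                 fit = fit),
            class = "bm_loglog")
}

#' @export
print.bm_loglog <- function(x, ...) {
  cat(sprintf("log10(RMSSD) = %.3f %+.3f * log10(ratio)   (n = %d)\n",
              x$intercept, x$slope, x$n))
  cat(sprintf("Pearson r = %.3f, R-squared = %.3f, p = %.4g\n",
              x$r, x$r2, x$p))
  invisible(x)
}

#' @export
summary.bm_loglog <- function(object, ...) {
  s <- summary(object$fit)
  cat(sprintf("Log-log coupling fit, n = %d\n", object$n))
  cat(sprintf("  slope     %8.4f  (SE %.4f)\n", object$slope,
              s$coefficients[2, 2]))
  cat(sprintf("  intercept %8.4f  (SE %.4f)\n", object$intercept,
              s$coefficients[1, 2]))
  cat(sprintf("  Pearson r %8.4f   R2 %.4f   p %.4g\n", object$r,
              object$r2, object$p))
  invisible(s)
}

#' @export
coef.bm_loglog <- function(object, ...) {
  c(intercept = object$intercept, slope = object$slope)
}

#' @export
residuals.bm_loglog <- function(object, ...) stats::residuals(object$fit)

#' Predict RMSSD from beat-to-meter ratio
#'
#' @param object a `bm_loglog` fit.
#' @param ratio new beat-to-meter ratios (natural scale).
#' @param ... unused.
#' @return Predicted RMSSD in ms (natural scale).
#' @export
predict.bm_loglog <- function(object, ratio, ...) {
  if (missing(ratio)) return(10^stats::fitted(object$fit))
  stopifnot(all(ratio > 0))
  10^(object$intercept + object$slope * log10(ratio))
}

#' @export
plot.bm_loglog <- function(x, ...) {
  graphics::plot(x$log10_ratio, x$log10_rmssd,
                 xlab = "log10(beat-to-meter ratio)",
                 ylab = "log10(RMSSD, ms)", pch = 19, ...)
  graphics::abline(x$intercept, x$slope, col = "red3", lwd = 2)
  invisible(x)
}

#' Pearson correlation with two-sided p-value
#'
#' Thin wrapper around [stats::cor.test()] that signals degenerate input
#' (zero variance) with a warning and `NA` rather than an error.
#'
#' @param x,y numeric vectors of equal length (n >= 3, finite).
#' @return List with `r` and `p`.
#' @export
pearson_cor <- function(x, y) {
  stopifnot(length(x) == length(y), length(x) >= 3)
  if (any(!is.finite(x)) || any(!is.finite(y))) stop("inputs must be finite")
  if (stats::sd(x) == 0 || stats::sd(y) == 0) {
    warning("zero variance: correlation undefined")
    return(list(r = NA_real_, p = NA_real_))
  }
  ct <- stats::cor.test(x, y)
  list(r = unname(ct$estimate), p = ct$p.value)
}

#' Paired Wilcoxon signed-rank test
#'
#' Generic utility for paired comparisons of non-normal quantities (for
#' example left- vs right-hemisphere ratios when such data are available).
#'
#' @param x,y paired numeric vectors.
#' @return List with `V` (test statistic) and `p`.
#' @export
signed_rank <- function(x, y) {
  w <- stats::wilcox.test(x, y, paired = TRUE, exact = FALSE)
  list(V = unname(w$statistic), p = w$p.value)
}
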