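#' ROC curve and AUC for a single-variable binary classifier
#'
#' Computes the receiver operating characteristic of classifying the positive
#' class (here: apoptotic cells) by a marker value, with higher values scoring
#' positive. The AUC is the tie-corrected Mann-Whitney pair statistic
#' `P(pos > neg) + 0.5 * P(pos = neg)`, computed from mid-ranks; the curve is
#' obtained by sweeping all observed thresholds. Values below 0.5 are
#' reported as computed, never flipped.
#'
#' @param values_pos Marker values of the positive class (non-empty).
#' @param values_neg Marker values of the negative class (non-empty).
#' @return A `roc_result`: list with `thresholds`, `fpr`, `tpr`, `auc`,
#'   `n_pos`, `n_neg`.
#' @examples
#' roc_auc(c(3, 5), c(1, 4))$auc  # 0.75
#' @export
roc_auc <- function(values_pos, values_neg) {
  if (length(values_pos) == 0 || length(values_neg) == 0) {
    stop("both classes must be non-empty")
  }
  np <- length(values_pos); nn <- length(values_neg)
  r <- rank(c(values_pos, values_neg))  # mid-ranks on ties
  auc <- (sum(r[seq_len(np)]) - np * (np + 1) / 2) / (np * nn)

  thr <- sort(unique(c(values_pos, values_neg)), decreasing = TRUE)
  tpr <- vapply(thr, function(t) mean(values_pos >= t), 0)
  fpr <- vapply(thr, function(t) mean(values_neg >= t), 0)
  structure(list(thresholds = c(Inf, thr), fpr = c(0, fpr), tpr = c(0, tpr),
                 auc = auc, n_pos = np, n_neg = nn),
            class = "roc_result")
}

#' @export
print.roc_result <- function(x, ...) {
  cat(sprintf("ROC: AUC = %.4f (%d positive, %d negative)\n",
              x$auc, x$n_pos, x$n_neg))
  invisible(x)
}

#' Plot a ROC curve
#'
#' @param x A `roc_result`.
#' @param ... Passed to [graphics::plot()].
#' @export
plot.roc_result <- function(x, ...) {
  graphics::plot(x$fpr, x$tpr, type = "l", xlim = c(0, 1), ylim = c(0, 1),
                 xlab = "False positive rate", ylab = "True positive rate",
                 ...)
  graphics::abline(0, 1, lty = 2, col = "grey")
  invisible(x)
}

#' Mitochondrial contribution to variability (MCV)
#'
#' Quantifies how much of a value's cell-to-cell variability is explained by
#' its linear dependence on mitochondrial content:
#' `MCV = (1 - CV_det / CV) * 100`, where `CV` is the coefficient of
#' variation of the raw values and `CV_det` the coefficient of variation of
#' the de-trended distribution, i.e. the residuals of an ordinary
#' least-squares regression of the values on mitochondrial level, shifted
#' back to the original mean. De-trending is performed in linear space by
#' default (matching regression on intensities); `log_space = TRUE` regresses
#' log on log instead. Negative sample MCVs (possible from noise) are
#' reported as computed.
#'
#' @param values Positive-mean numeric vector (length >= 3).
#' @param mito Mitochondrial levels, same length.
#' @param log_space Regress in log space instead of linear space.
#' @return An `mcv_result`: list with `cv`, `cv_det`, `mcv` (percent),
#'   `slope`, `r_squared`.
#' @examples
#' m <- exp(rnorm(1000, 0, 0.4))
#' mcv(2 * m, m)$mcv  # 100: perfect linear dependence
#' @export
mcv <- function(values, mito, log_space = FALSE) {
  if (length(values) != length(mito)) stop("values and mito must match")
  if (length(values) < 3) stop("need at least 3 observations")
  if (mean(values) <= 0) stop("mean of values must be positive")
  if (sd(values) == 0) stop("values have zero variance; CV undefined")
  v <- if (log_space) log(values) else values
  m <- if (log_space) log(mito) else mito
  fit <- lm(v ~ m)
  det <- stats::residuals(fit) + mean(v)
  if (log_space) det <- exp(det)
  raw <- values
  cv <- sd(raw) / mean(raw)
  cv_det <- sd(det) / mean(det)
  structure(list(cv = cv, cv_det = cv_det, mcv = (1 - cv_det / cv) * 100,
                 slope = unname(coef(fit)[2]),
                 r_squared = 1 - stats::var(stats::residuals(fit)) / stats::var(v)),
            class = "mcv_result")
}

#' @export
print.mcv_result <- function(x, ...) {
  cat(sprintf("MCV = %.1f%%  (CV = %.3f, de-trended CV = %.3f)\n",
              x$mcv, x$cv, x$cv_det))
  invisible(x)
}

#' Dispersion measures with bootstrap confidence intervals
#'
#' The two measures used to quantify variability in time-to-death
#' distributions: the coefficient of variation `sd/mean` and the mean-scaled
#' interquartile range `(Q3 - Q1)/mean`. Quartiles use the linear
#' interpolation convention (`quantile(type = 7)`), fixed for
#' reproducibility. Percentile bootstrap intervals are attached.
#'
#' @param values Positive-mean numeric vector (length >= 4).
#' @param reps Bootstrap replicates (default 1000).
#' @param seed Integer seed for the bootstrap.
#' @param level Confidence level (default 0.95).
#' @return A `dispersion_result`: list with `cv`, `iqr_over_mean`, `cv_ci`,
#'   `iqr_ci`, `n`.
#' @export
dispersion <- function(values, reps = 1000, seed = 1L, level = 0.95) {
  if (length(values) < 4) stop("need at least 4 observations")
  if (mean(values) <= 0) stop("mean must be positive")
  cv_fun <- function(x) sd(x) / mean(x)
  iqr_fun <- function(x) {
    q <- quantile(x, c(0.25, 0.75), type = 7, names = FALSE)
    (q[2] - q[1]) / mean(x)
  }
  structure(list(
    cv = cv_fun(values),
    iqr_over_mean = iqr_fun(values),
    cv_ci = bootstrap_ci(cv_fun, values, reps = reps, seed = seed,
                         level = level),
    iqr_ci = bootstrap_ci(iqr_fun, values, reps = reps,
                          seed = child_seed(seed, "iqr"), level = level),
    n = length(values)
  ), class = "dispersion_result")
}

#' @export
print.dispersion_result <- function(x, ...) {
  cat(sprintf("CV = %.3f [%.3f, %.3f];  IQR/mean = %.3f [%.3f, %.3f]  (n = %d)\n",
              x$cv, x$cv_ci[1], x$cv_ci[2],
              x$iqr_over_mean, x$iqr_ci[1], x$iqr_ci[2], x$n))
  invisible(x)
}

#' Spearman rank correlation
#'
#' Pearson correlation of mid-ranks (ties averaged). Errors on constant
#' input, where the correlation is undefined.
#'
#' @param x,y Numeric vectors of equal length (>= 3).
#' @return Correlation in `[-1, 1]`.
#' @export
spearman_rho <- function(x, y) {
  if (length(x) != length(y)) stop("x and y must have equal length")
  if (length(x) < 3) stop("need at least 3 observations")
  if (sd(x) == 0 || sd(y) == 0) stop("correlation undefined for constant input")
  cor(x, y, method = "spearman")
}

#' Percentile bootstrap confidence interval
#'
#' @param statistic Function of a numeric vector returning a scalar.
#' @param data Numeric vector to resample.
#' @param reps Number of resamples (>= 100).
#' @param seed Integer seed.
#' @param level Confidence level (default 0.95).
#' @return Numeric `c(lo, hi)` with attribute `dropped` counting resamples on
#'   which the statistic was non-finite (those are excluded).
#' @export
bootstrap_ci <- function(statistic, data, reps = 1000, seed = 1L,
                         level = 0.95) {
  if (reps < 100) stop("reps must be at least 100")
  n <- length(data)
  stats_ <- with_seed(seed, {
    vapply(seq_len(reps), function(i) {
      statistic(data[sample.int(n, n, replace = TRUE)])
    }, 0)
  })
  bad <- !is.finite(stats_)
  stats_ <- stats_[!bad]
  if (length(stats_) == 0) stop("statistic non-finite on every resample")
  a <- (1 - level) / 2
  ci <- quantile(stats_, c(a, 1 - a), names = FALSE, type = 7)
  attr(ci, "dropped") <- sum(bad)
  ci
}
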