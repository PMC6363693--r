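# Classification and regression performance metrics, multi-scheme confidence
# intervals, and Bland-Altman agreement statistics.
#
# Metrics with a zero denominator carry an explicit NA ("undefined") marker
# rather than NaN, and are excluded from cross-scheme averaging with a
# warning, so that average models are never corrupted by silent propagation.

#' Confusion counts from label vectors
#'
#' @param actual,predicted Vectors of class labels.
#' @param positive The positive ("sweet") class label.
#' @return Named list with integer fields `tp`, `tn`, `fp`, `fn`.
#' @export
confusion_counts <- function(actual, predicted, positive = "sweet") {
  stopifnot(length(actual) == length(predicted))
  a <- actual == positive
  p <- predicted == positive
  list(tp = sum(a & p), tn = sum(!a & !p), fp = sum(!a & p), fn = sum(a & !p))
}

.safe_div <- function(num, den) if (den == 0) NA_real_ else num / den

#' Binary classification metrics
#'
#' Computes accuracy, precision, specificity, sensitivity, F1-score
#' (`2 TP / (2 TP + FP + FN)`), Matthews correlation coefficient, and the
#' non-error rate NER = (sensitivity + specificity) / 2. A zero denominator
#' makes only the affected metric undefined (`NA`).
#'
#' @param counts A list with `tp`, `tn`, `fp`, `fn` (see
#'   [confusion_counts()]), or `tp` given as the first of four numbers.
#' @param tn,fp,fn Counts when `counts` is numeric.
#' @return Named list of class `classification_metrics`.
#' @export
classification_metrics <- function(counts, tn = NULL, fp = NULL, fn = NULL) {
  if (is.numeric(counts) && length(counts) == 1L) {
    counts <- list(tp = counts, tn = tn, fp = fp, fn = fn)
  }
  tp <- as.numeric(counts$tp); tn <- as.numeric(counts$tn)
  fp <- as.numeric(counts$fp); fn <- as.numeric(counts$fn)
  total <- tp + tn + fp + fn
  if (total == 0) stop("all confusion counts are zero")
  sens <- .safe_div(tp, tp + fn)
  spec <- .safe_div(tn, tn + fp)
  mcc_den <- sqrt(tp + fp) * sqrt(tp + fn) * sqrt(tn + fp) * sqrt(tn + fn)
  out <- list(
    accuracy = (tp + tn) / total,
    precision = .safe_div(tp, tp + fp),
    specificity = spec,
    sensitivity = sens,
    f1 = .safe_div(2 * tp, 2 * tp + fp + fn),
    mcc = if (mcc_den == 0) NA_real_ else (tp * tn - fp * fn) / mcc_den,
    ner = if (is.na(sens) || is.na(spec)) NA_real_ else (sens + spec) / 2
  )
  structure(out, class = "classification_metrics")
}

#' @export
print.classification_metrics <- function(x, ...) {
  vals <- unlist(x)
  cat("classification metrics:\n")
  print(round(vals, 4))
  invisible(x)
}

#' Absolute difference between a CV and a test metric
#'
#' The over-/under-fitting gauges ΔF1, ΔNER and ΔR² are all
#' `|metric(CV) - metric(test)|`.
#'
#' @param a,b Metric values.
#' @return `|a - b|`, or `NA` if either input is undefined.
#' @export
delta_metric <- function(a, b) {
  if (is.na(a) || is.na(b)) return(NA_real_)
  abs(a - b)
}

#' Regression metrics: R², MAE, MSE
#'
#' `r2 = 1 - SSres/SStot` (square of the coefficient of determination
#' relative to the constant-mean predictor), `mae` and `mse` are means of
#' `|e|` and `e^2`.
#'
#' @param y Observed responses (length >= 2).
#' @param yhat Predicted responses.
#' @return Named list of class `regression_metrics` (`r2` is `NA` when `y`
#'   is constant).
#' @export
regression_metrics <- function(y, yhat) {
  stopifnot(length(y) == length(yhat), length(y) >= 2L)
  e <- y - yhat
  sstot <- sum((y - mean(y))^2)
  r2 <- if (sstot == 0) {
    warning("constant y: R^2 undefined")
    NA_real_
  } else 1 - sum(e^2) / sstot
  structure(list(r2 = r2, mae = mean(abs(e)), mse = mean(e^2)),
            class = "regression_metrics")
}

#' t-based 95% confidence interval of a metric across splitting schemes
#'
#' Margin of error is `t(0.975, n-1) * sd / sqrt(n)`. Undefined (`NA`)
#' values are excluded with a warning.
#'
#' @param values Numeric vector of per-scheme metric values (n >= 2 after NA
#'   removal).
#' @param level Confidence level, default 0.95.
#' @return List of class `interval_estimate` with `mean`, `sd`, `n`,
#'   `margin`, `lower`, `upper`.
#' @export
confidence_interval <- function(values, level = 0.95) {
  if (anyNA(values)) {
    warning("excluding ", sum(is.na(values)),
            " undefined value(s) from the confidence interval")
    values <- values[!is.na(values)]
  }
  n <- length(values)
  if (n < 2L) stop("need at least 2 defined values")
  m <- mean(values)
  s <- stats::sd(values)
  margin <- stats::qt(1 - (1 - level) / 2, df = n - 1) * s / sqrt(n)
  structure(list(mean = m, sd = s, n = n, margin = margin,
                 lower = m - margin, upper = m + margin),
            class = "interval_estimate")
}

#' @export
print.interval_estimate <- function(x, ...) {
  cat(sprintf("%.4f +/- %.4f (95%% CI, n = %d, sd = %.4f)\n",
              x$mean, x$margin, x$n, x$sd))
  invisible(x)
}

#' Bland-Altman agreement statistics
#'
#' For paired measurements `(a, b)` computes the bias (mean difference), the
#' 95% limits of agreement `bias +/- 1.96 sd(diff)`, and 95% confidence
#' intervals for the bias (t-based) and for each limit (standard error
#' `sd * sqrt(1/n + 1.96^2 / (2(n-1)))`).
#'
#' @param a,b Numeric vectors of paired measurements (>= 3 pairs), or `a` a
#'   two-column matrix.
#' @return List of class `bland_altman` with `bias`, `sd_diff`, `loa_lower`,
#'   `loa_upper`, `bias_ci`, `loa_ci_halfwidth`, `n`.
#' @export
bland_altman <- function(a, b = NULL) {
  if (is.null(b)) {
    a <- as.matrix(a)
    stopifnot(ncol(a) == 2L)
    b <- a[, 2L]; a <- a[, 1L]
  }
  stopifnot(length(a) == length(b))
  n <- length(a)
  if (n < 3L) stop("need at least 3 pairs")
  d <- a - b
  bias <- mean(d)
  s <- stats::sd(d)
  z <- 1.96
  tq <- stats::qt(0.975, df = n - 1)
  loa_se <- s * sqrt(1 / n + z^2 / (2 * (n - 1)))
  structure(list(bias = bias, sd_diff = s,
                 loa_lower = bias - z * s, loa_upper = bias + z * s,
                 bias_ci = c(bias - tq * s / sqrt(n),
                             bias + tq * s / sqrt(n)),
                 loa_ci_halfwidth = tq * loa_se,
                 n = n),
            class = "bland_altman")
}

#' @export
print.bland_altman <- function(x, ...) {
  cat(sprintf("Bland-Altman (n = %d): bias %.4f, LoA [%.4f, %.4f]\n",
              x$n, x$bias, x$loa_lower, x$loa_upper))
  invisible(x)
}

#' Is a paired difference within the limits of agreement?
#'
#' @param ba A [bland_altman()] object.
#' @param a,b A query pair (or `a` the difference if `b` is `NULL`).
#' @return `TRUE` iff the difference lies in `[loa_lower, loa_upper]`.
#' @export
within_agreement <- function(ba, a, b = NULL) {
  d <- if (is.null(b)) a else a - b
  d >= ba$loa_lower & d <= ba$loa_upper
}
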