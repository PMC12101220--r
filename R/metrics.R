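#' Area under the ROC curve
#'
#' Mann-Whitney formulation: the probability that a randomly chosen
#' positive sample receives a higher score than a randomly chosen
#' negative sample, counting ties as one half.  Equivalent to the
#' trapezoidal area under the empirical ROC curve.
#'
#' @param labels binary labels: logical, 0/1, or a factor whose second
#'   level is the positive class.
#' @param scores numeric scores, higher = more positive.
#' @return AUC in \[0, 1\].
#' @export
auc <- function(labels, scores) {
  y <- as_binary(labels)
  if (length(y) != length(scores)) stop("labels and scores differ in length")
  npos <- sum(y == 1L)
  nneg <- sum(y == 0L)
  if (npos == 0L || nneg == 0L)
    stop("AUC needs both classes present")
  r <- rank(scores, ties.method = "average")
  (sum(r[y == 1L]) - npos * (npos + 1) / 2) / (npos * nneg)
}

as_binary <- function(labels) {
  if (is.factor(labels)) {
    if (nlevels(labels) != 2L) stop("labels must be binary")
    as.integer(labels == levels(labels)[2L])
  } else if (is.logical(labels)) {
    as.integer(labels)
  } else {
    u <- unique(labels)
    if (!all(u %in% c(0, 1))) stop("labels must be binary (0/1)")
    as.integer(labels)
  }
}

#' Sensitivity and specificity at a decision threshold
#'
#' A sample is called positive when its probability is greater than or
#' equal to the threshold (boundary counts as positive).
#'
#' @param labels binary labels (see [auc()]); positive = persistent.
#' @param probs predicted probabilities of the positive class.
#' @param threshold decision threshold in (0, 1).
#' @return named numeric vector `c(sensitivity, specificity)`.
#' @export
sens_spec <- function(labels, probs, threshold = 0.5) {
  y <- as_binary(labels)
  pred <- as.integer(probs >= threshold)
  tp <- sum(pred == 1L & y == 1L)
  fn <- sum(pred == 0L & y == 1L)
  tn <- sum(pred == 0L & y == 0L)
  fp <- sum(pred == 1L & y == 0L)
  c(sensitivity = if (tp + fn > 0) tp / (tp + fn) else NA_real_,
    specificity = if (tn + fp > 0) tn / (tn + fp) else NA_real_)
}

#' Geometric mean
#'
#' `(prod(v))^(1/n)`, computed through logs for stability; returns 0 as
#' soon as any value is 0.
#'
#' @param values non-negative numbers.
#' @return the geometric mean.
#' @export
geometric_mean <- function(values) {
  if (length(values) == 0L) stop("empty input")
  if (any(values < 0)) stop("geometric mean needs non-negative values")
  if (any(values == 0)) return(0)
  exp(mean(log(values)))
}

#' Mean and sample standard deviation of per-split statistics
#'
#' The aggregation used for the per-repeat result tables: arithmetic
#' mean and sample sd (n - 1 denominator), optionally rounded for
#' reporting.
#'
#' @param values numeric vector (e.g. AUCs of the 5 test sets).
#' @param digits decimal places for reporting; `NULL` for no rounding.
#' @return named vector `c(mean, sd)`.
#' @export
summarize_stat <- function(values, digits = 3) {
  out <- c(mean = mean(values), sd = stats::sd(values))
  if (!is.null(digits)) out <- round(out, digits)
  out
}

#' Verbal AUC performance band
#'
#' Convention used in the results prose: failed `< 0.6`, poor
#' `< 0.7`, moderate `< 0.8`, good `< 0.9`, excellent `>= 0.9`.
#'
#' @param auc_value numeric AUC(s).
#' @return character vector of band labels.
#' @export
auc_band <- function(auc_value) {
  cut(auc_value, breaks = c(-Inf, 0.6, 0.7, 0.8, 0.9, Inf),
      labels = c("failed", "poor", "moderate", "good", "excellent"),
      right = FALSE)
}
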