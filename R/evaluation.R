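#' Dice overlap coefficient between two masks
#'
#' `2 |A ∩ B| / (|A| + |B|)`. Two empty masks are in perfect agreement
#' (1.0); empty vs non-empty is 0.
#'
#' @param a,b [binary_mask()] objects or 0/1 matrices of equal shape.
#' @return Numeric in \[0, 1\].
#' @export
dice <- function(a, b) {
  ga <- if (is_binary_mask(a)) as_mask_matrix(a) else a
  gb <- if (is_binary_mask(b)) as_mask_matrix(b) else b
  if (!identical(dim(ga), dim(gb))) stop("masks must share the same shape")
  na <- sum(ga); nb <- sum(gb)
  if (na + nb == 0) return(1)
  2 * sum(ga == 1L & gb == 1L) / (na + nb)
}

check_paired <- function(predicted, truth, min_n = 1L) {
  if (length(predicted) != length(truth)) stop("predicted and truth must have equal length")
  if (anyNA(predicted) || anyNA(truth)) stop("missing values are not allowed")
  if (length(predicted) < min_n) stop("need at least ", min_n, " pairs")
  invisible(TRUE)
}

#' Mean absolute error of paired width measurements
#'
#' @param predicted,truth Equal-length numeric vectors (cm).
#' @return Mean of `|predicted - truth|`, in the input units.
#' @export
mae <- function(predicted, truth) {
  check_paired(predicted, truth, 1L)
  mean(abs(predicted - truth))
}

#' Squared Pearson correlation between predicted and true widths
#'
#' @param predicted,truth Equal-length numeric vectors; `truth` must not be
#'   constant.
#' @return R² in \[0, 1\].
#' @export
r_squared <- function(predicted, truth) {
  check_paired(predicted, truth, 2L)
  if (stats::sd(truth) == 0 || stats::sd(predicted) == 0) {
    stop("r_squared is undefined for constant input")
  }
  stats::cor(predicted, truth)^2
}

#' Intraclass correlation coefficient, ICC(2,1)
#'
#' Two-way random-effects, absolute-agreement, single-measure ICC between
#' two raters (here: automated pipeline vs manual ground truth), computed
#' from the two-way ANOVA decomposition of the n x 2 measurement table,
#' with the 95% confidence interval by the F-distribution method. Absolute
#' agreement penalises systematic offsets: a rater that is perfectly
#' correlated but shifted scores below 1.
#'
#' When both raters are constant there is no variance to apportion and the
#' value is 1 by convention, with a degenerate CI.
#'
#' @param predicted,truth Equal-length numeric vectors, n >= 5 for a CI.
#' @param conf_level Confidence level for the interval.
#' @return List with `value`, `ci_low`, `ci_high`.
#' @export
icc <- function(predicted, truth, conf_level = 0.95) {
  check_paired(predicted, truth, 2L)
  x <- cbind(predicted, truth)
  n <- nrow(x); k <- 2
  if (stats::sd(predicted) == 0 && stats::sd(truth) == 0) {
    return(list(value = 1, ci_low = 1, ci_high = 1))
  }
  grand <- mean(x)
  rm_ <- rowMeans(x); cm_ <- colMeans(x)
  SSB <- k * sum((rm_ - grand)^2)            # between subjects
  SSC <- n * sum((cm_ - grand)^2)            # between raters
  SST <- sum((x - grand)^2)
  SSE <- SST - SSB - SSC
  MSR <- SSB / (n - 1)
  MSC <- SSC / (k - 1)
  MSE <- SSE / ((n - 1) * (k - 1))
  r <- (MSR - MSE) / (MSR + (k - 1) * MSE + (k / n) * (MSC - MSE))
  alpha <- 1 - conf_level
  # Satterthwaite df for the absolute-agreement denominator
  a <- (k * r) / (n * (1 - r))
  b <- 1 + (k * r * (n - 1)) / (n * (1 - r))
  v <- (a * MSC + b * MSE)^2 /
    ((a * MSC)^2 / (k - 1) + (b * MSE)^2 / ((n - 1) * (k - 1)))
  FL <- stats::qf(1 - alpha / 2, n - 1, v)
  FU <- stats::qf(1 - alpha / 2, v, n - 1)
  lo <- n * (MSR - FL * MSE) /
    (FL * (k * MSC + (k * n - k - n) * MSE) + n * MSR)
  hi <- n * (FU * MSR - MSE) /
    (k * MSC + (k * n - k - n) * MSE + n * FU * MSR)
  list(value = r, ci_low = lo, ci_high = hi)
}

#' ROC area under the curve with confidence interval
#'
#' AUC by the Mann–Whitney rank statistic with midrank tie handling, with a
#' 95% CI by DeLong's method (default) or a seeded stratified bootstrap.
#'
#' @param scores Numeric detection scores (e.g. widths from
#'   [presence_score()]).
#' @param labels Binary 0/1 (or logical) ground-truth labels; both classes
#'   must be present.
#' @param ci_method `"delong"` or `"bootstrap"`.
#' @param boot_n Bootstrap resamples when `ci_method = "bootstrap"`.
#' @param conf_level Confidence level.
#' @return List with `auc`, `ci_low`, `ci_high`.
#' @export
roc_auc <- function(scores, labels, ci_method = c("delong", "bootstrap"),
                    boot_n = 2000L, conf_level = 0.95) {
  ci_method <- match.arg(ci_method)
  labels <- as.integer(labels)
  if (!all(labels %in% c(0L, 1L))) stop("labels must be binary 0/1")
  if (length(unique(labels)) < 2L) stop("both label classes must be present")
  check_paired(scores, labels, 2L)
  r <- pROC::roc(labels, scores, levels = c(0, 1), direction = "<", quiet = TRUE)
  a <- as.numeric(pROC::auc(r))
  ci <- tryCatch(
    suppressWarnings(as.numeric(pROC::ci.auc(r, conf.level = conf_level,
                                             method = ci_method,
                                             boot.n = boot_n))),
    error = function(e) c(NA_real_, a, NA_real_))
  list(auc = a, ci_low = ci[1], ci_high = ci[3])
}

#' Sensitivity and specificity of a binary prediction
#'
#' @param predicted Binary 0/1 predictions.
#' @param labels Binary 0/1 ground truth; both classes must be present.
#' @return List with `sensitivity` = TP/(TP+FN) and `specificity` =
#'   TN/(TN+FP).
#' @export
sensitivity_specificity <- function(predicted, labels) {
  predicted <- as.integer(predicted); labels <- as.integer(labels)
  if (!all(predicted %in% c(0L, 1L)) || !all(labels %in% c(0L, 1L))) {
    stop("predicted and labels must be binary 0/1")
  }
  if (length(unique(labels)) < 2L) stop("both label classes must be present")
  check_paired(predicted, labels, 2L)
  tp <- sum(predicted == 1L & labels == 1L)
  fn <- sum(predicted == 0L & labels == 1L)
  tn <- sum(predicted == 0L & labels == 0L)
  fp <- sum(predicted == 1L & labels == 0L)
  list(sensitivity = tp / (tp + fn), specificity = tn / (tn + fp))
}

#' Full metric report for paired width measurements
#'
#' Convenience wrapper computing MAE, ICC (with CI) and R² for a paired
#' width table, plus — when binary presence labels are supplied — AUC with
#' CI using the predicted width as detection score.
#'
#' @param predicted,truth Paired widths, cm.
#' @param labels Optional binary presence labels for ROC analysis.
#' @return List of class `metric_report`.
#' @export
metric_report <- function(predicted, truth, labels = NULL) {
  out <- list(mae = mae(predicted, truth),
              icc = icc(predicted, truth),
              r_squared = r_squared(predicted, truth))
  if (!is.null(labels)) {
    out$auc <- roc_auc(presence_score(predicted), labels)
  }
  structure(out, class = "metric_report")
}

#' @export
print.metric_report <- function(x, ...) {
  cat(sprintf("MAE: %.3f cm\nICC(2,1): %.3f (95%% CI %.3f-%.3f)\nR-squared: %.3f\n",
              x$mae, x$icc$value, x$icc$ci_low, x$icc$ci_high, x$r_squared))
  if (!is.null(x$auc)) {
    cat(sprintf("AUC: %.3f (95%% CI %.3f-%.3f)\n", x$auc$auc, x$auc$ci_low,
                x$auc$ci_high))
  }
  invisible(x)
}
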