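# Ratio biomarker and Mann-Whitney ROC analysis with Hanley-McNeil
# confidence intervals.

#' Per-sample ratio of two miRNA fold changes
#'
#' Computes the linear fold-change ratio (e.g. miR-146a / miR-106b) per
#' sample; a higher ratio is the disease-like direction. Samples missing
#' either fold change are omitted (recorded in the `"omitted"` attribute).
#'
#' @param fc_table Long fold-change table from [fold_change()].
#' @param numerator,denominator miRNA ids.
#' @return data.frame `sample_id`, `group`, `ratio`, with attribute
#'   `"omitted"`.
#' @export
ratio_values <- function(fc_table, numerator = "miR-146a",
                         denominator = "miR-106b") {
  num <- fc_table[fc_table$mir_id == numerator, c("sample_id", "group", "fc")]
  den <- fc_table[fc_table$mir_id == denominator, c("sample_id", "fc")]
  if (!nrow(den) || all(is.na(den$fc))) {
    stop("ratio_not_computable: denominator fold change undefined for all samples",
         call. = FALSE)
  }
  m <- merge(num, den, by = "sample_id", suffixes = c("_num", "_den"))
  ok <- is.finite(m$fc_num) & is.finite(m$fc_den) & m$fc_den > 0
  omitted <- union(setdiff(union(num$sample_id, den$sample_id), m$sample_id),
                   m$sample_id[!ok])
  out <- data.frame(sample_id = m$sample_id[ok], group = m$group[ok],
                    ratio = m$fc_num[ok] / m$fc_den[ok],
                    stringsAsFactors = FALSE)
  structure(out, omitted = omitted)
}

#' Mann-Whitney AUC
#'
#' The probability that a random case outranks a random control:
#' `AUC = (#{case > control} + 0.5 #{ties}) / (n_case * n_control)`,
#' computed from ranks. This equals the trapezoidal area under the
#' empirical ROC curve.
#'
#' @param cases,controls Numeric marker values (higher = more disease-like).
#' @return AUC in \[0, 1\].
#' @export
#' @examples
#' auc_mann_whitney(c(3, 5), c(1, 4)) # 0.75
auc_mann_whitney <- function(cases, controls) {
  cases <- cases[is.finite(cases)]
  controls <- controls[is.finite(controls)]
  n1 <- length(cases); n0 <- length(controls)
  stopifnot(n1 > 0, n0 > 0)
  r <- rank(c(cases, controls))
  u <- sum(r[seq_len(n1)]) - n1 * (n1 + 1) / 2
  u / (n1 * n0)
}

#' Empirical ROC points
#'
#' (false positive rate, true positive rate) pairs obtained by thresholding
#' the marker at every distinct observed value, from (0, 0) to (1, 1), with
#' the classification rule `marker >= threshold` = positive.
#'
#' @inheritParams auc_mann_whitney
#' @return data.frame `threshold`, `fpr`, `tpr` (threshold `Inf` for the
#'   (0,0) point and `-Inf` for (1,1)).
#' @export
roc_points <- function(cases, controls) {
  cases <- cases[is.finite(cases)]
  controls <- controls[is.finite(controls)]
  thr <- sort(unique(c(cases, controls)), decreasing = TRUE)
  tpr <- vapply(thr, function(t) mean(cases >= t), numeric(1))
  fpr <- vapply(thr, function(t) mean(controls >= t), numeric(1))
  data.frame(threshold = c(Inf, thr),
             fpr = c(0, fpr), tpr = c(0, tpr))
}

#' Hanley-McNeil standard error and confidence interval for an AUC
#'
#' Normal-approximation interval `A +/- z * SE` with
#' `SE^2 = (A(1-A) + (n_case-1)(Q1-A^2) + (n_control-1)(Q2-A^2)) /
#' (n_case * n_control)`, `Q1 = A/(2-A)`, `Q2 = 2A^2/(1+A)`. The interval is
#' deliberately not truncated at 1 (small-sample intervals around a high AUC
#' can exceed 1 under this approximation).
#'
#' @param auc AUC in \[0, 1\].
#' @param n_case,n_control Group sizes.
#' @param level Confidence level.
#' @return List with `se`, `ci_low`, `ci_high`.
#' @export
auc_ci <- function(auc, n_case, n_control, level = 0.95) {
  stopifnot(auc >= 0, auc <= 1, n_case >= 1, n_control >= 1)
  q1 <- auc / (2 - auc)
  q2 <- 2 * auc^2 / (1 + auc)
  se <- sqrt((auc * (1 - auc) + (n_case - 1) * (q1 - auc^2) +
                (n_control - 1) * (q2 - auc^2)) / (n_case * n_control))
  z <- stats::qnorm(1 - (1 - level) / 2)
  list(se = se, ci_low = auc - z * se, ci_high = auc + z * se)
}

#' P-value for AUC = 0.5
#'
#' Two-sided p-value for the null hypothesis of no discrimination, via the
#' normal approximation to the Mann-Whitney U statistic
#' (`U = AUC * n_case * n_control`, null mean `n1 n0 / 2`, null variance
#' `n1 n0 (n1 + n0 + 1) / 12`).
#'
#' @inheritParams auc_ci
#' @return Two-sided p-value.
#' @export
auc_pvalue <- function(auc, n_case, n_control) {
  stopifnot(auc >= 0, auc <= 1, n_case >= 1, n_control >= 1)
  u <- auc * n_case * n_control
  mu <- n_case * n_control / 2
  sigma <- sqrt(n_case * n_control * (n_case + n_control + 1) / 12)
  z <- (u - mu) / sigma
  min(1, 2 * stats::pnorm(-abs(z)))
}

#' ROC analysis of a marker
#'
#' Bundles the empirical ROC points, Mann-Whitney AUC, Hanley-McNeil SE and
#' confidence interval, and the normal-approximation p-value against
#' AUC = 0.5. AUC below 0.5 is reported as-is, never auto-flipped.
#'
#' @param values Numeric marker values (e.g. fold-change ratios).
#' @param labels Group labels aligned with `values`.
#' @param case Label identifying cases; all other labels are controls.
#' @param level Confidence level for the AUC interval.
#' @return Object of class `"mw_roc"`: `auc`, `se`, `ci_low`, `ci_high`,
#'   `p_value`, `points`, `n_case`, `n_control`.
#' @export
#' @examples
#' roc_curve(c(1, 2, 3, 8, 9, 10), rep(c("control", "case"), each = 3))
roc_curve <- function(values, labels, case = "case", level = 0.95) {
  stopifnot(length(values) == length(labels))
  ok <- is.finite(values)
  values <- values[ok]; labels <- labels[ok]
  cases <- values[labels == case]
  controls <- values[labels != case]
  auc <- auc_mann_whitney(cases, controls)
  ci <- auc_ci(auc, length(cases), length(controls), level)
  structure(list(auc = auc, se = ci$se, ci_low = ci$ci_low,
                 ci_high = ci$ci_high,
                 p_value = auc_pvalue(auc, length(cases), length(controls)),
                 points = roc_points(cases, controls),
                 n_case = length(cases), n_control = length(controls),
                 level = level),
            class = "mw_roc")
}

#' @export
print.mw_roc <- function(x, ...) {
  cat(sprintf("ROC: AUC = %.4f (SE %.4f; %g%% CI %.4f to %.4f), p = %.4g\n",
              x$auc, x$se, 100 * x$level, x$ci_low, x$ci_high, x$p_value))
  cat("  n_case =", x$n_case, ", n_control =", x$n_control, "\n")
  invisible(x)
}

#' @export
plot.mw_roc <- function(x, ...) {
  graphics::plot(x$points$fpr, x$points$tpr, type = "s",
                 xlim = c(0, 1), ylim = c(0, 1),
                 xlab = "False positive rate", ylab = "True positive rate",
                 ...)
  graphics::abline(0, 1, lty = 3, col = "grey60")
  graphics::legend("bottomright", bty = "n",
                   legend = sprintf("AUC = %.3f", x$auc))
  invisible(x)
}
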