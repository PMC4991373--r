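# Group comparison of centered log2 fold changes and per-miRNA summaries.

#' Student t-test between two groups
#'
#' Two-sided Student t-test, pooled-variance by default (df = n_a + n_b - 2)
#' with Welch available. Degenerate inputs are handled explicitly: zero
#' variance in both groups gives t = 0, p = 1 when the means are equal, and
#' p -> 0 with a warning when they differ.
#'
#' @param group_a,group_b Numeric vectors, each of length >= 2.
#' @param variant `"pooled"` (classic Student) or `"welch"`.
#' @return List with `t`, `df`, `p`.
#' @export
#' @examples
#' student_t(c(0, 1, 2), c(3, 4, 5)) # t = -3.674, df = 4, p ~ 0.0213
student_t <- function(group_a, group_b, variant = c("pooled", "welch")) {
  variant <- match.arg(variant)
  a <- group_a[is.finite(group_a)]
  b <- group_b[is.finite(group_b)]
  if (length(a) < 2 || length(b) < 2) {
    stop("each group needs at least 2 finite values", call. = FALSE)
  }
  if (stats::var(a) == 0 && stats::var(b) == 0) {
    if (mean(a) == mean(b)) {
      return(list(t = 0, df = length(a) + length(b) - 2, p = 1))
    }
    warning("zero variance with unequal means: p -> 0", call. = FALSE)
    return(list(t = sign(mean(a) - mean(b)) * Inf,
                df = length(a) + length(b) - 2, p = 0))
  }
  tt <- stats::t.test(a, b, var.equal = (variant == "pooled"))
  list(t = unname(tt$statistic), df = unname(tt$parameter),
       p = unname(tt$p.value))
}

#' Per-miRNA fold-change summary with group comparison
#'
#' Emits both the linear-scale and log2-scale case summaries (mean and SEM)
#' together with the Student-t comparison of centered log2 fold changes
#' between groups — the quantities reported for each validated miRNA.
#'
#' @param fc_table Long fold-change table from [fold_change()] /
#'   [log2_center()] (needs `mir_id`, `group`, `fc`, `centered_log2fc`).
#' @param mir_id The miRNA to summarise.
#' @param control_group Control group label.
#' @param variant t-test variant, see [student_t()].
#' @return List of class `"fc_summary"`: `mir_id`, `n_control`, `n_case`,
#'   `mean_linear_fc_case`, `sem_linear_case`, `mean_log2_case`, `sem_log2`,
#'   `t_statistic`, `df`, `p_value`, `evaluable`.
#' @export
summarize_mir <- function(fc_table, mir_id, control_group = "control",
                          variant = c("pooled", "welch")) {
  variant <- match.arg(variant)
  sub <- fc_table[fc_table$mir_id == mir_id & !is.na(fc_table$fc), ]
  ctrl <- sub[sub$group == control_group, ]
  case <- sub[sub$group != control_group, ]
  sem <- function(x) stats::sd(x) / sqrt(length(x))
  out <- list(mir_id = mir_id, n_control = nrow(ctrl), n_case = nrow(case),
              mean_linear_fc_case = NA_real_, sem_linear_case = NA_real_,
              mean_log2_case = NA_real_, sem_log2 = NA_real_,
              t_statistic = NA_real_, df = NA_real_, p_value = NA_real_,
              evaluable = FALSE)
  if (nrow(ctrl) < 2 || nrow(case) < 2) {
    class(out) <- "fc_summary"
    return(out)
  }
  tt <- student_t(case$centered_log2fc, ctrl$centered_log2fc, variant)
  out$mean_linear_fc_case <- mean(case$fc)
  out$sem_linear_case <- sem(case$fc)
  out$mean_log2_case <- mean(case$centered_log2fc)
  out$sem_log2 <- sem(case$centered_log2fc)
  out$t_statistic <- tt$t
  out$df <- tt$df
  out$p_value <- tt$p
  out$evaluable <- TRUE
  class(out) <- "fc_summary"
  out
}

#' @export
print.fc_summary <- function(x, ...) {
  if (!x$evaluable) {
    cat(x$mir_id, ": not evaluable (n_control =", x$n_control,
        ", n_case =", x$n_case, ")\n")
    return(invisible(x))
  }
  cat(sprintf("%s: linear FC %.3f +/- %.3f (log2 %.3f +/- %.3f), t = %.3f, df = %g, p = %.4g\n",
              x$mir_id, x$mean_linear_fc_case, x$sem_linear_case,
              x$mean_log2_case, x$sem_log2, x$t_statistic, x$df, x$p_value))
  invisible(x)
}

#' Correlation between patient age and fold change
#'
#' Pearson correlation between age and per-sample linear fold change of one
#' miRNA, reported as r-squared (with the signed r retained), used to check
#' that a disease-associated signature is not an age effect.
#'
#' @param fc_table Long fold-change table.
#' @param meta Sample metadata with `sample_id` and `age`.
#' @param mir_id The miRNA to test.
#' @return List with `r`, `r_squared`, `n`.
#' @export
age_correlation <- function(fc_table, meta, mir_id) {
  sub <- fc_table[fc_table$mir_id == mir_id & !is.na(fc_table$fc), ]
  age <- stats::setNames(meta$age, meta$sample_id)[sub$sample_id]
  keep <- is.finite(age) & is.finite(sub$fc)
  age <- age[keep]
  fcv <- sub$fc[keep]
  if (length(age) < 3) stop("need at least 3 samples with age and FC",
                            call. = FALSE)
  if (stats::sd(age) == 0) {
    stop("age is constant: correlation undefined", call. = FALSE)
  }
  r <- stats::cor(age, fcv)
  list(r = r, r_squared = r^2, n = length(age))
}
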