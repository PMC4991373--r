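# Quality-control exclusions applied before normalization: amplification
# efficiency cutoff, hemolysis index, clinical flags, Grubbs outlier test.

qc_row <- function(entity_id, entity_type, reason, value = NA_real_) {
  data.frame(entity_id = entity_id, entity_type = entity_type,
             reason = reason, value = value, stringsAsFactors = FALSE)
}

empty_qc_report <- function() {
  data.frame(entity_id = character(), entity_type = character(),
             reason = character(), value = numeric(),
             stringsAsFactors = FALSE)
}

#' Exclude reactions below the amplification-efficiency cutoff
#'
#' Removes reactions whose efficiency (percent of perfect doubling,
#' `100 * base / 2`) falls below the cutoff; the standard threshold is 80
#' percent.
#'
#' @param records Reaction table carrying an `efficiency_percent` column (or
#'   an `efficiency` base column, converted as `100 * base / 2`).
#' @param cutoff_percent Minimal acceptable percent efficiency.
#' @return A list with `records` (retained rows) and `report` (excluded
#'   reactions with reason `"efficiency_below_cutoff"`).
#' @export
filter_efficiency <- function(records, cutoff_percent = 80) {
  pct <- if ("efficiency_percent" %in% names(records)) {
    records$efficiency_percent
  } else if ("efficiency" %in% names(records)) {
    100 * records$efficiency / 2
  } else {
    stop("records must carry efficiency_percent or efficiency", call. = FALSE)
  }
  bad <- !is.na(pct) & pct < cutoff_percent
  report <- if (any(bad)) {
    qc_row(records$reaction_id[bad], "reaction", "efficiency_below_cutoff",
           pct[bad])
  } else empty_qc_report()
  list(records = records[!bad, , drop = FALSE], report = report)
}

#' Exclude plasma samples with hemolysis index above the cutoff
#'
#' Plasma samples whose hemolysis index is strictly greater than the cutoff
#' (default 1) are excluded; an index of exactly 1 is retained. Plasma
#' samples with a missing index are excluded conservatively. Vitreous
#' samples are never touched by this rule.
#'
#' @param meta Sample metadata with `sample_id`, `matrix` and
#'   `hemolysis_index` columns.
#' @param cutoff Exclusion cutoff (strict inequality).
#' @return A list with `meta` (retained rows) and `report`.
#' @export
filter_hemolysis <- function(meta, cutoff = 1) {
  plasma <- meta$matrix == "plasma"
  high <- plasma & !is.na(meta$hemolysis_index) &
    meta$hemolysis_index > cutoff
  missing <- plasma & is.na(meta$hemolysis_index)
  report <- rbind(
    if (any(high)) qc_row(meta$sample_id[high], "sample",
                          "hemolysis_index_above_cutoff",
                          meta$hemolysis_index[high]) else NULL,
    if (any(missing)) qc_row(meta$sample_id[missing], "sample",
                             "missing_hemolysis_index") else NULL
  )
  if (is.null(report)) report <- empty_qc_report()
  list(meta = meta[!(high | missing), , drop = FALSE], report = report)
}

#' Exclude samples with blocklisted clinical flags
#'
#' Samples whose `clinical_flags` field (a comma/semicolon-separated string
#' or list column) contains any blocklisted condition (e.g. glaucoma, eye
#' medical treatment) are excluded.
#'
#' @param meta Sample metadata with `sample_id` and `clinical_flags`.
#' @param blocklist Character vector of disqualifying flags.
#' @return A list with `meta` and `report`.
#' @export
filter_clinical <- function(meta,
                            blocklist = c("glaucoma", "eye_medical_treatment")) {
  flags <- meta$clinical_flags
  if (is.list(flags)) {
    bad <- vapply(flags, function(f) any(f %in% blocklist), logical(1))
  } else {
    split_flags <- strsplit(ifelse(is.na(flags), "", flags), "[,;]\\s*")
    bad <- vapply(split_flags, function(f) any(f %in% blocklist), logical(1))
  }
  report <- if (any(bad)) {
    qc_row(meta$sample_id[bad], "sample", "clinical_flag")
  } else empty_qc_report()
  list(meta = meta[!bad, , drop = FALSE], report = report)
}

#' Grubbs statistic for a single most-extreme value
#'
#' `G = max_i |x_i - mean(x)| / sd(x)` with the sample SD (n - 1
#' denominator). Ties are broken by the first occurrence.
#'
#' @param values Numeric vector, `n >= 3`, with positive sample SD.
#' @return List with `G` and `index` of the most extreme value.
#' @export
#' @examples
#' grubbs_statistic(c(0, 0, 0, 10)) # G = 1.5 at index 4
grubbs_statistic <- function(values) {
  n <- length(values)
  if (n < 3 || !all(is.finite(values)) || stats::sd(values) == 0) {
    stop("grubbs_undefined: need n >= 3 finite values with positive SD",
         call. = FALSE)
  }
  dev <- abs(values - mean(values))
  i <- which.max(dev)
  list(G = dev[i] / stats::sd(values), index = i)
}

#' Grubbs critical value
#'
#' Critical value of the single-outlier Grubbs test,
#' `G_crit = ((n-1)/sqrt(n)) * sqrt(t^2 / (n - 2 + t^2))` where `t` is the
#' upper `alpha/(2n)` (two-sided) or `alpha/n` (one-sided) Student-t
#' quantile on `n - 2` degrees of freedom.
#'
#' @param n Sample size (>= 3).
#' @param alpha Significance level.
#' @param two_sided Two-sided test (default) or one-sided.
#' @return The critical value `G_crit(n, alpha)`.
#' @export
grubbs_critical <- function(n, alpha = 0.05, two_sided = TRUE) {
  stopifnot(n >= 3)
  denom <- if (two_sided) 2 * n else n
  t <- stats::qt(1 - alpha / denom, df = n - 2)
  ((n - 1) / sqrt(n)) * sqrt(t^2 / (n - 2 + t^2))
}

#' Grubbs outlier test
#'
#' Flags the most extreme value when its Grubbs statistic exceeds the
#' critical value. By default a single pass flags at most one outlier,
#' matching the single-outlier calculator convention; `iterative = TRUE`
#' repeats the test on the reduced sample until no further value is flagged.
#'
#' @param values Numeric vector (`n >= 3`).
#' @param alpha Significance level.
#' @param two_sided Two-sided (default) or one-sided critical value.
#' @param iterative Repeat on the reduced set after each exclusion.
#' @return Integer positions (in the original vector) of flagged outliers;
#'   `integer(0)` when none.
#' @export
grubbs_test <- function(values, alpha = 0.05, two_sided = TRUE,
                        iterative = FALSE) {
  flagged <- integer(0)
  live <- seq_along(values)
  repeat {
    if (length(live) < 3 || stats::sd(values[live]) == 0) break
    g <- grubbs_statistic(values[live])
    if (g$G <= grubbs_critical(length(live), alpha, two_sided)) break
    flagged <- c(flagged, live[g$index])
    live <- live[-g$index]
    if (!iterative) break
  }
  sort(flagged)
}

#' Write a QC report to TSV
#'
#' Serializes exclusion records (`entity_id`, `entity_type`, `reason`,
#' `value`) as tab-separated text.
#'
#' @param report QC report data.frame.
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_qc_report <- function(report, path) {
  utils::write.table(report, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}
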