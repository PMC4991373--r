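# Efficiency-aware delta-delta-Ct quantification with a weighted-mean or
# single-miRNA endogenous reference.

#' Collapse technical replicates into a sample x miRNA Ct matrix
#'
#' Averages detected replicate Ct values per sample and miRNA (mean by
#' default, median optionally). A sample/miRNA cell where every replicate is
#' undetected becomes `NA`.
#'
#' @param records Reaction table with `sample_id`, `mir_id`, `ct` (`NA` for
#'   undetected reactions).
#' @param stat `"mean"` or `"median"`.
#' @return Numeric matrix, samples in rows, miRNAs in columns.
#' @export
collapse_replicates <- function(records, stat = c("mean", "median")) {
  stat <- match.arg(stat)
  fun <- if (stat == "mean") mean else stats::median
  samples <- unique(records$sample_id)
  mirs <- unique(records$mir_id)
  m <- tapply(records$ct, list(records$sample_id, records$mir_id),
              function(x) {
                x <- x[!is.na(x)]
                if (!length(x)) NA_real_ else fun(x)
              })
  m[samples, mirs, drop = FALSE]
}

#' Weighted-mean endogenous reference
#'
#' Computes the per-sample reference Ct0 as a weighted mean of the member
#' miRNAs' Ct values, with weights inversely proportional to each member's
#' across-sample variability: `w_j = (1/SD_j)^wmp / sum_k (1/SD_k)^wmp`.
#' With `wmp = 0` (or equal SDs) this reduces to the plain arithmetic mean.
#' Samples in which any member is undetected get `NA` and are reported in
#' the `"excluded"` attribute.
#'
#' @param ct Sample x miRNA Ct matrix (see [collapse_replicates()]).
#' @param members Character vector of reference miRNA ids (columns of `ct`).
#' @param wmp Weighted mean power (>= 0, default 1).
#' @return Named per-sample vector of Ct0 with attributes `"weights"`
#'   (normalized member weights) and `"excluded"` (samples lacking a member).
#' @export
weighted_reference <- function(ct, members, wmp = 1) {
  stopifnot(is.matrix(ct), wmp >= 0)
  missing_members <- setdiff(members, colnames(ct))
  if (length(missing_members)) {
    stop("reference member(s) absent from Ct table: ",
         paste(missing_members, collapse = ", "), call. = FALSE)
  }
  sub <- ct[, members, drop = FALSE]
  sds <- apply(sub, 2, stats::sd, na.rm = TRUE)
  if (wmp > 0 && any(!is.finite(sds) | sds <= 0)) {
    stop("weighted reference undefined: member SD across samples must be > 0 (",
         paste(members[!is.finite(sds) | sds <= 0], collapse = ", "), ")",
         call. = FALSE)
  }
  w <- if (wmp == 0) rep(1, length(members)) else (1 / sds)^wmp
  w <- w / sum(w)
  ct0 <- as.vector(sub %*% w)
  names(ct0) <- rownames(ct)
  excluded <- rownames(ct)[apply(sub, 1, anyNA)]
  ct0[excluded] <- NA_real_
  structure(ct0, weights = stats::setNames(w, members), excluded = excluded)
}

#' Single-miRNA endogenous reference
#'
#' Uses one miRNA (canonically miR-16 for plasma) as the reference:
#' `Ct0(sample) = Ct_reference(sample)`. Samples where the reference is
#' undetected get `NA` and are listed in the `"excluded"` attribute.
#'
#' @param ct Sample x miRNA Ct matrix.
#' @param reference_mir Column name of the reference miRNA.
#' @return Named per-sample vector of Ct0.
#' @export
single_reference <- function(ct, reference_mir = "miR-16") {
  stopifnot(is.matrix(ct))
  if (!reference_mir %in% colnames(ct)) {
    stop("reference miRNA absent from Ct table: ", reference_mir,
         call. = FALSE)
  }
  ct0 <- ct[, reference_mir]
  structure(ct0,
            weights = stats::setNames(1, reference_mir),
            excluded = rownames(ct)[is.na(ct0)])
}

#' Per-sample delta Ct against a reference
#'
#' `dCt = Ct_miR - Ct0`, per sample and miRNA.
#'
#' @param ct Sample x miRNA Ct matrix.
#' @param ct0 Per-sample reference from [weighted_reference()] or
#'   [single_reference()].
#' @return Matrix of delta-Ct values, same shape as `ct`.
#' @export
delta_ct <- function(ct, ct0) {
  sweep(ct, 1, as.numeric(ct0), `-`)
}

#' Efficiency-based fold change from delta Ct
#'
#' For every sample and miRNA, `ddCt = dCt - mean(dCt over control samples)`
#' and `FC = base^(-ddCt)`, where `base` is the per-cycle amplification
#' factor (2 for perfect doubling; 1.7 and 1.75 are typical measured values
#' for array and individual TaqMan qPCR). Per-sample fold changes exist for
#' cases and controls alike, so downstream t-tests, outlier tests, ratios
#' and ROC curves all operate on patient-level values. A miRNA with no
#' detected control values is dropped with a warning.
#'
#' @param dct Sample x miRNA delta-Ct matrix (see [delta_ct()]).
#' @param base Amplification base in (1, 2], a scalar or a named per-miRNA
#'   vector.
#' @param groups Named group vector (`names` = sample ids) or a vector
#'   aligned with `rownames(dct)`.
#' @param control_group Label of the control group.
#' @return Long data.frame: `sample_id`, `mir_id`, `group`, `ddct`, `fc`,
#'   `log2fc`.
#' @export
fold_change <- function(dct, base, groups, control_group = "control") {
  stopifnot(is.matrix(dct))
  if (any(base <= 1) || any(base > 2)) {
    stop("amplification base must lie in (1, 2]", call. = FALSE)
  }
  if (!is.null(names(groups))) groups <- groups[rownames(dct)]
  if (!any(groups == control_group)) {
    stop("no samples in control group '", control_group, "'", call. = FALSE)
  }
  base_vec <- if (length(base) == 1L) {
    stats::setNames(rep(base, ncol(dct)), colnames(dct))
  } else base[colnames(dct)]

  rows <- lapply(colnames(dct), function(m) {
    v <- dct[, m]
    ctrl <- v[groups == control_group]
    if (all(is.na(ctrl))) {
      warning("miRNA dropped (no detected control values): ", m,
              call. = FALSE)
      return(NULL)
    }
    ddct <- v - mean(ctrl, na.rm = TRUE)
    fc <- base_vec[[m]]^(-ddct)
    data.frame(sample_id = rownames(dct), mir_id = m,
               group = as.character(groups), ddct = unname(ddct),
               fc = unname(fc), log2fc = unname(log2(fc)),
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out[!is.na(out$ddct), , drop = FALSE]
}

#' Center log2 fold changes on the control group
#'
#' Adds a `centered_log2fc` column: `log2fc` minus the per-miRNA mean (or,
#' optionally, median) of the control-group log2 fold changes, so the
#' control average equals 0 per miRNA.
#'
#' @param fc_table Long fold-change table from [fold_change()].
#' @param control_group Label of the control group.
#' @param center `"mean"` (the operational definition) or `"median"`.
#' @return `fc_table` with a `centered_log2fc` column.
#' @export
log2_center <- function(fc_table, control_group = "control",
                        center = c("mean", "median")) {
  center <- match.arg(center)
  fun <- if (center == "mean") mean else stats::median
  shift <- tapply(fc_table$log2fc[fc_table$group == control_group],
                  fc_table$mir_id[fc_table$group == control_group],
                  fun, na.rm = TRUE)
  fc_table$centered_log2fc <- fc_table$log2fc -
    as.numeric(shift[fc_table$mir_id])
  fc_table
}

#' Fit the efficiency-aware delta-delta-Ct quantification model
#'
#' The package's central fitting function. Starting from reaction-level Ct
#' records and sample metadata, it (1) collapses technical replicates,
#' (2) computes a per-sample endogenous reference Ct0 — either the
#' variability-weighted mean of several member miRNAs (the vitreous-humour
#' mode, where no single housekeeping miRNA is established) or a single
#' reference miRNA (the plasma mode, canonically miR-16) — then (3) derives
#' `dCt = Ct - Ct0`, `ddCt = dCt - mean(control dCt)` and the
#' efficiency-corrected fold change `FC = base^(-ddCt)`, and (4) log2
#' transforms and centers the fold changes so the control mean is 0 per
#' miRNA.
#'
#' @param records Reaction table (`sample_id`, `mir_id`, `replicate`, `ct`).
#' @param meta Sample metadata with `sample_id` and `group`.
#' @param reference `"weighted_mean"` or `"single_mir"`.
#' @param members Reference member miRNAs (weighted-mean mode); defaults to
#'   the established vitreous set `miR-16, miR-106b, miR-146a, miR-152`,
#'   intersected with the observed panel.
#' @param reference_mir Reference miRNA (single-miR mode).
#' @param wmp Weighted mean power (see [weighted_reference()]).
#' @param efficiency Amplification base in (1, 2], scalar or named
#'   per-miRNA; 1.75 is the measured individual TaqMan qPCR value.
#' @param control_group Control group label in `meta$group`.
#' @param collapse Replicate collapse statistic.
#' @param center Control-centering statistic for log2 fold changes.
#' @return An object of class `"ddct_fit"` with components `ct` (collapsed
#'   matrix), `ct0`, `delta_ct`, `fc` (long table with centered log2 values),
#'   `reference` (mode, members, weights), `efficiency`, `groups`,
#'   `excluded_samples`, `meta` and `call`. Methods: `print`, `summary`,
#'   `coef`, `residuals`, `plot`.
#' @export
#' @examples
#' cohort <- simulate_cohort(sim_config(seed = 7))
#' fit <- ddct_fit(cohort$records, cohort$meta,
#'                 reference = "single_mir", reference_mir = "miR-16")
#' summary(fit)
ddct_fit <- function(records, meta,
                     reference = c("weighted_mean", "single_mir"),
                     members = NULL, reference_mir = "miR-16", wmp = 1,
                     efficiency = 1.75, control_group = "control",
                     collapse = c("mean", "median"),
                     center = c("mean", "median")) {
  reference <- match.arg(reference)
  collapse <- match.arg(collapse)
  center <- match.arg(center)
  stopifnot(all(c("sample_id", "mir_id", "ct") %in% names(records)),
            all(c("sample_id", "group") %in% names(meta)))
  records <- records[records$sample_id %in% meta$sample_id, , drop = FALSE]
  ct <- collapse_replicates(records, collapse)
  groups <- stats::setNames(meta$group, meta$sample_id)[rownames(ct)]

  ct0 <- if (reference == "weighted_mean") {
    if (is.null(members)) {
      members <- intersect(c("miR-16", "miR-106b", "miR-146a", "miR-152"),
                           colnames(ct))
    }
    if (length(members) < 1) stop("no reference members available", call. = FALSE)
    weighted_reference(ct, members, wmp)
  } else {
    single_reference(ct, reference_mir)
  }
  excluded <- attr(ct0, "excluded")

  dct <- delta_ct(ct, ct0)
  fc <- fold_change(dct, efficiency, groups, control_group)
  fc <- log2_center(fc, control_group, center)

  structure(list(
    ct = ct, ct0 = ct0, delta_ct = dct, fc = fc,
    reference = list(mode = reference,
                     members = if (reference == "weighted_mean") members
                               else reference_mir,
                     wmp = wmp, weights = attr(ct0, "weights")),
    efficiency = efficiency, groups = groups,
    control_group = control_group,
    excluded_samples = excluded, meta = meta, call = match.call()
  ), class = "ddct_fit")
}

#' @export
print.ddct_fit <- function(x, ...) {
  cat("Efficiency-aware ddCt fit\n")
  cat("  reference:", x$reference$mode,
      paste0("(", paste(x$reference$members, collapse = ", "), ")"), "\n")
  cat("  efficiency base:", paste(format(x$efficiency), collapse = ", "), "\n")
  cat("  samples:", nrow(x$ct),
      sprintf("(%d control, %d case)",
              sum(x$groups == x$control_group, na.rm = TRUE),
              sum(x$groups != x$control_group, na.rm = TRUE)),
      " miRNAs:", ncol(x$ct), "\n")
  if (length(x$excluded_samples)) {
    cat("  samples lacking reference:",
        paste(x$excluded_samples, collapse = ", "), "\n")
  }
  invisible(x)
}

#' @export
coef.ddct_fit <- function(object, ...) {
  case <- object$fc[object$fc$group != object$control_group, ]
  tapply(case$centered_log2fc, case$mir_id, mean, na.rm = TRUE)
}

#' @export
residuals.ddct_fit <- function(object, ...) {
  fc <- object$fc
  gm <- stats::ave(fc$centered_log2fc,
                   interaction(fc$mir_id, fc$group), FUN = mean)
  stats::setNames(fc$centered_log2fc - gm,
                  paste(fc$sample_id, fc$mir_id, sep = ":"))
}

#' @export
summary.ddct_fit <- function(object, variant = c("pooled", "welch"), ...) {
  variant <- match.arg(variant)
  mirs <- sort(unique(object$fc$mir_id))
  tab <- do.call(rbind, lapply(mirs, function(m) {
    s <- summarize_mir(object$fc, m, control_group = object$control_group,
                       variant = variant)
    as.data.frame(unclass(s), stringsAsFactors = FALSE)
  }))
  rownames(tab) <- NULL
  structure(list(table = tab, reference = object$reference,
                 efficiency = object$efficiency),
            class = "summary.ddct_fit")
}

#' @export
print.summary.ddct_fit <- function(x, digits = 4, ...) {
  cat("Per-miRNA fold-change summary (FC = base^(-ddCt), base =",
      paste(format(x$efficiency), collapse = ", "), ")\n")
  cat("Reference:", x$reference$mode,
      paste0("(", paste(x$reference$members, collapse = ", "), ")\n\n"))
  print(format(x$table, digits = digits), row.names = FALSE)
  invisible(x)
}

#' @export
plot.ddct_fit <- function(x, ...) {
  fc <- x$fc
  graphics::boxplot(centered_log2fc ~ interaction(group, mir_id), data = fc,
                    las = 2, ylab = "centered log2 fold change",
                    xlab = "", ...)
  graphics::abline(h = 0, lty = 2, col = "grey50")
  invisible(x)
}
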