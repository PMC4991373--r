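# File formats and the all-in-one pipeline: Ct tables, sample metadata,
# SNP/LD/gene-set tables, and report writers.

parse_ct_field <- function(x) {
  x <- trimws(as.character(x))
  undet <- is.na(x) | x %in% c("Undetermined", "NA", "", "undetermined")
  if (any(grepl("^[0-9]+,[0-9]+$", x))) {
    stop("decimal-comma Ct value found (e.g. '",
         x[grepl("^[0-9]+,[0-9]+$", x)][1],
         "'): use a decimal point", call. = FALSE)
  }
  ct <- suppressWarnings(as.numeric(x))
  if (any(!undet & is.na(ct))) {
    stop("unparseable ct value: '", x[!undet & is.na(ct)][1], "'",
         call. = FALSE)
  }
  ct[undet] <- NA_real_
  ct
}

#' Read a long-format Ct table
#'
#' Reads a CSV with header `sample_id,mir_id,replicate,ct`. The Ct field
#' accepts `"Undetermined"`, `"NA"` or an empty string for undetected
#' reactions; numeric values above 40 cycles (the detection threshold) are
#' coerced to undetected with a warning. Decimal-comma values are rejected
#' rather than silently mis-parsed.
#'
#' @param path CSV file path.
#' @param max_cycle Detection threshold in cycles.
#' @return data.frame `sample_id`, `mir_id`, `replicate`, `ct` (`NA` when
#'   undetected), `detected`.
#' @export
read_ct_table <- function(path, max_cycle = 40) {
  tab <- utils::read.csv(path, stringsAsFactors = FALSE,
                         colClasses = "character")
  required <- c("sample_id", "mir_id", "replicate", "ct")
  missing <- setdiff(required, names(tab))
  if (length(missing)) {
    stop("missing column: ", paste(missing, collapse = ", "), call. = FALSE)
  }
  key <- paste(tab$sample_id, tab$mir_id, tab$replicate, sep = "\r")
  if (anyDuplicated(key)) {
    dup <- tab[duplicated(key), ][1, ]
    stop("duplicate reaction: sample ", dup$sample_id, ", miRNA ",
         dup$mir_id, ", replicate ", dup$replicate, call. = FALSE)
  }
  ct <- parse_ct_field(tab$ct)
  over <- !is.na(ct) & ct > max_cycle
  if (any(over)) {
    warning(sum(over), " reaction(s) with Ct > ", max_cycle,
            " coerced to undetected", call. = FALSE)
    ct[over] <- NA_real_
  }
  out <- data.frame(sample_id = tab$sample_id, mir_id = tab$mir_id,
                    replicate = as.integer(tab$replicate), ct = ct,
                    detected = !is.na(ct), stringsAsFactors = FALSE)
  if ("efficiency_percent" %in% names(tab)) {
    out$efficiency_percent <- as.numeric(tab$efficiency_percent)
  }
  out
}

#' Read sample metadata
#'
#' CSV with header `sample_id,group,matrix,age,sex` and, for plasma cohorts,
#' `hemolysis_index`; an optional `clinical_flags` column holds
#' comma-separated condition flags.
#'
#' @param path CSV file path.
#' @return data.frame of sample metadata.
#' @export
read_sample_meta <- function(path) {
  meta <- utils::read.csv(path, stringsAsFactors = FALSE)
  required <- c("sample_id", "group", "matrix")
  missing <- setdiff(required, names(meta))
  if (length(missing)) {
    stop("missing column: ", paste(missing, collapse = ", "), call. = FALSE)
  }
  bad_group <- setdiff(unique(meta$group), c("control", "case"))
  if (length(bad_group)) {
    stop("unknown group label: ", paste(bad_group, collapse = ", "),
         call. = FALSE)
  }
  bad_matrix <- setdiff(unique(meta$matrix), c("vitreous", "plasma"))
  if (length(bad_matrix)) {
    stop("unknown matrix: ", paste(bad_matrix, collapse = ", "),
         call. = FALSE)
  }
  if (!"clinical_flags" %in% names(meta)) meta$clinical_flags <- ""
  meta
}

#' Read SNP association summary statistics
#'
#' TSV with header `rsid,chrom,pos,p` (an optional `gene` column is kept).
#'
#' @param path TSV file path.
#' @return data.frame `rsid`, `chrom`, `pos`, `p_value`, and `gene` if
#'   present.
#' @export
read_snp_table <- function(path) {
  tab <- utils::read.delim(path, stringsAsFactors = FALSE)
  required <- c("rsid", "chrom", "pos", "p")
  missing <- setdiff(required, names(tab))
  if (length(missing)) {
    stop("missing column: ", paste(missing, collapse = ", "), call. = FALSE)
  }
  if (any(tab$p <= 0 | tab$p > 1)) {
    stop("p-values must lie in (0, 1]", call. = FALSE)
  }
  out <- data.frame(rsid = tab$rsid, chrom = as.character(tab$chrom),
                    pos = as.integer(tab$pos), p_value = tab$p,
                    stringsAsFactors = FALSE)
  if ("gene" %in% names(tab)) out$gene <- tab$gene
  out
}

#' Read an LD proxy table
#'
#' TSV with header `rsid_a,rsid_b,r2` plus `chrom_b,pos_b` locating the
#' proxy.
#'
#' @param path TSV file path.
#' @return data.frame ready for [ld_proxy_expand()].
#' @export
read_ld_table <- function(path) {
  tab <- utils::read.delim(path, stringsAsFactors = FALSE)
  required <- c("rsid_a", "rsid_b", "r2")
  missing <- setdiff(required, names(tab))
  if (length(missing)) {
    stop("missing column: ", paste(missing, collapse = ", "), call. = FALSE)
  }
  tab
}

#' Read miRNA target gene sets
#'
#' Two-column TSV `mir_id,gene`.
#'
#' @param path TSV file path.
#' @return Named list mapping each miRNA id to a character vector of genes.
#' @export
read_gene_sets <- function(path) {
  tab <- utils::read.delim(path, stringsAsFactors = FALSE)
  missing <- setdiff(c("mir_id", "gene"), names(tab))
  if (length(missing)) {
    stop("missing column: ", paste(missing, collapse = ", "), call. = FALSE)
  }
  split(tab$gene, tab$mir_id)
}

#' Pipeline configuration
#'
#' Assembles and validates the declarative configuration for
#' [run_pipeline()]. A run is reproducible from the configuration and the
#' input files alone: the pipeline itself draws no random numbers.
#'
#' @param ct_path Path to the long-format Ct CSV.
#' @param meta_path Path to the sample metadata CSV.
#' @param out_dir Output directory for report files.
#' @param matrix `"vitreous"` or `"plasma"`; selects the default reference
#'   mode (weighted mean for vitreous, single miR-16 for plasma).
#' @param reference,members,reference_mir,wmp Reference model, see
#'   [ddct_fit()].
#' @param efficiency Amplification base in (1, 2].
#' @param efficiency_cutoff Percent-efficiency exclusion threshold.
#' @param hemolysis_cutoff Hemolysis index exclusion threshold (plasma).
#' @param grubbs_alpha Alpha for the per-group Grubbs outlier pass on log2
#'   fold changes.
#' @param t_variant `"pooled"` or `"welch"`.
#' @param ratio_numerator,ratio_denominator miRNAs of the ratio biomarker.
#' @param clinical_blocklist Disqualifying clinical flags.
#' @return A list of class `"pipeline_config"`.
#' @export
pipeline_config <- function(ct_path, meta_path, out_dir,
                            matrix = c("vitreous", "plasma"),
                            reference = NULL, members = NULL,
                            reference_mir = "miR-16", wmp = 1,
                            efficiency = 1.75, efficiency_cutoff = 80,
                            hemolysis_cutoff = 1, grubbs_alpha = 0.05,
                            t_variant = c("pooled", "welch"),
                            ratio_numerator = "miR-146a",
                            ratio_denominator = "miR-106b",
                            clinical_blocklist = c("glaucoma",
                                                   "eye_medical_treatment")) {
  matrix <- match.arg(matrix)
  t_variant <- match.arg(t_variant)
  if (is.null(reference)) {
    reference <- if (matrix == "vitreous") "weighted_mean" else "single_mir"
  }
  reference <- match.arg(reference, c("weighted_mean", "single_mir"))
  stopifnot(efficiency > 1, efficiency <= 2)
  structure(list(ct_path = ct_path, meta_path = meta_path, out_dir = out_dir,
                 matrix = matrix, reference = reference, members = members,
                 reference_mir = reference_mir, wmp = wmp,
                 efficiency = efficiency,
                 efficiency_cutoff = efficiency_cutoff,
                 hemolysis_cutoff = hemolysis_cutoff,
                 grubbs_alpha = grubbs_alpha, t_variant = t_variant,
                 ratio_numerator = ratio_numerator,
                 ratio_denominator = ratio_denominator,
                 clinical_blocklist = clinical_blocklist),
            class = "pipeline_config")
}

#' Run the full quantification pipeline
#'
#' Validates inputs, applies the QC exclusion chain in fixed order
#' (detection threshold at parse time, efficiency cutoff, hemolysis,
#' clinical flags, then a per-group Grubbs pass on log2 fold changes), fits
#' the delta-delta-Ct model, summarises each miRNA, and evaluates the ratio
#' biomarker by ROC. Writes five report files into `out_dir`:
#' `qc_report.tsv`, `fold_changes.tsv`, `mir_summary.tsv`,
#' `roc_points.tsv`, `roc_summary.json`. Reruns with identical inputs
#' produce byte-identical reports.
#'
#' @param config A [pipeline_config()] object.
#' @return Invisibly, a list with the fitted model (`fit`), `summary`,
#'   `roc`, `qc_report`, and output `paths`.
#' @export
run_pipeline <- function(config) {
  stopifnot(inherits(config, "pipeline_config"))
  if (!file.exists(config$ct_path)) {
    stop("stage input: Ct table not found: ", config$ct_path, call. = FALSE)
  }
  if (!file.exists(config$meta_path)) {
    stop("stage input: metadata not found: ", config$meta_path, call. = FALSE)
  }
  meta <- read_sample_meta(config$meta_path)
  if (config$matrix == "plasma" && !"hemolysis_index" %in% names(meta)) {
    stop("stage validate: plasma run requires a hemolysis_index column",
         call. = FALSE)
  }
  if (!"hemolysis_index" %in% names(meta)) meta$hemolysis_index <- NA_real_
  records <- read_ct_table(config$ct_path)

  qc <- empty_qc_report()

  # reaction-level efficiency cutoff (only when efficiency annotations exist)
  if (any(c("efficiency_percent", "efficiency") %in% names(records))) {
    fe <- filter_efficiency(records, config$efficiency_cutoff)
    records <- fe$records
    qc <- rbind(qc, fe$report)
  }

  if (config$matrix == "plasma") {
    fh <- filter_hemolysis(meta, config$hemolysis_cutoff)
    meta <- fh$meta
    qc <- rbind(qc, fh$report)
  }
  fc_cl <- filter_clinical(meta, config$clinical_blocklist)
  meta <- fc_cl$meta
  qc <- rbind(qc, fc_cl$report)

  fit <- ddct_fit(records, meta, reference = config$reference,
                  members = config$members,
                  reference_mir = config$reference_mir, wmp = config$wmp,
                  efficiency = config$efficiency)

  # Grubbs pass on per-group log2 fold changes, one outlier per pass
  fc <- fit$fc
  drop_rows <- integer(0)
  for (m in unique(fc$mir_id)) {
    for (g in unique(fc$group)) {
      rows <- which(fc$mir_id == m & fc$group == g & is.finite(fc$log2fc))
      if (length(rows) < 3) next
      out_idx <- grubbs_test(fc$log2fc[rows], alpha = config$grubbs_alpha)
      if (length(out_idx)) {
        drop_rows <- c(drop_rows, rows[out_idx])
        qc <- rbind(qc, qc_row(paste(fc$sample_id[rows[out_idx]], m,
                                     sep = ":"),
                               "fold_change", "grubbs_outlier",
                               fc$log2fc[rows[out_idx]]))
      }
    }
  }
  if (length(drop_rows)) fc <- fc[-drop_rows, , drop = FALSE]
  fit$fc <- fc

  summ <- summary(fit, variant = config$t_variant)
  ratios <- ratio_values(fit$fc, config$ratio_numerator,
                         config$ratio_denominator)
  roc <- roc_curve(ratios$ratio, ratios$group, case = "case")

  dir.create(config$out_dir, showWarnings = FALSE, recursive = TRUE)
  paths <- file.path(config$out_dir,
                     c("qc_report.tsv", "fold_changes.tsv",
                       "mir_summary.tsv", "roc_points.tsv",
                       "roc_summary.json"))
  names(paths) <- c("qc", "fc", "summary", "roc_points", "roc_summary")
  write_qc_report(qc, paths["qc"])
  utils::write.table(fit$fc, paths["fc"], sep = "\t", quote = FALSE,
                     row.names = FALSE)
  utils::write.table(summ$table, paths["summary"], sep = "\t", quote = FALSE,
                     row.names = FALSE)
  utils::write.table(roc$points, paths["roc_points"], sep = "\t",
                     quote = FALSE, row.names = FALSE)
  jsonlite::write_json(list(auc = roc$auc, se = roc$se,
                            ci_low = roc$ci_low, ci_high = roc$ci_high,
                            p_value = roc$p_value, n_case = roc$n_case,
                            n_control = roc$n_control),
                       paths["roc_summary"], auto_unbox = TRUE, digits = NA)

  invisible(list(fit = fit, summary = summ, roc = roc, qc_report = qc,
                 paths = paths))
}

#' Write a simulated cohort to pipeline input files
#'
#' Serializes a [simulate_cohort()] result as the long-format Ct CSV and
#' metadata CSV consumed by [run_pipeline()], plus a ground-truth sidecar
#' TSV for test harnesses.
#'
#' @param cohort A `"mir_cohort"` object.
#' @param dir Output directory.
#' @return Named character vector of file paths (`ct`, `meta`, `truth`).
#' @export
write_cohort <- function(cohort, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  ct_path <- file.path(dir, "ct_table.csv")
  meta_path <- file.path(dir, "sample_meta.csv")
  truth_path <- file.path(dir, "sim_truth.tsv")
  rec <- cohort$records
  rec$ct <- ifelse(is.na(rec$ct), "Undetermined", format(rec$ct, digits = 10))
  utils::write.csv(rec[, c("sample_id", "mir_id", "replicate", "ct")],
                   ct_path, row.names = FALSE, quote = FALSE)
  utils::write.csv(cohort$meta, meta_path, row.names = FALSE, quote = FALSE)
  ab <- as.data.frame(cohort$truth$abundance)
  ab$sample_id <- rownames(ab)
  utils::write.table(ab, truth_path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  c(ct = ct_path, meta = meta_path, truth = truth_path)
}
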