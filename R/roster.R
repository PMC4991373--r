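#' Clinical roster of the vitreous-biopsy validation cohort
#'
#' Returns the per-patient clinical characteristics of the two-arm
#' vitreous-biopsy cohort used throughout the package's worked examples:
#' 13 control patients operated for non-vascular ocular pathology
#' (epiretinal membrane, ERM, or macular hole, MH) and 13 patients with
#' neovascular age-related macular degeneration (NV AMD) with pronounced
#' choroidal neovascularization on OCT.
#'
#' @return A data.frame with one row per patient and columns `sample_id`,
#'   `group` (`"control"` or `"case"`), `sex` (`"F"`/`"M"`), `age` (years),
#'   `condition` (control pathology or AMD treatment status; `NA` where not
#'   recorded), `oct_um` (central retinal thickness in micrometres, cases
#'   only) and `analysis` (which assay stage the sample entered).
#' @seealso [cohort_summary()]
#' @export
#' @examples
#' roster <- nvamd_cohort_roster()
#' table(roster$group)
nvamd_cohort_roster <- function() {
  data.frame(
    sample_id = c(paste0("C", 1:13), paste0("AMD", 1:13)),
    group = rep(c("control", "case"), each = 13L),
    sex = c("F", "F", "F", "F", "F", "F", "F", "M", "F", "F", "F", "F", "M",
            "M", "M", "F", "M", "F", "F", "M", "F", "F", "F", "F", "F", "F"),
    age = c(54, 81, 65, 76, 70, 46, 84, 78, 63, 66, 54, 72, 57,
            76, 86, 91, 76, 85, 94, 63, 96, 74, 87, 75, 85, 75),
    condition = c(NA, "MH", "MH", "MH", "ERM", "ERM", "ERM", "ERM", "CAT-MH",
                  "ERM", "ERM", "ERM", "ERM",
                  "NAIVE", "NAIVE", "NAIVE", "ACTIVE", "NAIVE", "NAIVE",
                  "NAIVE", "NAIVE", "NAIVE", "NAIVE", "NAIVE", "NAIVE",
                  "NAIVE"),
    oct_um = c(rep(NA_real_, 13L),
               401, 438, 301, 260, 382, 1077, 622, 1150, 289, 223, 361, 250,
               492),
    analysis = c("qPCR", "qPCR", "qPCR", "qPCR", "microarray and qPCR",
                 "qPCR", "qPCR", "qPCR", "microarray", "qPCR", "qPCR",
                 "qPCR", "qPCR",
                 "microarray", "microarray", "qPCR", "microarray", "qPCR",
                 "qPCR", "qPCR", "microarray and qPCR", "qPCR", "qPCR",
                 "qPCR", "qPCR", "qPCR"),
    stringsAsFactors = FALSE
  )
}

#' Summarise a cohort roster per group
#'
#' Computes the baseline statistics of a clinical roster: group sizes, mean
#' and SD of age, percentage of female patients, and counts of control
#' pathology types (epiretinal membrane, macular hole; a combined
#' cataract/macular-hole entry counts as macular hole).
#'
#' @param roster A data.frame as returned by [nvamd_cohort_roster()]; must
#'   carry `group`, `sex`, `age` and `condition` columns.
#' @param sd Age dispersion convention: `"population"` (n denominator, the
#'   convention of clinical baseline tables) or `"sample"` (n - 1).
#' @return A data.frame with one row per group and columns `group`, `n`,
#'   `mean_age`, `sd_age`, `pct_female`, `n_erm`, `n_mh`.
#' @export
#' @examples
#' cohort_summary(nvamd_cohort_roster())
cohort_summary <- function(roster, sd = c("population", "sample")) {
  sd <- match.arg(sd)
  stopifnot(all(c("group", "sex", "age", "condition") %in% names(roster)))
  sd_fun <- if (sd == "population") {
    function(x) sqrt(mean((x - mean(x))^2))
  } else {
    stats::sd
  }
  groups <- unique(roster$group)
  out <- do.call(rbind, lapply(groups, function(g) {
    r <- roster[roster$group == g, , drop = FALSE]
    data.frame(
      group = g,
      n = nrow(r),
      mean_age = mean(r$age),
      sd_age = sd_fun(r$age),
      pct_female = 100 * mean(r$sex == "F"),
      n_erm = sum(r$condition == "ERM", na.rm = TRUE),
      n_mh = sum(grepl("MH", r$condition), na.rm = TRUE),
      stringsAsFactors = FALSE
    )
  }))
  rownames(out) <- NULL
  out
}
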