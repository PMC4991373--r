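# Synthetic cohort generator: Ct tables, amplification curves and SNP panels
# with the statistical structure the downstream analysis assumes.

#' Configuration for a synthetic qPCR cohort
#'
#' Builds and validates the parameter set for [simulate_cohort()]. Defaults
#' describe a two-arm vitreous-humour study: 13 controls and 13 neovascular
#' AMD cases assayed for a six-miRNA panel in technical triplicate, with
#' case/control fold effects of 3.02 (miR-146a), 0.23 (miR-106b) and 0.33
#' (miR-152), a per-reaction amplification base of 1.75 and additive
#' Gaussian noise of 1 cycle on the Ct scale.
#'
#' @param n_control,n_case Group sizes (each at least 2).
#' @param mir_panel Character vector of miRNA identifiers.
#' @param fold_effects Named numeric vector of multiplicative case effects
#'   (> 0); panel members not named default to 1 (no effect).
#' @param base_ct Named numeric vector of mean control Ct per miRNA (cycles);
#'   unnamed members default to 28.
#' @param ct_noise_sd Additive Gaussian noise SD on the Ct scale, in cycles.
#' @param efficiency_base Per-cycle amplification factor in (1, 2]; a scalar
#'   or a named vector per miRNA.
#' @param hemolysis_rate Fraction of plasma samples whose hemolysis index
#'   exceeds 1 (the exclusion cutoff), in [0, 1).
#' @param n_replicates Technical qPCR replicates per sample and miRNA.
#' @param matrix Biofluid: `"vitreous"` (no hemolysis index) or `"plasma"`.
#' @param seed Integer seed; identical seeds give bit-identical cohorts.
#' @return A validated list of class `"sim_config"`.
#' @export
sim_config <- function(n_control = 13L,
                       n_case = 13L,
                       mir_panel = c("miR-146a", "miR-106b", "miR-152",
                                     "miR-16", "miR-205", "miR-548a"),
                       fold_effects = c("miR-146a" = 3.02,
                                        "miR-106b" = 0.23,
                                        "miR-152" = 0.33),
                       base_ct = c("miR-146a" = 28, "miR-106b" = 30,
                                   "miR-152" = 29, "miR-16" = 20,
                                   "miR-205" = 27, "miR-548a" = 31),
                       ct_noise_sd = 1,
                       efficiency_base = 1.75,
                       hemolysis_rate = 0.15,
                       n_replicates = 3L,
                       matrix = c("vitreous", "plasma"),
                       seed = 1L) {
  matrix <- match.arg(matrix)
  fail <- function(field, why) {
    stop("invalid sim_config field '", field, "': ", why, call. = FALSE)
  }
  if (!is.numeric(n_control) || n_control < 2) fail("n_control", "must be >= 2")
  if (!is.numeric(n_case) || n_case < 2) fail("n_case", "must be >= 2")
  if (!is.character(mir_panel) || length(mir_panel) < 1 ||
      anyDuplicated(mir_panel)) {
    fail("mir_panel", "must be a non-empty set of unique miRNA ids")
  }
  fold <- rep(1, length(mir_panel))
  names(fold) <- mir_panel
  if (length(fold_effects)) {
    if (is.null(names(fold_effects))) fail("fold_effects", "must be named")
    unknown <- setdiff(names(fold_effects), mir_panel)
    if (length(unknown)) fail("fold_effects", paste("not in panel:", unknown[1]))
    fold[names(fold_effects)] <- fold_effects
  }
  if (any(!is.finite(fold)) || any(fold <= 0)) {
    fail("fold_effects", "every fold effect must be > 0")
  }
  bct <- rep(28, length(mir_panel))
  names(bct) <- mir_panel
  if (length(base_ct)) {
    if (is.null(names(base_ct))) fail("base_ct", "must be named")
    unknown <- setdiff(names(base_ct), mir_panel)
    if (length(unknown)) fail("base_ct", paste("not in panel:", unknown[1]))
    bct[names(base_ct)] <- base_ct
  }
  if (any(!is.finite(bct)) || any(bct <= 0)) fail("base_ct", "must be positive")
  if (!is.numeric(ct_noise_sd) || ct_noise_sd < 0) {
    fail("ct_noise_sd", "must be >= 0")
  }
  eff <- if (length(efficiency_base) == 1L && is.null(names(efficiency_base))) {
    stats::setNames(rep(efficiency_base, length(mir_panel)), mir_panel)
  } else {
    if (is.null(names(efficiency_base))) fail("efficiency_base", "must be named")
    e <- stats::setNames(rep(1.75, length(mir_panel)), mir_panel)
    unknown <- setdiff(names(efficiency_base), mir_panel)
    if (length(unknown)) fail("efficiency_base", paste("not in panel:", unknown[1]))
    e[names(efficiency_base)] <- efficiency_base
    e
  }
  if (any(eff <= 1) || any(eff > 2)) {
    fail("efficiency_base", "every base must lie in (1, 2]")
  }
  if (!is.numeric(hemolysis_rate) || hemolysis_rate < 0 || hemolysis_rate >= 1) {
    fail("hemolysis_rate", "must lie in [0, 1)")
  }
  if (!is.numeric(n_replicates) || n_replicates < 1) {
    fail("n_replicates", "must be >= 1")
  }
  if (!is.numeric(seed) || length(seed) != 1 || !is.finite(seed)) {
    fail("seed", "must be a single integer")
  }
  structure(list(
    n_control = as.integer(n_control), n_case = as.integer(n_case),
    mir_panel = mir_panel, fold_effects = fold, base_ct = bct,
    ct_noise_sd = ct_noise_sd, efficiency_base = eff,
    hemolysis_rate = hemolysis_rate, n_replicates = as.integer(n_replicates),
    matrix = matrix, seed = as.integer(seed)
  ), class = "sim_config")
}

#' Simulate a two-group qPCR cohort
#'
#' Generates reaction-level Ct values under the multiplicative qPCR model
#' `Ct = base_ct - log_E(abundance) + noise`, where case-sample abundance is
#' the control abundance multiplied by the configured fold effect and noise
#' is additive Gaussian on the cycle scale. Ct values beyond 40 cycles are
#' recorded as undetected (`NA`), mirroring the detection threshold of the
#' TaqMan protocol. Sample ages and sexes are drawn to match the baseline
#' statistics of the vitreous-biopsy cohort; for plasma cohorts a lognormal
#' hemolysis index is drawn so that approximately `hemolysis_rate` of
#' samples exceed the exclusion cutoff of 1.
#'
#' @param config A [sim_config()] object.
#' @return A list of class `"mir_cohort"` with elements
#'   \describe{
#'     \item{records}{data.frame of reactions: `reaction_id`, `sample_id`,
#'       `mir_id`, `replicate`, `ct` (`NA` when undetected), `detected`,
#'       `efficiency` (true per-reaction base) and `efficiency_percent`
#'       (percent of perfect doubling, `100 * base / 2`).}
#'     \item{meta}{data.frame of samples: `sample_id`, `group`, `matrix`,
#'       `age`, `sex`, `hemolysis_index` (`NA` for vitreous),
#'       `clinical_flags`.}
#'     \item{truth}{ground truth: `abundance` (sample x miRNA matrix of true
#'       relative abundance), `efficiency` (named vector of true bases),
#'       `group` (named vector), `latent_ct` (untruncated Ct matrix,
#'       replicate-averaged).}
#'   }
#' @export
#' @examples
#' cohort <- simulate_cohort(sim_config(seed = 42))
#' head(cohort$records)
simulate_cohort <- function(config) {
  if (!inherits(config, "sim_config")) config <- do.call(sim_config, config)
  set.seed(config$seed)
  n <- config$n_control + config$n_case
  sample_id <- c(sprintf("CTL%02d", seq_len(config$n_control)),
                 sprintf("AMD%02d", seq_len(config$n_case)))
  group <- rep(c("control", "case"), c(config$n_control, config$n_case))

  # Baseline demographics drawn to the cohort's observed moments.
  age <- round(c(stats::rnorm(config$n_control, 66.6, 11.2),
                 stats::rnorm(config$n_case, 81.9, 9.1)))
  sex <- ifelse(stats::runif(n) < rep(c(0.85, 0.69),
                                      c(config$n_control, config$n_case)),
                "F", "M")
  hemolysis_index <- rep(NA_real_, n)
  if (config$matrix == "plasma") {
    # P(index > 1) = hemolysis_rate for lognormal(meanlog, sdlog = 0.5)
    sdlog <- 0.5
    meanlog <- -sdlog * stats::qnorm(1 - config$hemolysis_rate)
    hemolysis_index <- stats::rlnorm(n, meanlog, sdlog)
  }
  meta <- data.frame(sample_id = sample_id, group = group,
                     matrix = config$matrix, age = age, sex = sex,
                     hemolysis_index = hemolysis_index,
                     clinical_flags = "", stringsAsFactors = FALSE)

  mirs <- config$mir_panel
  abundance <- matrix(1, n, length(mirs),
                      dimnames = list(sample_id, mirs))
  abundance[group == "case", ] <-
    rep(config$fold_effects, each = config$n_case)

  reps <- config$n_replicates
  grid <- expand.grid(replicate = seq_len(reps), mir_id = mirs,
                      sample_id = sample_id, stringsAsFactors = FALSE,
                      KEEP.OUT.ATTRS = FALSE)
  grid <- grid[, c("sample_id", "mir_id", "replicate")]
  e <- config$efficiency_base[grid$mir_id]
  mu <- config$base_ct[grid$mir_id] -
    log(abundance[cbind(grid$sample_id, grid$mir_id)]) / log(e)
  ct <- mu + stats::rnorm(nrow(grid), 0, config$ct_noise_sd)
  detected <- ct <= 40
  records <- data.frame(
    reaction_id = sprintf("%s_%s_r%d", grid$sample_id, grid$mir_id,
                          grid$replicate),
    sample_id = grid$sample_id, mir_id = grid$mir_id,
    replicate = grid$replicate,
    ct = ifelse(detected, ct, NA_real_),
    detected = detected,
    efficiency = unname(e),
    efficiency_percent = unname(100 * e / 2),
    stringsAsFactors = FALSE
  )

  latent_ct <- tapply(ct, list(grid$sample_id, grid$mir_id), mean)
  latent_ct <- latent_ct[sample_id, mirs, drop = FALSE]

  truth <- list(abundance = abundance,
                efficiency = config$efficiency_base,
                group = stats::setNames(group, sample_id),
                latent_ct = latent_ct)
  structure(list(records = records, meta = meta, truth = truth,
                 config = config),
            class = "mir_cohort")
}

#' @export
print.mir_cohort <- function(x, ...) {
  cat("Synthetic qPCR cohort:", x$config$n_control, "controls,",
      x$config$n_case, "cases;", length(x$config$mir_panel), "miRNAs;",
      x$config$n_replicates, "replicate(s);", x$config$matrix, "\n")
  cat("  reactions:", nrow(x$records),
      sprintf("(%d undetected)\n", sum(!x$records$detected)))
  invisible(x)
}

#' Simulate raw amplification curves for a reaction table
#'
#' Generates per-cycle fluorescence under the saturating exponential model
#' `F(c) = Fmax * F0 * E^c / (Fmax + F0 * E^c) + baseline + noise`, with the
#' initial fluorescence `F0` chosen so each detected reaction crosses the
#' fluorescence threshold at its recorded Ct (undetected reactions cross
#' beyond 40 cycles). The early-phase slope of log fluorescence equals
#' `log(E)`, which is what window-of-linearity efficiency estimation
#' recovers.
#'
#' @param records Reaction table as produced by [simulate_cohort()];
#'   requires `reaction_id`, `sample_id`, `mir_id`, `ct`, `efficiency`.
#' @param truth Optional `truth` element of a [simulate_cohort()] result;
#'   when supplied, per-miRNA true bases are taken from it.
#' @param cycles Number of PCR cycles (>= 25).
#' @param seed Integer seed.
#' @param f_max Plateau fluorescence.
#' @param f_threshold Fluorescence threshold the Ct is defined against.
#' @param baseline Constant background fluorescence.
#' @param noise_sd SD of additive Gaussian fluorescence noise.
#' @return Long data.frame: `reaction_id`, `sample_id`, `mir_id`, `cycle`,
#'   `fluorescence`.
#' @export
simulate_curves <- function(records, truth = NULL, cycles = 40L, seed = 1L,
                            f_max = 10, f_threshold = 0.2, baseline = 0.05,
                            noise_sd = 0.002) {
  stopifnot(cycles >= 25)
  set.seed(as.integer(seed))
  e <- if (!is.null(truth)) unname(truth$efficiency[records$mir_id])
       else records$efficiency
  ct_latent <- ifelse(is.na(records$ct), 45, records$ct)
  f0 <- f_threshold * e^(-ct_latent)
  cyc <- seq_len(cycles)
  out <- lapply(seq_len(nrow(records)), function(i) {
    expo <- f0[i] * e[i]^cyc
    f <- f_max * expo / (f_max + expo) + baseline +
      stats::rnorm(cycles, 0, noise_sd)
    data.frame(reaction_id = records$reaction_id[i],
               sample_id = records$sample_id[i],
               mir_id = records$mir_id[i],
               cycle = cyc, fluorescence = f, stringsAsFactors = FALSE)
  })
  do.call(rbind, out)
}

#' Simulate a SNP association panel around binding-site motifs
#'
#' Creates a panel of SNP association results in which `n_true` SNPs are
#' planted inside miRNA binding-site motif intervals with small p-values
#' (uniform on `true_p_range`) and the remaining SNPs lie outside every
#' motif with p-values uniform on (0, 1].
#'
#' @param n_snps Total number of SNPs.
#' @param motifs Motif table with `chrom`, `start`, `end` (1-based
#'   inclusive) and optionally `gene`, `mir_id`.
#' @param n_true Number of motif-resident associated SNPs (`<= n_snps`).
#' @param seed Integer seed.
#' @param true_p_range Range of planted p-values.
#' @return data.frame `rsid`, `chrom`, `pos`, `p_value`, `gene`, `planted`.
#' @export
simulate_snp_panel <- function(n_snps, motifs, n_true, seed = 1L,
                               true_p_range = c(1e-6, 1e-3)) {
  stopifnot(nrow(motifs) > 0, n_true <= n_snps, n_true >= 0)
  set.seed(as.integer(seed))
  chroms <- unique(motifs$chrom)
  span_hi <- max(motifs$end) + 1e6

  in_any_motif <- function(chrom, pos) {
    hit <- motifs$chrom == chrom & motifs$start <= pos & motifs$end >= pos
    any(hit)
  }

  n_bg <- n_snps - n_true
  bg_chrom <- character(n_bg)
  bg_pos <- integer(n_bg)
  for (i in seq_len(n_bg)) {
    repeat {
      ch <- sample(chroms, 1L)
      p <- sample.int(span_hi, 1L)
      if (!in_any_motif(ch, p)) break
    }
    bg_chrom[i] <- ch
    bg_pos[i] <- p
  }
  bg_gene <- rep(NA_character_, n_bg)

  idx <- if (n_true > 0) sample.int(nrow(motifs), n_true, replace = TRUE)
         else integer(0)
  tr_chrom <- motifs$chrom[idx]
  tr_pos <- vapply(idx, function(j) {
    as.integer(round(stats::runif(1, motifs$start[j], motifs$end[j])))
  }, integer(1))
  tr_gene <- if ("gene" %in% names(motifs)) motifs$gene[idx]
             else rep(NA_character_, n_true)
  tr_p <- stats::runif(n_true, true_p_range[1], true_p_range[2])

  out <- data.frame(
    rsid = sprintf("rs%07d", seq_len(n_snps)),
    chrom = c(tr_chrom, bg_chrom),
    pos = c(tr_pos, bg_pos),
    p_value = c(tr_p, stats::runif(n_bg)),
    gene = c(tr_gene, bg_gene),
    planted = rep(c(TRUE, FALSE), c(n_true, n_bg)),
    stringsAsFactors = FALSE
  )
  out[out$p_value == 0, "p_value"] <- .Machine$double.eps
  out
}
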