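# Phased filtering of GWAS association summary statistics against miRNA
# binding-site motif regions, with Bonferroni and Storey q-value adjustment.

normalize_chrom <- function(x) sub("^chr", "", as.character(x))

#' Read miRNA binding-site motifs from BED
#'
#' Reads a BED6 file (0-based half-open coordinates) of binding-site motif
#' intervals and converts to 1-based inclusive positions. The `name` field
#' is split on `|` into `mir_id`, `gene` and `evidence`
#' (`validated`/`microT`/`miRDB`); prediction-score thresholds (microT-CDS
#' > 0.70, miRDB Target Score > 80) are assumed applied upstream, but the
#' BED score column is retained.
#'
#' @param path BED file path.
#' @return data.frame `mir_id`, `gene`, `evidence`, `chrom`, `start`, `end`
#'   (1-based inclusive), `score`, `strand`.
#' @export
read_motif_bed <- function(path) {
  bed <- utils::read.table(path, sep = "\t", header = FALSE,
                           stringsAsFactors = FALSE)
  if (ncol(bed) < 3) {
    stop("BED file needs at least chrom, start, end", call. = FALSE)
  }
  fields <- c("chrom", "start", "end", "name", "score", "strand")
  names(bed)[seq_len(min(6, ncol(bed)))] <- fields[seq_len(min(6, ncol(bed)))]
  if (is.null(bed$name)) bed$name <- sprintf("motif%d", seq_len(nrow(bed)))
  if (is.null(bed$score)) bed$score <- NA_real_
  if (is.null(bed$strand)) bed$strand <- "*"
  parts <- strsplit(bed$name, "|", fixed = TRUE)
  get_part <- function(i) vapply(parts, function(p) {
    if (length(p) >= i) p[i] else NA_character_
  }, character(1))
  out <- data.frame(
    mir_id = get_part(1), gene = get_part(2), evidence = get_part(3),
    chrom = normalize_chrom(bed$chrom),
    start = bed$start + 1L,  # 0-based half-open -> 1-based inclusive
    end = bed$end,
    score = bed$score, strand = bed$strand, stringsAsFactors = FALSE
  )
  if (any(out$end - out$start + 1L > 50L)) {
    warning("motif interval longer than 50 bases: check input", call. = FALSE)
  }
  out
}

#' Overlap SNPs with binding-site motif intervals
#'
#' Emits one row per (SNP, motif) pair where the SNP position lies inside
#' the motif interval, with 1-based inclusive end points. Chromosome names
#' are normalized (`"chr6"` and `"6"` match, with a warning when the inputs
#' mix conventions); strand is ignored.
#'
#' @param snps SNP association table (`rsid`, `chrom`, `pos`, `p_value`, and
#'   optionally `gene`).
#' @param motifs Motif table (`chrom`, `start`, `end`, and optionally
#'   `mir_id`, `gene`).
#' @return data.frame with the SNP columns plus `mir_id`, `motif_gene`,
#'   `motif_start`, `motif_end`.
#' @export
overlap_snps <- function(snps, motifs) {
  sc <- normalize_chrom(snps$chrom)
  mc <- normalize_chrom(motifs$chrom)
  if (length(unique(grepl("^chr", c(snps$chrom, motifs$chrom)))) > 1) {
    warning("mixed chromosome naming conventions normalized ('chr6' vs '6')",
            call. = FALSE)
  }
  hits <- lapply(seq_len(nrow(motifs)), function(j) {
    i <- which(sc == mc[j] & snps$pos >= motifs$start[j] &
                 snps$pos <= motifs$end[j])
    if (!length(i)) return(NULL)
    cbind(snps[i, , drop = FALSE],
          data.frame(
            mir_id = if ("mir_id" %in% names(motifs)) motifs$mir_id[j]
                     else NA_character_,
            motif_gene = if ("gene" %in% names(motifs)) motifs$gene[j]
                         else NA_character_,
            motif_start = motifs$start[j], motif_end = motifs$end[j],
            stringsAsFactors = FALSE))
  })
  out <- do.call(rbind, hits)
  if (is.null(out)) {
    out <- cbind(snps[0, , drop = FALSE],
                 data.frame(mir_id = character(), motif_gene = character(),
                            motif_start = integer(), motif_end = integer(),
                            stringsAsFactors = FALSE))
  }
  rownames(out) <- NULL
  out
}

#' Alpha level for motif-region SNP testing
#'
#' The region-wise significance level `alpha = 0.05 / sqrt(N)`, where `N` is
#' the number of SNPs tested in the motif-encoding region.
#'
#' @param n_tested Number of SNPs tested (>= 1).
#' @return The adjusted alpha.
#' @export
#' @examples
#' phase2_alpha(4) # 0.025
phase2_alpha <- function(n_tested) {
  if (!is.numeric(n_tested) || n_tested < 1) {
    stop("n_tested must be >= 1", call. = FALSE)
  }
  0.05 / sqrt(n_tested)
}

#' Bonferroni adjustment
#'
#' `p_adj = min(1, m * p)` over the supplied family.
#'
#' @param p_values Numeric p-values in (0, 1].
#' @return Adjusted p-values.
#' @export
bonferroni <- function(p_values) {
  stats::p.adjust(p_values, method = "bonferroni")
}

#' Storey q-values
#'
#' Estimates the q-value (minimum FDR at which each test is significant)
#' following Storey: `q_(i) = min_{j >= i} pi0 * m * p_(j) / j`, monotone
#' non-decreasing in p. The null proportion `pi0` is estimated by the
#' smoother method over a lambda grid (a cubic smoothing spline through
#' `pi0(lambda) = #\{p > lambda\} / (m (1 - lambda))`, evaluated at the
#' largest lambda) or fixed by the caller; with `pi0 = 1` the q-values equal
#' Benjamini-Hochberg adjusted p-values. On panels too small for the
#' smoother (fewer than 20 p-values, or none beyond the lambda grid) the
#' conservative `pi0 = 1` is used.
#'
#' @param p_values Numeric p-values in (0, 1].
#' @param pi0 `"smoother"` or a fixed numeric value in (0, 1].
#' @param lambda Grid for the smoother estimate.
#' @return Numeric q-values, same order as `p_values`.
#' @export
storey_qvalues <- function(p_values, pi0 = "smoother",
                           lambda = seq(0.05, 0.95, 0.05)) {
  p <- p_values
  m <- length(p)
  stopifnot(m >= 1)
  if (any(!is.finite(p)) || any(p <= 0) || any(p > 1)) {
    stop("p-values must lie in (0, 1]", call. = FALSE)
  }
  if (identical(pi0, "smoother")) {
    # the smoother is unreliable on small panels or when no p-value reaches
    # the top of the lambda grid; fall back to the conservative pi0 = 1
    if (m < 20 || max(p) < max(lambda)) {
      pi0 <- 1
    } else {
      pi0_l <- vapply(lambda, function(l) mean(p > l) / (1 - l), numeric(1))
      fit <- stats::smooth.spline(lambda, pi0_l, df = 3)
      pi0 <- stats::predict(fit, x = max(lambda))$y
    }
  }
  if (pi0 > 1) {
    warning("pi0 estimate > 1 clamped to 1", call. = FALSE)
    pi0 <- 1
  }
  if (pi0 <= 0) {
    warning("pi0 estimate <= 0 clamped", call. = FALSE)
    pi0 <- .Machine$double.eps
  }
  o <- order(p)
  q_sorted <- pi0 * m * p[o] / seq_len(m)
  q_sorted <- rev(cummin(rev(q_sorted)))
  q_sorted <- pmin(q_sorted, 1)
  q <- numeric(m)
  q[o] <- q_sorted
  q
}

#' Attach LD proxies to a SNP panel
#'
#' For panel SNPs with a co-inherited partner at `r2` strictly greater than
#' the cutoff (default 0.80), the partner is appended as a proxy record
#' inheriting the index SNP's association p-value, with provenance in
#' `proxy_of`. Proxies are attached in a single hop: proxies of proxies are
#' never chained. The LD table is symmetrized at load.
#'
#' @param snps SNP association table (`rsid`, `chrom`, `pos`, `p_value`).
#' @param ld_table data.frame `rsid_a`, `rsid_b`, `r2`, plus `chrom_b`,
#'   `pos_b` giving the partner's position.
#' @param r2_cutoff Strict lower bound on r-squared.
#' @return The input table with proxy rows appended and a `proxy_of` column
#'   (`NA` for original records).
#' @export
ld_proxy_expand <- function(snps, ld_table, r2_cutoff = 0.80) {
  snps$proxy_of <- NA_character_
  if (is.null(ld_table) || !nrow(ld_table)) return(snps)
  stopifnot(all(c("rsid_a", "rsid_b", "r2", "chrom_b", "pos_b") %in%
                  names(ld_table)))
  keep <- ld_table$r2 > r2_cutoff  # strictly greater
  ld <- ld_table[keep & ld_table$rsid_a %in% snps$rsid &
                   !(ld_table$rsid_b %in% snps$rsid), , drop = FALSE]
  if (!nrow(ld)) return(snps)
  ld <- ld[!duplicated(ld$rsid_b), , drop = FALSE]
  idx <- match(ld$rsid_a, snps$rsid)
  proxies <- data.frame(
    rsid = ld$rsid_b,
    chrom = normalize_chrom(ld$chrom_b),
    pos = ld$pos_b,
    p_value = snps$p_value[idx],
    stringsAsFactors = FALSE
  )
  extra <- setdiff(names(snps), c(names(proxies), "proxy_of"))
  for (col in extra) proxies[[col]] <- snps[[col]][idx]
  proxies$proxy_of <- ld$rsid_a
  rbind(snps, proxies[names(snps)])
}

#' Run the three-phase miRSNP filtering procedure
#'
#' Phase 1 annotates and enumerates the motif-encoding regions of interest
#' and the SNPs resident in them. Phase 2 tests motif-resident SNPs at the
#' region-wise level `alpha = 0.05 / sqrt(N)` (N = SNPs tested in that
#' motif-encoding region); a conventional Bonferroni mode is available.
#' Phase 3 widens to all SNPs in each miRNA's target gene set, filters at
#' `p < 0.005`, and reports Bonferroni-adjusted p-values and Storey
#' q-values computed within the gene-set SNP pool.
#'
#' @param snps SNP association table (`rsid`, `chrom`, `pos`, `p_value`,
#'   optional `gene`).
#' @param motifs Motif table (see [read_motif_bed()]).
#' @param gene_sets Named list (or two-column data.frame `mir_id`, `gene`)
#'   mapping each miRNA to its target gene symbols.
#' @param ld_table Optional LD proxy table (see [ld_proxy_expand()]).
#' @param phase3_p Phase 3 raw p-value threshold.
#' @param phase2_mode `"sqrt_n"` (region-wise `0.05/sqrt(N)`) or
#'   `"bonferroni"` (`0.05/N`).
#' @return List of class `"mirsnp_phases"` with elements `phase1`, `phase2`,
#'   `phase3`; each carries `n_tested`, `alpha_used` (where applicable) and
#'   a `hits` data.frame.
#' @export
run_phases <- function(snps, motifs, gene_sets = NULL, ld_table = NULL,
                       phase3_p = 0.005,
                       phase2_mode = c("sqrt_n", "bonferroni")) {
  phase2_mode <- match.arg(phase2_mode)
  if (!is.null(ld_table)) snps <- ld_proxy_expand(snps, ld_table)

  pairs <- overlap_snps(snps, motifs)
  region_key <- paste(pairs$mir_id, pairs$motif_gene, pairs$motif_start,
                      pairs$motif_end, sep = "/")

  # Phase 1: enumeration of regions and resident variants
  motif_key <- paste(motifs$mir_id, motifs$gene, motifs$start, motifs$end,
                     sep = "/")
  counts <- table(factor(region_key, levels = motif_key))
  phase1 <- list(phase = 1L, n_tested = nrow(pairs), alpha_used = NA_real_,
                 hits = cbind(motifs,
                              n_snps = as.integer(counts[motif_key])))

  # Phase 2: motif-resident SNPs at the region-wise alpha
  if (nrow(pairs)) {
    n_region <- as.integer(table(region_key)[region_key])
    alpha <- if (phase2_mode == "sqrt_n") {
      vapply(n_region, phase2_alpha, numeric(1))
    } else {
      0.05 / n_region
    }
    sig <- pairs$p_value < alpha
    hits2 <- pairs[sig, , drop = FALSE]
    hits2$n_region <- n_region[sig]
    hits2$alpha_used <- alpha[sig]
    hits2$p_bonferroni <- bonferroni(pairs$p_value)[sig]
    hits2$q_value <- storey_qvalues(pairs$p_value)[sig]
  } else {
    hits2 <- pairs
  }
  phase2 <- list(phase = 2L, n_tested = nrow(pairs),
                 alpha_used = if (nrow(pairs))
                   phase2_alpha(nrow(pairs)) else NA_real_,
                 hits = hits2)

  # Phase 3: all SNPs in each miRNA's target gene set
  hits3 <- NULL
  n3 <- 0L
  if (!is.null(gene_sets)) {
    if (is.data.frame(gene_sets)) {
      gene_sets <- split(gene_sets$gene, gene_sets$mir_id)
    }
    if (!"gene" %in% names(snps)) {
      stop("Phase 3 requires a gene column in the SNP table", call. = FALSE)
    }
    for (mir in names(gene_sets)) {
      genes <- gene_sets[[mir]]
      if (!length(genes)) {
        message("Phase 3 skipped for ", mir, ": empty gene set")
        next
      }
      pool <- snps[!is.na(snps$gene) & snps$gene %in% genes, , drop = FALSE]
      if (!nrow(pool)) next
      n3 <- n3 + nrow(pool)
      p_bonf <- bonferroni(pool$p_value)
      q <- storey_qvalues(pool$p_value)
      sel <- pool$p_value < phase3_p
      if (!any(sel)) next
      h <- pool[sel, , drop = FALSE]
      h$mir_id <- mir
      h$p_bonferroni <- p_bonf[sel]
      h$q_value <- q[sel]
      hits3 <- rbind(hits3, h)
    }
  }
  if (is.null(hits3)) {
    hits3 <- data.frame(rsid = character(), chrom = character(),
                        pos = integer(), p_value = numeric(),
                        gene = character(), mir_id = character(),
                        p_bonferroni = numeric(), q_value = numeric(),
                        stringsAsFactors = FALSE)
  }
  phase3 <- list(phase = 3L, n_tested = n3, alpha_used = phase3_p,
                 hits = hits3)

  structure(list(phase1 = phase1, phase2 = phase2, phase3 = phase3),
            class = "mirsnp_phases")
}

#' @export
print.mirsnp_phases <- function(x, ...) {
  cat("miRSNP phased filtering\n")
  cat("  Phase 1:", nrow(x$phase1$hits), "motif regions,",
      x$phase1$n_tested, "resident SNP records\n")
  cat("  Phase 2:", x$phase2$n_tested, "motif SNPs tested,",
      nrow(x$phase2$hits), "hit(s) at alpha = 0.05/sqrt(N)\n")
  cat("  Phase 3:", x$phase3$n_tested, "gene-set SNPs tested,",
      nrow(x$phase3$hits), "hit(s) at p <", x$phase3$alpha_used, "\n")
  invisible(x)
}
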