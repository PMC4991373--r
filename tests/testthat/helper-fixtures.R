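# Shared fixtures built in code.

# A small deterministic motif table; the chr6 interval is the canonical
# HLA-G 3'UTR binding-site anchor for miR-152-3p.
fixture_motifs <- function() {
  data.frame(
    mir_id = c("miR-152-3p", "miR-146a-5p", "miR-106b-5p"),
    gene = c("HLA-G", "CFH", "SMAD3"),
    evidence = c("validated", "validated", "microT"),
    chrom = c("6", "1", "15"),
    start = c(29830959L, 196700000L, 67350000L),
    end = c(29830978L, 196700021L, 67350019L),
    score = c(NA, NA, 0.88),
    strand = "*",
    stringsAsFactors = FALSE
  )
}

# Hand-built long fold-change table: two miRNAs, 3 controls + 3 cases.
fixture_fc_table <- function(fc_case_a = 3, fc_case_b = 0.25) {
  df <- expand.grid(sample_id = sprintf("S%d", 1:6),
                    mir_id = c("mirA", "mirB"),
                    stringsAsFactors = FALSE)
  df$group <- rep(rep(c("control", "case"), each = 3), 2)
  df$fc <- ifelse(df$group == "control", 1,
                  ifelse(df$mir_id == "mirA", fc_case_a, fc_case_b))
  df$log2fc <- log2(df$fc)
  df$ddct <- -df$log2fc
  log2_center(df)
}

# Brute-force pairwise AUC oracle (deliberately independent of the
# rank-based implementation).
oracle_auc <- function(cases, controls) {
  wins <- 0
  for (x in cases) for (y in controls) {
    wins <- wins + (x > y) + 0.5 * (x == y)
  }
  wins / (length(cases) * length(controls))
}

# Trapezoidal area under a (fpr, tpr) polyline.
trapezoid_area <- function(points) {
  sum(diff(points$fpr) *
        (utils::head(points$tpr, -1) + utils::tail(points$tpr, -1)) / 2)
}

# Brute-force double-loop interval containment oracle.
oracle_overlap <- function(snps, motifs) {
  hits <- list()
  for (i in seq_len(nrow(snps))) {
    for (j in seq_len(nrow(motifs))) {
      if (sub("^chr", "", snps$chrom[i]) == sub("^chr", "", motifs$chrom[j]) &&
          snps$pos[i] >= motifs$start[j] && snps$pos[i] <= motifs$end[j]) {
        hits[[length(hits) + 1]] <- c(i, j)
      }
    }
  }
  if (!length(hits)) return(matrix(integer(0), ncol = 2))
  do.call(rbind, hits)
}
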