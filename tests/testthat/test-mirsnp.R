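test_that("motif overlap uses 1-based inclusive containment", {
  motifs <- fixture_motifs()
  snps <- data.frame(
    rsid = c("rs_in", "rs_start", "rs_end", "rs_past", "rs_other"),
    chrom = c("6", "6", "6", "6", "2"),
    pos = c(29830970L, 29830959L, 29830978L, 29830979L, 29830970L),
    p_value = rep(0.02, 5), stringsAsFactors = FALSE)
  hits <- overlap_snps(snps, motifs)
  expect_setequal(hits$rsid, c("rs_in", "rs_start", "rs_end"))
  expect_true(all(hits$mir_id == "miR-152-3p"))
})

test_that("mixed chromosome naming is normalized with a warning", {
  motifs <- fixture_motifs()
  snps <- data.frame(rsid = "rs1", chrom = "chr6", pos = 29830970L,
                     p_value = 0.026, stringsAsFactors = FALSE)
  expect_warning(hits <- overlap_snps(snps, motifs), "naming")
  expect_equal(nrow(hits), 1)
})

test_that("overlap agrees with a brute-force double loop", {
  set.seed(15)
  motifs <- data.frame(
    chrom = sample(c("1", "2", "chr3"), 60, replace = TRUE),
    start = sample.int(1e6, 60), stringsAsFactors = FALSE)
  motifs$end <- motifs$start + sample(10:30, 60, replace = TRUE)
  motifs$mir_id <- sprintf("mir%d", seq_len(60))
  snps <- data.frame(
    rsid = sprintf("rs%d", 1:3000),
    chrom = sample(c("1", "2", "3"), 3000, replace = TRUE),
    pos = sample.int(1e6, 3000, replace = TRUE),
    p_value = runif(3000), stringsAsFactors = FALSE)
  # seed some guaranteed hits
  snps$pos[1:60] <- motifs$start + 2L
  snps$chrom[1:60] <- sub("^chr", "", motifs$chrom)
  hits <- suppressWarnings(overlap_snps(snps, motifs))
  oracle <- oracle_overlap(snps, motifs)
  expect_equal(nrow(hits), nrow(oracle))
  expect_setequal(paste(hits$rsid, hits$mir_id),
                  paste(snps$rsid[oracle[, 1]], motifs$mir_id[oracle[, 2]]))
})

test_that("the region-wise alpha follows 0.05 / sqrt(N)", {
  expect_equal(phase2_alpha(1), 0.05)
  expect_equal(phase2_alpha(4), 0.025)
  expect_equal(phase2_alpha(100), 0.005)
  expect_error(phase2_alpha(0), "n_tested")
})

test_that("Bonferroni adjustment caps at 1", {
  expect_equal(bonferroni(0.2), 0.2)
  expect_equal(bonferroni(c(0.01, rep(0.5, 9)))[1], 0.1)
  expect_equal(bonferroni(c(0.5, rep(0.9, 9)))[1], 1)
})

test_that("Storey q-values with pi0 = 1 equal Benjamini-Hochberg", {
  set.seed(16)
  for (i in 1:10) {
    p <- runif(sample(5:400, 1))
    expect_equal(storey_qvalues(p, pi0 = 1),
                 stats::p.adjust(p, method = "BH"), tolerance = 1e-12)
  }
  expect_equal(storey_qvalues(0.04, pi0 = 1), 0.04)
})

test_that("q-values are monotone in p and bounded", {
  set.seed(17)
  p <- runif(300)
  q <- storey_qvalues(p)
  expect_true(all(q >= 0 & q <= 1))
  o <- order(p)
  expect_true(all(diff(q[o]) >= -1e-15))
  # estimated pi0 near 1 on a null panel; few discoveries at q < 0.05
  discoveries <- replicate(5, {
    # a uniform panel can push the smoother pi0 estimate above 1
    sum(suppressWarnings(storey_qvalues(runif(1000))) < 0.05)
  })
  expect_lte(max(discoveries), 1)
  expect_warning(storey_qvalues(c(0.9, 0.95, 0.99), pi0 = 1.4), "clamped")
  expect_error(storey_qvalues(c(0, 0.5)), "0, 1")
})

test_that("LD proxies require strict r2 > 0.80 and never chain", {
  snps <- data.frame(rsid = "rs1", chrom = "6", pos = 100L, p_value = 0.001,
                     stringsAsFactors = FALSE)
  ld <- data.frame(rsid_a = c("rs1", "rs1", "rs2"),
                   rsid_b = c("rs2", "rs3", "rs4"),
                   r2 = c(0.95, 0.80, 0.99),
                   chrom_b = "6", pos_b = c(150L, 160L, 170L),
                   stringsAsFactors = FALSE)
  out <- ld_proxy_expand(snps, ld)
  expect_setequal(out$rsid, c("rs1", "rs2"))      # rs3 at 0.80 exactly: no
  expect_equal(out$proxy_of[out$rsid == "rs2"], "rs1")
  expect_equal(out$p_value[out$rsid == "rs2"], 0.001)
  expect_false("rs4" %in% out$rsid)               # proxy-of-proxy not chained
})

test_that("the phased procedure applies its rules end to end", {
  motifs <- fixture_motifs()
  # panel with nothing in any motif
  far <- data.frame(rsid = c("rs_a", "rs_b"), chrom = c("6", "1"),
                    pos = c(1000L, 2000L), p_value = c(0.01, 0.5),
                    gene = c("HLA-G", "CFH"), stringsAsFactors = FALSE)
  rep0 <- run_phases(far, motifs)
  expect_equal(nrow(rep0$phase2$hits), 0)
  expect_equal(sum(rep0$phase1$hits$n_snps), 0)
  expect_equal(nrow(rep0$phase1$hits), nrow(motifs))

  # planted motif SNP at p = 1e-5 among N = 4 SNPs in the same region
  planted <- data.frame(
    rsid = sprintf("rs%d", 1:4), chrom = "6",
    pos = c(29830960L, 29830965L, 29830970L, 29830975L),
    p_value = c(1e-5, 0.3, 0.6, 0.9),
    gene = "HLA-G", stringsAsFactors = FALSE)
  rep1 <- run_phases(planted, motifs)
  expect_equal(rep1$phase2$hits$rsid, "rs1")   # 1e-5 < 0.05/sqrt(4) = 0.025
  expect_equal(rep1$phase2$hits$alpha_used, 0.025)
  expect_equal(rep1$phase2$n_tested, 4)

  # Phase 3: one gene-set gene with SNPs at p {0.004, 0.5, 0.9}
  gs <- list("miR-146a-5p" = "NFKB1")
  pool <- data.frame(rsid = sprintf("rs%d", 5:7), chrom = "4",
                     pos = c(100L, 200L, 300L),
                     p_value = c(0.004, 0.5, 0.9),
                     gene = "NFKB1", stringsAsFactors = FALSE)
  rep2 <- run_phases(pool, motifs, gene_sets = gs)
  expect_equal(nrow(rep2$phase3$hits), 1)
  expect_equal(rep2$phase3$hits$rsid, "rs5")
  expect_equal(rep2$phase3$hits$p_bonferroni, 0.012)  # 3 * 0.004

  # empty gene set is skipped with a message
  expect_message(run_phases(pool, motifs,
                            gene_sets = list("miR-152-3p" = character(0))),
                 "empty gene set")
  expect_output(print(rep1), "Phase 2")
})

test_that("phases recover planted associations on a simulated panel", {
  motifs <- fixture_motifs()
  panel <- simulate_snp_panel(500, motifs, n_true = 3, seed = 23)
  panel$gene <- ifelse(is.na(panel$gene), "OTHER", panel$gene)
  rep <- run_phases(panel, motifs)
  expect_setequal(rep$phase2$hits$rsid, panel$rsid[panel$planted])
})
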