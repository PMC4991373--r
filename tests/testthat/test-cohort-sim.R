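test_that("invalid configuration errors name the offending field", {
  expect_error(sim_config(n_control = 1), "n_control")
  expect_error(sim_config(fold_effects = c("miR-146a" = -1)), "fold_effects")
  expect_error(sim_config(efficiency_base = 2.3), "efficiency_base")
  expect_error(sim_config(hemolysis_rate = 1.2), "hemolysis_rate")
  expect_error(sim_config(fold_effects = c("miR-999" = 2)), "fold_effects")
})

test_that("identical seeds give bit-identical cohorts", {
  a <- simulate_cohort(sim_config(seed = 11))
  b <- simulate_cohort(sim_config(seed = 11))
  expect_identical(a$records, b$records)
  expect_identical(a$meta, b$meta)
  expect_identical(a$truth$abundance, b$truth$abundance)
})

test_that("null effects with zero noise give equal Ct in both groups", {
  cfg <- sim_config(fold_effects = c("miR-146a" = 1), ct_noise_sd = 0,
                    seed = 2)
  ch <- simulate_cohort(cfg)
  ct <- collapse_replicates(ch$records)
  for (m in colnames(ct)) {
    expect_equal(stats::sd(ct[, m]), 0)
  }
})

test_that("a fold effect shifts case Ct by log_E(effect) cycles", {
  cfg <- sim_config(ct_noise_sd = 0, seed = 5)
  ch <- simulate_cohort(cfg)
  ct <- collapse_replicates(ch$records)
  grp <- ch$truth$group[rownames(ct)]
  shift <- mean(ct[grp == "case", "miR-146a"]) -
    mean(ct[grp == "control", "miR-146a"])
  expect_equal(shift, -log(3.02) / log(1.75), tolerance = 1e-12)
  expect_equal(shift, -1.975, tolerance = 1e-3)
})

test_that("group sizes match the study design", {
  ch <- simulate_cohort(sim_config(n_control = 13, n_case = 13, seed = 1))
  expect_equal(nrow(ch$meta), 26)
  expect_equal(unname(table(ch$meta$group)["control"]), 13L)
  expect_equal(unname(table(ch$meta$group)["case"]), 13L)
})

test_that("Ct beyond 40 cycles is recorded as undetected", {
  cfg <- sim_config(mir_panel = "miR-x",
                    fold_effects = c("miR-x" = 0.1),
                    base_ct = c("miR-x" = 39.5), ct_noise_sd = 0, seed = 3)
  ch <- simulate_cohort(cfg)
  rec <- ch$records
  ctl <- rec[grepl("^CTL", rec$sample_id), ]
  amd <- rec[grepl("^AMD", rec$sample_id), ]
  expect_true(all(ctl$detected))            # control Ct 39.5
  expect_true(all(!amd$detected))           # case Ct 39.5 + log_E(10) > 40
  expect_true(all(is.na(amd$ct)))
})

test_that("hemolysis indices exceed 1 at about the configured rate", {
  cfg <- sim_config(n_control = 250, n_case = 250, matrix = "plasma",
                    hemolysis_rate = 0.15, seed = 8,
                    mir_panel = "miR-16", base_ct = c("miR-16" = 20),
                    fold_effects = NULL)
  ch <- simulate_cohort(cfg)
  frac <- mean(ch$meta$hemolysis_index > 1)
  expect_gt(frac, 0.15 - 3 * sqrt(0.15 * 0.85 / 500))
  expect_lt(frac, 0.15 + 3 * sqrt(0.15 * 0.85 / 500))
  # vitreous cohorts carry no index
  chv <- simulate_cohort(sim_config(seed = 8))
  expect_true(all(is.na(chv$meta$hemolysis_index)))
})

test_that("increasing a fold effect strictly decreases mean case Ct", {
  ct_at <- function(effect) {
    cfg <- sim_config(fold_effects = c("miR-146a" = effect), ct_noise_sd = 0,
                      seed = 4)
    ch <- simulate_cohort(cfg)
    ct <- collapse_replicates(ch$records)
    mean(ct[ch$truth$group[rownames(ct)] == "case", "miR-146a"])
  }
  v <- vapply(c(1, 2, 4, 8), ct_at, numeric(1))
  expect_true(all(diff(v) < 0))
})

test_that("fold_change inverts the generator exactly on noise-free data", {
  cfg <- sim_config(ct_noise_sd = 0, seed = 6)
  ch <- simulate_cohort(cfg)
  fit <- ddct_fit(ch$records, ch$meta, reference = "single_mir",
                  reference_mir = "miR-16")
  case_fc <- fit$fc[fit$fc$group == "case", ]
  recovered <- tapply(case_fc$fc, case_fc$mir_id, mean)
  expect_equal(as.numeric(recovered[names(cfg$fold_effects)]),
               unname(cfg$fold_effects), tolerance = 1e-12)
})

test_that("simulated curves follow the saturating exponential model", {
  ch <- simulate_cohort(sim_config(n_control = 2, n_case = 2,
                                   ct_noise_sd = 0, seed = 1))
  rec <- ch$records[1:2, ]
  # pure exponential limit: constant ratio E between consecutive cycles
  cur <- simulate_curves(rec, ch$truth, seed = 1, baseline = 0,
                         noise_sd = 0, f_max = 1e15)
  one <- cur[cur$reaction_id == rec$reaction_id[1], ]
  ratios <- one$fluorescence[-1] / one$fluorescence[-nrow(one)]
  expect_equal(ratios, rep(1.75, length(ratios)), tolerance = 1e-9)
  # determinism
  cur2 <- simulate_curves(rec, ch$truth, seed = 1, baseline = 0,
                          noise_sd = 0, f_max = 1e15)
  expect_identical(cur, cur2)
  expect_error(simulate_curves(rec, ch$truth, cycles = 10), "cycles")
})

test_that("curves cross the threshold at the recorded Ct", {
  ch <- simulate_cohort(sim_config(n_control = 3, n_case = 3, seed = 9))
  rec <- ch$records[1:6, ]
  cur <- simulate_curves(rec, ch$truth, seed = 2)
  for (i in seq_len(nrow(rec))) {
    called <- call_ct(cur[cur$reaction_id == rec$reaction_id[i], ],
                      threshold = 0.2)
    expect_equal(called, rec$ct[i], tolerance = 0.5)
  }
})

test_that("SNP panels plant exactly n_true motif-resident associations", {
  motifs <- fixture_motifs()
  hla <- motifs[motifs$gene == "HLA-G", ]
  one <- simulate_snp_panel(50, hla, n_true = 1, seed = 3)
  inside <- one$chrom == "6" & one$pos >= 29830959 & one$pos <= 29830978
  expect_equal(sum(inside), 1L)
  expect_true(one$planted[inside])
  expect_true(all(one$p_value[inside] < 1e-3))

  # null panel: uniform p-values, ~5% below 0.05
  null <- simulate_snp_panel(2000, motifs, n_true = 0, seed = 4)
  frac <- mean(null$p_value < 0.05)
  expect_lt(abs(frac - 0.05), 3 * sqrt(0.05 * 0.95 / 2000))

  # determinism
  expect_identical(simulate_snp_panel(100, motifs, 5, seed = 7),
                   simulate_snp_panel(100, motifs, 5, seed = 7))
})
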