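make_ct <- function(values, samples, mirs) {
  matrix(values, nrow = length(samples), ncol = length(mirs),
         dimnames = list(samples, mirs))
}

test_that("weighted reference reproduces hand-computed weights", {
  ct <- make_ct(0, sprintf("s%d", 1:4), c("a", "b"))
  # member b is exactly twice as variable as member a -> weights 2:1
  ct[, "a"] <- 20 + c(-1.5, -0.5, 0.5, 1.5)
  ct[, "b"] <- 25 + 2 * c(-1.5, -0.5, 0.5, 1.5)
  ct0 <- weighted_reference(ct, c("a", "b"), wmp = 1)
  w <- attr(ct0, "weights")
  expect_equal(unname(w), c(2 / 3, 1 / 3), tolerance = 1e-10)
  expect_equal(as.numeric(ct0),
               unname((2 * ct[, "a"] + ct[, "b"]) / 3), tolerance = 1e-10)
})

test_that("equal variability or wmp = 0 reduces to the plain mean", {
  set.seed(2)
  ct <- make_ct(rnorm(20, 25), sprintf("s%d", 1:5),
                c("a", "b", "c", "d"))
  ct[, "b"] <- ct[, "a"] + 3  # identical SD as member a
  ct0 <- weighted_reference(ct, c("a", "b"), wmp = 1)
  expect_equal(as.numeric(ct0), unname(rowMeans(ct[, c("a", "b")])),
               tolerance = 1e-10)
  ct0_p0 <- weighted_reference(ct, c("a", "b", "c"), wmp = 0)
  expect_equal(as.numeric(ct0_p0), unname(rowMeans(ct[, c("a", "b", "c")])),
               tolerance = 1e-12)
})

test_that("degenerate member variability is refused", {
  ct <- make_ct(20, c("s1", "s2", "s3"), c("a", "b"))
  expect_error(weighted_reference(ct, c("a", "b"), wmp = 1), "SD")
})

test_that("samples missing a reference member are excluded with reason", {
  set.seed(3)
  ct <- make_ct(rnorm(12, 24), sprintf("s%d", 1:4), c("a", "b", "c"))
  ct["s2", "b"] <- NA
  ct0 <- weighted_reference(ct, c("a", "b"), wmp = 1)
  expect_true(is.na(ct0["s2"]))
  expect_equal(attr(ct0, "excluded"), "s2")
})

test_that("single reference is the identity on its own column", {
  set.seed(4)
  ct <- make_ct(rnorm(8, 22), c("s1", "s2", "s3", "s4"), c("miR-16", "x"))
  ct0 <- single_reference(ct, "miR-16")
  expect_equal(unname(as.numeric(ct0)), unname(ct[, "miR-16"]))
  # constant reference of 20: delta Ct is Ct - 20
  ct[, "miR-16"] <- 20
  d <- delta_ct(ct, single_reference(ct, "miR-16"))
  expect_equal(unname(d[, "x"]), unname(ct[, "x"] - 20))
})

test_that("fold change follows the closed form base^(-ddCt)", {
  samples <- sprintf("s%d", 1:4)
  groups <- stats::setNames(rep(c("control", "case"), each = 2), samples)
  d <- make_ct(c(1, 1, 1, 1), samples, "m")  # ddCt all 0
  fc0 <- fold_change(d, base = 1.8, groups)
  expect_true(all(fc0$fc == 1))
  d2 <- make_ct(c(0, 0, -1, -1), samples, "m")
  expect_equal(fold_change(d2, 2, groups)$fc, c(1, 1, 2, 2))
  d3 <- make_ct(c(0, 0, -2, -2), samples, "m")
  expect_equal(fold_change(d3, 1.75, groups)$fc[3], 1.75^2)
  expect_equal(1.75^2, 3.0625)
  expect_error(fold_change(d3, 2.5, groups), "base")
  expect_error(fold_change(d3, 2, stats::setNames(rep("case", 4), samples)),
               "control")
})

test_that("centering zeroes the control mean and preserves structure", {
  fc <- data.frame(sample_id = sprintf("s%d", 1:4),
                   mir_id = "m",
                   group = rep(c("control", "case"), c(3, 1)),
                   fc = c(2, 2, 2, 8), stringsAsFactors = FALSE)
  fc$log2fc <- log2(fc$fc)
  out <- log2_center(fc)
  expect_equal(out$centered_log2fc, c(0, 0, 0, 2))
  # idempotence on centered data
  out2 <- out
  out2$log2fc <- out$centered_log2fc
  expect_equal(log2_center(out2)$centered_log2fc, out$centered_log2fc)
  # defining property on arbitrary data
  set.seed(5)
  fc$log2fc <- rnorm(4)
  ctr <- log2_center(fc)
  expect_equal(mean(ctr$centered_log2fc[ctr$group == "control"]), 0,
               tolerance = 1e-14)
})

test_that("a per-sample Ct shift cancels in weighted-mean mode", {
  set.seed(6)
  ch <- simulate_cohort(sim_config(seed = 16))
  ct <- collapse_replicates(ch$records)
  ct0 <- weighted_reference(ct, c("miR-16", "miR-106b", "miR-146a", "miR-152"))
  d1 <- delta_ct(ct, ct0)
  shifted <- ct
  shifted["CTL01", ] <- shifted["CTL01", ] + 3.7
  # weights are recomputed, so compare with the same weights applied
  w <- attr(ct0, "weights")
  ct0s <- as.vector(shifted[, names(w)] %*% w)
  d2 <- sweep(shifted, 1, ct0s, `-`)
  expect_equal(d2, d1, tolerance = 1e-10)
})

test_that("fold change and centered log2 values are mutually consistent", {
  ch <- simulate_cohort(sim_config(seed = 17))
  fit <- ddct_fit(ch$records, ch$meta)
  fc <- fit$fc
  for (m in unique(fc$mir_id)) {
    sub <- fc[fc$mir_id == m, ]
    geo <- 2^mean(sub$log2fc[sub$group == "control"])
    expect_equal(2^sub$centered_log2fc, sub$fc / geo, tolerance = 1e-10)
  }
})

test_that("ddct_fit matches the manual quantification chain", {
  ch <- simulate_cohort(sim_config(seed = 18))
  fit <- ddct_fit(ch$records, ch$meta, reference = "single_mir",
                  reference_mir = "miR-16", efficiency = 1.75)
  ct <- collapse_replicates(ch$records)
  d <- delta_ct(ct, single_reference(ct, "miR-16"))
  grp <- stats::setNames(ch$meta$group, ch$meta$sample_id)
  manual <- log2_center(fold_change(d, 1.75, grp))
  expect_equal(fit$fc$fc, manual$fc, tolerance = 1e-12)
  expect_equal(fit$fc$centered_log2fc, manual$centered_log2fc,
               tolerance = 1e-12)
  # S3 surface
  expect_s3_class(fit, "ddct_fit")
  expect_named(coef(fit), sort(unique(fit$fc$mir_id)), ignore.order = TRUE)
  expect_output(print(fit), "reference")
  s <- summary(fit)
  expect_s3_class(s, "summary.ddct_fit")
  expect_true(all(s$table$p_value > 0 & s$table$p_value <= 1, na.rm = TRUE))
  expect_equal(sum(abs(residuals(fit)) >= 0), nrow(fit$fc))
})
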