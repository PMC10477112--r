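test_that("ROUT leaves homogeneous and constant samples untouched", {
  r <- rout_outliers(c(10, 11, 9, 10, 10), Q = 0.001)
  expect_length(r$outlier_indices, 0)
  expect_identical(r$kept, c(10, 11, 9, 10, 10))
  rc <- rout_outliers(rep(5, 8), Q = 0.001)
  expect_length(rc$outlier_indices, 0)
  expect_identical(rc$rsdr, 0)
})

test_that("ROUT flags a gross contaminant and only it", {
  x <- c(10, 11, 9, 10, 10, 1000)
  r <- rout_outliers(x, Q = 0.001)
  expect_identical(r$outlier_indices, 6L)
  expect_identical(r$kept, x[-6])
  expect_lt(abs(r$robust_center - 10), 0.5)
})

test_that("ROUT never removes more than half the sample", {
  x <- c(rep(0, 5), rep(1000, 5))
  r <- rout_outliers(x, Q = 0.5)
  expect_lte(length(r$outlier_indices), 5L)
  expect_error(rout_outliers(c(1, 2), Q = 0.001), "at least 3")
})

test_that("Student's t matches its closed form and published example", {
  cmp <- t_test_two_tailed(c(1, 2, 3), c(4, 5, 6))
  expect_equal(cmp$t_statistic, -3.6742, tolerance = 1e-4)
  expect_identical(cmp$df, 4)
  expect_equal(cmp$p_value, 0.02131, tolerance = 1e-3)
  # closed-form oracle on random vectors
  set.seed(8)
  for (i in 1:5) {
    a <- rnorm(7, 1); b <- rnorm(9, 2)
    sp2 <- ((6 * var(a)) + (8 * var(b))) / 14
    t_oracle <- (mean(a) - mean(b)) / sqrt(sp2 * (1 / 7 + 1 / 9))
    p_oracle <- 2 * pt(-abs(t_oracle), 14)
    cmp <- t_test_two_tailed(a, b)
    expect_equal(cmp$t_statistic, t_oracle, tolerance = 1e-10)
    expect_equal(cmp$p_value, p_oracle, tolerance = 1e-10)
    swap <- t_test_two_tailed(b, a)
    expect_equal(swap$p_value, cmp$p_value, tolerance = 1e-12)
    expect_equal(swap$t_statistic, -cmp$t_statistic, tolerance = 1e-12)
  }
})

test_that("t test conventions: identical samples, scaling, zero variance", {
  idn <- t_test_two_tailed(c(1, 2, 3), c(1, 2, 3))
  expect_identical(idn$t_statistic, 0)
  expect_identical(idn$p_value, 1)
  a <- c(1.2, 3.4, 2.2, 4.1); b <- c(2.5, 3.9, 5.0, 4.4)
  base <- t_test_two_tailed(a, b)
  scaled <- t_test_two_tailed(10 * a, 10 * b)
  expect_equal(scaled$t_statistic, base$t_statistic, tolerance = 1e-12)
  expect_equal(scaled$p_value, base$p_value, tolerance = 1e-12)
  flat_same <- t_test_two_tailed(rep(2, 3), rep(2, 4))
  expect_identical(flat_same$p_value, 1)
  flat_diff <- t_test_two_tailed(rep(2, 3), rep(5, 4))
  expect_identical(flat_diff$p_value, 0)
  expect_true(flat_diff$degenerate)
})

test_that("group comparison applies ROUT per group before testing", {
  set.seed(3)
  a <- c(rnorm(12, 10, 0.5), 500)
  b <- rnorm(12, 12, 0.5)
  cmp <- compare_groups(a, b, rout_q = 0.001)
  expect_identical(cmp$n_a, 12L)
  expect_identical(cmp$rout_a$outlier_indices, 13L)
  expect_lt(cmp$mean_a, 11)
  plain <- compare_groups(a, b, rout_q = NULL)
  expect_identical(plain$n_a, 13L)
})

test_that("fold changes are calibrator-normalized", {
  fc <- fold_change_vs_calibrator(c(4, 4, 4), c(8, 2))
  expect_identical(fc$fold_values, c(2, 0.5))
  expect_identical(mean(fc$calibrator_fold_values), 1)
  expect_error(fold_change_vs_calibrator(c(-1, 1), c(2)), "zero")
})

test_that("delta-delta-CT reproduces direct formula evaluation", {
  tbl <- data.frame(
    sample = rep(c("npc1", "neu1"), each = 3),
    group = rep(c("NPC", "neuron"), each = 3),
    gene = rep(c("APP", "RPL27", "HPRT1"), 2),
    ct = c(24, 20, 22, 23, 21, 23))
  rq <- delta_delta_ct(tbl, target = "APP", calibrator = "NPC")
  # dCT: npc1 = 24 - 21 = 3; neu1 = 23 - 22 = 1; ddCT neuron = -2 -> RQ 4
  expect_identical(rq$rq[rq$sample == "npc1"], 1)
  expect_identical(rq$rq[rq$sample == "neu1"], 4)
  # identical CTs -> RQ 1
  same <- tbl; same$ct <- rep(c(25, 21, 23), 2)
  rq2 <- delta_delta_ct(same, target = "APP", calibrator = "NPC")
  expect_true(all(rq2$rq == 1))
})

test_that("ddCT is invariant to a global CT shift and averages duplicates", {
  set.seed(14)
  base <- expand.grid(sample = paste0("s", 1:4), gene = c("T", "R1", "R2"),
                      rep = 1:2, stringsAsFactors = FALSE)
  base$group <- ifelse(base$sample %in% c("s1", "s2"), "cal", "trt")
  base$ct <- runif(nrow(base), 18, 30)
  rq1 <- delta_delta_ct(base, target = "T", references = c("R1", "R2"),
                        calibrator = "cal")
  shifted <- base; shifted$ct <- shifted$ct + 3.7
  rq2 <- delta_delta_ct(shifted, target = "T", references = c("R1", "R2"),
                        calibrator = "cal")
  expect_equal(rq1$rq, rq2$rq, tolerance = 1e-12)
  # independent spreadsheet-style recomputation
  for (s in unique(base$sample)) {
    d <- base[base$sample == s, ]
    dct <- mean(d$ct[d$gene == "T"]) -
      mean(c(mean(d$ct[d$gene == "R1"]), mean(d$ct[d$gene == "R2"])))
    cal_rows <- base[base$group == "cal", ]
    dct_cal <- mean(vapply(unique(cal_rows$sample), function(cs) {
      dd <- cal_rows[cal_rows$sample == cs, ]
      mean(dd$ct[dd$gene == "T"]) -
        mean(c(mean(dd$ct[dd$gene == "R1"]), mean(dd$ct[dd$gene == "R2"])))
    }, numeric(1)))
    expect_equal(rq1$rq[rq1$sample == s], 2^(-(dct - dct_cal)),
                 tolerance = 1e-12)
  }
  missing_ref <- base[!(base$gene == "R2" & base$sample == "s1"), ]
  expect_error(delta_delta_ct(missing_ref, target = "T",
                              references = c("R1", "R2"), calibrator = "cal"),
               "lacks reference")
})

test_that("below-LOD censoring follows the strictly-below half-LOD rule", {
  out <- censor_below_lod(c(4, 12, 9), lod = 10)
  expect_identical(out$values, c(5, 12, 5))
  expect_identical(out$n_censored, 2L)
  expect_identical(censor_below_lod(c(11, 12), 10)$n_censored, 0L)
  expect_identical(censor_below_lod(c(10, 9.999), 10)$values, c(10, 5))
  expect_error(censor_below_lod(c(1, 2), -1), "positive")
})
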