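test_that("pooled t matches the hand-worked example and stats::t.test", {
  tg <- two_group_matrix(matrix(c(1, 2, 3), 1), matrix(c(4, 5, 6), 1))
  res <- t_test_de(tg$em, group_a = tg$group_a, group_b = tg$group_b)
  # pooled formula: means 2 and 5, sp^2 = 1, se = sqrt(2/3)
  expect_equal(res$t_statistic, -3 / sqrt(2 / 3), tolerance = 1e-6)
  expect_equal(res$df, 4)
  expect_equal(res$p_value, 2 * pt(-3 / sqrt(2 / 3), 4), tolerance = 1e-9)
  expect_equal(res$delta_log2, -3)
  ht <- t.test(c(1, 2, 3), c(4, 5, 6), var.equal = TRUE)
  expect_equal(res$p_value, ht$p.value, tolerance = 1e-9)
  expect_equal(res$t_statistic, unname(ht$statistic), tolerance = 1e-9)
})

test_that("vectorized t agrees with per-gene stats::t.test on random data", {
  set.seed(31)
  tg <- two_group_matrix(matrix(rnorm(200, 8), 40), matrix(rnorm(240, 8), 40))
  res <- t_test_de(tg$em, group_a = tg$group_a, group_b = tg$group_b)
  for (i in c(1, 7, 13, 40)) {
    ht <- t.test(tg$em$values[i, tg$group_a], tg$em$values[i, tg$group_b],
                 var.equal = TRUE)
    expect_equal(res$p_value[i], ht$p.value, tolerance = 1e-9)
  }
})

test_that("swapping the groups negates t and inverts the fold change", {
  set.seed(32)
  tg <- two_group_matrix(matrix(rnorm(50, 8), 10), matrix(rnorm(60, 8.5), 10))
  ab <- t_test_de(tg$em, group_a = tg$group_a, group_b = tg$group_b)
  ba <- t_test_de(tg$em, group_a = tg$group_b, group_b = tg$group_a)
  expect_equal(ab$t_statistic, -ba$t_statistic)
  expect_equal(ab$delta_log2, -ba$delta_log2)
  expect_equal(ab$fold_change_linear, 1 / ba$fold_change_linear)
  expect_equal(ab$p_value, ba$p_value)
})

test_that("fold change is 2^delta and identical groups give t = 0, p = 1", {
  tg <- two_group_matrix(matrix(c(5, 5, 5) + log2(1.25), 1),
                         matrix(c(5, 5, 5), 1))
  res <- t_test_de(tg$em, group_a = tg$group_a, group_b = tg$group_b)
  expect_equal(res$fold_change_linear, 1.25, tolerance = 1e-12)
  same <- two_group_matrix(matrix(c(4, 4, 4), 1), matrix(c(4, 4, 4), 1))
  r2 <- t_test_de(same$em, group_a = same$group_a, group_b = same$group_b)
  expect_equal(r2$t_statistic, 0)
  expect_equal(r2$p_value, 1)
  expect_true(r2$degenerate)
  # sign consistency invariant
  set.seed(33)
  tg3 <- two_group_matrix(matrix(rnorm(30, 8), 10), matrix(rnorm(30, 8), 10))
  r3 <- t_test_de(tg3$em, group_a = tg3$group_a, group_b = tg3$group_b)
  expect_true(all(sign(r3$delta_log2) == sign(r3$t_statistic)))
  expect_true(all(r3$p_value > 0 & r3$p_value <= 1))
  expect_true(all(r3$fold_change_linear > 0))
})

test_that("permutation FDR is deterministic under a fixed seed", {
  set.seed(34)
  tg <- two_group_matrix(matrix(rnorm(400, 8), 50), matrix(rnorm(400, 8), 50))
  f1 <- permutation_fdr(tg$em, tg$group_a, tg$group_b, p_threshold = 0.3,
                        fc_threshold = 1.05, n_perm = 50, seed = 99)
  f2 <- permutation_fdr(tg$em, tg$group_a, tg$group_b, p_threshold = 0.3,
                        fc_threshold = 1.05, n_perm = 50, seed = 99)
  expect_identical(f1$fdr, f2$fdr)
  expect_identical(f1$null_counts, f2$null_counts)
})

test_that("sampled permutation null matches exhaustive enumeration (3 vs 3)", {
  set.seed(35)
  vals <- matrix(rnorm(120, 8), 20, 6,
                 dimnames = list(sprintf("g%d", 1:20), sprintf("s%d", 1:6)))
  em <- expression_matrix(vals, "log2")
  ga <- paste0("s", 1:3)
  gb <- paste0("s", 4:6)
  p_thr <- 0.2
  fc_thr <- 1.1
  # oracle: every one of the choose(6,3) = 20 relabelings
  splits <- combn(6, 3)
  null_counts <- apply(splits, 2, function(idx) {
    a <- vals[, idx, drop = FALSE]
    b <- vals[, -idx, drop = FALSE]
    p <- sapply(seq_len(nrow(vals)), function(i)
      t.test(a[i, ], b[i, ], var.equal = TRUE)$p.value)
    fc <- 2^(rowMeans(a) - rowMeans(b))
    sum(p < p_thr & (fc > fc_thr | fc < 1 / fc_thr))
  })
  exhaustive_median <- median(null_counts)
  f <- permutation_fdr(em, ga, gb, p_threshold = p_thr, fc_threshold = fc_thr,
                       n_perm = 400, seed = 7)
  # sampled null median within Monte-Carlo error of the exhaustive one
  expect_lte(abs(median(f$null_counts) - exhaustive_median), 1)
  expect_equal(f$observed_count,
               null_counts[1])  # first split is the observed labeling
})

test_that("FDR is undefined (not an error) when nothing passes", {
  set.seed(36)
  tg <- two_group_matrix(matrix(rnorm(40, 8), 10), matrix(rnorm(40, 8), 10))
  f <- permutation_fdr(tg$em, tg$group_a, tg$group_b, p_threshold = 1e-12,
                       fc_threshold = 50, n_perm = 20, seed = 1)
  expect_equal(f$observed_count, 0)
  expect_true(is.na(f$fdr))
})

test_that("planted effects are recovered with high power and low FDR", {
  # delta = 1.0, sd = 0.5, n = 10 + 10: the regime where the test should
  # recover nearly all planted genes at p < 0.01
  set.seed(37)
  n_genes <- 400
  planted <- 1:60
  a <- matrix(rnorm(n_genes * 10, 8, 0.5), n_genes)
  b <- matrix(rnorm(n_genes * 10, 8, 0.5), n_genes)
  a[planted, ] <- a[planted, ] + 1.0
  tg <- two_group_matrix(a, b)
  res <- t_test_de(tg$em, group_a = tg$group_a, group_b = tg$group_b)
  hits <- which(res$p_value < 0.01)
  expect_gte(mean(planted %in% hits), 0.9)
  f <- permutation_fdr(tg$em, tg$group_a, tg$group_b, p_threshold = 0.01,
                       fc_threshold = 1.25, n_perm = 200, seed = 8)
  expect_lte(f$fdr, 0.15)
})

test_that("comparison_spec enforces its invariants", {
  expect_error(comparison_spec("x", c("a"), c("a", "b")), "disjoint")
  expect_error(comparison_spec("x", character(0), "b"), "non-empty")
  expect_error(comparison_spec("x", "a", "b", fc_threshold = 1), "fc_threshold")
  sp <- comparison_spec("1M+R vs 1NR", c("a1", "a2"), c("b1", "b2"))
  expect_s3_class(sp, "ComparisonSpec")
  expect_equal(sp$p_threshold, 0.01)
})
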