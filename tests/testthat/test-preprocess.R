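test_that("qspline maps an array identical to the reference to itself", {
  set.seed(7)
  v <- sort(2^rnorm(500, 8, 1))
  m <- cbind(s1 = v, s2 = v)
  rownames(m) <- sprintf("g%d", seq_along(v))
  em <- expression_matrix(m, scale = "linear")
  out <- qspline_normalize(em)
  expect_equal(out$values, em$values, tolerance = 1e-9)
})

test_that("qspline equalizes a pure scaling distortion at the quantiles", {
  set.seed(11)
  a <- 2^rnorm(2000, 8, 1)
  m <- cbind(s1 = a, s2 = 2 * a)
  rownames(m) <- sprintf("g%d", seq_len(nrow(m)))
  out <- qspline_normalize(expression_matrix(m, scale = "linear"))
  qa <- quantile(out$values[, 1], seq(0.05, 0.95, 0.05))
  qb <- quantile(out$values[, 2], seq(0.05, 0.95, 0.05))
  expect_true(all(abs(qb / qa - 1) < 0.01))
  # pure scaling lies on a line through the anchors: mapping is exact
  expect_equal(sort(out$values[, 1]), sort(out$values[, 2]),
               tolerance = 1e-6)
})

test_that("qspline mappings are monotone and idempotent-within-tolerance", {
  set.seed(13)
  m <- matrix(2^rnorm(900, 8, 1.2), 300, 3,
              dimnames = list(sprintf("g%d", 1:300), c("s1", "s2", "s3")))
  m[, 2] <- m[, 2] * 1.6
  em <- expression_matrix(m, scale = "linear")
  out <- qspline_normalize(em)
  for (j in 1:3) {
    ord <- order(m[, j])
    expect_true(all(diff(out$values[ord, j]) >= -1e-9))
  }
  twice <- qspline_normalize(out)
  expect_equal(twice$values, out$values, tolerance = 0.02)
})

test_that("qspline rejects non-positive input and warns on a single array", {
  m <- matrix(c(1, -2, 3, 4), 2, 2,
              dimnames = list(c("g1", "g2"), c("s1", "s2")))
  expect_error(qspline_normalize(expression_matrix(m, scale = "linear")),
               "positive")
  one <- matrix(c(1, 2), 2, 1, dimnames = list(c("g1", "g2"), "s1"))
  expect_warning(out <- qspline_normalize(expression_matrix(one, "linear")),
                 "single array")
  expect_equal(out$values, one)
})

test_that("probe summarization takes per-gene medians with both parities", {
  m <- matrix(c(1, 3, 5, 1, 3, 7,
                2, 4, 6, 2, 4, 8), 6, 2,
              dimnames = list(c("pA1", "pA2", "pA3", "pB1", "pB2", "pX"),
                              c("s1", "s2")))
  map <- c(pA1 = "GA", pA2 = "GA", pA3 = "GA", pB1 = "GB", pB2 = "GB")
  out <- summarize_probes(expression_matrix(m, "log2"), map)
  expect_equal(out$values["GA", ], c(s1 = 3, s2 = 4))   # odd count: middle
  expect_equal(out$values["GB", ], c(s1 = 2, s2 = 3))   # even: mean of pair
  expect_equal(attr(out, "dropped_probes"), 1L)         # pX unmapped
  single <- summarize_probes(expression_matrix(m[6, , drop = FALSE], "log2"),
                             c(pX = "GX"))
  expect_equal(unname(single$values["GX", ]), unname(m[6, ]))
})

test_that("batch correction removes a planted offset and keeps grand means", {
  set.seed(5)
  base <- matrix(rnorm(60, 8, 1), 10, 6,
                 dimnames = list(sprintf("g%d", 1:10),
                                 sprintf("s%d", 1:6)))
  batch <- c("A", "A", "A", "B", "B", "B")
  m <- base
  m[, batch == "B"] <- m[, batch == "B"] + 1.0
  out <- batch_correct(expression_matrix(m, "log2"), batch)
  diff_means <- rowMeans(out$values[, batch == "B"]) -
    rowMeans(out$values[, batch == "A"])
  expect_true(all(abs(diff_means) < 1e-9))
  expect_equal(rowMeans(out$values), rowMeans(m), tolerance = 1e-9)
  # balanced design: the LS batch coefficient is the observed mean difference
  closed_form <- rowMeans(m[, batch == "B"]) - rowMeans(m[, batch == "A"])
  expect_equal(unname(attr(out, "batch_coefficients")[, "B"]),
               unname(closed_form), tolerance = 1e-9)
})

test_that("batch correction agrees with the limma reference up to a
           per-gene constant", {
  skip_if_not_installed("limma")
  set.seed(6)
  m <- matrix(rnorm(200, 8, 1), 20, 10,
              dimnames = list(sprintf("g%d", 1:20), sprintf("s%d", 1:10)))
  batch <- rep(c("A", "B"), each = 5)
  m[, batch == "B"] <- m[, batch == "B"] + rnorm(20, 0.8, 0.2)
  ours <- batch_correct(expression_matrix(m, "log2"), batch)$values
  ref <- limma::removeBatchEffect(m, batch = batch)
  # identical up to a per-gene shift (different reference coding)
  delta <- ours - ref
  expect_true(all(abs(delta - rowMeans(delta)) < 1e-9))
})

test_that("degenerate batch layouts behave as documented", {
  m <- matrix(rnorm(20, 8), 5, 4,
              dimnames = list(sprintf("g%d", 1:5), sprintf("s%d", 1:4)))
  em <- expression_matrix(m, "log2")
  expect_equal(batch_correct(em, rep("A", 4))$values, m)   # single batch
  expect_warning(batch_correct(em, c("A", "A", "A", "B")), "single sample")
})

test_that("median centering yields exactly zero per-array medians", {
  em <- expression_matrix(matrix(8, 3, 2, dimnames = list(
    c("g1", "g2", "g3"), c("s1", "s2"))), "log2")
  expect_true(all(median_center_log2(em)$values == 0))
  m <- matrix(c(1, 2, 3), 3, 1, dimnames = list(c("g1", "g2", "g3"), "s1"))
  expect_equal(unname(median_center_log2(
    expression_matrix(m, "log2"))$values[, 1]), c(-1, 0, 1))
  r <- toy_matrix(101, 4, seed = 9)
  centered <- median_center_log2(r)
  expect_equal(unname(apply(centered$values, 2, median)), rep(0, 4))
})

test_that("log2 transform names the offending cell on non-positive input", {
  m <- matrix(c(1, 0, 4, 2), 2, 2,
              dimnames = list(c("g1", "g2"), c("s1", "s2")))
  expect_error(transform_log2(expression_matrix(m, "linear")),
               "'g2', sample 's1'")
})

test_that("the full chain collapses batch-explained variance", {
  co <- generate_cohort(simulation_config(seed = 21, n_genes = 800,
                                          n_up = 40, n_down = 20))
  batch <- co$annotation$batch
  r2 <- function(vals) {
    f <- factor(batch)
    mean(apply(vals, 1, function(y) summary(lm(y ~ f))$r.squared))
  }
  raw_log2 <- log2(em_values(co$expression))
  norm <- normalize_pipeline(co$expression, batch = batch)
  # per-gene R^2 against batch labels drops by at least 90%
  expect_lt(r2(norm$matrix$values), 0.1 * r2(raw_log2))
  expect_equal(unname(apply(norm$matrix$values, 2, median)),
               rep(0, ncol(norm$matrix$values)), tolerance = 1e-12)
  expect_equal(nrow(norm$report$pre_quantiles),
               ncol(co$expression$values))
})
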