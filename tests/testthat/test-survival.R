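test_that("cohort filter applies the inclusion rules with logged reasons", {
  empty <- filter_survival_cohort(validate_annotation(ann_row())[0, ])
  expect_equal(nrow(empty), 0)
  ann <- validate_annotation(rbind(
    ann_row("x1", "III", "NA", simpson = 4),                    # Simpson 4
    ann_row("x2", "I", "NR", followup_months = 30,
            pfs_months = 30),                                   # short FU
    ann_row("x3", "I", "NR", followup_months = 40),             # retained
    ann_row("x4", "I", "R", followup_months = 14, pfs_months = 12,
            progression_event = TRUE)))                         # event
  out <- filter_survival_cohort(ann)
  expect_setequal(out$sample_id, c("x3", "x4"))
  excl <- attr(out, "exclusions")
  expect_match(excl$reason[excl$sample_id == "x1"], "Simpson")
  expect_match(excl$reason[excl$sample_id == "x2"], "follow-up < 36")
})

test_that("pretreated and recurrent-surgery records are excluded", {
  ann <- validate_annotation(rbind(
    ann_row("t1", treatment_naive = FALSE, is_primary = TRUE),
    ann_row("t2", treatment_naive = TRUE, is_primary = FALSE),
    ann_row("t3", treatment_naive = TRUE, is_primary = TRUE)))
  out <- filter_survival_cohort(ann)
  expect_identical(out$sample_id, "t3")
  excl <- attr(out, "exclusions")
  expect_match(excl$reason[excl$sample_id == "t1"], "radio-/chemo")
  expect_match(excl$reason[excl$sample_id == "t2"], "recurrent")
})

test_that("dichotomization cuts at the median or upper quartile", {
  med <- dichotomize(c(1, 2, 3, 4), "median")
  expect_equal(as.character(med), c("low", "low", "high", "high"))
  expect_equal(attr(med, "cut"), 2.5)
  uq <- dichotomize(c(1, 2, 3, 4), "upper_quartile")
  expect_equal(as.character(uq), c("low", "low", "low", "high"))
  expect_equal(attr(uq, "cut"), 3.25)   # linear-interpolation Q3
  # a value exactly at the cut goes to low (strict >)
  at_cut <- dichotomize(c(1, 2, 2, 3), "median")
  expect_equal(as.character(at_cut), c("low", "low", "low", "high"))
  expect_error(dichotomize(c(2, 2, 2)), "identical")
})

test_that("KM estimate matches the hand product-limit computation", {
  # all events at 1, 2, 3: survival steps 2/3, 1/3, 0
  km <- km_estimate(c(1, 2, 3), c(TRUE, TRUE, TRUE))
  expect_equal(km$survival, c(2 / 3, 1 / 3, 0), tolerance = 1e-12)
  # events at 1 and 3, censored at 2:
  # S(1) = 1 * (1 - 1/3) = 2/3; at t=3 one at risk -> S = 2/3 * 0 = 0
  km2 <- km_estimate(c(1, 2, 3), c(TRUE, FALSE, TRUE))
  expect_equal(km2$survival[km2$n_event > 0], c(2 / 3, 0), tolerance = 1e-12)
  # no events: flat at 1
  km3 <- km_estimate(c(5, 7), c(FALSE, FALSE))
  expect_true(all(km3$survival == 1))
  # without censoring KM equals the empirical survival function
  set.seed(81)
  tt <- rexp(40)
  km4 <- km_estimate(tt, rep(TRUE, 40))
  ecdf_surv <- sapply(km4$time, function(t) mean(tt > t))
  expect_equal(km4$survival, ecdf_surv, tolerance = 1e-12)
})

test_that("log-rank statistic matches the hand O-E/V computation", {
  time <- c(3, 5, 7, 9, 11, 14, 2, 4, 6, 8, 10, 12)
  event <- c(TRUE, TRUE, FALSE, TRUE, FALSE, TRUE,
             TRUE, TRUE, TRUE, FALSE, TRUE, TRUE)
  group <- rep(c("A", "B"), each = 6)
  # independent oracle: loop over distinct event times accumulating
  # observed minus expected events in group A and the hypergeometric variance
  oe <- 0; v <- 0
  for (t in sort(unique(time[event]))) {
    at_risk <- time >= t
    d <- sum(event & time == t)
    n <- sum(at_risk)
    n1 <- sum(at_risk & group == "A")
    d1 <- sum(event & time == t & group == "A")
    oe <- oe + d1 - d * n1 / n
    if (n > 1) v <- v + d * (n1 / n) * (1 - n1 / n) * (n - d) / (n - 1)
  }
  oracle_chisq <- oe^2 / v
  lr <- logrank_test(time, event, group)
  expect_equal(lr$chisq, oracle_chisq, tolerance = 1e-6)
  expect_equal(lr$p_value, pchisq(oracle_chisq, 1, lower.tail = FALSE),
               tolerance = 1e-9)
})

test_that("identical groups give a null log-rank result", {
  time <- c(2, 4, 6, 8)
  event <- c(TRUE, TRUE, FALSE, TRUE)
  lr <- logrank_test(c(time, time), c(event, event), rep(c("A", "B"), each = 4))
  expect_equal(lr$chisq, 0, tolerance = 1e-12)
  expect_equal(lr$p_value, 1)
  expect_error(logrank_test(time, event, rep("A", 4)), "two non-empty")
})

test_that("a planted hazard ratio of 3 is detected in nearly every run", {
  detected <- sapply(1:20, function(s) {
    d <- generate_ph_cohort(400, hr = 3, censor_frac = 0.2, seed = 100 + s)
    logrank_test(d$time, d$event, d$x)$p_value < 0.01
  })
  expect_gte(mean(detected), 0.95)
})

test_that("Cox fit recovers structure and flags degenerate covariates", {
  d <- generate_ph_cohort(500, hr = 2, censor_frac = 0.2, seed = 7)
  fit <- cox_fit(d, "x")
  expect_s3_class(fit, "CoxFit")
  expect_true(fit$ci_lower < fit$hr & fit$hr < fit$ci_upper)
  expect_gt(fit$hr, 1.5)
  d$const <- 1
  expect_error(cox_fit(d, "const"), "constant covariate")
  w <- capture_warnings(cox_fit(d[1:8, ], c("x", "time"),
                                model = "multivariate"))
  expect_true(any(grepl("events", w)))  # coxph may add its own warnings
})

test_that("categorical covariates expand against the reference level", {
  set.seed(83)
  n <- 120
  d <- data.frame(time = rexp(n), event = TRUE,
                  who = factor(sample(c("I", "II", "III"), n, TRUE),
                               levels = c("I", "II", "III")))
  fit <- cox_fit(d, "who")
  expect_setequal(fit$term, c("whoII", "whoIII"))
})

test_that("multivariate covariate selection is a pure threshold rule", {
  uni <- data.frame(model = c("age", "male", "whoIII", "PTTG1", "LEPR"),
                    term = c("age", "male", "whoIII", "PTTG1", "LEPR"),
                    p_score = c(0.09, 0.005, 0.015, 0.0005, 0.002))
  picked <- select_multivariate_covariates(
    uni, threshold = 0.05, gene_covariates = c("PTTG1", "LEPR"),
    gene_threshold = 0.001)
  # clinical confounders at p < 0.05; genes only below the stricter 0.001
  expect_setequal(picked, c("male", "whoIII", "PTTG1"))
})

test_that("combined two-marker groups apply the documented cuts", {
  pttg1 <- setNames(1:8, sprintf("s%d", 1:8))
  lepr <- setNames(c(5, 6, 7, 8, 1, 2, 3, 4), sprintf("s%d", 1:8))
  # PTTG1 Q3 = 6.25 -> high = {7, 8}; LEPR median 4.5 -> high = {5..8}
  cg <- combined_gene_groups(pttg1, lepr)
  expect_equal(sum(cg$sizes), 8)
  expect_equal(as.character(cg$group[c(1, 8)]),
               c("PTTG1-low/LEPR-high", "PTTG1-high/LEPR-low"))
  expect_equal(unname(cg$cuts), c(6.25, 4.5))
})

test_that("low-PTTG1/high-LEPR patients fare best under planted hazards", {
  co <- generate_cohort(simulation_config(seed = 84))
  ann <- co$annotation
  em <- normalize_pipeline(co$expression, batch = ann$batch)$matrix
  # cuts are applied to measured expression, as in the assay
  p_expr <- em$values[co$truth$pttg1_like, ann$sample_id]
  l_expr <- em$values[co$truth$lepr_like, ann$sample_id]
  cg <- combined_gene_groups(p_expr, l_expr, time = ann$pfs_months,
                             event = ann$progression_event)
  med <- cg$median_pfs
  best <- med["PTTG1-low/LEPR-high"]
  others <- med[setdiff(names(med), "PTTG1-low/LEPR-high")]
  expect_true(all(is.na(others) | others <= best | is.na(best)))
  expect_lt(cg$logrank$p_value, 0.05)
})
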