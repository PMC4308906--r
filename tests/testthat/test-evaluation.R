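test_that("group comparisons from raw data equal those from summary statistics", {
  set.seed(23)
  d <- data.frame(g = rep(0:1, c(30, 25)))
  d$v <- rnorm(55) + 0.5 * d$g
  raw <- compare_groups(d, "v", "g")
  s <- raw$summary
  summ <- compare_groups(summary = list(m1 = s$m1, s1 = s$s1, n1 = s$n1,
                                        m0 = s$m0, s0 = s$s0, n0 = s$n0))
  expect_equal(raw$statistic, summ$statistic, tolerance = 1e-10)
  expect_equal(raw$p, summ$p, tolerance = 1e-10)
  # pooled-variance t oracle
  tt <- t.test(v ~ g, data = d, var.equal = TRUE)
  expect_equal(abs(raw$statistic), abs(unname(tt$statistic)), tolerance = 1e-10)
  expect_equal(raw$p, tt$p.value, tolerance = 1e-10)
})

test_that("null group comparisons give zero statistics and p = 1", {
  summ <- compare_groups(summary = list(m1 = 5, s1 = 1, n1 = 10,
                                        m0 = 5, s0 = 1, n0 = 12))
  expect_equal(summ$statistic, 0)
  expect_equal(summ$p, 1)
  chi <- compare_groups(summary = list(x1 = 20, n1 = 100, x0 = 10, n0 = 50))
  expect_equal(chi$statistic, 0, tolerance = 1e-12)
  expect_equal(chi$p, 1, tolerance = 1e-12)
})

test_that("printed sex-difference summaries are strongly significant", {
  # male vs female height from the calibrated summary table
  gc <- compare_groups(summary = list(m1 = 166.73, s1 = 6.45, n1 = 6939,
                                      m0 = 155.71, s0 = 6.17, n0 = 8233))
  expect_lt(gc$p, 0.001)
  expect_gt(abs(gc$statistic), 100)
})

test_that("binary variables route to the Pearson chi-squared test", {
  set.seed(24)
  d <- data.frame(g = rep(0:1, each = 100),
                  y = rbinom(200, 1, rep(c(0.2, 0.4), each = 100)))
  gc <- compare_groups(d, "y", "g")
  expect_equal(gc$test, "chisq")
  or <- chisq.test(table(d$g, d$y), correct = FALSE)
  expect_equal(gc$statistic, unname(or$statistic), tolerance = 1e-10)
  expect_equal(gc$p, or$p.value, tolerance = 1e-10)
})

test_that("correlation matrix is symmetric with unit diagonal and calibrated values", {
  d <- data.frame(x = c(1, 2, 3, 4), y = c(2, 4, 6, 8))
  d$z <- -d$x
  cm <- correlation_matrix(d, c("x", "y", "z"))
  expect_equal(cm$r["x", "x"], 1)
  expect_equal(cm$r["x", "y"], 1, tolerance = 1e-12)
  expect_equal(cm$r["x", "z"], -1, tolerance = 1e-12)
  expect_equal(cm$r, t(cm$r))
  # constant column flagged, not fatal
  d$c <- 5
  cm2 <- correlation_matrix(d, c("x", "c"))
  expect_true(is.na(cm2$r["x", "c"]))
  # large calibrated sample reproduces the generator's correlation
  m <- build_default_moments("male")
  pop <- generate_population(m, 60000, seed = 25,
                             variables = c("bmi", "wc", "hip"))
  cm3 <- correlation_matrix(pop, c("bmi", "wc", "hip"))
  expect_equal(cm3$r["bmi", "wc"], 0.757, tolerance = 0.01 / 0.757)
  expect_lt(cm3$p["bmi", "wc"], 1e-10)
})

test_that("AUC equals the brute-force pair count, with half weight for ties", {
  expect_equal(roc_auc(c(1, 2, 3, 4), c(0, 0, 1, 1))$auc, 1.0)
  expect_equal(roc_auc(c(1, 2, 2, 3), c(0, 1, 0, 1))$auc, 0.875)
  set.seed(26)
  for (i in 1:5) {
    n <- sample(30:200, 1)
    sc <- sample(round(rnorm(n), 1)) # coarse scores force ties
    lb <- rbinom(n, 1, 0.4)
    if (length(unique(lb)) < 2) next
    expect_equal(roc_auc(sc, lb)$auc, auc_bruteforce(sc, lb),
                 tolerance = 1e-12)
  }
})

test_that("ROC output satisfies its structural contracts", {
  set.seed(27)
  sc <- rnorm(500); lb <- rbinom(500, 1, plogis(sc))
  r <- roc_auc(sc, lb)
  expect_equal(unlist(r$curve[1, ]), c(fpr = 0, tpr = 0))
  expect_equal(unlist(r$curve[nrow(r$curve), ]), c(fpr = 1, tpr = 1))
  expect_true(all(diff(r$curve$fpr) >= 0))
  # invariance under strictly increasing transforms
  expect_equal(roc_auc(exp(sc), lb)$auc, r$auc, tolerance = 1e-12)
  expect_true(r$ci95[1] < r$auc && r$auc < r$ci95[2])
  # uninformative score
  expect_equal(roc_auc(rnorm(10000), rbinom(10000, 1, 0.3))$auc, 0.5,
               tolerance = 0.04)
  expect_error(roc_auc(sc, rep(1, 500)), "classes")
})

test_that("paired AUC comparison is symmetric and null on identical scores", {
  set.seed(28)
  sc <- rnorm(400); lb <- rbinom(400, 1, plogis(sc))
  same <- auc_compare(sc, sc, lb)
  expect_equal(same$delta_auc, 0)
  expect_equal(same$p, 1, tolerance = 1e-12)
  other <- rnorm(400)
  ab <- auc_compare(sc, other, lb)
  ba <- auc_compare(other, sc, lb)
  expect_equal(ab$p, ba$p, tolerance = 1e-12)
  expect_equal(ab$delta_auc, -ba$delta_auc, tolerance = 1e-12)
  expect_error(auc_compare(sc, other[-1], lb), "align")
})

test_that("informative scores beat pure noise in the paired AUC test", {
  set.seed(29)
  n <- 2000
  x <- rnorm(n)
  lb <- rbinom(n, 1, plogis(1.5 * x - 1))
  cmp <- auc_compare(x, rnorm(n), lb)
  expect_gt(cmp$delta_auc, 0)
  expect_lt(cmp$p, 0.05)
})

test_that("trend analysis recovers perfect linearity and flat nulls", {
  codes <- rep(1:9, each = 10)
  perfect <- 40 + 2 * codes
  tr <- bst_trend(perfect + rnorm(90, sd = 1e-8), codes)
  expect_equal(tr$r_squared, 1, tolerance = 1e-6)
  expect_equal(tr$slope, 2, tolerance = 1e-4)
  set.seed(30)
  flat <- bst_trend(rnorm(90), codes)
  expect_gt(flat$anova_p, 0.001)
  expect_false(any(flat$lsd$significant & flat$anova_p >= 0.05))
  expect_error(bst_trend(rnorm(10), rep(3, 10)), "2 occupied")
  # F statistic equals the aov oracle
  set.seed(31)
  y <- rnorm(90) + 0.3 * codes
  tr2 <- bst_trend(y, codes)
  or <- summary(aov(y ~ factor(codes)))[[1]]
  expect_equal(tr2$anova_F, or[["F value"]][1], tolerance = 1e-10)
})

test_that("body-shape score rises across types on calibrated synthetic cohorts", {
  cohort <- synth_cohort(2500, delta = 0.325, seed = 33)
  male <- cohort[cohort$sex == "male", ]
  fit <- fit_plspm(male, model_catalog()$a)
  bss1 <- compute_bss(fit, "BSS1")
  bst <- classify_body_shape(male$bmi, male$whr, male$sex)
  tr <- bst_trend(bss1, bst$code)
  expect_lt(tr$anova_p, 1e-10)
  expect_gt(tr$slope, 0)
  # group means broadly non-decreasing: allow small inversions only between
  # sparsely occupied neighbouring types
  gs <- tr$group_stats[tr$group_stats$n >= 20, ]
  expect_true(all(diff(gs$mean) > -0.15))
})

test_that("the age-adjusted predictor reduces correctly and helps prediction", {
  cohort <- synth_cohort(1500, delta = 0.325, seed = 34)
  male <- cohort[cohort$sex == "male", ]
  fit <- fit_plspm(male, model_catalog()$a)
  pred <- age_adjusted_predictor(fit)
  b_bss <- path_coef(fit, "BSS1", "BPS")
  b_age <- path_coef(fit, "AGE", "BPS")
  expect_equal(pred, b_bss * fit$scores[, "BSS1"] + b_age * fit$scores[, "AGE"],
               tolerance = 1e-12)
  # with a zero age path the predictor rank-correlates perfectly with BSS
  expect_equal(cor(b_bss * fit$scores[, "BSS1"], fit$scores[, "BSS1"],
                   method = "spearman"), 1)
  # informative predictor beats noise
  set.seed(35)
  expect_gt(roc_auc(pred, male$hypertensive)$auc,
            roc_auc(rnorm(nrow(male)), male$hypertensive)$auc)
  fit_noage <- fit_plspm(male, model_catalog(include_age = FALSE)$a)
  expect_error(age_adjusted_predictor(fit_noage), "AGE")
})
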