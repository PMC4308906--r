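test_that("standardize centers, scales with n-1, and rejects degenerate input", {
  expect_equal(unname(standardize(matrix(1:3))[, 1]), c(-1, 0, 1))
  set.seed(1)
  x <- matrix(rnorm(40), 20, 2, dimnames = list(NULL, c("a", "b")))
  xs <- standardize(x)
  expect_equal(unname(colMeans(xs)), c(0, 0), tolerance = 1e-14)
  expect_equal(unname(apply(xs, 2, sd)), c(1, 1), tolerance = 1e-14)
  expect_equal(standardize(xs), xs, tolerance = 1e-12) # idempotent
  x[, 2] <- 5
  expect_error(standardize(x), "b")
  expect_error(standardize(matrix(1)), "2 observations")
})

test_that("model specification rejects cyclic graphs, empty and shared blocks", {
  expect_error(pls_model(list(A = "x", B = "y"),
                         rbind(c("A", "B"), c("B", "A"))), "cycle")
  expect_error(pls_model(list(A = character(0), B = "y"), cbind("A", "B")),
               "empty")
  expect_error(pls_model(list(A = c("x", "y"), B = "y"), cbind("A", "B")),
               "exactly one block")
  expect_error(pls_model(list(A = "x", B = "y"), cbind("A", "C")), "unknown")
})

test_that("single-indicator path coefficients match correlation and OLS oracles", {
  set.seed(11)
  n <- 400
  x <- rnorm(n); a <- rnorm(n)
  y <- 0.4 * x - 0.25 * a + rnorm(n)
  d <- data.frame(x = x, a = a, y = y)
  # bivariate: beta equals the Pearson correlation
  f1 <- fit_plspm(d, pls_model(list(X = "x", Y = "y"), cbind("X", "Y")))
  expect_equal(path_coef(f1, "X", "Y"), cor(x, y), tolerance = 1e-10)
  # two predictors: betas equal standardized OLS coefficients
  f2 <- fit_plspm(d, pls_model(list(X = "x", A = "a", Y = "y"),
                               rbind(c("X", "Y"), c("A", "Y"))))
  ols <- coef(lm(scale(y) ~ scale(x) + scale(a)))
  expect_equal(path_coef(f2, "X", "Y"), unname(ols[2]), tolerance = 1e-8)
  expect_equal(path_coef(f2, "A", "Y"), unname(ols[3]), tolerance = 1e-8)
  # and this holds for every inner scheme
  for (sch in c("centroid", "factorial")) {
    fs <- fit_plspm(d, pls_model(list(X = "x", A = "a", Y = "y"),
                                 rbind(c("X", "Y"), c("A", "Y")),
                                 scheme = sch))
    expect_equal(path_coef(fs, "X", "Y"), unname(ols[2]), tolerance = 1e-8)
  }
})

test_that("a block of exact copies gets equal weights, unit loadings, the variable's score", {
  set.seed(2)
  v <- rnorm(100); y <- 0.5 * v + rnorm(100)
  d <- data.frame(v1 = v, v2 = v, v3 = v, y = y)
  f <- fit_plspm(d, pls_model(list(V = c("v1", "v2", "v3"), Y = "y"),
                              cbind("V", "Y")))
  w <- f$outer_weights[c("v1", "v2", "v3")]
  expect_equal(unname(w / w[1]), c(1, 1, 1), tolerance = 1e-10)
  expect_equal(unname(f$loadings[c("v1", "v2", "v3")]), rep(1, 3),
               tolerance = 1e-10)
  expect_equal(unname(f$scores[, "V"]), as.numeric(scale(v)),
               tolerance = 1e-10)
})

test_that("Mode A loadings equal manifest-score correlations after convergence", {
  cohort <- synth_cohort(400, seed = 5)
  male <- cohort[cohort$sex == "male", ]
  for (key in c("a", "b")) {
    m <- model_catalog()[[key]]
    f <- fit_plspm(male, m)
    lat <- setdiff(names(m$blocks), c("BPS", "AGE"))
    for (mm in m$blocks[[lat]])
      expect_equal(unname(f$loadings[mm]), cor(male[[mm]], f$scores[, lat]),
                   tolerance = 1e-8)
  }
})

test_that("fits are deterministic and invariant to row order and affine rescaling", {
  cohort <- synth_cohort(300, seed = 6)
  male <- cohort[cohort$sex == "male", ]
  m <- model_catalog()$a
  f1 <- fit_plspm(male, m)
  f2 <- fit_plspm(male, m)
  expect_identical(f1$path_coefficients, f2$path_coefficients) # bitwise
  perm <- sample(nrow(male))
  fp <- fit_plspm(male[perm, ], m)
  expect_equal(fp$path_coefficients$estimate, f1$path_coefficients$estimate,
               tolerance = 1e-10)
  expect_equal(fp$scores[, "BSS1"], f1$scores[perm, "BSS1"],
               tolerance = 1e-10)
  resc <- male
  resc$wc <- resc$wc * 3.7 + 12 # affine change of units is absorbed
  fr <- fit_plspm(resc, m)
  expect_equal(fr$path_coefficients$estimate, f1$path_coefficients$estimate,
               tolerance = 1e-10)
  expect_equal(fr$loadings, f1$loadings, tolerance = 1e-10)
})

test_that("the model catalogue defines the six structures", {
  cat6 <- model_catalog()
  expect_length(cat6, 6)
  expect_named(cat6, c("a", "b", "c", "d", "e", "f"))
  expect_setequal(cat6$a$blocks$BSS1, c("bmi", "wc", "hip"))
  expect_setequal(cat6$b$blocks$BSS2, c("bmi", "wc", "whr", "wsr"))
  expect_equal(cat6$c$blocks$BMI, "bmi")
  expect_equal(cat6$f$blocks$WSR, "wsr")
  for (m in cat6) {
    expect_true("BPS" %in% names(m$blocks))
    expect_equal(m$blocks$BPS, "hypertensive")
    expect_true("AGE" %in% names(m$blocks))
    expect_true(any(m$paths[, "from"] == "AGE" & m$paths[, "to"] == "BPS"))
  }
  # variants
  nosim <- model_catalog(include_age = FALSE)
  expect_false("AGE" %in% names(nosim$a$blocks))
  cont <- model_catalog(bp_manifest = "sbp")
  expect_equal(cont$a$blocks$BPS, "sbp")
})

test_that("body-shape scores are standardized, sign-anchored to BMI, rescalable", {
  cohort <- synth_cohort(400, seed = 8)
  female <- cohort[cohort$sex == "female", ]
  f <- fit_plspm(female, model_catalog()$a)
  s <- compute_bss(f, "BSS1")
  expect_equal(mean(s), 0, tolerance = 1e-10)
  expect_equal(sd(s), 1, tolerance = 1e-10)
  expect_gt(cor(s, female$bmi), 0)
  # single-index model: score is exactly the standardized manifest
  fc <- fit_plspm(female, model_catalog()$c)
  expect_equal(compute_bss(fc, "BMI"), as.numeric(scale(female$bmi)),
               tolerance = 1e-12)
  r <- compute_bss(f, "BSS1", mean = 50, sd = 5)
  expect_equal(mean(r), 50, tolerance = 1e-8)
  expect_equal(sd(r), 5, tolerance = 1e-8)
  expect_error(compute_bss(f, "nope"), "no block")
})

test_that("path coefficients under the binary outcome increase strictly with delta", {
  m <- build_default_moments("male")
  pop <- generate_population(m, 40000, seed = 31)
  betas <- vapply(c(0.10, 0.15, 0.20, 0.25, 0.30), function(d) {
    p <- attach_bp(pop, d, m, seed = 32)
    path_coef(fit_plspm(p, model_catalog(include_age = FALSE)$a),
              "BSS1", "BPS")
  }, 0)
  expect_true(all(diff(betas) > 0))
  # dichotomization attenuates relative to delta
  expect_true(all(betas < c(0.10, 0.15, 0.20, 0.25, 0.30)))
})

test_that("fit errors are informative", {
  cohort <- synth_cohort(100, seed = 9)
  male <- cohort[cohort$sex == "male", ]
  male$hip <- NULL
  expect_error(fit_plspm(male, model_catalog()$a), "hip")
  male2 <- cohort[cohort$sex == "male", ]
  male2$bmi[3] <- NA
  expect_error(fit_plspm(male2, model_catalog()$a), "missing")
})
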