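#' Two-group comparison (t or chi-squared)
#'
#' Numeric variables are compared with the unpaired pooled-variance Student
#' t-test, binary variables with the Pearson chi-squared test (no continuity
#' correction). Raw data is reduced to per-group summary statistics and
#' routed through the same summary-based computation, so raw and printed
#' summary inputs give identical results.
#'
#' @param cohort data.frame (omit when giving summary input).
#' @param variable name of the variable to compare; treated as binary when it
#'   has at most two distinct values.
#' @param group name of the binary grouping column.
#' @param summary optional list for printed-table verification:
#'   `list(m1=, s1=, n1=, m0=, s0=, n0=)` for a t-test, or
#'   `list(x1=, n1=, x0=, n0=)` (successes and sizes) for chi-squared.
#' @return object of class `group_comparison`: test name, per-group
#'   summaries, statistic, df, p-value.
#' @export
compare_groups <- function(cohort = NULL, variable = NULL, group = NULL,
                           summary = NULL) {
  if (is.null(summary)) {
    stopifnot(is.data.frame(cohort), variable %in% names(cohort),
              group %in% names(cohort))
    g <- cohort[[group]]
    lev <- sort(unique(g[!is.na(g)]))
    if (length(lev) != 2) stop("compare_groups: group must have two levels")
    v <- cohort[[variable]]
    ok <- !is.na(v) & !is.na(g)
    v <- v[ok]; g <- g[ok]
    binary <- length(unique(v)) <= 2
    if (binary) {
      vmax <- max(v)
      summary <- list(x1 = sum(v[g == lev[2]] == vmax), n1 = sum(g == lev[2]),
                      x0 = sum(v[g == lev[1]] == vmax), n0 = sum(g == lev[1]))
    } else {
      summary <- list(m1 = mean(v[g == lev[2]]), s1 = stats::sd(v[g == lev[2]]),
                      n1 = sum(g == lev[2]),
                      m0 = mean(v[g == lev[1]]), s0 = stats::sd(v[g == lev[1]]),
                      n0 = sum(g == lev[1]))
    }
  }
  if (!is.null(summary$m1)) {
    s <- summary
    if (s$n1 < 2 || s$n0 < 2)
      stop("compare_groups: each group needs n >= 2 for the t test")
    df <- s$n1 + s$n0 - 2
    sp2 <- ((s$n1 - 1) * s$s1^2 + (s$n0 - 1) * s$s0^2) / df
    tstat <- (s$m1 - s$m0) / sqrt(sp2 * (1 / s$n1 + 1 / s$n0))
    if (is.nan(tstat)) tstat <- 0
    out <- list(test = "t", statistic = tstat, df = df,
                p = 2 * stats::pt(-abs(tstat), df), summary = s)
  } else {
    s <- summary
    tab <- rbind(c(s$x1, s$n1 - s$x1), c(s$x0, s$n0 - s$x0))
    suppressWarnings(ct <- stats::chisq.test(tab, correct = FALSE))
    stat <- unname(ct$statistic)
    if (is.nan(stat)) stat <- 0
    out <- list(test = "chisq", statistic = stat,
                df = unname(ct$parameter),
                p = if (is.nan(ct$p.value)) 1 else ct$p.value, summary = s)
  }
  structure(out, class = "group_comparison")
}

#' @export
print.group_comparison <- function(x, ...) {
  cat(sprintf("%s test: statistic = %.4f, df = %s, p = %.3g\n",
              x$test, x$statistic, format(x$df), x$p))
  invisible(x)
}

#' Pairwise Pearson correlation matrix with p-values
#'
#' @param cohort data.frame.
#' @param variables columns to correlate (>= 3 complete rows required).
#' @return list with `r` (symmetric, unit diagonal) and `p` matrices;
#'   constant variables yield NA cells rather than an error.
#' @export
correlation_matrix <- function(cohort, variables) {
  stopifnot(all(variables %in% names(cohort)))
  X <- as.matrix(cohort[variables])
  X <- X[stats::complete.cases(X), , drop = FALSE]
  if (nrow(X) < 3) stop("correlation_matrix: need >= 3 complete rows")
  k <- length(variables)
  r <- diag(k); p <- matrix(NA_real_, k, k)
  dimnames(r) <- dimnames(p) <- list(variables, variables)
  sds <- apply(X, 2, stats::sd)
  for (i in seq_len(k - 1)) for (j in (i + 1):k) {
    if (sds[i] < 1e-12 || sds[j] < 1e-12) {
      r[i, j] <- r[j, i] <- NA_real_
      next
    }
    ct <- stats::cor.test(X[, i], X[, j])
    r[i, j] <- r[j, i] <- unname(ct$estimate)
    p[i, j] <- p[j, i] <- ct$p.value
  }
  list(r = r, p = p, n = nrow(X))
}

#' ROC curve and AUC for a continuous score
#'
#' AUC is the rank statistic (probability a random case outscores a random
#' control, tied pairs counted one half); the 95% CI uses the DeLong
#' placement-value variance. Invariant under strictly increasing transforms
#' of the score.
#'
#' @param scores numeric risk score.
#' @param labels 0/1 outcome (both classes present).
#' @return object of class `roc_result`: `auc`, `ci95`, `n_pos`, `n_neg`,
#'   and `curve` (data.frame of (1-specificity, sensitivity) from (0,0) to
#'   (1,1)).
#' @export
roc_auc <- function(scores, labels) {
  stopifnot(length(scores) == length(labels))
  labels <- as.integer(labels)
  if (length(unique(labels)) < 2)
    stop("roc_auc: both classes must be present")
  r <- pROC::roc(response = labels, predictor = scores,
                 levels = c(0, 1), direction = "<", quiet = TRUE)
  a <- as.numeric(pROC::auc(r))
  ci <- if (a %in% c(0, 1)) # degenerate separation: CI collapses
    suppressWarnings(as.numeric(pROC::ci.auc(r, method = "delong")))
  else as.numeric(pROC::ci.auc(r, method = "delong"))
  curve <- data.frame(fpr = rev(1 - r$specificities),
                      tpr = rev(r$sensitivities))
  structure(list(auc = a,
                 ci95 = c(ci[1], ci[3]),
                 n_pos = sum(labels == 1), n_neg = sum(labels == 0),
                 curve = curve, roc = r),
            class = "roc_result")
}

#' @export
print.roc_result <- function(x, ...) {
  cat(sprintf("AUC = %.4f (95%% CI %.4f-%.4f), %d cases / %d controls\n",
              x$auc, x$ci95[1], x$ci95[2], x$n_pos, x$n_neg))
  invisible(x)
}

#' Compare two correlated AUCs on the same subjects
#'
#' DeLong test for paired ROC curves: the two scores are computed on the same
#' subjects, so the placement-value covariance is used.
#'
#' @param scores_a,scores_b two risk scores on the same subjects.
#' @param labels 0/1 outcome.
#' @return list with `delta_auc` (AUC_a - AUC_b), `auc_a`, `auc_b`, and the
#'   two-sided `p`.
#' @export
auc_compare <- function(scores_a, scores_b, labels) {
  if (length(scores_a) != length(scores_b) ||
      length(scores_a) != length(labels))
    stop("auc_compare: score and label vectors must align")
  labels <- as.integer(labels)
  ra <- pROC::roc(labels, scores_a, levels = c(0, 1), direction = "<",
                  quiet = TRUE)
  rb <- pROC::roc(labels, scores_b, levels = c(0, 1), direction = "<",
                  quiet = TRUE)
  tt <- pROC::roc.test(ra, rb, method = "delong", paired = TRUE)
  list(delta_auc = as.numeric(pROC::auc(ra)) - as.numeric(pROC::auc(rb)),
       auc_a = as.numeric(pROC::auc(ra)), auc_b = as.numeric(pROC::auc(rb)),
       p = tt$p.value)
}

#' Trend of a body-shape score across the nine body-shape types
#'
#' One-way analysis of variance of the score across occupied types, protected
#' least-significant-difference pairwise comparisons (only reported as
#' significant when the omnibus F is significant at 0.05), and the
#' least-squares line of the score on the numeric type code.
#'
#' @param bss numeric score vector.
#' @param bst integer type codes 1-9.
#' @param alpha omnibus protection level for the LSD table (default 0.05).
#' @return object of class `bst_trend`: `anova_F`, `anova_p`, `lsd`
#'   (data.frame of pairwise mean differences, t, p, significant),
#'   `slope`, `intercept`, `r_squared`, `group_stats`.
#' @export
bst_trend <- function(bss, bst, alpha = 0.05) {
  stopifnot(length(bss) == length(bst))
  ok <- !is.na(bss) & !is.na(bst)
  bss <- bss[ok]; bst <- as.integer(bst[ok])
  groups <- sort(unique(bst))
  if (length(groups) < 2) stop("bst_trend: need >= 2 occupied types")
  f <- factor(bst, levels = groups)
  av <- stats::aov(bss ~ f)
  ss <- summary(av)[[1]]
  anova_F <- ss[["F value"]][1]
  anova_p <- ss[["Pr(>F)"]][1]
  mse <- ss[["Mean Sq"]][2]
  dfe <- ss[["Df"]][2]
  gs <- data.frame(code = groups,
                   n = as.integer(table(f)),
                   mean = as.numeric(tapply(bss, f, mean)),
                   sd = as.numeric(tapply(bss, f, stats::sd)))
  cmb <- utils::combn(seq_along(groups), 2)
  lsd <- data.frame(a = groups[cmb[1, ]], b = groups[cmb[2, ]])
  lsd$diff <- gs$mean[cmb[2, ]] - gs$mean[cmb[1, ]]
  se <- sqrt(mse * (1 / gs$n[cmb[1, ]] + 1 / gs$n[cmb[2, ]]))
  lsd$t <- lsd$diff / se
  lsd$p <- 2 * stats::pt(-abs(lsd$t), dfe)
  lsd$significant <- !is.na(anova_p) & anova_p < alpha & lsd$p < alpha
  lm_fit <- stats::lm(bss ~ bst)
  structure(list(anova_F = anova_F, anova_p = anova_p, lsd = lsd,
                 slope = unname(stats::coef(lm_fit)[2]),
                 intercept = unname(stats::coef(lm_fit)[1]),
                 r_squared = summary(lm_fit)$r.squared,
                 group_stats = gs),
            class = "bst_trend")
}

#' @export
print.bst_trend <- function(x, ...) {
  cat(sprintf("ANOVA F = %.2f, p = %.3g; linear trend slope %.3f, R^2 = %.3f\n",
              x$anova_F, x$anova_p, x$slope, x$r_squared))
  print(x$group_stats, row.names = FALSE)
  invisible(x)
}

#' Age-adjusted linear predictor from a fitted path model
#'
#' The model-implied predictor of the blood-pressure latent:
#' `beta_bss * BSS + beta_age * AgeScore`, used as the ROC score when
#' age is adjusted inside the path model.
#'
#' @param fit a converged `pls_fit` whose model has both a body-shape path
#'   and an AGE -> BPS path.
#' @return numeric score vector.
#' @export
age_adjusted_predictor <- function(fit) {
  stopifnot(inherits(fit, "pls_fit"))
  pc <- fit$path_coefficients
  into_bp <- pc[pc$to == "BPS", , drop = FALSE]
  if (!"AGE" %in% into_bp$from)
    stop("age_adjusted_predictor: model has no AGE -> BPS path")
  pred <- numeric(fit$n)
  for (i in seq_len(nrow(into_bp)))
    pred <- pred + into_bp$estimate[i] * fit$scores[, into_bp$from[i]]
  pred
}
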