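#' Generate a complete synthetic cohort for the analysis pipeline
#'
#' Convenience wrapper producing an analysis-ready two-sex cohort: per sex,
#' anthropometric indices (age, BMI, WC, WHR, WSR, Hip) are drawn from the
#' calibrated moment specification, and blood pressure is attached at effect
#' size `delta` (default 0.325, the standardized SBP-on-BMI slope that
#' anchors the simulation's effect grid), giving hypertension-group mean
#' shifts in the anthropometrics.
#'
#' @param n_male,n_female stratum sizes.
#' @param delta standardized BMI -> BP effect size.
#' @param seed integer seed.
#' @return data.frame cohort with id, sex, age, indices, sbp, dbp,
#'   hypertensive.
#' @export
generate_cohort <- function(n_male, n_female, delta = 0.325, seed = 1) {
  vars <- c("age", "bmi", "wc", "whr", "wsr", "hip")
  parts <- list()
  sizes <- c(male = n_male, female = n_female)
  for (i in seq_along(sizes)) {
    sx <- names(sizes)[i]
    mo <- build_default_moments(sx)
    pop <- generate_population(mo, sizes[[i]],
                               seed = .sub_seed(seed, 100 + i),
                               variables = vars)
    parts[[sx]] <- attach_bp(pop, delta, mo, seed = .sub_seed(seed, 200 + i))
  }
  out <- rbind(parts$male, parts$female)
  out$id <- seq_len(nrow(out))
  rownames(out) <- NULL
  out
}

.manifests_for_models <- function(models) {
  need <- list(a = c("bmi", "wc", "hip"), b = c("bmi", "wc", "whr", "wsr"),
               c = "bmi", d = "wc", e = "whr", f = "wsr")
  unique(unlist(need[models]))
}

#' Run the full body-shape analysis pipeline
#'
#' Executes, per sex stratum: listwise filtering, descriptives, the
#' correlation matrix over the five obesity measurements, the selected path
#' model fits with bootstrap tests of the body-shape -> blood-pressure
#' coefficient, body-shape score extraction, nine-type classification with
#' the score-by-type trend analysis, and ROC/AUC comparison of every index
#' against BSS1 (age-adjusted predictor and raw score). Sex stratification is
#' mandatory unless `pooled = TRUE`. Also reports male-vs-female comparisons
#' of the shared variables.
#'
#' @param cohort data.frame with sex, age, the anthropometric indices needed
#'   by the selected models (raw height/weight/wc/hip columns are accepted
#'   and indices derived), and either a `hypertensive` flag or sbp/dbp
#'   (+ optional on_htn_med) from which it is derived.
#' @param models subset of c("a","b","c","d","e","f") (default all six).
#' @param bootstrap_B bootstrap resamples for the path tests (default 500).
#' @param seed integer seed.
#' @param out_dir optional directory; when given, tables are written as TSV
#'   plus a JSON manifest.
#' @param pooled analyse the pooled cohort instead of per-sex strata.
#' @return list bundle: `sex_comparison`, and per stratum `descriptives`,
#'   `correlations`, `fits`, `bootstrap`, `summary_table` (path coefficient
#'   CI + AUC CI + p vs BSS1 per index), `trend`, `bst_distribution`,
#'   `n`, `removed`.
#' @export
run_analysis <- function(cohort, models = c("a", "b", "c", "d", "e", "f"),
                         bootstrap_B = 500, seed = 1, out_dir = NULL,
                         pooled = FALSE) {
  stopifnot(is.data.frame(cohort), all(models %in% letters[1:6]))
  if (!"sex" %in% names(cohort)) stop("run_analysis: cohort needs a sex column")
  if (all(c("height", "weight", "wc", "hip") %in% names(cohort)) &&
      !all(c("bmi", "whr", "wsr") %in% names(cohort)))
    cohort <- derive_indices(cohort)
  manifests <- .manifests_for_models(models)
  if (!"hypertensive" %in% names(cohort)) {
    if (!all(c("sbp", "dbp") %in% names(cohort)))
      stop("run_analysis: need hypertensive flag or sbp/dbp columns")
    med <- if ("on_htn_med" %in% names(cohort)) cohort$on_htn_med else "no"
    cohort$hypertensive <- flag_hypertension(cohort$sbp, cohort$dbp, med)
  }
  required <- unique(c("sex", "age", manifests, "hypertensive"))
  missing_cols <- setdiff(required, names(cohort))
  if (length(missing_cols))
    stop("run_analysis: cohort is missing column(s): ",
         paste(missing_cols, collapse = ", "))
  flt <- filter_complete(cohort, required)
  cohort <- flt$cohort

  desc_vars <- intersect(c("age", "sbp", "dbp", "height", "weight", "hip",
                           "wc", "bmi", "whr", "wsr"), names(cohort))
  sex_comparison <- NULL
  if (!pooled && length(unique(cohort$sex)) == 2) {
    sex_comparison <- do.call(rbind, lapply(desc_vars, function(v) {
      gc <- compare_groups(cohort, v, "sex")
      data.frame(variable = v, test = gc$test, statistic = gc$statistic,
                 p = gc$p, stringsAsFactors = FALSE)
    }))
    prev <- compare_groups(cohort, "hypertensive", "sex")
    sex_comparison <- rbind(sex_comparison,
                            data.frame(variable = "hypertensive",
                                       test = prev$test,
                                       statistic = prev$statistic, p = prev$p,
                                       stringsAsFactors = FALSE))
  }

  strata <- if (pooled) list(pooled = cohort) else
    split(cohort, cohort$sex)
  catalog <- model_catalog(bp_manifest = "hypertensive", include_age = TRUE)
  index_names <- c(a = "BSS1", b = "BSS2", c = "BMI", d = "WC", e = "WHR",
                   f = "WSR")
  out <- list(sex_comparison = sex_comparison, removed = flt$removed,
              strata = list())
  si <- 0L
  for (sname in names(strata)) {
    si <- si + 1L
    dat <- strata[[sname]]
    if (nrow(dat) < 50) {
      warning("run_analysis: stratum '", sname, "' too small; skipped")
      next
    }
    res <- list(n = nrow(dat))
    res$descriptives <- data.frame(
      variable = desc_vars,
      mean = vapply(desc_vars, function(v) mean(dat[[v]]), 0),
      sd = vapply(desc_vars, function(v) stats::sd(dat[[v]]), 0))
    corr_vars <- intersect(c("bmi", "wc", "whr", "wsr", "hip"), names(dat))
    if (length(corr_vars) >= 2)
      res$correlations <- correlation_matrix(dat, corr_vars)
    fits <- list(); boots <- list()
    tab <- NULL
    roc_scores <- list()
    for (m in models) {
      fit <- fit_plspm(dat, catalog[[m]])
      fits[[m]] <- fit
      lat <- index_names[[m]]
      bres <- bootstrap_fit(dat, catalog[[m]],
                            parameter = paste0(lat, "->BPS"),
                            B = bootstrap_B,
                            seed = .sub_seed(seed, 300 + 10L * si + match(m, letters)))
      boots[[m]] <- bres
      roc_scores[[m]] <- age_adjusted_predictor(fit)
      rr <- roc_auc(roc_scores[[m]], dat$hypertensive)
      tab <- rbind(tab, data.frame(
        index = lat, path_coefficient = bres$estimate,
        ci_low = bres$ci95[1], ci_high = bres$ci95[2],
        auc = rr$auc, auc_ci_low = rr$ci95[1], auc_ci_high = rr$ci95[2],
        stringsAsFactors = FALSE))
    }
    if ("a" %in% models) {
      tab$p_vs_bss1 <- vapply(models, function(m) {
        if (m == "a") return(NA_real_)
        auc_compare(roc_scores[[m]], roc_scores[["a"]], dat$hypertensive)$p
      }, 0)
      bss1 <- compute_bss(fits[["a"]], "BSS1")
      if ("whr" %in% names(dat)) {
        bst <- classify_body_shape(dat$bmi, dat$whr, dat$sex)
        res$bst_distribution <- data.frame(
          code = 1:9, label = .bst_labels,
          n = as.integer(table(factor(bst$code, levels = 1:9))))
        res$bst_distribution$pct <- 100 * res$bst_distribution$n / nrow(dat)
        res$trend <- bst_trend(bss1, bst$code)
      }
    }
    res$fits <- fits
    res$bootstrap <- boot_table(boots)
    res$summary_table <- tab
    out$strata[[sname]] <- res
  }
  if (!is.null(out_dir)) .write_bundle(out, out_dir, seed)
  out
}

.write_bundle <- function(bundle, out_dir, seed) {
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  wt <- function(x, f) utils::write.table(
    x, file.path(out_dir, f), sep = "\t", row.names = FALSE, quote = FALSE)
  if (!is.null(bundle$sex_comparison))
    wt(bundle$sex_comparison, "sex_comparison.tsv")
  for (sname in names(bundle$strata)) {
    s <- bundle$strata[[sname]]
    wt(s$descriptives, paste0("descriptives_", sname, ".tsv"))
    wt(s$summary_table, paste0("path_auc_", sname, ".tsv"))
    wt(s$bootstrap, paste0("bootstrap_", sname, ".tsv"))
    if (!is.null(s$bst_distribution)) {
      tr <- merge(s$bst_distribution,
                  stats::setNames(s$trend$group_stats,
                                  c("code", "n_obs", "bss1_mean", "bss1_sd")),
                  by = "code", all.x = TRUE)
      wt(tr[c("code", "label", "n", "pct", "bss1_mean", "bss1_sd")],
         paste0("body_shape_types_", sname, ".tsv"))
    }
  }
  jsonlite::write_json(
    list(seed = seed, created = format(Sys.time(), "%Y-%m-%d %H:%M:%S"),
         strata = lapply(bundle$strata, function(s) list(n = s$n)),
         removed = bundle$removed,
         package_version = as.character(utils::packageVersion("bsspm"))),
    file.path(out_dir, "manifest.json"), auto_unbox = TRUE, digits = NA)
  invisible(out_dir)
}

#' Run the simulation study end to end
#'
#' Wraps [run_type1()] and/or [run_power()] for a design and writes tidy
#' results when an output directory is given.
#'
#' @param design a [simulation_design()].
#' @param which "type1", "power", or "both".
#' @param moments generator calibration (default male).
#' @param test test used inside replicates ("bootstrap" or "ols").
#' @param out_dir optional output directory for TSV + manifest.
#' @return list with elements `type1` and/or `power` (`sim_result`s).
#' @export
run_simulation <- function(design, which = c("both", "type1", "power"),
                           moments = build_default_moments("male"),
                           test = "bootstrap", out_dir = NULL) {
  which <- match.arg(which)
  out <- list()
  if (which %in% c("both", "type1"))
    out$type1 <- run_type1(design, moments, test)
  if (which %in% c("both", "power"))
    out$power <- run_power(design, moments, test)
  if (!is.null(out_dir)) {
    dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
    for (nm in names(out))
      write_sim_result(out[[nm]],
                       file.path(out_dir, paste0(nm, ".tsv")),
                       file.path(out_dir, paste0(nm, "_manifest.json")))
  }
  out
}
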