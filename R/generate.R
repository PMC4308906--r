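#' Generate a synthetic population from summary moments
#'
#' Draws `size` subjects from the multivariate normal distribution with the
#' specification's mean vector and covariance (SD-scaled correlations) over
#' the requested anthropometric variables. The correlation submatrix is
#' repaired to positive semi-definiteness first if needed. Variables outside
#' the correlation block (age) are drawn independently by default, reflecting
#' the assumption of zero age–anthropometry correlation.
#'
#' @param moments a `moment_spec` from [build_default_moments()].
#' @param size number of subjects.
#' @param seed integer seed; the draw is reproducible given the seed.
#' @param variables which variables to simulate; any of the correlation-block
#'   variables plus "age". Default `c("bmi","wc","hip")`, the primitives of
#'   the simulation design.
#' @return data.frame with columns `id`, `sex`, and the requested variables.
#' @export
generate_population <- function(moments, size, seed,
                                variables = c("bmi", "wc", "hip")) {
  stopifnot(inherits(moments, "moment_spec"), size >= 0)
  corvars <- intersect(variables, colnames(moments$cor))
  extra <- setdiff(variables, c(corvars, "age"))
  if (length(extra))
    stop("generate_population: unknown variable(s): ",
         paste(extra, collapse = ", "))
  out <- data.frame(id = seq_len(size),
                    sex = rep(moments$sex, size),
                    stringsAsFactors = FALSE)
  if (size == 0) {
    for (v in variables) out[[v]] <- numeric(0)
    return(out)
  }
  set.seed(seed)
  if (length(corvars)) {
    R <- psd_repair(moments$cor[corvars, corvars, drop = FALSE])
    s <- moments$sd[corvars]
    Sigma <- R * tcrossprod(s)
    X <- MASS::mvrnorm(size, mu = moments$mean[corvars], Sigma = Sigma)
    X <- matrix(X, nrow = size, dimnames = list(NULL, corvars))
    for (v in corvars) out[[v]] <- X[, v]
  }
  if ("age" %in% variables)
    out$age <- stats::rnorm(size, moments$mean["age"], moments$sd["age"])
  out[, c("id", "sex", variables), drop = FALSE]
}

#' Attach blood pressure driven by BMI at effect size delta
#'
#' Implements the simulation's blood-pressure step on the standardized scale:
#' `SBP_z = delta * BMI_z + eps`, `eps ~ N(0, 1 - delta^2)`, then affinely
#' mapped to the specification's SBP mean/SD, so the marginal BP moments are
#' preserved for every delta and `cor(BMI_z, SBP_z) = delta` in expectation.
#' DBP is generated the same way with its own noise stream; the two noise
#' streams share the specification's residual correlation (default 0.5). At
#' `delta = 0` blood pressure is independent of all anthropometrics. A
#' `hypertensive` flag is then derived with [flag_hypertension()] (no
#' medication use in simulated data).
#'
#' @param population data.frame with a `bmi` column.
#' @param delta standardized effect size, `0 <= delta < 1`.
#' @param moments the `moment_spec` providing SBP/DBP means and SDs.
#' @param seed integer seed for the noise streams.
#' @return `population` with `sbp`, `dbp` and `hypertensive` columns added.
#' @export
attach_bp <- function(population, delta, moments, seed) {
  stopifnot(is.data.frame(population), "bmi" %in% names(population))
  if (!is.numeric(delta) || delta < 0 || delta >= 1)
    stop("attach_bp: delta must satisfy 0 <= delta < 1")
  n <- nrow(population)
  if (n == 0) {
    population$sbp <- population$dbp <- numeric(0)
    population$hypertensive <- integer(0)
    return(population)
  }
  set.seed(seed)
  bmi_z <- as.numeric(scale(population$bmi))
  rho <- moments$sbp_dbp_residual
  z1 <- stats::rnorm(n)
  z2 <- rho * z1 + sqrt(1 - rho^2) * stats::rnorm(n)
  sd_eps <- sqrt(1 - delta^2)
  sbp_z <- delta * bmi_z + sd_eps * z1
  dbp_z <- delta * bmi_z + sd_eps * z2
  population$sbp <- moments$mean["sbp"] + moments$sd["sbp"] * sbp_z
  population$dbp <- moments$mean["dbp"] + moments$sd["dbp"] * dbp_z
  population$hypertensive <- flag_hypertension(population$sbp,
                                               population$dbp, "no")
  population
}

#' Point-biserial correlation from two-group summary statistics
#'
#' Recovers the Pearson correlation between a binary group indicator and a
#' continuous variable from per-group means, SDs and sizes:
#' `r = (m1 - m0) * sqrt(p * (1 - p)) / s_total`, with `p = n1/(n1 + n0)` and
#' `s_total` the combined SD reconstructed from the group moments
#' (n-1 denominator). Useful for checking internal consistency of printed
#' subgroup tables and for calibrating outcome-linked mean shifts.
#'
#' @param m1,s1,n1 mean, SD, size of the positive (e.g. hypertensive) group.
#' @param m0,s0,n0 mean, SD, size of the reference group.
#' @return list with `r`, `combined_mean`, `combined_sd`.
#' @export
point_biserial_from_groups <- function(m1, s1, n1, m0, s0, n0) {
  stopifnot(n1 >= 2, n0 >= 2, s1 > 0, s0 > 0)
  n <- n1 + n0
  p <- n1 / n
  m <- (n1 * m1 + n0 * m0) / n
  ss <- (n1 - 1) * s1^2 + (n0 - 1) * s0^2 + n1 * n0 / n * (m1 - m0)^2
  s_total <- sqrt(ss / (n - 1))
  if (s_total <= 0) stop("point_biserial_from_groups: zero combined variance")
  list(r = (m1 - m0) * sqrt(p * (1 - p)) / s_total,
       combined_mean = m, combined_sd = s_total)
}

#' Simulation design for the type-I-error / power study
#'
#' Bundles the effect-size and sample-size grids, replicate count, nominal
#' test sizes, population size, the reference standardized slope anchoring
#' the delta range, and the root seed. Defaults follow the study design:
#' delta in \{0.10, ..., 0.30\}, n in \{500, ..., 2500\}, 1000 replicates per
#' cell, population of 500,000.
#'
#' @param delta_grid standardized effect sizes (each in `[0, 1)`).
#' @param n_grid per-replicate sample sizes.
#' @param replicates Monte-Carlo replicates per cell.
#' @param alpha_levels nominal sizes at which rejections are tallied.
#' @param population_size size of the fixed simulated population.
#' @param bootstrap_B bootstrap resamples inside each replicate's test.
#' @param reference_coefficient printed standardized SBP-on-BMI slope that
#'   anchored the delta range.
#' @param seed root seed; all per-stage and per-replicate seeds derive from it.
#' @return object of class `simulation_design`.
#' @export
simulation_design <- function(delta_grid = c(0.10, 0.15, 0.20, 0.25, 0.30),
                              n_grid = c(500, 1000, 1500, 2000, 2500),
                              replicates = 1000,
                              alpha_levels = c(0.05, 0.01),
                              population_size = 500000,
                              bootstrap_B = 200,
                              reference_coefficient = 0.325,
                              seed = 1) {
  stopifnot(all(delta_grid >= 0), all(delta_grid < 1),
            all(n_grid >= 1), replicates >= 1,
            all(alpha_levels > 0), all(alpha_levels < 1),
            population_size >= max(n_grid))
  structure(list(delta_grid = delta_grid, n_grid = n_grid,
                 replicates = as.integer(replicates),
                 alpha_levels = alpha_levels,
                 population_size = as.integer(population_size),
                 bootstrap_B = as.integer(bootstrap_B),
                 reference_coefficient = reference_coefficient,
                 seed = as.integer(seed)),
            class = "simulation_design")
}
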