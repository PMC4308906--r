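# Sex-specific summary moments used to calibrate the synthetic cohort
# generator. Means/SDs are per-variable; the correlation matrix covers the
# five obesity-related measurements. Cells the source tables do not print
# (age x anthropometrics, Hip x WHR, Hip x WSR, SBP-DBP residual co-movement)
# carry documented defaults and are flagged in `assumed`.

.moment_tables <- local({
  vars <- c("age", "sbp", "dbp", "height", "weight", "hip", "wc", "bmi",
            "whr", "wsr")
  male_mean <- c(42.64, 120.13, 78.69, 166.73, 62.38, 91.85, 79.57, 22.38,
                 0.87, 0.48)
  male_sd   <- c(15.44,  16.83, 10.83,   6.45, 10.19,  7.93,  9.75,  3.04,
                 0.07, 0.06)
  female_mean <- c(41.63, 115.83, 75.41, 155.71, 54.52, 91.69, 76.54, 22.45,
                   0.83, 0.49)
  female_sd   <- c(15.90,  18.83, 11.37,   6.17,  9.01,  8.17,  9.71,  3.25,
                   0.08, 0.06)
  cv <- c("bmi", "wc", "whr", "wsr", "hip")
  mk <- function(x) {
    R <- diag(5); dimnames(R) <- list(cv, cv)
    R[upper.tri(R)] <- x
    R[lower.tri(R)] <- t(R)[lower.tri(R)]
    R
  }
  # upper triangle column-wise over (bmi, wc, whr, wsr, hip)
  male_cor <- mk(c(0.757,
                   0.434, 0.698,
                   0.751, 0.948, 0.722,
                   0.673, 0.786, 0.15, 0.60))
  female_cor <- mk(c(0.725,
                     0.315, 0.673,
                     0.709, 0.950, 0.697,
                     0.695, 0.726, 0.10, 0.60))
  list(
    male = list(mean = stats::setNames(male_mean, vars),
                sd = stats::setNames(male_sd, vars), cor = male_cor),
    female = list(mean = stats::setNames(female_mean, vars),
                  sd = stats::setNames(female_sd, vars), cor = female_cor)
  )
})

#' Default sex-specific moment specification
#'
#' Returns the calibrated means, standard deviations and the correlation
#' matrix over \{BMI, WC, WHR, WSR, Hip\} for one sex, as printed in the
#' source survey summaries. Pairwise correlations never printed there —
#' Hip–WHR (0.15 male / 0.10 female), Hip–WSR (0.60 both), all age links (0),
#' and the SBP–DBP residual co-movement (0.5) — are package assumptions,
#' listed in the `assumed` field and overridable.
#'
#' @param sex "male" or "female".
#' @param hip_whr,hip_wsr overrides for the unprinted Hip correlations.
#' @param sbp_dbp_residual residual correlation of the SBP and DBP noise
#'   streams used by [attach_bp()].
#' @return object of class `moment_spec`: list with `sex`, `mean`, `sd`,
#'   `cor`, `sbp_dbp_residual`, `assumed`.
#' @export
build_default_moments <- function(sex = c("male", "female"),
                                  hip_whr = NULL, hip_wsr = NULL,
                                  sbp_dbp_residual = 0.5) {
  sex <- match.arg(sex)
  tab <- .moment_tables[[sex]]
  R <- tab$cor
  if (!is.null(hip_whr)) R["hip", "whr"] <- R["whr", "hip"] <- hip_whr
  if (!is.null(hip_wsr)) R["hip", "wsr"] <- R["wsr", "hip"] <- hip_wsr
  structure(list(sex = sex, mean = tab$mean, sd = tab$sd, cor = R,
                 sbp_dbp_residual = sbp_dbp_residual,
                 assumed = c("cor(hip,whr)", "cor(hip,wsr)",
                             "age links = 0", "sbp-dbp residual")),
            class = "moment_spec")
}

#' @export
print.moment_spec <- function(x, ...) {
  cat("Moment specification (", x$sex, ")\n", sep = "")
  print(round(rbind(mean = x$mean, sd = x$sd), 2))
  cat("Correlations over {", paste(colnames(x$cor), collapse = ", "), "}\n")
  print(round(x$cor, 3))
  invisible(x)
}

#' Repair a correlation matrix to positive semi-definiteness
#'
#' Correlation matrices assembled from printed pairwise values can be
#' indefinite. Repairs by clipping eigenvalues at `eps`, reconstructing, and
#' re-normalising to unit diagonal. A message reports the smallest original
#' eigenvalue whenever a repair was applied.
#'
#' @param R symmetric matrix with unit diagonal.
#' @param eps eigenvalue floor (default 1e-8).
#' @return repaired positive semi-definite correlation matrix.
#' @export
psd_repair <- function(R, eps = 1e-8) {
  if (!isSymmetric(unname(R), tol = 1e-12))
    stop("psd_repair: matrix is not symmetric")
  e <- eigen(R, symmetric = TRUE)
  if (min(e$values) >= eps) return(R)
  message(sprintf(
    "psd_repair: clipping eigenvalues (smallest = %.3g) to restore PSD",
    min(e$values)))
  v <- pmax(e$values, eps)
  R2 <- e$vectors %*% (v * t(e$vectors))
  d <- sqrt(diag(R2))
  R2 <- R2 / tcrossprod(d)
  diag(R2) <- 1
  dimnames(R2) <- dimnames(R)
  if (min(eigen(R2, symmetric = TRUE, only.values = TRUE)$values) < -eps)
    stop("psd_repair: matrix not repairable; smallest eigenvalue ",
         min(e$values))
  R2
}

#' Serialize / deserialize a moment specification as YAML
#'
#' @param spec a `moment_spec`.
#' @param path file path.
#' @export
write_moments <- function(spec, path) {
  yaml::write_yaml(list(sex = spec$sex,
                        mean = as.list(spec$mean), sd = as.list(spec$sd),
                        cor_variables = colnames(spec$cor),
                        cor = apply(spec$cor, 1, as.list),
                        sbp_dbp_residual = spec$sbp_dbp_residual), path)
  invisible(path)
}

#' @rdname write_moments
#' @export
read_moments <- function(path) {
  y <- yaml::read_yaml(path)
  cv <- unlist(y$cor_variables)
  R <- matrix(unlist(y$cor), length(cv), length(cv), dimnames = list(cv, cv))
  structure(list(sex = y$sex,
                 mean = unlist(y$mean), sd = unlist(y$sd), cor = R,
                 sbp_dbp_residual = y$sbp_dbp_residual,
                 assumed = character(0)),
            class = "moment_spec")
}
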