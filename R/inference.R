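#' Normal (U) test for a PLS parameter
#'
#' The sampling distribution of PLS path-model parameters is unknown, so a
#' parameter `w` is tested against H0: w = 0 with `U = |w| / se(w)` referred
#' to the standard normal, where `se(w)` is the bootstrapped standard error.
#'
#' @param w parameter estimate.
#' @param se its (bootstrap) standard error, > 0.
#' @return list with `U` and two-sided `p = 2 * (1 - pnorm(U))`.
#' @export
u_test <- function(w, se) {
  if (!is.numeric(se) || se <= 0) stop("u_test: se must be > 0")
  U <- abs(w) / se
  list(U = U, p = 2 * stats::pnorm(-U))
}

# Parse a parameter name: "FROM->BPS" (path) or "loading:manifest".
.parse_parameter <- function(parameter) {
  if (grepl("->", parameter, fixed = TRUE)) {
    p <- trimws(strsplit(parameter, "->", fixed = TRUE)[[1]])
    list(type = "path", from = p[1], to = p[2])
  } else if (grepl("^loading:", parameter)) {
    list(type = "loading", manifest = sub("^loading:", "", parameter))
  } else stop("bootstrap_fit: parameter must be 'FROM->TO' or 'loading:<manifest>'")
}

.extract_parameter <- function(fit, par) {
  if (par$type == "path") path_coef(fit, par$from, par$to)
  else {
    if (!par$manifest %in% names(fit$loadings))
      stop("bootstrap_fit: unknown manifest '", par$manifest, "'")
    unname(fit$loadings[par$manifest])
  }
}

#' Bootstrap test of a PLS parameter
#'
#' Resamples subjects with replacement `B` times, refits the model on each
#' resample, and collects the requested parameter. Each bootstrap fit is
#' sign-aligned with the original through the block sign anchors (applied
#' inside the estimator), so sign indeterminacy does not inflate the standard
#' error. Replicates whose refit fails (e.g. a manifest constant in the
#' resample, or non-convergence) are dropped and counted; more than 10%
#' failures is an error.
#'
#' @param data data.frame with all manifests.
#' @param model a [pls_model()].
#' @param parameter `"FROM->TO"` for a path coefficient (default the model's
#'   first inner path) or `"loading:<manifest>"` for a loading.
#' @param B bootstrap resamples (>= 50; default 500).
#' @param seed integer seed; results are reproducible given the seed.
#' @return object of class `boot_result`: `parameter`, `estimate`,
#'   `replicates`, `se`, `U`, `p`, `ci95` (normal), `ci95_percentile`, `B`,
#'   `failed`, `seed`.
#' @export
bootstrap_fit <- function(data, model, parameter = NULL, B = 500, seed = 1) {
  stopifnot(inherits(model, "pls_model"), B >= 50)
  if (is.null(parameter))
    parameter <- paste0(model$paths[1, "from"], "->", model$paths[1, "to"])
  par <- .parse_parameter(parameter)
  fit <- fit_plspm(data, model)
  w <- .extract_parameter(fit, par)

  lay <- .pls_layout(model, names(data))
  X <- as.matrix(data[lay$manifests])
  n <- nrow(X)
  pi_ <- if (par$type == "path") {
    c(which(lay$latents == par$from), which(lay$latents == par$to))
  } else match(par$manifest, lay$manifests)
  set.seed(seed)
  reps <- numeric(B)
  failed <- 0L
  for (b in seq_len(B)) {
    idx <- sample.int(n, n, replace = TRUE)
    val <- tryCatch({
      ef <- .pls_engine(standardize(X[idx, , drop = FALSE]),
                        lay$bidx, lay$pred, lay$succ,
                        model$scheme, model$tol, model$maxit, lay$anchor)
      if (!ef$converged) stop("no convergence")
      if (par$type == "path") {
        bb <- ef$betas[[pi_[2]]]
        bb[match(pi_[1], lay$pred[[pi_[2]]])]
      } else {
        j <- which(vapply(lay$bidx, function(ix) pi_ %in% ix, TRUE))
        ef$loadings[[j]][match(pi_, lay$bidx[[j]])]
      }
    }, error = function(e) NA_real_)
    if (is.na(val)) failed <- failed + 1L else reps[b - failed] <- val
  }
  reps <- reps[seq_len(B - failed)]
  if (failed > 0.1 * B)
    stop(sprintf("bootstrap_fit: %d of %d bootstrap refits failed", failed, B))
  se <- stats::sd(reps)
  ut <- if (se > 0) u_test(w, se) else list(U = Inf, p = 0)
  structure(list(parameter = parameter, estimate = w, replicates = reps,
                 se = se, U = ut$U, p = ut$p,
                 ci95 = c(w - 1.96 * se, w + 1.96 * se),
                 ci95_percentile = unname(stats::quantile(reps,
                                                          c(0.025, 0.975))),
                 B = B, failed = failed, seed = seed),
            class = "boot_result")
}

#' @export
print.boot_result <- function(x, ...) {
  cat(sprintf("%s = %.4f (bootstrap se %.4f, B = %d, failed %d)\n",
              x$parameter, x$estimate, x$se, x$B, x$failed))
  cat(sprintf("U = %.3f, p = %.3g; 95%% CI normal [%.4f, %.4f], percentile [%.4f, %.4f]\n",
              x$U, x$p, x$ci95[1], x$ci95[2],
              x$ci95_percentile[1], x$ci95_percentile[2]))
  invisible(x)
}

#' Tabulate bootstrap results
#'
#' Flattens one or more `boot_result` objects into the flat export layout
#' (parameter, estimate, se, U, p, ci_low, ci_high, B, failed_replicates).
#'
#' @param ... `boot_result` objects (or a single list of them).
#' @return data.frame.
#' @export
boot_table <- function(...) {
  xs <- list(...)
  if (length(xs) == 1 && !inherits(xs[[1]], "boot_result")) xs <- xs[[1]]
  do.call(rbind, lapply(xs, function(x)
    data.frame(parameter = x$parameter, estimate = x$estimate, se = x$se,
               U = x$U, p = x$p, ci_low = x$ci95[1], ci_high = x$ci95[2],
               B = x$B, failed_replicates = x$failed,
               stringsAsFactors = FALSE)))
}
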