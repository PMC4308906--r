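#' Column-standardize a matrix
#'
#' Centers each column to mean 0 and scales to SD 1 (n-1 denominator).
#' Constant columns are rejected by name: latent scoring is undefined for a
#' zero-variance manifest.
#'
#' @param x numeric matrix (observations x variables), >= 2 rows, no NAs.
#' @return standardized matrix of the same dimensions.
#' @export
standardize <- function(x) {
  x <- as.matrix(x)
  if (nrow(x) < 2) stop("standardize: need at least 2 observations")
  if (anyNA(x)) stop("standardize: missing values not allowed")
  n <- nrow(x)
  m <- colMeans(x)
  xc <- x - rep(m, each = n)
  s <- sqrt(colSums(xc^2) / (n - 1))
  bad <- s < 1e-12
  if (any(bad))
    stop("standardize: constant column(s): ",
         paste(colnames(x)[bad], collapse = ", "))
  xc / rep(s, each = n)
}

#' Define a PLS path model
#'
#' A model is a set of latent blocks (each a non-empty set of manifest
#' variables, estimated in reflective Mode A; a one-manifest block is the
#' single-indicator case whose score is the standardized manifest) and an
#' acyclic set of directed inner paths between latents.
#'
#' @param blocks named list; each element a character vector of manifest
#'   column names for that latent.
#' @param paths two-column matrix or data.frame of latent names
#'   (predictor, outcome).
#' @param scheme inner weighting scheme: "path" (regression weights for
#'   predecessors, correlations for successors), "centroid" (correlation
#'   signs) or "factorial" (correlations).
#' @param tol convergence tolerance on the maximum absolute outer-weight
#'   change (default 1e-7).
#' @param maxit maximum iterations (default 300).
#' @param anchors named character vector giving, per latent, the manifest
#'   whose correlation with the score is constrained nonnegative (resolves
#'   PLS sign indeterminacy). Defaults to each block's first manifest.
#' @return object of class `pls_model`.
#' @export
pls_model <- function(blocks, paths, scheme = c("path", "centroid", "factorial"),
                      tol = 1e-7, maxit = 300, anchors = NULL) {
  scheme <- match.arg(scheme)
  stopifnot(is.list(blocks), length(blocks) >= 1,
            !is.null(names(blocks)), all(nzchar(names(blocks))))
  if (any(vapply(blocks, length, 1L) == 0)) stop("pls_model: empty block")
  manifests <- unlist(blocks, use.names = FALSE)
  if (anyDuplicated(manifests))
    stop("pls_model: a manifest may belong to exactly one block")
  paths <- as.matrix(paths)
  if (ncol(paths) != 2) stop("pls_model: paths must have two columns")
  colnames(paths) <- c("from", "to")
  unknown <- setdiff(c(paths), names(blocks))
  if (length(unknown))
    stop("pls_model: unknown latent(s) in paths: ",
         paste(unknown, collapse = ", "))
  # acyclicity by repeated leaf-stripping
  g <- paths
  nodes <- names(blocks)
  while (length(nodes)) {
    sinks <- setdiff(nodes, g[, "from"])
    if (!length(sinks)) stop("pls_model: inner path graph has a cycle")
    nodes <- setdiff(nodes, sinks)
    g <- g[g[, "to"] %in% nodes, , drop = FALSE]
  }
  if (is.null(anchors))
    anchors <- vapply(blocks, `[`, "", 1L)
  stopifnot(all(names(blocks) %in% names(anchors)))
  structure(list(blocks = blocks, paths = paths, scheme = scheme,
                 tol = tol, maxit = maxit, anchors = anchors[names(blocks)]),
            class = "pls_model")
}

# Core iterative estimator on a pre-standardized manifest matrix.
# Xs: standardized n x p matrix; bidx: column indices per latent;
# pred/succ: adjacency (latent indices); anchor: column index per latent.
# Returns weights (score-scale), scores, loadings, betas, iterations.
.pls_engine <- function(Xs, bidx, pred, succ, scheme, tol, maxit, anchor) {
  n <- nrow(Xs)
  J <- length(bidx)
  W <- lapply(bidx, function(ix) rep(1, length(ix)))
  Wn <- lapply(W, function(w) w / sqrt(sum(w^2)))
  Y <- matrix(0, n, J)
  score <- function(j, w) {
    y <- Xs[, bidx[[j]], drop = FALSE] %*% w
    y / sqrt(sum(y^2) / (n - 1))
  }
  it <- 0L
  repeat {
    it <- it + 1L
    for (j in seq_len(J)) {
      y <- score(j, Wn[[j]])
      if (sum(y * Xs[, anchor[j]]) < 0) {
        y <- -y
        Wn[[j]] <- -Wn[[j]]
      }
      Y[, j] <- y
    }
    Wold <- Wn
    for (j in seq_len(J)) {
      z <- numeric(n)
      if (length(pred[[j]])) {
        Yp <- Y[, pred[[j]], drop = FALSE]
        b <- tryCatch(solve(crossprod(Yp), crossprod(Yp, Y[, j])),
                      error = function(e)
                        stop("fit_plspm: rank-deficient inner regression for block ",
                             j, call. = FALSE))
        if (scheme == "centroid") b <- sign(crossprod(Yp, Y[, j]) / (n - 1))
        if (scheme == "factorial") b <- crossprod(Yp, Y[, j]) / (n - 1)
        z <- z + Yp %*% b
      }
      if (length(succ[[j]])) {
        Ys <- Y[, succ[[j]], drop = FALSE]
        r <- crossprod(Ys, Y[, j]) / (n - 1)
        if (scheme == "centroid") r <- sign(r)
        z <- z + Ys %*% r
      }
      if (length(pred[[j]]) + length(succ[[j]]) == 0L) z <- Y[, j]
      # Mode A: weights proportional to manifest-proxy covariance
      w <- crossprod(Xs[, bidx[[j]], drop = FALSE], z)[, 1L] / (n - 1)
      Wn[[j]] <- w / sqrt(sum(w^2))
    }
    delta <- max(vapply(seq_len(J),
                        function(j) max(abs(Wn[[j]] - Wold[[j]])), 0))
    if (delta < tol || it >= maxit) break
  }
  converged <- delta < tol
  for (j in seq_len(J)) {
    y <- score(j, Wn[[j]])
    if (sum(y * Xs[, anchor[j]]) < 0) {
      y <- -y
      Wn[[j]] <- -Wn[[j]]
    }
    Y[, j] <- y
  }
  # report weights on the score scale: Y_j = Xs_j %*% w
  W <- lapply(seq_len(J), function(j) {
    y <- Xs[, bidx[[j]], drop = FALSE] %*% Wn[[j]]
    Wn[[j]] / sqrt(sum(y^2) / (n - 1))
  })
  lambda <- lapply(seq_len(J), function(j)
    crossprod(Xs[, bidx[[j]], drop = FALSE], Y[, j])[, 1L] / (n - 1))
  betas <- vector("list", J)
  for (j in seq_len(J)) {
    if (!length(pred[[j]])) next
    Yp <- Y[, pred[[j]], drop = FALSE]
    betas[[j]] <- tryCatch(
      solve(crossprod(Yp), crossprod(Yp, Y[, j]))[, 1L],
      error = function(e)
        stop("fit_plspm: collinear predecessors for an outcome latent",
             call. = FALSE))
  }
  list(weights = W, scores = Y, loadings = lambda, betas = betas,
       iterations = it, converged = converged, last_change = delta)
}

# Resolve a pls_model against a data frame: column indices, adjacency,
# anchors. Shared by fit_plspm and the bootstrap/simulation fast paths.
.pls_layout <- function(model, varnames) {
  manifests <- unlist(model$blocks, use.names = FALSE)
  miss <- setdiff(manifests, varnames)
  if (length(miss))
    stop("fit_plspm: manifest(s) not in data: ", paste(miss, collapse = ", "))
  latents <- names(model$blocks)
  pos <- stats::setNames(seq_along(manifests), manifests)
  bidx <- lapply(model$blocks, function(mm) unname(pos[mm]))
  J <- length(latents)
  pred <- succ <- rep(list(integer(0)), J)
  if (nrow(model$paths)) {
    fi <- match(model$paths[, "from"], latents)
    ti <- match(model$paths[, "to"], latents)
    for (k in seq_along(fi)) {
      pred[[ti[k]]] <- c(pred[[ti[k]]], fi[k])
      succ[[fi[k]]] <- c(succ[[fi[k]]], ti[k])
    }
  }
  anchor <- unname(pos[model$anchors[latents]])
  list(manifests = manifests, latents = latents, bidx = bidx,
       pred = pred, succ = succ, anchor = anchor)
}

#' Fit a PLS path model (Lohmoeller algorithm)
#'
#' Iterates the outer approximation (latent score = standardized weighted sum
#' of its own standardized manifests), the inner approximation (proxy =
#' weighted sum of adjacent latent scores under the chosen scheme), and the
#' Mode A outer-weight update (weight of a manifest proportional to its
#' covariance with the block proxy) until the maximum absolute outer-weight
#' change falls below the tolerance. After convergence, path coefficients are
#' ordinary-least-squares coefficients of each outcome latent on its
#' standardized predecessors, and loadings are manifest–score correlations.
#' Each block's score sign is fixed by requiring nonnegative correlation with
#' its anchor manifest.
#'
#' @param data data.frame containing every manifest, complete and
#'   non-constant, with more rows than manifests.
#' @param model a [pls_model()].
#' @return object of class `pls_fit`: latent `scores` (n x J, standardized),
#'   `outer_weights`, `loadings`, `path_coefficients` (data.frame from/to/
#'   estimate), `iterations`, `converged`, plus the model and n.
#' @export
fit_plspm <- function(data, model) {
  stopifnot(inherits(model, "pls_model"))
  lay <- .pls_layout(model, names(data))
  X <- as.matrix(data[lay$manifests])
  if (!is.numeric(X)) stop("fit_plspm: manifests must be numeric")
  if (anyNA(X)) stop("fit_plspm: missing values in manifests")
  if (nrow(X) <= ncol(X))
    stop("fit_plspm: need more observations than manifests")
  Xs <- standardize(X)
  fit <- .pls_engine(Xs, lay$bidx, lay$pred, lay$succ,
                     model$scheme, model$tol, model$maxit, lay$anchor)
  if (!fit$converged)
    stop(sprintf("fit_plspm: no convergence in %d iterations (last change %.3g)",
                 model$maxit, fit$last_change))
  scores <- fit$scores
  colnames(scores) <- lay$latents
  pc <- NULL
  for (j in seq_along(lay$latents)) {
    if (is.null(fit$betas[[j]])) next
    pc <- rbind(pc, data.frame(from = lay$latents[lay$pred[[j]]],
                               to = lay$latents[j],
                               estimate = fit$betas[[j]],
                               stringsAsFactors = FALSE))
  }
  rownames(pc) <- NULL
  structure(list(scores = scores,
                 outer_weights = stats::setNames(unlist(fit$weights),
                                                 lay$manifests),
                 loadings = stats::setNames(unlist(fit$loadings),
                                            lay$manifests),
                 path_coefficients = pc,
                 iterations = fit$iterations, converged = fit$converged,
                 model = model, n = nrow(X)),
            class = "pls_fit")
}

#' @export
print.pls_fit <- function(x, ...) {
  cat("PLS path model fit: n =", x$n, ", converged in",
      x$iterations, "iterations\n")
  cat("Path coefficients:\n")
  print(x$path_coefficients, row.names = FALSE)
  cat("Loadings:\n")
  print(round(x$loadings, 3))
  invisible(x)
}

#' Extract a path coefficient from a fit
#'
#' @param fit a `pls_fit`.
#' @param from,to latent names of the inner edge.
#' @return numeric estimate.
#' @export
path_coef <- function(fit, from, to) {
  pc <- fit$path_coefficients
  i <- which(pc$from == from & pc$to == to)
  if (!length(i)) stop("path_coef: no path ", from, " -> ", to)
  pc$estimate[i]
}

#' The six body-shape path models
#'
#' Returns the catalogue of six model specifications linking a body-shape
#' latent to the blood-pressure latent: (a) BSS1 measured reflectively by
#' BMI/WC/Hip; (b) BSS2 by BMI/WC/WHR/WSR; (c)-(f) single-index models using
#' BMI, WC, WHR and WSR respectively. The blood-pressure score (BPS) is fed
#' by a single manifest — the binary hypertension flag by default, or
#' continuous SBP for sensitivity runs — and each model may include the age
#' latent with its own path into BPS.
#'
#' @param bp_manifest manifest feeding the BPS block (default
#'   "hypertensive"; use "sbp" for the continuous sensitivity variant).
#' @param include_age include the single-indicator age latent and its
#'   AGE -> BPS path (default TRUE; the simulation study, whose generated
#'   data has no age variable, uses FALSE).
#' @param ... passed to [pls_model()] (scheme, tol, maxit).
#' @return named list of six `pls_model` objects: a, b, c, d, e, f.
#' @export
model_catalog <- function(bp_manifest = "hypertensive", include_age = TRUE,
                          ...) {
  body <- list(a = list(name = "BSS1", mm = c("bmi", "wc", "hip")),
               b = list(name = "BSS2", mm = c("bmi", "wc", "whr", "wsr")),
               c = list(name = "BMI", mm = "bmi"),
               d = list(name = "WC",  mm = "wc"),
               e = list(name = "WHR", mm = "whr"),
               f = list(name = "WSR", mm = "wsr"))
  out <- lapply(body, function(b) {
    blocks <- stats::setNames(list(b$mm), b$name)
    blocks$BPS <- bp_manifest
    paths <- cbind(from = b$name, to = "BPS")
    anchors <- stats::setNames(c(b$mm[1], bp_manifest), c(b$name, "BPS"))
    if (include_age) {
      blocks$AGE <- "age"
      paths <- rbind(paths, cbind(from = "AGE", to = "BPS"))
      anchors <- c(anchors, AGE = "age")
    }
    pls_model(blocks, paths, anchors = anchors, ...)
  })
  names(out) <- names(body)
  out
}

#' Extract a body-shape score from a fit
#'
#' Returns the standardized latent score of the requested block. The score
#' is sign-anchored at fit time (nonnegative correlation with the block's
#' anchor manifest, BMI for body-shape blocks). An optional affine rescale to
#' a presentation mean/SD is available; no claim is made that any particular
#' rescale reproduces externally printed score scales.
#'
#' @param fit a converged `pls_fit`.
#' @param block latent name (e.g. "BSS1").
#' @param mean,sd optional presentation scale.
#' @return numeric score vector.
#' @export
compute_bss <- function(fit, block, mean = NULL, sd = NULL) {
  stopifnot(inherits(fit, "pls_fit"))
  if (!block %in% colnames(fit$scores))
    stop("compute_bss: no block named '", block, "'")
  s <- fit$scores[, block]
  if (!is.null(mean) || !is.null(sd))
    s <- (if (is.null(mean)) 0 else mean) + (if (is.null(sd)) 1 else sd) * s
  s
}

#' Export a fit as JSON / scores as CSV
#'
#' @param fit a `pls_fit`.
#' @param path output file.
#' @param ids optional subject identifiers for the scores CSV.
#' @export
write_fit_json <- function(fit, path) {
  jsonlite::write_json(list(
    n = fit$n, iterations = fit$iterations, converged = fit$converged,
    outer_weights = as.list(fit$outer_weights),
    loadings = as.list(fit$loadings),
    path_coefficients = fit$path_coefficients), path,
    auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname write_fit_json
#' @export
write_scores_csv <- function(fit, path, ids = seq_len(fit$n)) {
  df <- data.frame(id = ids, fit$scores, check.names = FALSE)
  utils::write.csv(df, path, row.names = FALSE)
  invisible(path)
}
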