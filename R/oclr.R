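# One-class logistic regression (OCLR). The model is trained on positive
# (stem-class) reference profiles only, minimizing
#
#     L(w) = (1/n) sum_i log(1 + exp(-<w, x_i>)) + (lambda/2) ||w||^2
#
# with no intercept, initialized at w = 0. The problem is strongly convex,
# so the fitted weights are unique and deterministic. The weight vector is
# the gene signature later correlated against each cell's expression.
#
# Note on centering: if every gene is mean-centered across the training
# samples then sum_i <w, x_i> = 0 for all w, and by Jensen's inequality on
# the convex logistic loss the unique minimizer is w = 0. A one-class model
# is therefore fitted on uncentered (log-scale) profiles, or on profiles
# centered against an *external* baseline; center_genes() exists for the
# latter use and for constructing degenerate test inputs.

#' Construct a training matrix
#'
#' Reference profiles of the positive (stem) class, samples in rows and
#' genes in columns — typically log-scale bulk or pseudobulk expression.
#'
#' @param values Numeric matrix, samples x genes.
#' @param gene_ids Gene identifiers (columns); uppercased for matching.
#' @param sample_ids Sample identifiers (rows); defaults to `S1..Sn`.
#' @param centered Whether the genes have been centered (see
#'   [center_genes()]).
#' @return A list of class `training_matrix`.
#' @export
training_matrix <- function(values, gene_ids, sample_ids = NULL,
                            centered = FALSE) {
  values <- as.matrix(values)
  storage.mode(values) <- "double"
  gene_ids <- toupper(as.character(gene_ids))
  if (ncol(values) != length(gene_ids))
    stop("column count does not match gene_ids length", call. = FALSE)
  if (is.null(sample_ids)) sample_ids <- paste0("S", seq_len(nrow(values)))
  if (nrow(values) != length(sample_ids))
    stop("row count does not match sample_ids length", call. = FALSE)
  if (anyDuplicated(gene_ids))
    stop("duplicate gene identifiers in training matrix", call. = FALSE)
  dimnames(values) <- list(sample_ids, gene_ids)
  structure(list(values = values, gene_ids = gene_ids,
                 sample_ids = as.character(sample_ids), centered = centered),
            class = "training_matrix")
}

#' Center each gene across training samples
#'
#' Subtracts each gene's mean so every column of the training matrix has
#' mean zero. Centering a one-class training set within itself makes the
#' origin the optimum of the OCLR objective (see the package vignette), so
#' this is intended for centering against external baselines and for
#' constructing degenerate inputs, not as a default pipeline step.
#'
#' @param t A [training_matrix()] with at least 2 samples.
#' @return The centered [training_matrix()] (`centered = TRUE`).
#' @export
center_genes <- function(t) {
  if (nrow(t$values) < 2)
    stop("centering needs at least 2 training samples", call. = FALSE)
  v <- scale(t$values, center = TRUE, scale = FALSE)
  attr(v, "scaled:center") <- NULL
  training_matrix(v, t$gene_ids, t$sample_ids, centered = TRUE)
}

#' Construct a stemness model
#'
#' @param gene_ids Ordered gene identifiers.
#' @param w Per-gene weights (no NaN/Inf).
#' @param lambda Ridge strength used in training.
#' @param n_train Number of training samples.
#' @param objective_value Objective at the fitted weights.
#' @return A list of class `stemness_model`.
#' @export
stemness_model <- function(gene_ids, w, lambda = NA_real_,
                           n_train = NA_integer_,
                           objective_value = NA_real_) {
  gene_ids <- toupper(as.character(gene_ids))
  w <- as.numeric(w)
  if (length(gene_ids) != length(w))
    stop("gene_ids and w must have equal length", call. = FALSE)
  if (any(!is.finite(w)))
    stop("non-finite weight(s) in model", call. = FALSE)
  if (anyDuplicated(gene_ids))
    stop("duplicate gene identifiers in model", call. = FALSE)
  structure(list(gene_ids = gene_ids, w = stats::setNames(w, gene_ids),
                 lambda = lambda, n_train = n_train,
                 objective_value = objective_value),
            class = "stemness_model")
}

#' @export
print.stemness_model <- function(x, ...) {
  cat(sprintf("stemness_model: %d genes (lambda = %s, n_train = %s)\n",
              length(x$gene_ids), format(x$lambda), format(x$n_train)))
  invisible(x)
}

# numerically stable log(1 + exp(-s))
log1pexp_neg <- function(s) {
  ifelse(s > 0, log1p(exp(-s)), -s + log1p(exp(s)))
}

oclr_objective <- function(w, X, lambda) {
  s <- drop(X %*% w)
  mean(log1pexp_neg(s)) + lambda / 2 * sum(w^2)
}

oclr_gradient <- function(w, X, lambda) {
  s <- drop(X %*% w)
  -drop(crossprod(X, stats::plogis(-s))) / nrow(X) + lambda * w
}

#' Fit the one-class logistic regression
#'
#' Damped Newton iteration on the OCLR objective (see the header comment of
#' this file) from `w = 0`, with backtracking line search, run until the
#' sup-norm of the gradient falls below `tol`. When there are many more
#' genes than samples the Newton system is solved in the n-dimensional
#' sample space via the Woodbury identity, so panels of any width and
#' transcriptome-wide models are both cheap.
#'
#' @param t A [training_matrix()].
#' @param lambda Ridge strength (> 0). Default 1.
#' @param tol Gradient sup-norm tolerance. Default 1e-8.
#' @param max_iter Iteration cap. Default 10000.
#' @return A [stemness_model()] with the fitted weights and the objective
#'   value at the optimum.
#' @export
fit_oclr <- function(t, lambda = 1.0, tol = 1e-8, max_iter = 10000) {
  if (!inherits(t, "training_matrix"))
    stop("`t` must be a training_matrix", call. = FALSE)
  if (lambda <= 0) stop("lambda must be positive", call. = FALSE)
  X <- t$values
  n <- nrow(X)
  G <- ncol(X)
  w <- numeric(G)
  converged <- FALSE
  for (iter in seq_len(max_iter)) {
    g <- oclr_gradient(w, X, lambda)
    if (max(abs(g)) <= tol) {
      converged <- TRUE
      break
    }
    s <- drop(X %*% w)
    d2 <- pmax(stats::plogis(s) * stats::plogis(-s), 1e-12) / n
    if (G <= 2L * n) {
      H <- crossprod(X * d2, X)
      diag(H) <- diag(H) + lambda
      dir <- -solve(H, g)
    } else {
      # (lambda I + X' D X)^-1 g  via Woodbury in the n x n sample space
      K <- tcrossprod(X) / lambda           # X X' / lambda
      M <- diag(1 / d2, n) + K
      Xg <- drop(X %*% g)
      dir <- -(g - drop(crossprod(X, solve(M, Xg))) / lambda) / lambda
    }
    obj0 <- oclr_objective(w, X, lambda)
    slope <- sum(g * dir)
    step <- 1
    while (oclr_objective(w + step * dir, X, lambda) >
           obj0 + 1e-4 * step * slope && step > 1e-12) {
      step <- step / 2
    }
    w <- w + step * dir
  }
  if (!converged) {
    g <- oclr_gradient(w, X, lambda)
    stop(sprintf(
      "OCLR did not converge in %d iterations (gradient sup-norm %.3e > %.1e)",
      max_iter, max(abs(g)), tol), call. = FALSE)
  }
  stemness_model(t$gene_ids, w, lambda = lambda, n_train = n,
                 objective_value = oclr_objective(w, X, lambda))
}

#' Refit the model on a restricted feature panel
#'
#' Restricts the training matrix to the genes shared with a panel
#' (case-insensitive) and refits, so targeted probe or antibody panels get
#' weights trained on exactly the features they measure. The returned
#' model's gene set is the intersection, in training-matrix column order.
#'
#' @param t A [training_matrix()].
#' @param panel_genes Character vector of panel gene identifiers.
#' @param lambda Ridge strength passed to [fit_oclr()].
#' @param min_overlap Smallest usable intersection (default 10).
#' @param center Center the sliced matrix before fitting (default `FALSE`;
#'   see [center_genes()] for why).
#' @param ... Further arguments to [fit_oclr()].
#' @return A [stemness_model()] over the intersection genes.
#' @export
refit_on_panel <- function(t, panel_genes, lambda = 1.0, min_overlap = 10,
                           center = FALSE, ...) {
  panel <- unique(toupper(as.character(panel_genes)))
  keep <- which(t$gene_ids %in% panel)
  if (length(keep) < min_overlap)
    stop(sprintf(
      "panel shares only %d gene(s) with the training data (minimum %d)",
      length(keep), min_overlap), call. = FALSE)
  sub <- training_matrix(t$values[, keep, drop = FALSE], t$gene_ids[keep],
                         t$sample_ids, centered = t$centered)
  if (center) sub <- center_genes(sub)
  fit_oclr(sub, lambda = lambda, ...)
}
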