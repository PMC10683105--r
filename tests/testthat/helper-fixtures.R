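# Fixtures and independent oracles shared across the suite. Oracles are
# deliberately naive (per-cell loops, brute-force enumeration) so they stay
# independent of the vectorized implementation paths they check.

make_counts <- function(G, n, seed = 1, max_count = 20, genes = NULL,
                        cells = NULL) {
  set.seed(seed)
  vals <- matrix(rpois(G * n, lambda = max_count / 4), G, n)
  expression_matrix(vals,
                    genes %||% sprintf("G%03d", seq_len(G)),
                    cells %||% sprintf("c%03d", seq_len(n)),
                    "counts")
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# naive per-cell QC loop
qc_oracle <- function(m, mito_prefix = "MT-") {
  v <- as.matrix(m$values)
  mito <- startsWith(toupper(m$gene_ids), toupper(mito_prefix))
  do.call(rbind, lapply(seq_along(m$cell_ids), function(j) {
    col <- v[, j]
    tot <- sum(col)
    data.frame(cell_id = m$cell_ids[j],
               n_features = sum(col > 0),
               n_counts = tot,
               pct_mito = if (tot > 0) 100 * sum(col[mito]) / tot else 0,
               stringsAsFactors = FALSE)
  }))
}

# brute-force two-sided rank-sum p by enumerating all group assignments
exact_ranksum_oracle <- function(x, y) {
  n1 <- length(x)
  n <- n1 + length(y)
  r <- rank(c(x, y))
  obs <- sum(r[seq_len(n1)])
  mu <- n1 * (n + 1) / 2
  all_w <- apply(utils::combn(n, n1), 2, function(ix) sum(r[ix]))
  mean(abs(all_w - mu) >= abs(obs - mu) - 1e-9)
}

# golden-section minimizer of a 1-D function on [lo, hi]
golden_min <- function(f, lo, hi, tol = 1e-8) {
  phi <- (sqrt(5) - 1) / 2
  a <- lo; b <- hi
  c <- b - phi * (b - a); d <- a + phi * (b - a)
  while (abs(b - a) > tol) {
    if (f(c) < f(d)) b <- d else a <- c
    c <- b - phi * (b - a); d <- a + phi * (b - a)
  }
  (a + b) / 2
}

# objective of the one-class logistic fit, written independently of the
# package internals
oclr_obj_oracle <- function(w, X, lambda) {
  s <- as.vector(X %*% w)
  mean(log(1 + exp(-s))) + lambda / 2 * sum(w^2)
}

# generic-optimizer oracle: L-BFGS-B from stats::optim
oclr_optim_oracle <- function(X, lambda, start = NULL) {
  G <- ncol(X)
  gr <- function(w, X, lambda) {
    s <- as.vector(X %*% w)
    -as.vector(t(X) %*% (1 / (1 + exp(s)))) / nrow(X) + lambda * w
  }
  fit <- stats::optim(start %||% numeric(G), fn = oclr_obj_oracle,
                      gr = gr, X = X, lambda = lambda, method = "L-BFGS-B",
                      control = list(maxit = 5000, factr = 10, pgtol = 1e-12))
  fit
}

default_cohort <- function(seed = 1, ...) gen_cohort(sim_params(seed = seed, ...))
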