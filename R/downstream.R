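# Downstream interpretation of the stemness index: quartile stratification,
# Wilcoxon rank-sum differential expression with Bonferroni correction,
# effect sizes in the log-normalized convention, gene-list overlap
# statistics, marker-set cluster annotation, and bootstrap stability of the
# cohort median.

# round half away from zero (for positive x: half up); base round() is
# half-to-even and would not reproduce quartile counts like 45,079 from
# 180,315
round_half_up <- function(x, digits = 0) {
  f <- 10^digits
  floor(x * f + 0.5) / f
}

#' Stratify cells into top/bottom stemness quartiles
#'
#' The `k = round_half_up(0.25 N)` cells with the highest stemness index
#' form the top stratum, the `k` lowest the bottom, everything else the
#' middle, so the two compared groups always have equal size. Boundary ties
#' are broken by lexicographic `cell_id` so the strata are reproducible.
#'
#' @param s A scaled `score_result` ([minmax_scale()]), at least 4 cells.
#' @return A data.frame with `cell_id` and `stratum`
#'   (`top`/`middle`/`bottom`), carrying attributes `n_top` and `n_bottom`.
#' @export
stratify_quartiles <- function(s) {
  if (is.null(s$stemness_index))
    stop("stemness_index absent; run minmax_scale() first", call. = FALSE)
  n <- length(s$cell_ids)
  if (n < 4) stop("at least 4 scored cells are required", call. = FALSE)
  k <- as.integer(round_half_up(0.25 * n))
  ord_low <- order(s$stemness_index, s$cell_ids)
  ord_high <- order(-s$stemness_index, s$cell_ids)
  stratum <- rep("middle", n)
  stratum[ord_low[seq_len(k)]] <- "bottom"
  stratum[ord_high[seq_len(k)]] <- "top"
  out <- data.frame(cell_id = s$cell_ids, stratum = stratum,
                    stringsAsFactors = FALSE)
  attr(out, "n_top") <- k
  attr(out, "n_bottom") <- k
  out
}

# two-sided rank-sum p for x vs y: exact enumeration when both groups have
# <= `exact_max` observations (handles ties by enumerating the observed
# ranks), otherwise normal approximation with tie correction and
# continuity correction
rank_sum_p <- function(x, y, exact_max = 7) {
  n1 <- length(x)
  n2 <- length(y)
  n <- n1 + n2
  r <- rank(c(x, y))
  W <- sum(r[seq_len(n1)])
  mu <- n1 * (n + 1) / 2
  if (max(n1, n2) <= exact_max) {
    combos <- utils::combn(n, n1)
    Wdist <- colSums(matrix(r[combos], nrow = n1))
    mean(abs(Wdist - mu) >= abs(W - mu) - 1e-9)
  } else {
    ties <- table(r)
    sig2 <- n1 * n2 / 12 * ((n + 1) - sum(ties^3 - ties) / (n * (n - 1)))
    if (sig2 <= 0) return(1)
    z <- (W - mu - sign(W - mu) * 0.5) / sqrt(sig2)
    min(1, 2 * stats::pnorm(-abs(z)))
  }
}

#' Per-gene effect sizes between two cell groups
#'
#' On the log-normalized layer: `log2_fc` is the log2 ratio of the groups'
#' mean de-logged expression (with a pseudocount of 1 in numerator and
#' denominator), and `pct_diff` the difference, in percentage points, of
#' the fraction of cells expressing the gene (value > 0). This is the
#' convention of the standard single-cell marker tests, so fold-change
#' cutoffs transfer directly.
#'
#' @param m A normalized [expression_matrix()].
#' @param top_ids,bottom_ids Cell identifiers of the two groups.
#' @return A data.frame with `gene`, `log2_fc`, `pct_diff`.
#' @export
effect_sizes <- function(m, top_ids, bottom_ids) {
  v <- dense_values(m)
  it <- match(top_ids, m$cell_ids)
  ib <- match(bottom_ids, m$cell_ids)
  if (anyNA(it) || anyNA(ib))
    stop("group contains cell id(s) absent from the matrix", call. = FALSE)
  xt <- v[, it, drop = FALSE]
  xb <- v[, ib, drop = FALSE]
  log2_fc <- log2((rowMeans(expm1(xt)) + 1) / (rowMeans(expm1(xb)) + 1))
  pct_diff <- 100 * (rowMeans(xt > 0) - rowMeans(xb > 0))
  data.frame(gene = m$gene_ids, log2_fc = as.numeric(log2_fc),
             pct_diff = as.numeric(pct_diff), stringsAsFactors = FALSE)
}

#' Wilcoxon rank-sum differential expression, top vs bottom stratum
#'
#' For each gene, a two-sided rank-sum test between the two groups — exact
#' enumeration when both groups have at most 7 cells, a tie-corrected
#' normal approximation with continuity correction otherwise — with
#' Bonferroni correction over the genes tested. Effect sizes come from
#' [effect_sizes()]; a gene is called significant when
#' `p_adj < alpha` and `|log2_fc| > fc_floor`.
#'
#' @param m A normalized [expression_matrix()].
#' @param top_ids,bottom_ids Disjoint groups of cell identifiers, each with
#'   at least 3 cells.
#' @param alpha Adjusted-p significance cutoff (default 0.05).
#' @param fc_floor Absolute log2 fold-change floor (default 0.5).
#' @return A data.frame with `gene`, `p_value`, `p_adj`, `log2_fc`,
#'   `pct_diff`, `significant`.
#' @export
wilcoxon_deg <- function(m, top_ids, bottom_ids, alpha = 0.05,
                         fc_floor = 0.5) {
  if (length(intersect(top_ids, bottom_ids)) > 0)
    stop("top and bottom groups overlap", call. = FALSE)
  if (length(top_ids) < 3 || length(bottom_ids) < 3)
    stop("each group needs at least 3 cells", call. = FALSE)
  v <- dense_values(m)
  it <- match(top_ids, m$cell_ids)
  ib <- match(bottom_ids, m$cell_ids)
  if (anyNA(it) || anyNA(ib))
    stop("group contains cell id(s) absent from the matrix", call. = FALSE)
  p <- vapply(seq_len(nrow(v)), function(g) {
    rank_sum_p(v[g, it], v[g, ib])
  }, numeric(1))
  eff <- effect_sizes(m, top_ids, bottom_ids)
  out <- data.frame(gene = m$gene_ids, p_value = p,
                    p_adj = stats::p.adjust(p, method = "bonferroni"),
                    log2_fc = eff$log2_fc, pct_diff = eff$pct_diff,
                    stringsAsFactors = FALSE)
  out$significant <- out$p_adj < alpha & abs(out$log2_fc) > fc_floor
  out
}

#' Overlap statistics for two gene lists
#'
#' Size of the intersection and, for each list, the intersection as a
#' percentage of that list, reported at one decimal (round half up).
#' Matching is case-insensitive. An empty list's percentage is `NA` rather
#' than a division error.
#'
#' @param list_a,list_b Character vectors of gene identifiers.
#' @return A list with `n_common`, `pct_of_a`, `pct_of_b`.
#' @export
overlap_stats <- function(list_a, list_b) {
  a <- unique(toupper(as.character(list_a)))
  b <- unique(toupper(as.character(list_b)))
  n_common <- length(intersect(a, b))
  pct <- function(n) if (n == 0) NA_real_ else
    round_half_up(100 * n_common / n, 1)
  list(n_common = n_common, pct_of_a = pct(length(a)),
       pct_of_b = pct(length(b)))
}

#' Annotate clusters by marker-set scoring
#'
#' For each cluster and candidate label, the score is the mean — over the
#' label's marker genes present in the matrix — of the z-score of that
#' cluster's mean expression of the gene across clusters. Each cluster gets
#' the highest-scoring label; ties are broken alphabetically with a
#' warning.
#'
#' @param m A normalized [expression_matrix()].
#' @param cluster_of Named character vector mapping every cell id of `m` to
#'   a cluster.
#' @param marker_sets Named list of character vectors: candidate label ->
#'   marker genes.
#' @return A list with `labels` (named vector cluster -> label) and
#'   `scores` (clusters x labels matrix).
#' @export
annotate_clusters <- function(m, cluster_of, marker_sets) {
  missing <- setdiff(m$cell_ids, names(cluster_of))
  if (length(missing) > 0)
    stop("cells without a cluster assignment: ",
         paste(utils::head(missing, 5), collapse = ", "), call. = FALSE)
  cl <- as.character(cluster_of[m$cell_ids])
  clusters <- sort(unique(cl))
  v <- dense_values(m)
  cmean <- vapply(clusters, function(cc)
    rowMeans(v[, cl == cc, drop = FALSE]), numeric(nrow(v)))
  mu <- rowMeans(cmean)
  sdv <- apply(cmean, 1, stats::sd)
  z <- (cmean - mu) / ifelse(sdv > 0, sdv, 1)
  z[sdv == 0, ] <- 0
  genes_up <- toupper(m$gene_ids)
  scores <- vapply(names(marker_sets), function(lab) {
    hit <- genes_up %in% toupper(marker_sets[[lab]])
    if (!any(hit))
      stop("marker set '", lab, "' shares no genes with the matrix",
           call. = FALSE)
    colMeans(z[hit, , drop = FALSE])
  }, numeric(length(clusters)))
  scores <- matrix(scores, nrow = length(clusters),
                   dimnames = list(clusters, names(marker_sets)))
  labels <- apply(scores, 1, function(row) {
    best <- names(which(row == max(row)))
    if (length(best) > 1)
      warning("tied cluster label scores; choosing alphabetically first of: ",
              paste(best, collapse = ", "))
    sort(best)[1]
  })
  list(labels = labels, scores = scores)
}

#' Bootstrap stability of the cohort median stemness index
#'
#' Draws, for each requested subset size, `reps` subsets of cells (without
#' replacement by default) and records the median stemness index of each —
#' the dispersion of those medians as the subset grows toward the full
#' cohort measures how stable the index is to cell sampling. At
#' `size == N` every subset is the full cohort, so every rep's median
#' equals the full-cohort median exactly.
#'
#' @param s A scaled `score_result`.
#' @param sizes Subset sizes, each at most the cohort size.
#' @param reps Draws per size (default 100).
#' @param seed Integer seed; the full table is a pure function of it.
#' @param replace Draw with replacement instead (default `FALSE`).
#' @return A data.frame with `size`, `rep`, `median_index`.
#' @export
bootstrap_stability <- function(s, sizes, reps = 100, seed = 1,
                                replace = FALSE) {
  if (is.null(s$stemness_index))
    stop("stemness_index absent; run minmax_scale() first", call. = FALSE)
  n <- length(s$stemness_index)
  if (any(sizes > n))
    stop(sprintf("subset size %d exceeds cohort size %d",
                 max(sizes), n), call. = FALSE)
  if (reps < 1) stop("reps must be >= 1", call. = FALSE)
  set.seed(seed)
  out <- expand.grid(rep = seq_len(reps), size = as.integer(sizes))[, 2:1]
  out$median_index <- NA_real_
  row <- 1L
  for (k in as.integer(sizes)) {
    for (r in seq_len(reps)) {
      idx <- sample.int(n, k, replace = replace)
      out$median_index[row] <- stats::median(s$stemness_index[idx])
      row <- row + 1L
    }
  }
  rownames(out) <- NULL
  out
}
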