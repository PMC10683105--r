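# Per-cell stemness scoring: Spearman correlation between the model's gene
# weights and each cell's expression over the matched genes, then min-max
# scaling of the correlations over the cohort to a [0,1] stemness index.
# Because Spearman operates on ranks, the score is invariant to any
# per-cell strictly monotone transform of expression, so raw counts and
# log-normalized values give identical correlations.

#' Spearman correlation of a weight vector and an expression profile
#'
#' Pearson correlation of average ranks (ties share the mean of the ranks
#' they span). If either vector is constant in rank the correlation is
#' undefined; 0 is returned with a warning so cohort-level scoring never
#' produces NaN.
#'
#' @param w Numeric weight vector.
#' @param p Numeric expression profile of equal length (>= 3).
#' @return The correlation in [-1, 1].
#' @export
spearman_rho <- function(w, p) {
  if (length(w) != length(p))
    stop(sprintf("length mismatch: %d weights vs %d expression values",
                 length(w), length(p)), call. = FALSE)
  if (length(w) < 3)
    stop("at least 3 paired values are needed", call. = FALSE)
  if (max(w) == min(w) || max(p) == min(p)) {
    warning("zero rank variance; returning rho = 0")
    return(0)
  }
  stats::cor(w, p, method = "spearman")
}

#' Score every cell of a cohort against a model
#'
#' Matches the matrix's genes to the model with [match_genes()] and
#' computes the per-cell Spearman correlation over the shared genes. The
#' scaled stemness index is added separately by [minmax_scale()] so raw
#' correlations remain available.
#'
#' @param m An [expression_matrix()] (normalized values preferred; any
#'   per-cell monotone layer gives the same correlations).
#' @param model A [stemness_model()].
#' @param min_overlap Passed to [match_genes()].
#' @return A list of class `score_result` with `cell_ids`, `rho`,
#'   `stemness_index` (NULL until scaled), `n_genes_used`, `model_id`.
#' @export
score_cells <- function(m, model, min_overlap = 10) {
  matched <- match_genes(m, model, min_overlap = min_overlap)
  v <- dense_values(matched$matrix)
  w <- matched$weights
  wc <- max(w) > min(w)
  n_flat <- 0L
  rho <- vapply(seq_len(ncol(v)), function(j) {
    p <- v[, j]
    if (!wc || max(p) == min(p)) {
      n_flat <<- n_flat + 1L
      return(0)
    }
    stats::cor(w, p, method = "spearman")
  }, numeric(1))
  if (n_flat > 0)
    warning(sprintf("%d cell(s) had zero rank variance; their rho was set to 0",
                    n_flat))
  structure(list(cell_ids = matched$matrix$cell_ids, rho = rho,
                 stemness_index = NULL,
                 n_genes_used = matched$n_matched,
                 model_id = sprintf("oclr_%dg_lambda%s",
                                    length(model$gene_ids),
                                    format(model$lambda))),
            class = "score_result")
}

#' @export
print.score_result <- function(x, ...) {
  cat(sprintf("score_result: %d cells over %d genes (%s)\n",
              length(x$cell_ids), x$n_genes_used,
              if (is.null(x$stemness_index)) "unscaled" else "scaled"))
  invisible(x)
}

#' Min-max scale correlations to the [0,1] stemness index
#'
#' `index_i = (rho_i - min rho) / (max rho - min rho)` over the whole
#' scored cohort, so the least stem-like cell maps to 0 and the most to 1.
#' A degenerate cohort (all correlations equal) maps to 0.5 everywhere,
#' with a warning.
#'
#' @param s A `score_result` from [score_cells()].
#' @return The same object with `stemness_index` filled in.
#' @export
minmax_scale <- function(s) {
  if (length(s$rho) < 1) stop("no cells to scale", call. = FALSE)
  lo <- min(s$rho)
  hi <- max(s$rho)
  if (hi == lo) {
    warning("all correlations identical; stemness index set to 0.5")
    s$stemness_index <- rep(0.5, length(s$rho))
  } else {
    s$stemness_index <- (s$rho - lo) / (hi - lo)
  }
  s
}

#' Score a spatial cohort
#'
#' Identical mathematics to [score_cells()] + [minmax_scale()]; the spatial
#' flavor only joins the per-spot metadata (centroid coordinates, sample,
#' label) onto the result, preserving the tissue context for mapping the
#' index back onto the section.
#'
#' @param m An [expression_matrix()] of spots or segmented cells.
#' @param model A [stemness_model()].
#' @param meta Metadata data.frame (see [read_cell_metadata()]) covering
#'   every cell of `m`.
#' @param min_overlap Passed to [match_genes()].
#' @return A data.frame with `cell_id`, `rho`, `stemness_index`, `sample`,
#'   `label`, `x`, `y`.
#' @export
score_spatial <- function(m, model, meta, min_overlap = 10) {
  missing <- setdiff(m$cell_ids, meta$cell_id)
  if (length(missing) > 0)
    stop("metadata lacks cell(s): ", paste(missing, collapse = ", "),
         call. = FALSE)
  s <- minmax_scale(score_cells(m, model, min_overlap = min_overlap))
  idx <- match(s$cell_ids, meta$cell_id)
  out <- data.frame(cell_id = s$cell_ids, rho = s$rho,
                    stemness_index = s$stemness_index,
                    stringsAsFactors = FALSE)
  for (col in c("sample", "label", "x", "y"))
    out[[col]] <- if (col %in% names(meta)) meta[[col]][idx] else NA
  out
}
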