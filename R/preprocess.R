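# Standard single-cell preprocessing: per-cell QC metrics, threshold
# filtering and log-normalization, plus matching of matrix genes against a
# model's gene set.

#' Quality-control thresholds
#'
#' Defaults follow common single-cell practice for human tissue: between
#' 200 and 5000 detected genes, under 10% mitochondrial counts, and more
#' than 200 total counts per cell. All four comparisons are strict, so
#' boundary cells are removed. Mitochondrial genes are identified by symbol
#' prefix (`MT-` for human).
#'
#' @param min_features,max_features Detected-gene bounds (exclusive).
#' @param max_pct_mito Mitochondrial percentage bound (exclusive), in
#'   0--100.
#' @param min_counts Total-count lower bound (exclusive).
#' @param mito_prefix Gene-symbol prefix marking mitochondrial genes
#'   (matched case-insensitively).
#' @return A list of class `qc_thresholds`.
#' @export
qc_thresholds <- function(min_features = 200, max_features = 5000,
                          max_pct_mito = 10, min_counts = 200,
                          mito_prefix = "MT-") {
  if (min_features >= max_features)
    stop("min_features must be below max_features", call. = FALSE)
  if (max_pct_mito < 0 || max_pct_mito > 100)
    stop("max_pct_mito must lie in [0, 100]", call. = FALSE)
  structure(list(min_features = min_features, max_features = max_features,
                 max_pct_mito = max_pct_mito, min_counts = min_counts,
                 mito_prefix = mito_prefix),
            class = "qc_thresholds")
}

#' Per-cell QC metrics
#'
#' For each cell: the number of genes with a positive count, the total
#' count, and the percentage of counts from mitochondrial genes. Cells with
#' zero total counts get `pct_mito = 0` by definition (no counts, so no
#' mitochondrial fraction).
#'
#' @param m An [expression_matrix()] with `layer_tag = "counts"`.
#' @param mito_prefix Gene-symbol prefix marking mitochondrial genes.
#' @return A data.frame with columns `cell_id`, `n_features`, `n_counts`,
#'   `pct_mito`.
#' @export
compute_qc <- function(m, mito_prefix = "MT-") {
  if (m$layer_tag != "counts")
    stop("QC metrics are defined on the counts layer, got '", m$layer_tag, "'",
         call. = FALSE)
  v <- m$values
  n_counts <- Matrix::colSums(v)
  n_features <- Matrix::colSums(v > 0)
  mito <- startsWith(toupper(m$gene_ids), toupper(mito_prefix))
  mito_counts <- if (any(mito)) Matrix::colSums(v[mito, , drop = FALSE]) else
    numeric(length(m$cell_ids))
  pct_mito <- ifelse(n_counts > 0, 100 * mito_counts / n_counts, 0)
  data.frame(cell_id = m$cell_ids, n_features = as.integer(n_features),
             n_counts = as.numeric(n_counts), pct_mito = pct_mito,
             stringsAsFactors = FALSE)
}

#' Filter cells on QC thresholds
#'
#' Keeps cells satisfying all of: `n_features > min_features`,
#' `n_features < max_features`, `pct_mito < max_pct_mito`,
#' `n_counts > min_counts` (all strict). The gene set and the order of
#' surviving cells are unchanged.
#'
#' @param m An [expression_matrix()] with counts.
#' @param thresholds A [qc_thresholds()].
#' @return The filtered [expression_matrix()].
#' @export
qc_filter <- function(m, thresholds = qc_thresholds()) {
  qc <- compute_qc(m, thresholds$mito_prefix)
  keep <- qc$n_features > thresholds$min_features &
    qc$n_features < thresholds$max_features &
    qc$pct_mito < thresholds$max_pct_mito &
    qc$n_counts > thresholds$min_counts
  if (!any(keep))
    stop("QC filtering removed every cell; review the thresholds against ",
         "compute_qc() output", call. = FALSE)
  subset_matrix(m, cells = which(keep))
}

#' Log-normalize a count matrix
#'
#' Per-cell normalization `ln(1 + v * scale_factor / T)` where `T` is the
#' cell's total count. Cells with `T = 0` map to all-zero profiles (QC
#' normally removes them first). The result carries
#' `layer_tag = "normalized"`.
#'
#' @param m An [expression_matrix()] with counts.
#' @param scale_factor Library-size target (default 10,000).
#' @return A normalized [expression_matrix()].
#' @export
log_normalize <- function(m, scale_factor = 10000) {
  if (m$layer_tag != "counts")
    stop("log_normalize expects the counts layer, got '", m$layer_tag, "'",
         call. = FALSE)
  v <- dense_values(m)
  if (any(v < 0)) stop("negative counts are not allowed", call. = FALSE)
  totals <- colSums(v)
  scale <- ifelse(totals > 0, scale_factor / totals, 0)
  out <- log1p(sweep(v, 2, scale, "*"))
  expression_matrix(out, m$gene_ids, m$cell_ids, "normalized")
}

#' Match matrix genes against a model
#'
#' Intersects the matrix's gene identifiers with the model's
#' (case-insensitively) and returns the aligned submatrix and weight
#' vector, ordered as in the model. Scoring a matrix against a model always
#' goes through this step, so a restricted panel is scored on exactly the
#' features the model and panel share.
#'
#' @param m An [expression_matrix()].
#' @param model A [stemness_model()].
#' @param min_overlap Smallest usable intersection (default 10); a rank
#'   correlation over fewer features is too unstable to report.
#' @return A list with `matrix` (the aligned [expression_matrix()]),
#'   `weights` (aligned numeric vector) and `n_matched`.
#' @export
match_genes <- function(m, model, min_overlap = 10) {
  mg <- toupper(m$gene_ids)
  keep <- which(model$gene_ids %in% mg)   # model order
  idx <- match(model$gene_ids[keep], mg)
  n_matched <- length(idx)
  if (n_matched < min_overlap)
    stop(sprintf(
      "only %d gene(s) shared between matrix and model (minimum %d)",
      n_matched, min_overlap), call. = FALSE)
  list(matrix = subset_matrix(m, genes = idx),
       weights = model$w[keep],
       n_matched = n_matched)
}
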