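#' Construct an expression matrix
#'
#' The central container of the package: a genes-by-cells numeric matrix
#' with gene and cell identifiers and a layer tag recording what the values
#' are. Counts and intensities must be non-negative; normalized values may
#' be any real number.
#'
#' @param values Numeric matrix (genes in rows, cells in columns), dense or a
#'   `Matrix` sparse matrix.
#' @param gene_ids Character vector of gene (or protein channel) identifiers,
#'   one per row. Must be unique after uppercasing; gene matching throughout
#'   the package is case-insensitive.
#' @param cell_ids Character vector of cell/spot identifiers, one per column.
#' @param layer_tag One of `"counts"`, `"normalized"`, `"intensity"`.
#'
#' @return An object of class `ExpressionMatrix`: a list with elements
#'   `values`, `gene_ids`, `cell_ids`, `layer_tag`.
#' @export
expression_matrix <- function(values, gene_ids, cell_ids,
                              layer_tag = c("counts", "normalized", "intensity")) {
  layer_tag <- match.arg(layer_tag)
  if (!(is.matrix(values) || methods::is(values, "Matrix")))
    stop("`values` must be a matrix", call. = FALSE)
  gene_ids <- as.character(gene_ids)
  cell_ids <- as.character(cell_ids)
  if (nrow(values) != length(gene_ids))
    stop(sprintf("row count (%d) does not match number of gene_ids (%d)",
                 nrow(values), length(gene_ids)), call. = FALSE)
  if (ncol(values) != length(cell_ids))
    stop(sprintf("column count (%d) does not match number of cell_ids (%d)",
                 ncol(values), length(cell_ids)), call. = FALSE)
  up <- toupper(gene_ids)
  if (anyDuplicated(up))
    stop("duplicate gene identifiers (case-insensitive): ",
         paste(unique(gene_ids[duplicated(up)]), collapse = ", "), call. = FALSE)
  if (anyDuplicated(cell_ids))
    stop("duplicate cell identifiers: ",
         paste(unique(cell_ids[duplicated(cell_ids)]), collapse = ", "), call. = FALSE)
  if (layer_tag %in% c("counts", "intensity") && any(values < 0))
    stop(sprintf("%s layer must be non-negative", layer_tag), call. = FALSE)
  dimnames(values) <- list(gene_ids, cell_ids)
  structure(list(values = values, gene_ids = gene_ids, cell_ids = cell_ids,
                 layer_tag = layer_tag),
            class = "ExpressionMatrix")
}

#' @export
print.ExpressionMatrix <- function(x, ...) {
  cat(sprintf("ExpressionMatrix: %d genes x %d cells [%s]\n",
              length(x$gene_ids), length(x$cell_ids), x$layer_tag))
  invisible(x)
}

#' @export
dim.ExpressionMatrix <- function(x) dim(x$values)

# dense numeric view of the values (sparse inputs are expanded)
dense_values <- function(m) {
  v <- m$values
  if (methods::is(v, "Matrix")) v <- as.matrix(v)
  storage.mode(v) <- "double"
  v
}

# subset rows/columns, preserving class and layer
subset_matrix <- function(m, genes = NULL, cells = NULL) {
  v <- m$values
  gi <- m$gene_ids
  ci <- m$cell_ids
  if (!is.null(genes)) {
    v <- v[genes, , drop = FALSE]
    gi <- gi[genes]
  }
  if (!is.null(cells)) {
    v <- v[, cells, drop = FALSE]
    ci <- ci[cells]
  }
  expression_matrix(v, gi, ci, m$layer_tag)
}
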