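# Readers and writers for the formats the tool touches: 10x-style Matrix
# Market triplet directories, dense delimited tables, cell metadata, model
# weight files and score tables. All readers validate strictly and refuse
# malformed input rather than coercing.

open_maybe_gz <- function(path) {
  if (grepl("\\.gz$", path)) gzfile(path, "r") else file(path, "r")
}

find_part <- function(dir_path, stems) {
  for (stem in stems) {
    for (ext in c("", ".gz")) {
      p <- file.path(dir_path, paste0(stem, ext))
      if (file.exists(p)) return(p)
    }
  }
  stop("no file matching ", paste(stems, collapse = " / "), " in ", dir_path,
       call. = FALSE)
}

#' Read a 10x-style Matrix Market directory
#'
#' Expects `matrix.mtx(.gz)` plus a features/genes table and a barcodes
#' table in the directory. The triplet file uses the general coordinate
#' dialect with 1-based indices; genes are rows, cells are columns;
#' coordinates not listed are zero. When the features table has two or more
#' columns the second (the gene symbol in 10x output) is used as the gene
#' identifier, otherwise the first. Gene identifiers are uppercased on read.
#'
#' @param dir_path Directory containing the three files.
#' @param layer_tag Layer of the stored values; vendor matrices do not
#'   declare whether they hold raw counts or pre-normalized values, so the
#'   caller states it (default `"counts"`).
#' @return An [expression_matrix()].
#' @export
read_matrix_market <- function(dir_path, layer_tag = "counts") {
  if (!dir.exists(dir_path)) stop("not a directory: ", dir_path, call. = FALSE)
  mtx_path <- find_part(dir_path, "matrix.mtx")
  feat_path <- find_part(dir_path, c("features.tsv", "genes.tsv"))
  bc_path <- find_part(dir_path, "barcodes.tsv")

  con <- open_maybe_gz(mtx_path)
  on.exit(close(con), add = TRUE)
  m <- Matrix::readMM(con)
  m <- methods::as(m, "TsparseMatrix")
  if (anyDuplicated(cbind(m@i, m@j)))
    stop("duplicate triplet coordinates in ", mtx_path, call. = FALSE)

  feats <- utils::read.delim(feat_path, header = FALSE,
                             colClasses = "character")
  barcodes <- utils::read.delim(bc_path, header = FALSE,
                                colClasses = "character")[[1]]
  gene_ids <- toupper(if (ncol(feats) >= 2) feats[[2]] else feats[[1]])
  if (nrow(m) != length(gene_ids))
    stop(sprintf("matrix header declares %d rows but features table has %d entries",
                 nrow(m), length(gene_ids)), call. = FALSE)
  if (ncol(m) != length(barcodes))
    stop(sprintf("matrix header declares %d columns but barcodes table has %d entries",
                 ncol(m), length(barcodes)), call. = FALSE)
  expression_matrix(methods::as(m, "CsparseMatrix"), gene_ids, barcodes, layer_tag)
}

#' Write an expression matrix as a Matrix Market directory
#'
#' Inverse of [read_matrix_market()]: writes `matrix.mtx`, `features.tsv`
#' and `barcodes.tsv` (optionally gzipped) into `dir_path`.
#'
#' @param m An [expression_matrix()].
#' @param dir_path Output directory (created if absent).
#' @param gzip Compress the three files.
#' @return `dir_path`, invisibly.
#' @export
write_matrix_market <- function(m, dir_path, gzip = FALSE) {
  dir.create(dir_path, showWarnings = FALSE, recursive = TRUE)
  sm <- m$values
  if (!methods::is(sm, "Matrix")) sm <- Matrix::Matrix(sm, sparse = TRUE)
  sm <- methods::as(methods::as(sm, "CsparseMatrix"), "generalMatrix")
  ext <- if (gzip) ".gz" else ""
  mtx <- file.path(dir_path, paste0("matrix.mtx", ext))
  if (gzip) {
    tmp <- tempfile(fileext = ".mtx")
    Matrix::writeMM(sm, tmp)
    lines <- readLines(tmp)
    con <- gzfile(mtx, "w")
    writeLines(lines, con)
    close(con)
    unlink(tmp)
  } else {
    Matrix::writeMM(sm, mtx)
  }
  write_one <- function(x, stem) {
    p <- file.path(dir_path, paste0(stem, ext))
    con <- if (gzip) gzfile(p, "w") else file(p, "w")
    writeLines(x, con)
    close(con)
  }
  write_one(m$gene_ids, "features.tsv")
  write_one(m$cell_ids, "barcodes.tsv")
  invisible(dir_path)
}

#' Read a dense delimited expression table
#'
#' One header row, one identifier column, numeric body. Comma-separated for
#' `.csv` paths, tab-separated otherwise. Protein-imaging exports
#' conventionally put channels (genes) in rows; `genes_in = "columns"` flips
#' a transposed table.
#'
#' @param path File path.
#' @param genes_in `"rows"` (default) or `"columns"`.
#' @param layer_tag Layer of the stored values (default `"intensity"`, the
#'   protein-panel case this reader mainly serves).
#' @return An [expression_matrix()].
#' @export
read_dense_table <- function(path, genes_in = c("rows", "columns"),
                             layer_tag = "intensity") {
  genes_in <- match.arg(genes_in)
  sep <- if (grepl("\\.csv(\\.gz)?$", path)) "," else "\t"
  df <- utils::read.table(path, header = TRUE, sep = sep, check.names = FALSE,
                          colClasses = "character", comment.char = "")
  ids <- df[[1]]
  body <- df[, -1, drop = FALSE]
  vals <- suppressWarnings(
    matrix(as.numeric(as.matrix(body)), nrow = nrow(body),
           dimnames = list(NULL, colnames(body))))
  bad <- which(is.na(vals) & !is.na(as.matrix(body)), arr.ind = TRUE)
  if (nrow(bad) > 0)
    stop(sprintf("non-numeric value '%s' at data row %d, column '%s'",
                 as.matrix(body)[bad[1, 1], bad[1, 2]],
                 bad[1, 1], colnames(body)[bad[1, 2]]), call. = FALSE)
  if (anyNA(vals))
    stop("missing values in expression table ", path, call. = FALSE)
  if (genes_in == "rows") {
    gene_ids <- toupper(ids)
    cell_ids <- colnames(body)
  } else {
    vals <- t(vals)
    gene_ids <- toupper(colnames(body))
    cell_ids <- ids
  }
  if (anyDuplicated(gene_ids))
    stop("duplicate gene identifier(s): ",
         paste(unique(gene_ids[duplicated(gene_ids)]), collapse = ", "),
         call. = FALSE)
  expression_matrix(vals, gene_ids, cell_ids, layer_tag)
}

#' Read a cell metadata table
#'
#' Delimited text with a `cell_id` column and optional `sample`, `label`,
#' `x`, `y` columns (centroid coordinates, stored as given — no unit
#' conversion). `x` and `y` must be present together or not at all.
#'
#' @param path File path (comma-separated for `.csv`, tab otherwise).
#' @return A data.frame with columns `cell_id`, `sample`, `label`, `x`, `y`;
#'   absent optional fields are `NA`.
#' @export
read_cell_metadata <- function(path) {
  sep <- if (grepl("\\.csv(\\.gz)?$", path)) "," else "\t"
  df <- utils::read.table(path, header = TRUE, sep = sep, check.names = FALSE,
                          stringsAsFactors = FALSE)
  if (!"cell_id" %in% names(df))
    stop("metadata file lacks a cell_id column", call. = FALSE)
  df$cell_id <- as.character(df$cell_id)
  if (anyDuplicated(df$cell_id))
    stop("duplicate cell_id: ",
         paste(unique(df$cell_id[duplicated(df$cell_id)]), collapse = ", "),
         call. = FALSE)
  if (xor("x" %in% names(df), "y" %in% names(df)))
    stop("coordinate columns must come in pairs: found one of x/y without the other",
         call. = FALSE)
  out <- data.frame(cell_id = df$cell_id, stringsAsFactors = FALSE)
  out$sample <- if ("sample" %in% names(df)) as.character(df$sample) else NA_character_
  out$label <- if ("label" %in% names(df)) as.character(df$label) else NA_character_
  if ("x" %in% names(df)) {
    out$x <- as.numeric(df$x)
    out$y <- as.numeric(df$y)
    if (any(is.na(out$x) != is.na(out$y)))
      stop("cells with x but not y (or vice versa): ",
           paste(out$cell_id[is.na(out$x) != is.na(out$y)], collapse = ", "),
           call. = FALSE)
  } else {
    out$x <- NA_real_
    out$y <- NA_real_
  }
  out
}

#' Read / write a stemness model file
#'
#' The model file is a two-column tab-separated table (`gene`, `weight`)
#' preceded by `#`-prefixed metadata lines (`lambda`, `n_training_samples`,
#' `objective`, `created`). Weights are written with 17 significant digits
#' so a write/read round trip reproduces them exactly.
#'
#' @param path File path.
#' @return `read_model`: a [stemness_model()]. `write_model`: `path`,
#'   invisibly.
#' @export
read_model <- function(path) {
  lines <- readLines(path)
  hdr <- grep("^#", lines, value = TRUE)
  meta <- list()
  for (h in hdr) {
    kv <- sub("^#\\s*", "", h)
    key <- trimws(sub(":.*$", "", kv))
    val <- trimws(sub("^[^:]*:", "", kv))
    meta[[key]] <- val
  }
  df <- utils::read.table(text = lines[!grepl("^#", lines)], header = TRUE,
                          sep = "\t", stringsAsFactors = FALSE)
  if (!all(c("gene", "weight") %in% names(df)))
    stop("model file must have 'gene' and 'weight' columns", call. = FALSE)
  w <- as.numeric(df$weight)
  if (anyNA(w) || any(is.nan(w)))
    stop("missing or NaN weight(s) in model file for gene(s): ",
         paste(df$gene[is.na(w) | is.nan(w)], collapse = ", "), call. = FALSE)
  stemness_model(gene_ids = toupper(df$gene), w = w,
                 lambda = as.numeric(meta$lambda %||% NA),
                 n_train = as.integer(meta$n_training_samples %||% NA),
                 objective_value = as.numeric(meta$objective %||% NA))
}

#' @param model A [stemness_model()].
#' @rdname read_model
#' @export
write_model <- function(model, path) {
  hdr <- c(sprintf("# lambda: %s", format(model$lambda, digits = 17)),
           sprintf("# n_training_samples: %s", model$n_train),
           sprintf("# objective: %s",
                   format(model$objective_value, digits = 17)),
           sprintf("# created: %s", format(Sys.time(), "%Y-%m-%dT%H:%M:%S%z")))
  body <- sprintf("%s\t%s", model$gene_ids,
                  vapply(model$w, function(v) sprintf("%.17g", v), ""))
  writeLines(c(hdr, "gene\tweight", body), path)
  invisible(path)
}

#' Write per-cell scores to a tab-separated table
#'
#' Columns are `cell_id`, `rho`, `stemness_index`, plus `sample`, `label`,
#' `x`, `y` when metadata is supplied. Cell order follows the score object.
#'
#' @param scores A score result from [score_cells()] / [minmax_scale()].
#' @param path Output path.
#' @param meta Optional metadata data.frame (see [read_cell_metadata()]);
#'   must cover every scored cell.
#' @return `path`, invisibly.
#' @export
write_scores <- function(scores, path, meta = NULL) {
  df <- data.frame(cell_id = scores$cell_ids, rho = scores$rho,
                   stemness_index = if (is.null(scores$stemness_index))
                     NA_real_ else scores$stemness_index,
                   stringsAsFactors = FALSE)
  if (!is.null(meta)) {
    missing <- setdiff(df$cell_id, meta$cell_id)
    if (length(missing) > 0)
      stop("metadata lacks scored cell(s): ", paste(missing, collapse = ", "),
           call. = FALSE)
    idx <- match(df$cell_id, meta$cell_id)
    for (col in intersect(c("sample", "label", "x", "y"), names(meta)))
      df[[col]] <- meta[[col]][idx]
  }
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
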