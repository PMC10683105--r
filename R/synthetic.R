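# Synthetic cohorts with known per-cell stemness ground truth. Each cell's
# expected expression is a convex mixture alpha * stem + (1 - alpha) * diff
# of two signatures sharing a common baseline, observed through Poisson
# count noise at a chosen library size. Every generator is a pure function
# of its parameters including the seed.

#' Simulation parameters
#'
#' Defaults describe a mid-sized validation cohort: 500 genes, 1000 cells,
#' 30 stem-class training profiles, uniform per-cell stem fraction, an
#' expected 5000 counts per cell, and Gaussian noise of 0.2 (log scale) on
#' training profiles.
#'
#' @param G Gene count (>= 20).
#' @param n_cells Cohort size.
#' @param n_train Training-profile count.
#' @param alpha_dist Function `n -> n` stem fractions in [0,1]; default
#'   `runif`.
#' @param lib_size Expected per-cell total counts.
#' @param train_noise_sd Gaussian sd on log-scale training profiles.
#' @param blob Optional spatial stem-rich disc:
#'   `list(center_x, center_y, radius, alpha_in, alpha_out)` in unit-square
#'   coordinates.
#' @param seed Integer seed.
#' @return A list of class `sim_params`.
#' @export
sim_params <- function(G = 500, n_cells = 1000, n_train = 30,
                       alpha_dist = stats::runif, lib_size = 5000,
                       train_noise_sd = 0.2, blob = NULL, seed = 1) {
  if (G < 20) stop("G must be at least 20", call. = FALSE)
  if (n_cells < 1 || n_train < 2 || lib_size <= 0)
    stop("counts must be positive (n_cells >= 1, n_train >= 2, lib_size > 0)",
         call. = FALSE)
  if (!is.null(blob)) {
    need <- c("center_x", "center_y", "radius", "alpha_in", "alpha_out")
    if (!all(need %in% names(blob)))
      stop("blob needs fields: ", paste(need, collapse = ", "), call. = FALSE)
    if (blob$radius <= 0) stop("blob radius must be positive", call. = FALSE)
    if (any(c(blob$alpha_in, blob$alpha_out) < 0 |
            c(blob$alpha_in, blob$alpha_out) > 1))
      stop("blob alpha values must lie in [0,1]", call. = FALSE)
  }
  structure(list(G = G, n_cells = n_cells, n_train = n_train,
                 alpha_dist = alpha_dist, lib_size = lib_size,
                 train_noise_sd = train_noise_sd, blob = blob,
                 seed = as.integer(seed)),
            class = "sim_params")
}

#' Generate stem and differentiated mean-expression signatures
#'
#' A shared positive baseline per gene; a designated 20% of genes are
#' 4-fold up in the stem signature and a disjoint 20% are 4-fold up in the
#' differentiated signature. Deterministic per seed.
#'
#' @param G Gene count (>= 20).
#' @param seed Integer seed.
#' @return A list with `stem_signature`, `diff_signature` (named
#'   non-negative vectors), `gene_ids`, `stem_up`, `diff_up` (indices of
#'   the up-gene sets).
#' @export
gen_signatures <- function(G, seed = 1) {
  if (G < 20) stop("G must be at least 20", call. = FALSE)
  set.seed(seed)
  gene_ids <- sprintf("GENE%04d", seq_len(G))
  baseline <- stats::runif(G, 0.5, 2)
  k <- floor(0.2 * G)
  picks <- sample.int(G, 2 * k)
  stem_up <- picks[seq_len(k)]
  diff_up <- picks[k + seq_len(k)]
  stem <- baseline
  stem[stem_up] <- stem[stem_up] * 4
  diff <- baseline
  diff[diff_up] <- diff[diff_up] * 4
  list(stem_signature = stats::setNames(stem, gene_ids),
       diff_signature = stats::setNames(diff, gene_ids),
       gene_ids = gene_ids, stem_up = stem_up, diff_up = diff_up)
}

#' Generate a stem-class training matrix
#'
#' Each training profile is the stem signature on log scale
#' (`log1p(stem_signature)`) plus i.i.d. Gaussian noise — the structure of
#' replicate bulk profiles of a homogeneous stem-cell reference.
#'
#' @param p A [sim_params()].
#' @return A [training_matrix()] (`n_train` x `G`, uncentered).
#' @export
gen_training_matrix <- function(p) {
  sig <- gen_signatures(p$G, p$seed)
  set.seed(p$seed + 1L)
  base <- log1p(sig$stem_signature)
  vals <- matrix(rep(base, each = p$n_train), p$n_train, p$G) +
    matrix(stats::rnorm(p$n_train * p$G, 0, p$train_noise_sd), p$n_train, p$G)
  training_matrix(vals, sig$gene_ids,
                  sprintf("TRAIN%03d", seq_len(p$n_train)))
}

# internal: Poisson counts for given per-cell alphas
mixture_counts <- function(sig, alpha, lib_size) {
  mu <- outer(sig$stem_signature, alpha) +
    outer(sig$diff_signature, 1 - alpha)
  mu <- sweep(mu, 2, colSums(mu), "/")
  n_cells <- length(alpha)
  counts <- matrix(stats::rpois(length(mu), lib_size * mu),
                   nrow = length(sig$gene_ids))
  expression_matrix(counts, sig$gene_ids,
                    sprintf("CELL%05d", seq_len(n_cells)), "counts")
}

#' Generate a mixture cohort with known per-cell stemness
#'
#' Per cell: a stem fraction `alpha` from `alpha_dist`, an expected profile
#' proportional to `alpha * stem + (1 - alpha) * diff` normalized to sum 1,
#' and Poisson counts at the expected library size. `alpha` is recorded as
#' ground truth for validation.
#'
#' @param p A [sim_params()].
#' @return A list of class `synthetic_cohort` with `matrix`
#'   (an [expression_matrix()] of counts), `meta` (cell metadata
#'   data.frame), `alpha`, `stem_signature`, `diff_signature`, `stem_up`,
#'   `diff_up`.
#' @export
gen_cohort <- function(p) {
  sig <- gen_signatures(p$G, p$seed)
  set.seed(p$seed + 2L)
  alpha <- p$alpha_dist(p$n_cells)
  if (any(alpha < 0 | alpha > 1))
    stop("alpha_dist produced values outside [0,1]", call. = FALSE)
  m <- mixture_counts(sig, alpha, p$lib_size)
  meta <- data.frame(cell_id = m$cell_ids, sample = "SIM1",
                     label = NA_character_, x = NA_real_, y = NA_real_,
                     stringsAsFactors = FALSE)
  structure(list(matrix = m, meta = meta,
                 alpha = stats::setNames(alpha, m$cell_ids),
                 stem_signature = sig$stem_signature,
                 diff_signature = sig$diff_signature,
                 stem_up = sig$stem_up, diff_up = sig$diff_up),
            class = "synthetic_cohort")
}

#' Generate a spatial cohort with a stem-rich disc
#'
#' Cells sit on a uniform square grid covering the unit square (so disc
#' membership is deterministic); the stem fraction is `blob$alpha_in` for
#' cells within `blob$radius` of the disc center and `blob$alpha_out`
#' outside. Counts are drawn as in [gen_cohort()]; the metadata carries the
#' grid coordinates.
#'
#' @param p A [sim_params()] with `blob` set. The grid is
#'   `round(sqrt(n_cells))` cells per side.
#' @return A `synthetic_cohort` whose `meta` has `x`, `y` filled in.
#' @export
gen_spatial_cohort <- function(p) {
  if (is.null(p$blob)) stop("blob parameters are required", call. = FALSE)
  side <- max(2L, as.integer(round(sqrt(p$n_cells))))
  coord <- (seq_len(side) - 0.5) / side
  grid <- expand.grid(x = coord, y = coord)
  inside <- (grid$x - p$blob$center_x)^2 + (grid$y - p$blob$center_y)^2 <=
    p$blob$radius^2
  alpha <- ifelse(inside, p$blob$alpha_in, p$blob$alpha_out)
  sig <- gen_signatures(p$G, p$seed)
  set.seed(p$seed + 3L)
  m <- mixture_counts(sig, alpha, p$lib_size)
  meta <- data.frame(cell_id = m$cell_ids, sample = "SIM1",
                     label = ifelse(inside, "disc", "background"),
                     x = grid$x, y = grid$y, stringsAsFactors = FALSE)
  structure(list(matrix = m, meta = meta,
                 alpha = stats::setNames(alpha, m$cell_ids),
                 stem_signature = sig$stem_signature,
                 diff_signature = sig$diff_signature,
                 stem_up = sig$stem_up, diff_up = sig$diff_up),
            class = "synthetic_cohort")
}

#' Restrict a cohort to a reduced feature panel
#'
#' Samples `k` genes without replacement, stratified so at least 5 stem-up
#' genes (or all of them, if fewer exist) are included — a panel with no
#' informative features would make panel scoring vacuous. `k == G` returns
#' the identity panel in original gene order.
#'
#' @param cohort A `synthetic_cohort`.
#' @param k Panel size (<= G). Values below 10 trigger a warning: they are
#'   below the gene-match floor used elsewhere.
#' @param seed Integer seed.
#' @return A list with `matrix` (the restricted [expression_matrix()]) and
#'   `genes` (the panel gene identifiers).
#' @export
gen_panel_subset <- function(cohort, k, seed = 1) {
  G <- length(cohort$matrix$gene_ids)
  if (k > G) stop(sprintf("panel size %d exceeds gene count %d", k, G),
                  call. = FALSE)
  if (k < 10)
    warning("panel smaller than 10 genes is below the default match floor")
  if (k == G) {
    idx <- seq_len(G)
  } else {
    set.seed(seed)
    n_stem <- min(5L, length(cohort$stem_up), k)
    stem_pick <- sample(cohort$stem_up, n_stem)
    rest <- setdiff(seq_len(G), stem_pick)
    idx <- sort(c(stem_pick, sample(rest, k - n_stem)))
  }
  sub <- subset_matrix(cohort$matrix, genes = idx)
  list(matrix = sub, genes = sub$gene_ids)
}
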