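score_fixture <- function(idx, ids = NULL) {
  structure(list(cell_ids = ids %||% sprintf("c%06d", seq_along(idx)),
                 rho = idx * 2 - 1, stemness_index = idx,
                 n_genes_used = 10L, model_id = "m"),
            class = "score_result")
}

test_that("quartile stratification reproduces the published cohort counts", {
  set.seed(31)
  s1 <- score_fixture(runif(80682))
  st1 <- stratify_quartiles(s1)
  expect_equal(attr(st1, "n_top"), 20171L)
  expect_equal(sum(st1$stratum == "top"), 20171)
  expect_equal(sum(st1$stratum == "bottom"), 20171)

  s2 <- score_fixture(runif(180315))
  st2 <- stratify_quartiles(s2)
  expect_equal(attr(st2, "n_top"), 45079L)
  expect_equal(sum(st2$stratum == "bottom"), 45079)
})

test_that("strata are extreme, equal-sized and reproducible under permutation", {
  s <- score_fixture(c(0, 0.1, 0.9, 1), ids = c("a", "b", "c", "d"))
  st <- stratify_quartiles(s)
  expect_equal(st$stratum, c("bottom", "middle", "middle", "top"))

  set.seed(32)
  idx <- sample(rep(seq(0, 1, length.out = 20), each = 5))  # heavy ties
  s <- score_fixture(idx)
  st <- stratify_quartiles(s)
  top <- sort(st$cell_id[st$stratum == "top"])
  bottom <- sort(st$cell_id[st$stratum == "bottom"])
  expect_equal(length(top), length(bottom))
  # every top index >= every middle index >= every bottom index
  expect_gte(min(s$stemness_index[st$stratum == "top"]),
             max(s$stemness_index[st$stratum == "middle"]))
  expect_lte(max(s$stemness_index[st$stratum == "bottom"]),
             min(s$stemness_index[st$stratum == "middle"]))

  # permuting the cells yields the same strata (tie-break by cell_id)
  perm <- sample(length(idx))
  sp <- score_fixture(idx[perm], ids = s$cell_ids[perm])
  stp <- stratify_quartiles(sp)
  expect_equal(sort(stp$cell_id[stp$stratum == "top"]), top)
  expect_equal(sort(stp$cell_id[stp$stratum == "bottom"]), bottom)

  expect_error(stratify_quartiles(score_fixture(c(0, 1, 0.5))), "at least 4")
})

test_that("the rank-sum test is exact for small groups and matches enumeration", {
  norm <- function(vals, ids) expression_matrix(
    matrix(vals, nrow = 1), "G1", ids, "normalized")

  # printed toy case: 2 of the 20 arrangements are as extreme
  m <- norm(c(1, 2, 3, 4, 5, 6), paste0("c", 1:6))
  deg <- wilcoxon_deg(m, paste0("c", 1:3), paste0("c", 4:6))
  expect_equal(deg$p_value, 0.1)

  # gene identical in both groups: p = 1, fc = 0, not significant
  m1 <- norm(rep(2, 8), paste0("c", 1:8))
  deg1 <- wilcoxon_deg(m1, paste0("c", 1:4), paste0("c", 5:8))
  expect_equal(deg1$p_value, 1)
  expect_equal(deg1$log2_fc, 0)
  expect_false(deg1$significant)

  # exact path agrees with a brute-force enumeration oracle, with and
  # without ties, for all group sizes up to 7
  set.seed(41)
  for (n1 in c(3, 5, 7)) {
    for (rep in 1:3) {
      x <- sample(6, n1, replace = TRUE)           # ties likely
      y <- sample(6, n1, replace = TRUE)
      m2 <- norm(c(x, y), paste0("c", seq_len(2 * n1)))
      got <- wilcoxon_deg(m2, paste0("c", seq_len(n1)),
                          paste0("c", n1 + seq_len(n1)))$p_value
      expect_equal(got, exact_ranksum_oracle(x, y))
    }
  }

  # tie-free exact path agrees with wilcox.test's exact p
  set.seed(42)
  x <- rnorm(6); y <- rnorm(7)
  m3 <- norm(c(x, y), paste0("c", 1:13))
  got <- wilcoxon_deg(m3, paste0("c", 1:6), paste0("c", 7:13))$p_value
  expect_equal(got, stats::wilcox.test(x, y, exact = TRUE)$p.value)
})

test_that("the normal approximation tracks the exact tail at moderate sizes", {
  # at group sizes 8-12 (beyond the exact switch) the approximate p must
  # stay within 0.01 of full enumeration on tie-free data
  set.seed(43)
  for (n1 in c(8, 10, 12)) {
    x <- rnorm(n1, 0.5)
    y <- rnorm(n1)
    m <- expression_matrix(matrix(c(x, y), 1), "G1",
                           paste0("c", seq_len(2 * n1)), "normalized")
    approx_p <- wilcoxon_deg(m, paste0("c", seq_len(n1)),
                             paste0("c", n1 + seq_len(n1)))$p_value
    exact_p <- stats::wilcox.test(x, y, exact = TRUE)$p.value
    expect_lt(abs(approx_p - exact_p), 0.01)
  }
})

test_that("Bonferroni correction and the significance rule follow their definitions", {
  set.seed(44)
  G <- 10
  vals <- rbind(matrix(rnorm(9 * 20), 9, 20),
                c(rnorm(10, 5), rnorm(10)))    # one strongly shifted gene
  m <- expression_matrix(abs(vals), sprintf("G%02d", 1:G),
                         paste0("c", 1:20), "normalized")
  deg <- wilcoxon_deg(m, paste0("c", 1:10), paste0("c", 11:20))
  expect_equal(deg$p_adj, pmin(1, deg$p_value * G))
  expect_equal(deg$significant, deg$p_adj < 0.05 & abs(deg$log2_fc) > 0.5)

  expect_error(wilcoxon_deg(m, paste0("c", 1:10), paste0("c", 10:20)),
               "overlap")
  expect_error(wilcoxon_deg(m, paste0("c", 1:2), paste0("c", 11:20)),
               "at least 3")
})

test_that("effect sizes equal a naive per-gene loop", {
  set.seed(45)
  m <- log_normalize(make_counts(30, 16, seed = 45))
  top <- m$cell_ids[1:8]
  bottom <- m$cell_ids[9:16]
  eff <- effect_sizes(m, top, bottom)
  v <- as.matrix(m$values)
  for (g in seq_len(30)) {
    xt <- v[g, 1:8]
    xb <- v[g, 9:16]
    expect_equal(eff$log2_fc[g],
                 log2((mean(expm1(xt)) + 1) / (mean(expm1(xb)) + 1)),
                 tolerance = 1e-12)
    expect_equal(eff$pct_diff[g], 100 * (mean(xt > 0) - mean(xb > 0)),
                 tolerance = 1e-12)
  }
  # all-zero gene in both groups: no fold change, no pct difference
  z <- expression_matrix(matrix(0, 1, 16), "GZ", m$cell_ids, "normalized")
  effz <- effect_sizes(z, top, bottom)
  expect_equal(effz$log2_fc, 0)
  expect_equal(effz$pct_diff, 0)
})

test_that("overlap statistics reproduce the published list arithmetic", {
  # 104 genes shared by lists of 336 and 311
  shared <- sprintf("SH%03d", 1:104)
  a <- c(shared, sprintf("A%03d", 1:232))
  b <- c(shared, sprintf("B%03d", 1:207))
  ov <- overlap_stats(a, b)
  expect_equal(ov$n_common, 104)
  expect_equal(ov$pct_of_b, 33.4)
  expect_lte(abs(ov$pct_of_a - 30.9), 0.1 + 1e-9)
  # symmetry of the intersection
  rev <- overlap_stats(b, a)
  expect_equal(rev$n_common, ov$n_common)
  expect_equal(rev$pct_of_a, ov$pct_of_b)

  expect_equal(overlap_stats(a, a), list(n_common = 336, pct_of_a = 100,
                                         pct_of_b = 100))
  expect_equal(overlap_stats(c("X"), c("Y"))$n_common, 0)
  expect_true(is.na(overlap_stats(character(), b)$pct_of_a))
})

test_that("marker-set scoring labels clusters by their planted signatures", {
  set.seed(51)
  G <- 40
  genes <- sprintf("G%03d", 1:G)
  sets <- list(typeA = genes[1:5], typeB = genes[6:10],
               typeC = genes[11:15], typeD = genes[16:20])
  n_per <- 25
  cl <- rep(paste0("cl", 1:4), each = n_per)
  vals <- matrix(abs(rnorm(G * 100, 1, 0.1)), G, 100)
  for (i in 1:4) # plant signature i in cluster i
    vals[(5 * (i - 1) + 1):(5 * i), cl == paste0("cl", i)] <-
      vals[(5 * (i - 1) + 1):(5 * i), cl == paste0("cl", i)] + 3
  m <- expression_matrix(vals, genes, sprintf("c%03d", 1:100), "normalized")
  cluster_of <- setNames(cl, m$cell_ids)
  ann <- annotate_clusters(m, cluster_of, sets)
  expect_equal(unname(ann$labels), c("typeA", "typeB", "typeC", "typeD"))

  # score matrix equals a per-cluster/per-label loop oracle
  cmeans <- sapply(paste0("cl", 1:4),
                   function(cc) rowMeans(vals[, cl == cc, drop = FALSE]))
  z <- t(scale(t(cmeans)))
  for (lab in names(sets)) {
    hit <- genes %in% sets[[lab]]
    expect_equal(unname(ann$scores[, lab]), unname(colMeans(z[hit, ])),
                 tolerance = 1e-12)
  }

  # swapping two labels' marker sets swaps the assigned labels
  swapped <- sets
  names(swapped)[1:2] <- names(sets)[2:1]
  ann2 <- annotate_clusters(m, cluster_of, swapped)
  expect_equal(unname(ann2$labels[1:2]), c("typeB", "typeA"))

  expect_error(annotate_clusters(m, cluster_of, list(bad = c("NOPE"))),
               "bad")
  expect_error(annotate_clusters(m, cluster_of[-1], sets), "without a cluster")
})

test_that("bootstrap medians are exact at full size and deterministic per seed", {
  set.seed(61)
  s <- score_fixture(runif(300))
  tab <- bootstrap_stability(s, sizes = c(50, 300), reps = 20, seed = 7)
  expect_equal(nrow(tab), 40)
  full_median <- median(s$stemness_index)
  expect_true(all(tab$median_index[tab$size == 300] == full_median))

  tab2 <- bootstrap_stability(s, sizes = c(50, 300), reps = 20, seed = 7)
  expect_identical(tab, tab2)
  tab3 <- bootstrap_stability(s, sizes = c(50, 300), reps = 20, seed = 8)
  expect_false(identical(tab$median_index, tab3$median_index))

  expect_error(bootstrap_stability(s, sizes = 301, seed = 1), "exceeds")
})

test_that("median dispersion shrinks as the subset approaches the cohort", {
  set.seed(62)
  s <- score_fixture(runif(800))
  tab <- bootstrap_stability(s, sizes = c(50, 200, 800), reps = 60, seed = 3)
  sds <- tapply(tab$median_index, tab$size, sd)
  expect_lt(sds[["200"]], sds[["50"]])
  expect_equal(sds[["800"]], 0)
})
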