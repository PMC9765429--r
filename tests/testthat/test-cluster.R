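test_that("z-scoring follows the sample-SD convention and drops constants", {
  cv <- tibble::tibble(gene_id = "a", dose = c(0, 0.5, 1, 2),
                       fold_change = c(1, 2, 3, 4))
  z <- zscore_trends(cv)
  expect_equal(as.numeric(z),
               (c(1, 2, 3, 4) - 2.5) / stats::sd(c(1, 2, 3, 4)))
  expect_lt(abs(mean(z)), 1e-9)
  expect_equal(stats::sd(z), 1, tolerance = 1e-9)
  # idempotence up to the affine map: re-zscoring a z-scored row is itself
  z2 <- (z - mean(z)) / stats::sd(z)
  expect_equal(as.numeric(z2), as.numeric(z))
  both <- dplyr::bind_rows(cv, tibble::tibble(gene_id = "const",
                                              dose = c(0, 0.5, 1, 2),
                                              fold_change = rep(1, 4)))
  expect_warning(z3 <- zscore_trends(both), "constant")
  expect_equal(rownames(z3), "a")
})

test_that("Pearson distance has the required metric-like properties", {
  m <- rbind(a = c(1, 2, 3, 4), b = c(2, 4, 6, 8), c = c(4, 3, 2, 1),
             d = c(1, -1, 1, -1))
  d <- as.matrix(pearson_distance(m))
  expect_equal(unname(diag(d)), rep(0, 4))
  expect_equal(d["a", "b"], 0)            # identical shape
  expect_equal(d["a", "c"], 2)            # mirrored
  expect_true(all(d >= 0 & d <= 2 + 1e-12))
  expect_equal(d, t(d))
  set.seed(1)
  r <- matrix(rnorm(50), 10)
  dr <- as.matrix(pearson_distance(r))
  expect_true(all(dr >= 0 & dr <= 2 + 1e-12))
})

test_that("average-linkage clustering recovers planted families and ignores order", {
  curves <- planted_curves()
  z <- zscore_trends(curves)
  hc <- hierarchical_average(pearson_distance(z), k = 4)
  truth <- sub("_.*", "", hc$assignment$gene_id)
  expect_gte(oracle_label_agreement(hc$assignment$cluster, truth), 0.95)
  # permutation invariance up to relabeling
  perm <- sample(nrow(z))
  hc2 <- hierarchical_average(pearson_distance(z[perm, ]), k = 4)
  merged <- dplyr::inner_join(hc$assignment, hc2$assignment, by = "gene_id")
  expect_equal(oracle_label_agreement(merged$cluster.x,
                                      as.character(merged$cluster.y)), 1)
  two <- hierarchical_average(stats::as.dist(matrix(c(0, 1, 1, 0), 2)), k = 2)
  expect_equal(two$tree$height, 1)
})

test_that("k-means recovers planted archetypes and is reproducible", {
  z <- zscore_trends(planted_curves())
  km <- kmeans_trends(z, 4, seed = 3)
  truth <- sub("_.*", "", km$assignment$gene_id)
  expect_gte(oracle_label_agreement(km$assignment$cluster, truth), 0.95)
  km2 <- kmeans_trends(z, 4, seed = 3)
  expect_equal(km$assignment, km2$assignment)
  expect_lte(km$tot_withinss, km$totss)
  # multiple restarts never do worse than a single one
  km1 <- kmeans_trends(z, 4, seed = 3, restarts = 1)
  expect_lte(km$tot_withinss, km1$tot_withinss + 1e-9)
  one <- kmeans_trends(z, 1, seed = 1)
  expect_equal(one$tot_withinss, one$totss, tolerance = 1e-9)
  expect_error(kmeans_trends(z, nrow(z) + 1), "k must be")
})

test_that("optimum-k diagnostics point to the planted cluster count", {
  # three well-separated trend families
  curves <- planted_curves()
  curves <- curves[curves$archetype %in% c("S", "L", "NMb"), ]
  z <- zscore_trends(curves)
  diag <- choose_k(z, k_range = 2:6, seed = 2, gap_b = 20)
  rec <- recommended_k(diag)
  expect_equal(rec$k[rec$method == "silhouette"], 3)
  expect_equal(rec$k[rec$method == "gap"], 3)
  expect_equal(rec$k[rec$method == "wss"], 3)
  # a single Gaussian blob shows no strong silhouette optimum
  set.seed(5)
  blob <- matrix(rnorm(60 * 8), 60)
  rownames(blob) <- paste0("g", 1:60)
  dblob <- choose_k(blob, k_range = 2:5, seed = 2, gap_b = 10)
  expect_lt(max(dblob$silhouette), 0.5)
  expect_error(choose_k(z, k_range = 1:3), "k_range")
})

test_that("PCA embedding satisfies the SVD identities", {
  z <- zscore_trends(planted_curves())
  pc <- pca_embed(z)
  expect_equal(sum(pc$var_explained), 1)
  expect_true(all(diff(pc$var_explained) <= 1e-12))
  # reconstruction from all components equals the centered matrix
  centered <- sweep(z, 2, colMeans(z))
  sc <- as.matrix(pc$scores[, -1])
  expect_equal(unname(sc %*% t(pc$loadings)), unname(centered),
               tolerance = 1e-9)
  # sign convention: largest loading of each component is positive
  for (j in seq_len(ncol(pc$loadings))) {
    v <- pc$loadings[, j]
    expect_gt(v[which.max(abs(v))], 0)
  }
  # rank-1 input: PC1 explains everything
  r1 <- outer(c(1, 2, 3, 4, 5), c(1, 0.5, 0.2, 0.1)) +
    matrix(0, 5, 4)
  rownames(r1) <- paste0("g", 1:5)
  p1 <- pca_embed(r1)
  expect_equal(p1$var_explained[1], 1, tolerance = 1e-9)
  # planted two-family data separate along PC1
  two <- zscore_trends(planted_curves()[
    planted_curves()$archetype %in% c("S", "NMb"), ])
  p2 <- pca_embed(two)
  fam <- sub("_.*", "", p2$scores$gene_id)
  expect_gte(oracle_label_agreement(
    as.integer(p2$scores$PC1 > stats::median(p2$scores$PC1)), fam), 0.95)
})

test_that("crosstab counts, percentages and matching behave", {
  a <- tibble::tibble(gene_id = paste0("g", 1:6),
                      cluster = c(1, 1, 2, 2, 3, 3))
  ct <- crosstab(a, tibble::tibble(gene_id = paste0("g", 1:6),
                                   class = c("x", "x", "y", "y", "z", "z")))
  expect_equal(unname(diag(ct$counts)), rep(2, 3))
  expect_true(all(apply(ct$row_pct, 1, max) == 100))
  expect_equal(ct$matching$overlap_pct, rep(100, 3))
  expect_true(all(rowSums(ct$counts) == 2))
  expect_error(
    crosstab(a, tibble::tibble(gene_id = paste0("h", 1:6), class = "x")),
    "different gene sets")
})

test_that("operon trends correlate more within than between operons", {
  curves <- planted_curves(n_per = 10, cv = 0.15, seed = 12)
  # operons = pairs of consecutive genes within an archetype: shared shape
  ids <- unique(curves$gene_id)
  op_map <- tibble::tibble(gene_id = ids,
                           operon_id = paste0("op",
                                              ceiling(match(ids, ids) / 2)))
  res <- operon_correlation_check(curves, op_map, seed = 2)
  expect_gt(stats::median(res$intra), stats::median(res$inter))
  expect_lt(res$test$p.value, 0.05)
  # fake operons over independent genes: no signal (typical seed)
  set.seed(77)
  grid <- default_dose_grid()
  indep <- purrr::map(1:40, function(i) {
    tibble::tibble(gene_id = paste0("r", i), dose = grid,
                   fold_change = c(1, exp(rnorm(9, 0, 0.3))))
  }) |> purrr::list_rbind()
  fake_map <- tibble::tibble(gene_id = paste0("r", 1:40),
                             operon_id = paste0("op", rep(1:20, each = 2)))
  null_res <- operon_correlation_check(indep, fake_map, seed = 3)
  expect_gt(null_res$test$p.value, 0.05)
  expect_error(operon_correlation_check(
    curves, tibble::tibble(gene_id = ids, operon_id = ids)),
    "multi-gene")
})
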