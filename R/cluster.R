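#' Z-score-normalized trend matrix
#'
#' Converts dose-response curves into a genes-by-doses matrix of row-wise
#' z scores (sample standard deviation, n - 1 denominator), so clustering
#' compares the shapes of trends rather than their magnitudes. Constant
#' rows carry no shape and are excluded with a warning. The zero-dose
#' anchor column is included by default; set `drop_zero_dose = TRUE` to
#' z score over the measured doses only.
#'
#' @param curves long curves tibble (see [validate_curves()]).
#' @param drop_zero_dose exclude the dose-0 reference column.
#' @return numeric matrix, rownames = gene ids, colnames = doses; row
#'   means 0 and row SDs 1.
#' @export
zscore_trends <- function(curves, drop_zero_dose = FALSE) {
  validate_curves(curves)
  if (drop_zero_dose) curves <- curves[curves$dose > 0, ]
  wide <- tidyr::pivot_wider(curves, id_cols = "gene_id",
                             names_from = "dose",
                             values_from = "fold_change")
  m <- as.matrix(wide[, -1])
  rownames(m) <- wide$gene_id
  sds <- apply(m, 1, stats::sd)
  const <- sds == 0
  if (any(const)) {
    warning(sum(const), " constant row(s) excluded from the trend matrix")
    m <- m[!const, , drop = FALSE]
    sds <- sds[!const]
  }
  (m - rowMeans(m)) / sds
}

#' Pearson distance between gene trends
#'
#' `d(i, j) = 1 - r(i, j)` on rows: 0 for identical shapes, 1 for
#' uncorrelated, 2 for mirror-image trends.
#'
#' @param matrix genes-by-doses numeric matrix (rows are observations).
#' @return a `dist` object.
#' @export
pearson_distance <- function(matrix) {
  if (nrow(matrix) < 2) stop("need at least 2 rows", call. = FALSE)
  sds <- apply(matrix, 1, stats::sd)
  if (any(sds == 0)) stop("zero-variance row; z score the trends first", call. = FALSE)
  stats::as.dist(1 - stats::cor(t(matrix)))
}

#' Average-linkage hierarchical clustering of trends
#'
#' UPGMA agglomeration on a trend distance matrix, with labels obtained by
#' cutting the tree at a requested cluster count.
#'
#' @param distance a `dist` (e.g. [pearson_distance()]).
#' @param k optional cluster count to cut at.
#' @return list with `tree` (an `hclust`) and, when `k` is given,
#'   `assignment` (tibble `gene_id`, `cluster`).
#' @export
hierarchical_average <- function(distance, k = NULL) {
  tree <- stats::hclust(distance, method = "average")
  out <- list(tree = tree)
  if (!is.null(k)) {
    labels <- stats::cutree(tree, k = k)
    out$assignment <- tibble::tibble(gene_id = names(labels),
                                     cluster = unname(labels))
  }
  out
}

#' k-means clustering of the trend matrix
#'
#' Lloyd-style k-means with multiple random restarts; the restart with the
#' lowest within-cluster sum of squares is kept. Reproducible under the
#' seed.
#'
#' @param matrix z-scored trend matrix (see [zscore_trends()]).
#' @param k number of clusters (`1 <= k <= nrow`).
#' @param seed integer seed.
#' @param restarts random restarts.
#' @param max_iter iteration cap per restart.
#' @return list of class `trend_kmeans`: `assignment` (tibble `gene_id`,
#'   `cluster`), `centers`, `tot_withinss`, `totss`, `seed`.
#' @export
kmeans_trends <- function(matrix, k, seed = 1L, restarts = 50,
                          max_iter = 300) {
  if (k < 1 || k > nrow(matrix)) stop("k must be in [1, rows]", call. = FALSE)
  set.seed(seed)
  km <- stats::kmeans(matrix, centers = k, nstart = restarts,
                      iter.max = max_iter)
  structure(list(
    assignment = tibble::tibble(gene_id = rownames(matrix),
                                cluster = unname(km$cluster)),
    centers = km$centers, tot_withinss = km$tot.withinss, totss = km$totss,
    seed = seed), class = "trend_kmeans")
}

#' Optimum-cluster-count diagnostics
#'
#' Per candidate `k`: total within-cluster sum of squares (WSS), mean
#' silhouette width (Euclidean distance on the trend matrix), and the gap
#' statistic with uniform-reference resampling. Each method's recommended
#' `k` is reported separately — WSS by the elbow (largest drop in slope),
#' silhouette by the maximum mean width, gap by the first-SE-max rule — and
#' no consensus is forced, since continuous trend data need not have a
#' well-defined cluster count.
#'
#' @param matrix z-scored trend matrix.
#' @param k_range candidate cluster counts (within `[2, rows - 1]`).
#' @param seed integer seed (k-means restarts and gap resampling).
#' @param restarts k-means restarts per k.
#' @param gap_b gap-statistic reference resamples.
#' @return tibble with `k`, `wss`, `silhouette`, `gap`, `gap_se`;
#'   recommendations in attribute `"recommended"` ([recommended_k()]).
#' @export
choose_k <- function(matrix, k_range = 2:8, seed = 1L, restarts = 25,
                     gap_b = 50) {
  if (length(k_range) < 1 || any(k_range < 2) || any(k_range > nrow(matrix) - 1)) {
    stop("k_range must lie within [2, rows - 1]", call. = FALSE)
  }
  d_euc <- stats::dist(matrix)
  rows <- purrr::map(k_range, function(k) {
    km <- kmeans_trends(matrix, k, seed = seed, restarts = restarts)
    sil <- cluster::silhouette(km$assignment$cluster, d_euc)
    tibble::tibble(k = k, wss = km$tot_withinss,
                   silhouette = mean(sil[, "sil_width"]))
  }) |> purrr::list_rbind()
  set.seed(seed)
  gap <- cluster::clusGap(
    matrix, FUNcluster = function(x, k) {
      list(cluster = stats::kmeans(x, k, nstart = restarts,
                                   iter.max = 300)$cluster)
    },
    K.max = max(k_range), B = gap_b, verbose = FALSE)
  gt <- as.data.frame(gap$Tab)[k_range, ]
  rows$gap <- gt$gap
  rows$gap_se <- gt$SE.sim
  rec_wss <- if (nrow(rows) >= 3) {
    # elbow: largest second difference of WSS
    d2 <- diff(diff(rows$wss))
    rows$k[which.max(d2) + 1]
  } else rows$k[which.min(rows$wss)]
  rec_sil <- rows$k[which.max(rows$silhouette)]
  rec_gap <- k_range[1] - 1 +
    cluster::maxSE(gt$gap, gt$SE.sim, method = "firstSEmax")
  attr(rows, "recommended") <- tibble::tibble(
    method = c("wss", "silhouette", "gap"),
    k = c(rec_wss, rec_sil, rec_gap))
  rows
}

#' @rdname choose_k
#' @param diagnostics a [choose_k()] table.
#' @export
recommended_k <- function(diagnostics) attr(diagnostics, "recommended")

#' PCA embedding of the trend matrix
#'
#' Principal components of the column-centered trend matrix
#' ([stats::prcomp()], no rescaling). Component signs follow the
#' convention that each component's largest-magnitude loading is positive,
#' so embeddings are reproducible across platforms.
#'
#' @param matrix z-scored trend matrix (>= 2 rows and columns).
#' @return list of class `trend_pca`: `scores` (tibble with `gene_id` and
#'   `PC*` columns), `loadings`, `var_explained` (fractions summing to 1).
#' @export
pca_embed <- function(matrix) {
  if (nrow(matrix) < 2 || ncol(matrix) < 2) {
    stop("need at least 2 rows and 2 columns", call. = FALSE)
  }
  pc <- stats::prcomp(matrix, center = TRUE, scale. = FALSE)
  flip <- apply(pc$rotation, 2, function(v) sign(v[which.max(abs(v))]))
  flip[flip == 0] <- 1
  rot <- sweep(pc$rotation, 2, flip, `*`)
  scores <- sweep(pc$x, 2, flip, `*`)
  ve <- pc$sdev^2 / sum(pc$sdev^2)
  structure(list(
    scores = dplyr::bind_cols(tibble::tibble(gene_id = rownames(matrix)),
                              tibble::as_tibble(scores)),
    loadings = rot, var_explained = ve), class = "trend_pca")
}

#' Cross-tabulate two cluster assignments
#'
#' Counts and row percentages of assignment A's clusters against
#' assignment B's, with a maximum-overlap matching of A clusters to B
#' clusters (e.g. naming k-means clusters after the model-fit class they
#' are dominated by).
#'
#' @param assign_a,assign_b tibbles with `gene_id` and a label column
#'   (`cluster` or `class`) over the same gene universe.
#' @return list with `counts` (matrix, rows = A), `row_pct`, and
#'   `matching` (tibble `a`, `b`, `overlap_pct`).
#' @export
crosstab <- function(assign_a, assign_b) {
  la <- assign_a[[setdiff(names(assign_a), "gene_id")[1]]]
  lb <- assign_b[[setdiff(names(assign_b), "gene_id")[1]]]
  if (!setequal(assign_a$gene_id, assign_b$gene_id)) {
    stop("assignments cover different gene sets", call. = FALSE)
  }
  lb <- lb[match(assign_a$gene_id, assign_b$gene_id)]
  counts <- table(a = la, b = lb)
  row_pct <- 100 * counts / rowSums(counts)
  matching <- tibble::tibble(
    a = rownames(counts),
    b = colnames(counts)[apply(counts, 1, which.max)],
    overlap_pct = unname(apply(row_pct, 1, max)))
  list(counts = unclass(counts), row_pct = unclass(row_pct),
       matching = matching)
}

#' Intra- versus inter-operon trend correlation
#'
#' Genes of one operon are transcribed together, so their dose-response
#' trends should correlate more tightly than trends of genes from
#' different transcription units — an internal control for using Pearson
#' correlation as the clustering metric.
#'
#' @param curves long curves tibble.
#' @param operon_map tibble with `gene_id` and `operon_id`; needs at least
#'   2 multi-gene operons.
#' @param seed seed for sampling the size-matched inter-operon pair set.
#' @return list with `intra` and `inter` correlation vectors and `test`
#'   (two-sided Wilcoxon rank-sum).
#' @export
operon_correlation_check <- function(curves, operon_map, seed = 1L) {
  validate_curves(curves)
  wide <- tidyr::pivot_wider(curves, id_cols = "gene_id",
                             names_from = "dose", values_from = "fold_change")
  m <- as.matrix(wide[, -1]); rownames(m) <- wide$gene_id
  operon_map <- operon_map[operon_map$gene_id %in% rownames(m), ]
  sizes <- table(operon_map$operon_id)
  multi <- names(sizes)[sizes >= 2]
  if (length(multi) < 2) stop("need at least 2 multi-gene operons", call. = FALSE)
  cors <- stats::cor(t(m))
  pair_cor <- function(g1, g2) cors[g1, g2]
  intra <- purrr::map(multi, function(op) {
    genes <- operon_map$gene_id[operon_map$operon_id == op]
    cmb <- utils::combn(genes, 2)
    purrr::map2_dbl(cmb[1, ], cmb[2, ], pair_cor)
  }) |> unlist()
  op_of <- stats::setNames(operon_map$operon_id, operon_map$gene_id)
  set.seed(seed)
  inter <- replicate(length(intra), {
    repeat {
      g <- sample(operon_map$gene_id, 2)
      if (op_of[g[1]] != op_of[g[2]]) break
    }
    pair_cor(g[1], g[2])
  })
  list(intra = intra, inter = inter,
       test = stats::wilcox.test(intra, inter, alternative = "two.sided",
                                 exact = FALSE))
}
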