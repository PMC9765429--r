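#' Robust summary of a fitted-parameter distribution
#'
#' Median, interquartile range (linear-interpolation quantiles, type 7),
#' the median absolute deviation from the median expressed as a percent of
#' the median (`MADM = 100 * median(|x - median|) / median`), extremes, and
#' the share of the full range covered by the IQR.
#'
#' @param values numeric vector (>= 2 finite values).
#' @param parameter optional parameter name carried into the output.
#' @return one-row tibble: `parameter`, `n`, `median`, `iqr`, `madm_pct`,
#'   `min`, `max`, `iqr_over_range_pct`.
#' @export
#' @examples
#' summarize_parameter(c(1, 2, 3, 4, 5))
summarize_parameter <- function(values, parameter = NA_character_) {
  values <- values[is.finite(values)]
  if (length(values) < 2) stop("need at least 2 finite values", call. = FALSE)
  med <- stats::median(values)
  q <- stats::quantile(values, c(0.25, 0.75), type = 7, names = FALSE)
  rng <- max(values) - min(values)
  tibble::tibble(
    parameter = parameter, n = length(values), median = med,
    iqr = q[2] - q[1],
    madm_pct = 100 * stats::median(abs(values - med)) / med,
    min = min(values), max = max(values),
    iqr_over_range_pct = if (rng > 0) 100 * (q[2] - q[1]) / rng else NA_real_)
}

#' Compare two value distributions by rank sum
#'
#' Two-sided Wilcoxon rank-sum test: exact for small tie-free samples,
#' normal approximation with tie correction otherwise.
#'
#' @param values_a,values_b numeric vectors (each nonempty).
#' @return one-row tibble: `statistic` (W), `p_value`, `n_a`, `n_b`,
#'   `method`.
#' @export
compare_groups <- function(values_a, values_b) {
  if (length(values_a) == 0 || length(values_b) == 0) {
    stop("both groups must be nonempty", call. = FALSE)
  }
  exact <- length(values_a) <= 20 && length(values_b) <= 20 &&
    !any(duplicated(c(values_a, values_b)))
  wt <- stats::wilcox.test(values_a, values_b, alternative = "two.sided",
                           exact = exact, correct = !exact)
  tibble::tibble(statistic = unname(wt$statistic), p_value = wt$p.value,
                 n_a = length(values_a), n_b = length(values_b),
                 method = if (exact) "exact" else "normal_approx")
}

#' Correlation between two variables
#'
#' @param x,y equal-length numeric vectors (n >= 3).
#' @param method `"spearman"` (rank correlation, midranks for ties) or
#'   `"pearson"`.
#' @return one-row tibble: `method`, `estimate`, `p_value`, `n`;
#'   `NA` estimate when either vector is constant.
#' @export
correlate <- function(x, y, method = c("spearman", "pearson")) {
  method <- match.arg(method)
  if (length(x) != length(y)) stop("x and y differ in length", call. = FALSE)
  if (length(x) < 3) stop("need at least 3 pairs", call. = FALSE)
  if (stats::sd(x) == 0 || stats::sd(y) == 0) {
    return(tibble::tibble(method = method, estimate = NA_real_,
                          p_value = NA_real_, n = length(x)))
  }
  ct <- suppressWarnings(
    stats::cor.test(x, y, method = method, alternative = "two.sided",
                    exact = FALSE))
  tibble::tibble(method = method, estimate = unname(ct$estimate),
                 p_value = ct$p.value, n = length(x))
}

#' Category enrichment of a gene class
#'
#' 2x2 table of class membership against category membership over a gene
#' universe, with the conditional maximum-likelihood odds ratio and
#' two-sided Fisher's exact p-value.
#'
#' @param category_members,class_members character vectors of gene ids,
#'   subsets of `universe`.
#' @param universe character vector of all genes considered.
#' @return one-row tibble: counts `a` (in class & category), `b`, `c`,
#'   `d`, `odds_ratio` (`Inf` for a structural zero), `p_value`.
#' @export
enrichment <- function(category_members, class_members, universe) {
  if (length(universe) == 0) stop("empty universe", call. = FALSE)
  in_cat <- universe %in% category_members
  in_cls <- universe %in% class_members
  a <- sum(in_cls & in_cat); b <- sum(in_cls & !in_cat)
  cc <- sum(!in_cls & in_cat); d <- sum(!in_cls & !in_cat)
  ft <- stats::fisher.test(matrix(c(a, b, cc, d), nrow = 2, byrow = TRUE),
                           alternative = "two.sided")
  tibble::tibble(a = a, b = b, c = cc, d = d,
                 odds_ratio = unname(ft$estimate), p_value = ft$p.value)
}

#' Enrichment of every category against every class
#'
#' Runs [enrichment()] for each class-category pair and adjusts p-values
#' across categories within each class (Holm by default).
#'
#' @param categories tibble with `gene_id` and `category` (a gene may
#'   appear in several categories).
#' @param classes tibble with `gene_id` and `class`.
#' @param universe gene universe; defaults to all classified genes.
#' @param adjust p-adjustment method (see [stats::p.adjust()]).
#' @return tibble with one row per class-category pair.
#' @export
enrichment_table <- function(categories, classes, universe = NULL,
                             adjust = "holm") {
  if (is.null(universe)) universe <- unique(classes$gene_id)
  combos <- tidyr::expand_grid(class = unique(classes$class),
                               category = unique(categories$category))
  out <- purrr::pmap(combos, function(class, category) {
    res <- enrichment(
      categories$gene_id[categories$category == category],
      classes$gene_id[classes$class == class], universe)
    dplyr::bind_cols(tibble::tibble(class = class, category = category), res)
  }) |> purrr::list_rbind()
  out <- dplyr::mutate(dplyr::group_by(out, .data$class),
                       p_adjusted = stats::p.adjust(.data$p_value,
                                                    method = adjust))
  dplyr::ungroup(out)
}

#' Quartile bins of a parameter
#'
#' Assigns Q1-Q4 labels by the same linear-interpolation quantile rule as
#' [summarize_parameter()]; values tied with a boundary go to the lower
#' bin, so degenerate all-equal input lands entirely in Q1.
#'
#' @param values numeric vector (>= 4 values).
#' @return factor of labels `Q1`-`Q4`, same length as `values`.
#' @export
#' @examples
#' quartile_bins(1:8)
quartile_bins <- function(values) {
  if (length(values) < 4) stop("need at least 4 values", call. = FALSE)
  q <- stats::quantile(values, c(0.25, 0.5, 0.75), type = 7, names = FALSE)
  labs <- c("Q1", "Q2", "Q3", "Q4")
  idx <- 1L + (values > q[1]) + (values > q[2]) + (values > q[3])
  factor(labs[idx], levels = labs)
}

#' Vocabulary bins for steepness and midpoint
#'
#' Field vocabulary for Hill parameters: steepness `n` is "high" above 5,
#' "moderate" in [3, 5], "low" below 3; midpoint `k` is "low" below 0.68
#' mM, "moderate" in [0.68, 0.94], "high" above 0.94 mM.
#'
#' @param n,k numeric vectors (either may be `NULL`).
#' @param n_breaks,k_breaks the two interior break points.
#' @return tibble with the supplied values and their labels.
#' @export
parameter_vocabulary <- function(n = NULL, k = NULL, n_breaks = c(3, 5),
                                 k_breaks = c(0.68, 0.94)) {
  lab3 <- function(x, br) {
    factor(ifelse(x < br[1], "low", ifelse(x <= br[2], "moderate", "high")),
           levels = c("low", "moderate", "high"))
  }
  out <- tibble::tibble(.rows = max(length(n), length(k)))
  if (!is.null(n)) { out$n <- n; out$n_label <- lab3(n, n_breaks) }
  if (!is.null(k)) { out$k <- k; out$k_label <- lab3(k, k_breaks) }
  out
}
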