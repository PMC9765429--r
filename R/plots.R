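#' Plot a fitted dose-response curve
#'
#' Observed fold changes with the fitted model curve overlaid on a dense
#' dose grid.
#'
#' @param object a `trend_fit` from [fit_curve()].
#' @param ... unused.
#' @return a ggplot.
#' @method autoplot trend_fit
#' @export
autoplot.trend_fit <- function(object, ...) {
  curve <- attr(object, "curve")
  dense <- seq(min(curve$dose), max(curve$dose), length.out = 200)
  pred <- tibble::tibble(dose = dense,
                         fold_change = predict(object, dense))
  ggplot2::ggplot(curve, ggplot2::aes(.data$dose, .data$fold_change)) +
    ggplot2::geom_point() +
    ggplot2::geom_line(data = pred, colour = "steelblue") +
    ggplot2::labs(x = "dose (mM)", y = "fold change",
                  title = paste0(object$gene_id, " (", object$model, ")")) +
    ggplot2::theme_minimal()
}

#' Median trend per class of a classified regulon
#'
#' @param classification a [classify_regulon()] result.
#' @param curves the curves the classification was computed from.
#' @return a ggplot of per-class median fold change by dose, with median
#'   absolute deviation ribbons.
#' @export
plot_class_trends <- function(classification, curves) {
  joined <- dplyr::left_join(
    curves, tibble::tibble(gene_id = classification$gene_id,
                           class = classification$class), by = "gene_id")
  med <- dplyr::summarise(
    dplyr::group_by(joined, .data$class, .data$dose),
    median_fc = stats::median(.data$fold_change),
    mad_fc = stats::mad(.data$fold_change), .groups = "drop")
  ggplot2::ggplot(med, ggplot2::aes(.data$dose, .data$median_fc,
                                    colour = .data$class)) +
    ggplot2::geom_ribbon(
      ggplot2::aes(ymin = .data$median_fc - .data$mad_fc,
                   ymax = .data$median_fc + .data$mad_fc,
                   fill = .data$class),
      alpha = 0.15, colour = NA) +
    ggplot2::geom_line() + ggplot2::geom_point() +
    ggplot2::labs(x = "dose (mM)", y = "median fold change") +
    ggplot2::theme_minimal()
}

#' Plot a PCA embedding of gene trends
#'
#' @param object a `trend_pca` from [pca_embed()].
#' @param labels optional tibble `gene_id`, `class` (or `cluster`) to
#'   colour points by.
#' @param ... unused.
#' @return a ggplot of PC1 vs PC2.
#' @method autoplot trend_pca
#' @export
autoplot.trend_pca <- function(object, labels = NULL, ...) {
  sc <- object$scores
  if (!is.null(labels)) {
    lab_col <- setdiff(names(labels), "gene_id")[1]
    sc <- dplyr::left_join(sc, labels, by = "gene_id")
    p <- ggplot2::ggplot(sc, ggplot2::aes(.data$PC1, .data$PC2,
                                          colour = .data[[lab_col]]))
  } else {
    p <- ggplot2::ggplot(sc, ggplot2::aes(.data$PC1, .data$PC2))
  }
  ve <- round(100 * object$var_explained[1:2], 1)
  p + ggplot2::geom_point(alpha = 0.7) +
    ggplot2::labs(x = paste0("PC1 (", ve[1], "%)"),
                  y = paste0("PC2 (", ve[2], "%)")) +
    ggplot2::theme_minimal()
}

#' Plot per-level apparent-parameter distributions of a cascade ensemble
#'
#' @param object a `cascade_ensemble` from [simulate_ensemble()].
#' @param parameter `"apparent_k"` or `"apparent_n"`.
#' @param ... unused.
#' @return a ggplot of per-level densities.
#' @method autoplot cascade_ensemble
#' @export
autoplot.cascade_ensemble <- function(object,
                                      parameter = c("apparent_k",
                                                    "apparent_n"), ...) {
  parameter <- match.arg(parameter)
  tb <- tibble::as_tibble(object)
  tb <- tb[tb$converged, ]
  tb$level <- factor(tb$level)
  ggplot2::ggplot(tb, ggplot2::aes(.data[[parameter]],
                                   colour = .data$level)) +
    ggplot2::geom_density() +
    ggplot2::scale_x_log10() +
    ggplot2::labs(x = parameter, y = "density") +
    ggplot2::theme_minimal()
}
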