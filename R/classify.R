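#' Selection thresholds for model classification
#'
#' The cascading acceptance rules: a gene is sigmoid (HM) only if the Hill
#' fit has the strictly smallest residual variance among converged models,
#' `r2_nlfit > hm_r2_min` with `p < p_max`, `slope_nlfit` within
#' `slope_center +/- slope_tol`, and relative standard errors of `k` and
#' `emax` below `rse_max`. RSEs of `b0` and `n` are deliberately not
#' filtered on: the sparse dose sampling around the transition region makes
#' `n` (and the near-degenerate `b0`) poorly determined even for clean
#' sigmoid curves. Linear/nonsaturating (LM) and null (NR) fits use the
#' looser `r2 > 0.7` rule; the R-squared/slope criteria are skipped for NR
#' because a constant predictor leaves them undefined.
#'
#' @param hm_r2_min,lm_r2_min,nr_r2_min minimum `r2_nlfit` per class.
#' @param p_max maximum correlation p-value.
#' @param slope_center,slope_tol acceptance band for `slope_nlfit`.
#' @param rse_max maximum relative standard error for `k` and `emax`.
#' @param nr_max_fc flatness gate for NR: the null model is only accepted
#'   when no dose shows a fold change at or beyond this value (or its
#'   reciprocal) — the differential-expression cutoff that defines a
#'   responsive gene. Without it a rise-and-fall gene, which no monotone
#'   model tracks, would hand the flat model the smallest residual
#'   variance by its larger denominator and be mislabeled nonresponsive.
#' @param b0_band flag (not reject) winning fits whose `b0` falls outside
#'   this fold-change band.
#' @return list of class `selection_thresholds`.
#' @export
selection_thresholds <- function(hm_r2_min = 0.80, lm_r2_min = 0.70,
                                 nr_r2_min = 0.70, p_max = 0.05,
                                 slope_center = 1.0, slope_tol = 0.2,
                                 rse_max = 0.20, nr_max_fc = 2,
                                 b0_band = c(0.8, 1.2)) {
  out <- list(hm_r2_min = hm_r2_min, lm_r2_min = lm_r2_min,
              nr_r2_min = nr_r2_min, p_max = p_max,
              slope_center = slope_center, slope_tol = slope_tol,
              rse_max = rse_max, nr_max_fc = nr_max_fc, b0_band = b0_band)
  class(out) <- "selection_thresholds"
  out
}

.slope_ok <- function(slope, th) {
  !is.na(slope) && abs(slope - th$slope_center) <= th$slope_tol
}

.check_hm <- function(fit, th) {
  fails <- character(0)
  if (is.na(fit$r2_nlfit) || fit$r2_nlfit <= th$hm_r2_min) fails <- c(fails, "r2_nlfit")
  if (is.na(fit$p_value) || fit$p_value >= th$p_max) fails <- c(fails, "p_value")
  if (!.slope_ok(fit$slope_nlfit, th)) fails <- c(fails, "slope_nlfit")
  if (is.na(fit$rse_k) || fit$rse_k >= th$rse_max) fails <- c(fails, "rse_k")
  if (is.na(fit$rse_emax) || fit$rse_emax >= th$rse_max) fails <- c(fails, "rse_emax")
  fails
}

.check_nr <- function(curve, th) {
  # flat acceptance: no dose differentially expressed (R-squared/slope are
  # undefined for a constant predictor and cannot be used here)
  fc <- if (!is.null(curve)) curve$fold_change else NULL
  if (!is.null(fc) && !is.null(th$nr_max_fc) &&
      any(fc >= th$nr_max_fc | fc <= 1 / th$nr_max_fc)) {
    "responsive"
  } else {
    character(0)
  }
}

.check_lm <- function(fit, th) {
  fails <- character(0)
  if (is.na(fit$r2_nlfit) || fit$r2_nlfit <= th$lm_r2_min) fails <- c(fails, "r2_nlfit")
  if (is.na(fit$p_value) || fit$p_value >= th$p_max) fails <- c(fails, "p_value")
  if (!.slope_ok(fit$slope_nlfit, th)) fails <- c(fails, "slope_nlfit")
  fails
}

#' Classify one gene from its four model fits
#'
#' Converged fits compete on residual variance `sigma2 = SSE/(N-p)`; the
#' strictly smallest wins (exact ties broken by parsimony, fewer
#' parameters). The winner must then pass its class's acceptance rules
#' ([selection_thresholds()]); a gene whose winner fails every rule — or
#' with no converged fit — is nonmonotonic (NM), a class defined purely by
#' exclusion. The rejection log records every failed criterion per model to
#' support manual review of NM genes.
#'
#' @param fits tibble of [fit_curve()] rows for one gene, one row per model
#'   in [model_ids()].
#' @param thresholds a [selection_thresholds()] list.
#' @param curve the gene's curve (`dose`, `fold_change`), needed for the
#'   NR flatness gate; without it the gate is skipped.
#' @return one-row tibble: `gene_id`, `class` (HM/LM/NR/NM), `model`
#'   (winning model id or `NA`), the winning fit's statistics, a `b0_flag`
#'   for basal levels outside the expected band, and a `rejection_log`
#'   list-column.
#' @export
classify_gene <- function(fits, thresholds = selection_thresholds(),
                          curve = NULL) {
  if (nrow(fits) == 0) stop("no fits supplied", call. = FALSE)
  th <- thresholds
  log <- stats::setNames(vector("list", nrow(fits)), fits$model)
  conv <- fits[fits$converged & !is.na(fits$sigma2), ]
  for (m in fits$model[!fits$model %in% conv$model]) log[[m]] <- "not_converged"

  winner <- NULL
  if (nrow(conv) > 0) {
    # strict minimum sigma2; exact ties broken by fewer parameters
    np <- vapply(conv$model, n_params, numeric(1))
    ord <- order(conv$sigma2, np)
    conv <- conv[ord, ]
    winner <- conv[1, ]
    for (m in conv$model[-1]) {
      log[[m]] <- unique(c(log[[m]], "sigma2_not_smallest"))
    }
  }

  out_class <- "NM"
  win_row <- NULL
  if (!is.null(winner)) {
    m <- winner$model
    fails <- switch(m,
      HM = .check_hm(winner, th),
      NONSAT = , LIN = .check_lm(winner, th),
      NR = .check_nr(curve, th))
    if (length(fails) == 0) {
      out_class <- switch(m, HM = "HM", NONSAT = "LM", LIN = "LM", NR = "NR")
      win_row <- winner
    } else {
      log[[m]] <- unique(c(log[[m]], fails))
    }
  }

  base <- if (is.null(win_row)) {
    r <- .empty_fit_row(fits$gene_id[1], NA_character_)
    r$converged <- NA
    r
  } else tibble::as_tibble(win_row)
  names(base)[names(base) == "model"] <- "model"
  res <- tibble::tibble(gene_id = fits$gene_id[1], class = out_class)
  res <- dplyr::bind_cols(res, base[, setdiff(names(base), "gene_id")])
  res$b0_flag <- !is.na(res$b0) &
    (res$b0 < th$b0_band[1] | res$b0 > th$b0_band[2])
  res$rejection_log <- list(log)
  res
}

#' Classify every gene of a regulon
#'
#' Fits all four models to each curve ([fit_models()]) and applies
#' [classify_gene()].
#'
#' @param curves long curves tibble (see [validate_curves()]); duplicate
#'   gene/dose rows are an error.
#' @param thresholds a [selection_thresholds()] list.
#' @param fits optionally, a precomputed [fit_models()] table (skips
#'   refitting).
#' @return tibble of class `regulon_classification`, one row per gene (see
#'   [classify_gene()]); class counts available via [class_counts()] or
#'   [glance()].
#' @export
classify_regulon <- function(curves, thresholds = selection_thresholds(),
                             fits = NULL) {
  if (!is.null(curves)) {
    validate_curves(curves)
    if (anyDuplicated(curves[, c("gene_id", "dose")]) > 0) {
      stop("duplicate gene_id/dose rows", call. = FALSE)
    }
    if (nrow(curves) == 0) stop("no curves to classify", call. = FALSE)
  }
  if (is.null(fits)) fits <- fit_models(curves)
  split_curves <- if (!is.null(curves)) split(curves, curves$gene_id)
  out <- split(fits, fits$gene_id) |>
    purrr::imap(function(f, g) {
      classify_gene(f, thresholds = thresholds, curve = split_curves[[g]])
    }) |>
    purrr::list_rbind()
  out <- out[order(match(out$gene_id, unique(fits$gene_id))), ]
  attr(out, "thresholds") <- thresholds
  class(out) <- c("regulon_classification", class(out))
  out
}

#' Class counts of a classified regulon
#'
#' @param classification a [classify_regulon()] result.
#' @return tibble with columns `class` (HM, LM, NR, NM) and `n`.
#' @export
class_counts <- function(classification) {
  lv <- c("HM", "LM", "NR", "NM")
  counts <- table(factor(classification$class, levels = lv))
  tibble::tibble(class = lv, n = as.integer(counts))
}

#' @method glance regulon_classification
#' @export
glance.regulon_classification <- function(x, ...) {
  cc <- class_counts(x)
  out <- tibble::as_tibble(as.list(stats::setNames(cc$n, cc$class)))
  out$n_genes <- nrow(x)
  out$n_b0_flagged <- sum(x$b0_flag, na.rm = TRUE)
  out
}
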