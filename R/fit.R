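#' Goodness of fit for a nonlinear model
#'
#' Classical R-squared is not meaningful for nonlinear fits, so model quality
#' is judged by regressing the observed responses on the model-predicted
#' ones: `r2_nlfit` is the squared Pearson correlation between predicted and
#' observed values, `slope_nlfit` the ordinary least-squares slope of
#' observed on predicted (1 for an unbiased fit), and `p_value` the
#' two-sided significance of the correlation. The residual variance is
#' `sigma2 = SSE / (N - p)`, the criterion used to compare competing models.
#'
#' When the predictions are constant (the null model, or a degenerate fit)
#' the correlation is undefined and `r2_nlfit`, `slope_nlfit` and `p_value`
#' are returned as `NA`.
#'
#' @param observed,predicted numeric vectors of equal length `N > n_params`.
#' @param n_params number of fitted parameters `p`.
#' @return one-row tibble with `sigma2`, `r2_nlfit`, `slope_nlfit`,
#'   `p_value`.
#' @export
#' @examples
#' goodness_of_fit(c(1, 2, 3), c(1, 2, 3), 1)
goodness_of_fit <- function(observed, predicted, n_params) {
  if (length(observed) != length(predicted)) {
    stop("observed and predicted must have equal length", call. = FALSE)
  }
  N <- length(observed)
  if (N <= n_params) stop("need more observations than parameters", call. = FALSE)
  sse <- sum((observed - predicted)^2)
  sigma2 <- sse / (N - n_params)
  if (stats::sd(predicted) < .Machine$double.eps^0.5 * max(1, abs(mean(predicted)))) {
    return(tibble::tibble(sigma2 = sigma2, r2_nlfit = NA_real_,
                          slope_nlfit = NA_real_, p_value = NA_real_))
  }
  ct <- stats::cor.test(predicted, observed, method = "pearson")
  slope <- unname(stats::coef(stats::lm(observed ~ predicted))[2])
  tibble::tibble(
    sigma2 = sigma2,
    r2_nlfit = unname(ct$estimate)^2,
    slope_nlfit = slope,
    p_value = ct$p.value
  )
}

#' Relative standard error of a parameter estimate
#'
#' `rse = |std_error / estimate|`; undefined (`NA`) when the estimate is 0.
#'
#' @param estimate,std_error numeric scalars (vectorized).
#' @return numeric; `NA` where `estimate == 0`.
#' @export
#' @examples
#' relative_standard_error(2, 0.2)
relative_standard_error <- function(estimate, std_error) {
  out <- abs(std_error / estimate)
  out[estimate == 0] <- NA_real_
  out
}

#' Default start values for model fitting
#'
#' Start values anchor the nonlinear optimizer in the biologically plausible
#' region: `b0` is the mean fold change at the three lowest nonzero doses
#' (mapped by nearest dose to 0.01, 0.05 and 0.1 mM on nonstandard grids,
#' where no response is expected), `emax` the mean at the doses nearest 1
#' and 2 mM (where most regulated genes have saturated), `n = 2`, `k = 0.6`
#' mM, `m = 1`.
#'
#' @param curve tibble with `dose` and `fold_change` for one gene.
#' @param model_id one of [model_ids()].
#' @return named list of start values for the model's parameters.
#' @export
default_start_values <- function(curve, model_id) {
  model_id <- match.arg(model_id, model_ids())
  doses <- curve$dose
  validate_grid(sort(doses))
  fc <- curve$fold_change[order(doses)]
  doses <- sort(doses)
  nearest <- function(target) doses[-1][which.min(abs(doses[-1] - target))]
  low <- unique(vapply(c(0.01, 0.05, 0.1), nearest, numeric(1)))
  high <- unique(vapply(c(1, 2), nearest, numeric(1)))
  b0 <- mean(fc[doses %in% low])
  emax <- mean(fc[doses %in% high])
  switch(model_id,
    HM     = list(b0 = b0, k = 0.6, n = 2, emax = emax),
    NONSAT = list(b0 = b0, m = 1, n = 2),
    LIN    = list(b0 = b0, m = 1),
    NR     = list(b0 = b0)
  )
}

#' Default optimizer bounds
#'
#' Keeps the solver in the biologically meaningful region: positive basal
#' and saturating levels, `k` up to 10 times the maximum tested dose
#' (beyond which the midpoint is unidentifiable), `n` in (0.1, 20],
#' positive `m`.
#'
#' @param model_id one of [model_ids()].
#' @param max_dose largest dose of the grid (mM).
#' @return list with numeric vectors `lower` and `upper` in parameter order.
#' @export
default_bounds <- function(model_id, max_dose = 4) {
  eps <- 1e-8
  b <- switch(match.arg(model_id, model_ids()),
    HM     = list(lower = c(b0 = eps, k = eps, n = 0.1, emax = eps),
                  upper = c(b0 = Inf, k = 10 * max_dose, n = 20, emax = Inf)),
    NONSAT = list(lower = c(b0 = eps, m = eps, n = 0.1),
                  upper = c(b0 = Inf, m = Inf, n = 20)),
    LIN    = list(lower = c(b0 = eps, m = eps),
                  upper = c(b0 = Inf, m = Inf)),
    NR     = list(lower = c(b0 = eps), upper = c(b0 = Inf))
  )
  b
}

# Deterministic start set: the user-supplied or default start, plus for the
# nonlinear models a data-driven start (midpoint at the half-rise crossing,
# top-dose response as the saturation level) and a steep variant. The fit
# with the smallest SSE among converged candidates is kept — selection is by
# the least-squares objective only.
.start_set <- function(curve, model_id, start) {
  starts <- list(start)
  if (model_id %in% c("HM", "NONSAT")) {
    doses <- curve$dose
    fc <- curve$fold_change
    top <- fc[which.max(doses)]
    b0_dd <- fc[which.min(doses)]
    half <- (b0_dd + top) / 2
    above <- which(fc >= half & doses > 0)
    k_dd <- if (length(above) > 0) {
      max(min(doses[above]), min(doses[doses > 0]))
    } else stats::median(doses)
    if (model_id == "HM") {
      starts <- c(starts, list(
        list(b0 = b0_dd, k = k_dd, n = 2, emax = top),
        list(b0 = b0_dd, k = k_dd, n = 6, emax = top)))
    } else {
      m_dd <- max((top - b0_dd) / max(doses)^1.5, 1e-6)
      starts <- c(starts, list(list(b0 = b0_dd, m = m_dd, n = 1.5)))
    }
  }
  starts
}

# Standard errors from the Jacobian restricted to the free (interior)
# parameters, scaled by the residual variance. Central finite differences.
.reduced_se <- function(model_id, est, doses, sigma2, free) {
  pars <- names(est)
  ses <- stats::setNames(rep(NA_real_, length(est)), pars)
  free_pars <- pars[free]
  if (length(free_pars) == 0) return(ses)
  J <- vapply(free_pars, function(pm) {
    h <- max(abs(est[pm]) * 1e-6, 1e-8)
    up <- as.list(est); up[[pm]] <- up[[pm]] + h
    dn <- as.list(est); dn[[pm]] <- dn[[pm]] - h
    (evaluate_model(model_id, up, doses) -
       evaluate_model(model_id, dn, doses)) / (2 * h)
  }, numeric(length(doses)))
  cov_red <- tryCatch(sigma2 * solve(crossprod(J)), error = function(e) NULL)
  if (!is.null(cov_red)) {
    d <- diag(cov_red)
    d[d < 0] <- NA_real_
    ses[free_pars] <- sqrt(d)
  }
  ses
}

.model_formula <- function(model_id) {
  switch(model_id,
    HM     = fold_change ~ b0 + (emax - b0) * dose^n / (k^n + dose^n),
    NONSAT = fold_change ~ b0 + m * dose^n,
    LIN    = fold_change ~ b0 + m * dose,
    NR     = fold_change ~ b0
  )
}

.empty_fit_row <- function(gene_id, model_id) {
  tibble::tibble(
    gene_id = gene_id, model = model_id, converged = FALSE,
    b0 = NA_real_, k = NA_real_, n = NA_real_, emax = NA_real_, m = NA_real_,
    se_b0 = NA_real_, se_k = NA_real_, se_n = NA_real_, se_emax = NA_real_,
    se_m = NA_real_,
    rse_b0 = NA_real_, rse_k = NA_real_, rse_n = NA_real_, rse_emax = NA_real_,
    rse_m = NA_real_,
    sigma2 = NA_real_, r2_nlfit = NA_real_, slope_nlfit = NA_real_,
    p_value = NA_real_
  )
}

#' Fit one response model to one gene's dose-response curve
#'
#' Bounded nonlinear least squares (Levenberg-Marquardt via
#' [minpack.lm::nlsLM()]) from the start values of
#' [default_start_values()]. The null model has the closed-form solution
#' `b0 = mean(fold_change)` and is computed directly. Standard errors come
#' from the linearized covariance of the least-squares objective at the
#' optimum; a singular curvature leaves them `NA` with `converged = TRUE`.
#' Non-convergence is reported in the `converged` flag, never raised.
#'
#' @param curve tibble with columns `dose` and `fold_change` (and optionally
#'   `gene_id`) for a single gene.
#' @param model_id one of [model_ids()].
#' @param start optional named list overriding [default_start_values()].
#' @param bounds optional list with `lower`/`upper` named vectors overriding
#'   [default_bounds()].
#' @param max_iter optimizer iteration cap.
#' @return object of class `trend_fit`: a one-row tibble with estimates,
#'   standard errors, relative standard errors, `sigma2`, the
#'   [goodness_of_fit()] panel, and a `converged` flag. Fitted model object
#'   and data are kept in attributes for [predict()] and [autoplot()].
#' @export
#' @examples
#' curve <- tibble::tibble(
#'   dose = default_dose_grid(),
#'   fold_change = evaluate_model("HM", list(b0 = 1, k = 0.8, n = 4, emax = 10),
#'                                default_dose_grid()))
#' fit_curve(curve, "HM")
fit_curve <- function(curve, model_id, start = NULL, bounds = NULL,
                      max_iter = 200) {
  model_id <- match.arg(model_id, model_ids())
  if (!all(c("dose", "fold_change") %in% names(curve))) {
    stop("curve needs columns dose and fold_change", call. = FALSE)
  }
  gene_id <- if ("gene_id" %in% names(curve)) curve$gene_id[1] else NA_character_
  curve <- curve[order(curve$dose), c("dose", "fold_change")]
  N <- nrow(curve)
  p <- n_params(model_id)
  if (N <= p) stop("more parameters than doses", call. = FALSE)
  if (is.null(start)) start <- default_start_values(curve, model_id)
  if (is.null(bounds)) bounds <- default_bounds(model_id, max(curve$dose))
  pars <- model_params(model_id)

  if (model_id == "NR") {
    b0 <- mean(curve$fold_change)
    sse <- sum((curve$fold_change - b0)^2)
    sigma2 <- sse / (N - 1)
    se <- sqrt(sigma2 / N)
    est <- c(b0 = b0); ses <- c(b0 = se); ok <- TRUE
  } else {
    starts <- .start_set(curve, model_id, start)
    fit <- NULL
    best_sse <- Inf
    for (st in starts) {
      cand <- tryCatch(
        minpack.lm::nlsLM(
          .model_formula(model_id), data = curve,
          start = st[pars],
          lower = bounds$lower[pars], upper = bounds$upper[pars],
          control = minpack.lm::nls.lm.control(maxiter = max_iter)),
        error = function(e) NULL)
      if (!is.null(cand)) {
        sse <- sum(stats::resid(cand)^2)
        if (sse < best_sse) { best_sse <- sse; fit <- cand }
      }
    }
    if (is.null(fit)) {
      out <- .empty_fit_row(gene_id, model_id)
      return(.as_trend_fit(out, NULL, curve))
    }
    est <- stats::coef(fit)
    sse <- sum(stats::resid(fit)^2)
    at_bound <- est <= bounds$lower[pars] + 1e-6 |
      est >= bounds$upper[pars] - 1e-6
    if (any(at_bound)) {
      # an active bound makes the full linearized covariance singular or
      # meaningless; SEs of the free parameters come from the reduced
      # Jacobian, the bound-pinned parameter's SE is undefined
      ses <- .reduced_se(model_id, est, curve$dose, sse / (N - p), !at_bound)
    } else {
      ses <- tryCatch(summary(fit)$coefficients[, "Std. Error"],
                      error = function(e) stats::setNames(rep(NA_real_, p), pars))
      ses <- stats::setNames(as.numeric(ses[pars]), pars)
    }
    ok <- TRUE
  }

  predicted <- evaluate_model(model_id, as.list(est), curve$dose)
  gof <- goodness_of_fit(curve$fold_change, predicted, p)
  out <- .empty_fit_row(gene_id, model_id)
  out$converged <- ok
  for (nm in pars) {
    out[[nm]] <- unname(est[nm])
    out[[paste0("se_", nm)]] <- unname(ses[nm])
    out[[paste0("rse_", nm)]] <- unname(relative_standard_error(est[nm], ses[nm]))
  }
  out$sigma2 <- gof$sigma2
  out$r2_nlfit <- gof$r2_nlfit
  out$slope_nlfit <- gof$slope_nlfit
  out$p_value <- gof$p_value
  .as_trend_fit(out, if (model_id == "NR") NULL else NULL, curve)
}

.as_trend_fit <- function(row, fit, curve) {
  attr(row, "curve") <- curve
  class(row) <- c("trend_fit", class(row))
  row
}

#' Predicted responses from a fitted model
#'
#' @param object a `trend_fit` from [fit_curve()].
#' @param doses doses at which to predict; defaults to the fitted doses.
#' @param ... unused.
#' @return numeric vector of predictions (`NA` if the fit did not converge).
#' @method predict trend_fit
#' @export
predict.trend_fit <- function(object, doses = NULL, ...) {
  if (is.null(doses)) doses <- attr(object, "curve")$dose
  if (!isTRUE(object$converged)) return(rep(NA_real_, length(doses)))
  pars <- model_params(object$model)
  evaluate_model(object$model, as.list(object)[pars], doses)
}

#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' Tidy a fitted response model
#'
#' @param x a `trend_fit` from [fit_curve()].
#' @param ... unused.
#' @return tibble with one row per parameter: `term`, `estimate`,
#'   `std.error`, `rse`.
#' @method tidy trend_fit
#' @export
tidy.trend_fit <- function(x, ...) {
  pars <- model_params(x$model)
  tibble::tibble(
    term = pars,
    estimate = vapply(pars, function(p) x[[p]], numeric(1),
                      USE.NAMES = FALSE),
    std.error = vapply(pars, function(p) x[[paste0("se_", p)]], numeric(1),
                       USE.NAMES = FALSE),
    rse = vapply(pars, function(p) x[[paste0("rse_", p)]], numeric(1),
                 USE.NAMES = FALSE)
  )
}

#' One-row fit summary
#'
#' @param x a `trend_fit`.
#' @param ... unused.
#' @return tibble with `model`, `converged`, `sigma2`, `r2_nlfit`,
#'   `slope_nlfit`, `p_value`.
#' @method glance trend_fit
#' @export
glance.trend_fit <- function(x, ...) {
  tibble::as_tibble(x)[, c("model", "converged", "sigma2", "r2_nlfit",
                           "slope_nlfit", "p_value")]
}

#' Fit all four response models to every gene
#'
#' @param curves long tibble (`gene_id`, `dose`, `fold_change`), all genes on
#'   one grid (see [validate_curves()]).
#' @param models models to fit (default all four).
#' @param start_overrides optional named list `gene_id -> model -> start list`.
#' @return tibble with one row per gene and model, the union of all
#'   [fit_curve()] columns.
#' @export
fit_models <- function(curves, models = model_ids(), start_overrides = NULL) {
  validate_curves(curves)
  split_curves <- split(curves, curves$gene_id)
  rows <- purrr::map(split_curves, function(cv) {
    purrr::map(models, function(m) {
      st <- start_overrides[[cv$gene_id[1]]][[m]]
      res <- fit_curve(cv, m, start = st)
      tibble::as_tibble(res)
    }) |> purrr::list_rbind()
  }) |> purrr::list_rbind()
  rows[order(match(rows$gene_id, unique(curves$gene_id))), ]
}
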