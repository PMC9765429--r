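#' Response models for dose-response curves
#'
#' Four phenomenological models describe how a gene's expression fold change
#' responds to an effector concentration `c` (mM):
#'
#' * `HM` (Hill): `b0 + (emax - b0) * c^n / (k^n + c^n)` — sigmoid response
#'   with basal level `b0`, half-saturation midpoint `k` (mM), steepness `n`
#'   and saturating fold change `emax`.
#' * `NONSAT` (nonsaturating power law): `b0 + m * c^n` — the Hill limit for
#'   `k` far above the tested dose range.
#' * `LIN` (linear): `b0 + m * c` — the `n = 1` special case of `NONSAT`.
#' * `NR` (null / nonresponsive): constant `b0`.
#'
#' @format NULL
#' @name response_models
NULL

#' Model identifiers and parameter sets
#'
#' @return `model_ids()` returns the four model identifiers; `model_params()`
#'   returns the parameter names of one model; `n_params()` its parameter
#'   count.
#' @param model_id one of `"HM"`, `"NONSAT"`, `"LIN"`, `"NR"`.
#' @export
#' @examples
#' model_ids()
#' model_params("HM")
model_ids <- function() c("HM", "NONSAT", "LIN", "NR")

.model_param_sets <- list(
  HM     = c("b0", "k", "n", "emax"),
  NONSAT = c("b0", "m", "n"),
  LIN    = c("b0", "m"),
  NR     = c("b0")
)

#' @rdname model_ids
#' @export
model_params <- function(model_id) {
  model_id <- match.arg(model_id, model_ids())
  .model_param_sets[[model_id]]
}

#' @rdname model_ids
#' @export
n_params <- function(model_id) length(model_params(model_id))

#' Evaluate a response model at given doses
#'
#' @param model_id one of `"HM"`, `"NONSAT"`, `"LIN"`, `"NR"`.
#' @param params named list or vector with the model's parameters
#'   (see [model_params()]). Fold-change units for `b0` and `emax`, mM for
#'   `k`, dimensionless `n`, fold change per mM^n for `m`.
#' @param doses numeric vector of nonnegative effector concentrations (mM).
#' @return numeric vector of predicted responses, same length as `doses`.
#' @export
#' @examples
#' evaluate_model("HM", list(b0 = 1, k = 0.6, n = 2, emax = 5), c(0, 0.6, 4))
evaluate_model <- function(model_id, params, doses) {
  model_id <- match.arg(model_id, model_ids())
  params <- as.list(params)
  need <- model_params(model_id)
  missing <- setdiff(need, names(params))
  if (length(missing) > 0) {
    stop("missing parameter(s) for ", model_id, ": ",
         paste(missing, collapse = ", "), call. = FALSE)
  }
  if (any(doses < 0)) stop("doses must be nonnegative", call. = FALSE)
  p <- lapply(params[need], as.numeric)
  switch(model_id,
    HM = {
      if (p$k <= 0 || p$n <= 0) {
        stop("HM requires k > 0 and n > 0", call. = FALSE)
      }
      p$b0 + (p$emax - p$b0) * doses^p$n / (p$k^p$n + doses^p$n)
    },
    NONSAT = p$b0 + p$m * doses^p$n,
    LIN = p$b0 + p$m * doses,
    NR = rep(p$b0, length(doses))
  )
}

#' Default dose grid
#'
#' Ten effector concentrations from 0 to 4 mM: dense below 1 mM where the
#' transition region of most regulated genes lies, sparse above.
#'
#' @return numeric vector of 10 doses (mM), strictly increasing from 0.
#' @export
default_dose_grid <- function() c(0, 0.01, 0.05, 0.1, 0.3, 0.6, 0.8, 1, 2, 4)

#' Validate a dose grid
#'
#' A valid grid has at least 4 doses, starts at 0, and is strictly
#' increasing.
#'
#' @param doses numeric vector of concentrations (mM).
#' @return the grid, invisibly; errors otherwise.
#' @export
validate_grid <- function(doses) {
  if (length(doses) < 4) stop("dose grid needs at least 4 doses", call. = FALSE)
  if (doses[1] != 0) stop("dose grid must start at 0", call. = FALSE)
  if (any(diff(doses) <= 0)) stop("dose grid must be strictly increasing", call. = FALSE)
  invisible(doses)
}

#' Validate a dose-response curve table
#'
#' Curves are long tibbles with columns `gene_id`, `dose` and `fold_change`
#' (linear fold change relative to the zero-dose reference; the value at
#' dose 0 is 1 by construction). All genes must share one grid.
#'
#' @param curves tibble with columns `gene_id`, `dose`, `fold_change`.
#' @return `curves`, invisibly; errors on malformed input.
#' @export
validate_curves <- function(curves) {
  need <- c("gene_id", "dose", "fold_change")
  missing <- setdiff(need, names(curves))
  if (length(missing) > 0) {
    stop("curves table is missing column(s): ",
         paste(missing, collapse = ", "), call. = FALSE)
  }
  grids <- dplyr::summarise(
    dplyr::group_by(curves, .data$gene_id),
    key = paste(sort(.data$dose), collapse = ","), .groups = "drop")
  if (dplyr::n_distinct(grids$key) != 1) {
    stop("all genes must share one dose grid", call. = FALSE)
  }
  validate_grid(sort(unique(curves$dose)))
  if (any(curves$fold_change <= 0)) {
    stop("fold changes must be positive (linear scale)", call. = FALSE)
  }
  invisible(curves)
}
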