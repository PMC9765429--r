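#' Compose a linear chain of Hill edges
#'
#' Null model for indirect regulation: a feed-forward chain R -> g1 -> g2
#' -> ... where every edge follows a Hill function with basal level 0 and
#' saturating level 1, steepness `edge_n`, and its own midpoint `k`. Node 1
#' responds directly to the input dose; node `j` responds to node `j - 1`'s
#' output, evaluated pointwise (memoryless composition, no dynamics).
#'
#' @param edge_ks positive numeric vector, one midpoint per edge.
#' @param edge_n Hill coefficient shared by all edges.
#' @param grid input-dose grid (regulator units).
#' @return tibble with columns `level`, `dose`, `response`; responses lie
#'   in `[0, 1)`.
#' @export
#' @examples
#' compose_chain(c(0.8, 0.3), edge_n = 2, grid = default_dose_grid())
compose_chain <- function(edge_ks, edge_n = 2, grid) {
  if (any(edge_ks <= 0)) stop("edge k values must be positive", call. = FALSE)
  hill01 <- function(x, k, n) x^n / (k^n + x^n)
  out <- vector("list", length(edge_ks))
  resp <- grid
  for (j in seq_along(edge_ks)) {
    resp <- hill01(resp, edge_ks[j], edge_n)
    out[[j]] <- tibble::tibble(level = j, dose = grid, response = resp)
  }
  purrr::list_rbind(out)
}

#' Apparent Hill parameters of a composed response
#'
#' Fits a Hill curve with the basal level fixed at 0 and `k`, `n`, `emax`
#' free, mapping a downstream node's response back to the input dose axis.
#' The composed response saturates below 1 even though every edge has
#' saturating level 1, so `emax` must stay free. A response that has not
#' plateaued over the grid (last two values differing by more than 1%
#' relative) is fitted anyway but flagged `reliable = FALSE`.
#'
#' @param response numeric, monotone nondecreasing response values.
#' @param grid matching input-dose grid.
#' @return one-row tibble: `apparent_k`, `apparent_n`, `apparent_emax`,
#'   `converged`, `reliable`.
#' @export
apparent_parameters <- function(response, grid) {
  stopifnot(length(response) == length(grid))
  nlast <- length(response)
  plateau <- abs(response[nlast] - response[nlast - 1]) <=
    0.01 * abs(response[nlast])
  emax0 <- response[nlast]
  half <- emax0 / 2
  above <- which(response >= half)
  k0 <- if (length(above) > 0 && above[1] > 1) {
    i <- above[1]
    # linear interpolation of the half-max crossing
    grid[i - 1] + (half - response[i - 1]) /
      (response[i] - response[i - 1]) * (grid[i] - grid[i - 1])
  } else stats::median(grid)
  dat <- tibble::tibble(dose = grid, y = response)
  fit <- tryCatch(
    minpack.lm::nlsLM(
      y ~ emax * dose^n / (k^n + dose^n), data = dat,
      start = list(k = max(k0, min(grid[grid > 0])), n = 2, emax = emax0),
      lower = c(k = 1e-12, n = 0.05, emax = 1e-12),
      upper = c(k = Inf, n = 50, emax = Inf),
      control = minpack.lm::nls.lm.control(maxiter = 200)),
    error = function(e) NULL)
  if (is.null(fit)) {
    return(tibble::tibble(apparent_k = NA_real_, apparent_n = NA_real_,
                          apparent_emax = NA_real_, converged = FALSE,
                          reliable = FALSE))
  }
  cf <- stats::coef(fit)
  tibble::tibble(apparent_k = unname(cf["k"]), apparent_n = unname(cf["n"]),
                 apparent_emax = unname(cf["emax"]), converged = TRUE,
                 reliable = plateau)
}

#' Log-normal midpoint sampler matched to a median and IQR
#'
#' @param k_median,k_iqr target median and interquartile range.
#' @return function of `n` returning `n` positive draws.
#' @export
lnorm_k_sampler <- function(k_median = 0.79, k_iqr = 0.26) {
  s <- .lnorm_sdlog(k_median, k_iqr)
  function(n) stats::rlnorm(n, meanlog = log(k_median), sdlog = s)
}

#' Empirical midpoint sampler from observed values
#'
#' @param k_values positive numeric vector (e.g. fitted midpoints of the
#'   sigmoid genes of a study).
#' @return function of `n` resampling `k_values` with replacement.
#' @export
empirical_k_sampler <- function(k_values) {
  stopifnot(all(k_values > 0))
  force(k_values)
  function(n) sample(k_values, n, replace = TRUE)
}

#' Configuration for the cascade ensemble simulation
#'
#' @param n_edges chain length (levels).
#' @param edge_n Hill coefficient of every edge.
#' @param n_trials number of sampled chains.
#' @param k_sampler function of `n` returning positive midpoints; defaults
#'   to [lnorm_k_sampler()]. One value per edge per trial, independently.
#' @param grid_points log-spaced evaluation doses per trial.
#' @param grid_span the per-trial grid spans `min(k)/grid_span[1]` to
#'   `max(k)*grid_span[2]` of that trial's sampled midpoints, so every
#'   transition and plateau is resolved.
#' @param seed integer seed.
#' @return list of class `chain_config`.
#' @export
chain_config <- function(n_edges = 3, edge_n = 2, n_trials = 10000,
                         k_sampler = lnorm_k_sampler(),
                         grid_points = 60, grid_span = c(100, 100),
                         seed = 1L) {
  stopifnot(n_edges >= 1, edge_n > 0, n_trials >= 1)
  structure(list(n_edges = n_edges, edge_n = edge_n, n_trials = n_trials,
                 k_sampler = k_sampler, grid_points = grid_points,
                 grid_span = grid_span, seed = as.integer(seed)),
            class = "chain_config")
}

#' Simulate an ensemble of Hill cascades
#'
#' For each trial: sample one midpoint per edge, compose the chain over a
#' trial-specific log-spaced dose grid, and fit apparent Hill parameters
#' at every level against the input dose. The per-level distributions of
#' apparent `k` and `n` are the null expectation for how indirect
#' regulation reshapes dose-response parameters.
#'
#' @param config a [chain_config()].
#' @return object of class `cascade_ensemble`: tibble with one row per
#'   trial and level (`trial`, `level`, `edge_k`, `apparent_k`,
#'   `apparent_n`, `apparent_emax`, `converged`, `reliable`); summaries via
#'   [tidy()] and [glance()].
#' @export
simulate_ensemble <- function(config = chain_config()) {
  stopifnot(inherits(config, "chain_config"))
  set.seed(config$seed)
  ne <- config$n_edges
  kmat <- matrix(config$k_sampler(ne * config$n_trials), ncol = ne)
  if (any(kmat <= 0)) stop("k sampler returned nonpositive values", call. = FALSE)
  rows <- vector("list", config$n_trials)
  for (t in seq_len(config$n_trials)) {
    ks <- kmat[t, ]
    grid <- exp(seq(log(min(ks) / config$grid_span[1]),
                    log(max(ks) * config$grid_span[2]),
                    length.out = config$grid_points))
    chain <- compose_chain(ks, config$edge_n, grid)
    per_level <- purrr::map(seq_len(ne), function(j) {
      resp <- chain$response[chain$level == j]
      ap <- apparent_parameters(resp, grid)
      ap$trial <- t; ap$level <- j; ap$edge_k <- ks[j]
      ap
    }) |> purrr::list_rbind()
    rows[[t]] <- per_level
  }
  out <- purrr::list_rbind(rows)
  out <- out[, c("trial", "level", "edge_k", "apparent_k", "apparent_n",
                 "apparent_emax", "converged", "reliable")]
  if (all(!out$converged)) stop("all cascade fits failed", call. = FALSE)
  attr(out, "config") <- config
  class(out) <- c("cascade_ensemble", class(out))
  out
}

#' Per-level summary of a cascade ensemble
#'
#' @param x a [simulate_ensemble()] result.
#' @param ... unused.
#' @return tibble with per-level mean and variance of apparent `k` and `n`
#'   (converged fits only) and the fraction of unreliable fits.
#' @method tidy cascade_ensemble
#' @export
tidy.cascade_ensemble <- function(x, ...) {
  dplyr::summarise(
    dplyr::group_by(tibble::as_tibble(x)[x$converged, ], .data$level),
    mean_k = mean(.data$apparent_k), var_k = stats::var(.data$apparent_k),
    mean_n = mean(.data$apparent_n), var_n = stats::var(.data$apparent_n),
    mean_emax = mean(.data$apparent_emax),
    frac_unreliable = mean(!.data$reliable),
    n_trials = dplyr::n(), .groups = "drop")
}

#' @method glance cascade_ensemble
#' @export
glance.cascade_ensemble <- function(x, ...) {
  tb <- tibble::as_tibble(x)
  lvl2 <- tb[tb$level == 2 & tb$converged, ]
  lvl1 <- tb[tb$level == 1, c("trial", "edge_k")]
  names(lvl1)[2] <- "k1"
  lvl2 <- dplyr::left_join(lvl2, lvl1, by = "trial")
  tibble::tibble(
    n_trials = max(tb$trial),
    n_levels = max(tb$level),
    frac_converged = mean(tb$converged),
    frac_k2_lt_k1 = if (nrow(lvl2) > 0) {
      mean(lvl2$apparent_k < lvl2$k1)
    } else NA_real_
  )
}
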