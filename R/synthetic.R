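#' Configuration for the synthetic regulon generator
#'
#' The generator emulates the statistical structure of a ~300-gene
#' activator-controlled regulon profiled over a 10-dose effector grid:
#' class proportions default to 74% sigmoid (HM), 9% linear/nonsaturating
#' (LM), 6% nonresponsive (NR) and 11% nonmonotonic (NM); Hill midpoints
#' `k` are log-normal with median 0.79 mM and IQR 0.26 mM, steepness `n`
#' log-normal with median 3.9 (IQR 2) truncated to (1, 20], and saturating
#' fold changes `emax` right-skewed log-normal truncated below at 1.2-fold.
#' The log-normal forms are a modelling choice (only medians and IQRs are
#' constrained); their scale parameters follow in closed form from
#' `sdlog = asinh(IQR / (2 * median)) / qnorm(0.75)`.
#'
#' Noise is multiplicative log-normal per dose with coefficient of
#' variation `noise_cv`, mean-one so fold changes stay unbiased; the
#' zero-dose anchor is exactly 1 by construction (it is the reference
#' point, not a measurement).
#'
#' @param n_genes number of genes.
#' @param class_proportions named fractions over HM/LM/NR/NM, summing to 1.
#' @param k_median,k_iqr log-normal midpoint distribution (mM).
#' @param n_median,n_iqr,n_support steepness distribution, truncated.
#' @param emax_meanlog,emax_sdlog,emax_min saturating fold-change
#'   distribution, truncated below.
#' @param noise_cv multiplicative noise CV (0 disables noise).
#' @param grid dose grid (mM), see [default_dose_grid()].
#' @param exclude_high_k_high_n reject sampled (k, n) with k > 1 and n > 5,
#'   mimicking the observed empty high-k/high-n region. Off by default.
#' @param seed integer seed for reproducibility.
#' @return list of class `regulon_config`.
#' @export
regulon_config <- function(n_genes = 305,
                           class_proportions = c(HM = 0.74, LM = 0.09,
                                                 NR = 0.06, NM = 0.11),
                           k_median = 0.79, k_iqr = 0.26,
                           n_median = 3.9, n_iqr = 2, n_support = c(1, 20),
                           emax_meanlog = log(8.9), emax_sdlog = 0.77,
                           emax_min = 1.2,
                           noise_cv = 0.10,
                           grid = default_dose_grid(),
                           exclude_high_k_high_n = FALSE,
                           seed = 1L) {
  if (abs(sum(class_proportions) - 1) > 1e-8) {
    stop("class proportions must sum to 1", call. = FALSE)
  }
  if (!all(sort(names(class_proportions)) == sort(c("HM", "LM", "NR", "NM")))) {
    stop("class proportions must be named HM, LM, NR, NM", call. = FALSE)
  }
  if (noise_cv < 0) stop("noise_cv must be nonnegative", call. = FALSE)
  validate_grid(grid)
  structure(list(
    n_genes = n_genes, class_proportions = class_proportions,
    k_median = k_median, k_iqr = k_iqr,
    n_median = n_median, n_iqr = n_iqr, n_support = n_support,
    emax_meanlog = emax_meanlog, emax_sdlog = emax_sdlog, emax_min = emax_min,
    noise_cv = noise_cv, grid = grid,
    exclude_high_k_high_n = exclude_high_k_high_n, seed = as.integer(seed)
  ), class = "regulon_config")
}

#' sdlog of a log-normal with given median and IQR
#' @noRd
.lnorm_sdlog <- function(median, iqr) {
  asinh(iqr / (2 * median)) / stats::qnorm(0.75)
}

.rlnorm_med_iqr <- function(n, median, iqr, support = c(0, Inf)) {
  s <- .lnorm_sdlog(median, iqr)
  out <- numeric(0)
  while (length(out) < n) {
    x <- stats::rlnorm(n, meanlog = log(median), sdlog = s)
    out <- c(out, x[x > support[1] & x <= support[2]])
  }
  out[seq_len(n)]
}

.rlnorm_trunc <- function(n, meanlog, sdlog, lower) {
  out <- numeric(0)
  while (length(out) < n) {
    x <- stats::rlnorm(n, meanlog, sdlog)
    out <- c(out, x[x >= lower])
  }
  out[seq_len(n)]
}

#' Nonmonotonic rise-and-fall template
#'
#' Unimodal beta-shaped bump over the dose range: 1 at dose 0, peaks at
#' `peak_dose` with fold change `height`, and decays back toward 1 at the
#' top of the range.
#'
#' @param doses dose vector (mM).
#' @param height peak fold change.
#' @param peak_dose dose of the peak (mM).
#' @param shape sharpness of the bump (larger = narrower).
#' @param max_dose top of the dose range (mM).
#' @return numeric responses.
#' @export
nm_template <- function(doses, height = 3, peak_dose = 0.8, shape = 2,
                        max_dose = max(doses)) {
  a <- shape
  b <- a * (max_dose - peak_dose) / peak_dose
  u <- pmin(doses / max_dose, 1)
  g <- u^a * (1 - u)^b
  peak <- (peak_dose / max_dose)^a * (1 - peak_dose / max_dose)^b
  1 + (height - 1) * g / peak
}

#' Generate a synthetic regulon with known ground truth
#'
#' Draws a class per gene (multinomial with the configured proportions),
#' samples class-specific true parameters, evaluates the noiseless curve,
#' and applies multiplicative log-normal noise at every dose except the
#' zero-dose reference (fixed at 1). LM-truth genes split evenly between
#' the linear and the nonsaturating power form with `n` in (1.2, 2.2) and
#' a total rise at the top dose drawn log-normally around 5-fold.
#'
#' @param config a [regulon_config()].
#' @return list with `curves` (long tibble `gene_id`, `dose`,
#'   `fold_change`) and `truth` (tibble `gene_id`, `class`, true
#'   parameters).
#' @export
#' @examples
#' synth <- generate_regulon(regulon_config(n_genes = 20, seed = 7))
#' dplyr::count(synth$truth, class)
generate_regulon <- function(config = regulon_config()) {
  stopifnot(inherits(config, "regulon_config"))
  set.seed(config$seed)
  ng <- config$n_genes
  classes <- sample(names(config$class_proportions), ng, replace = TRUE,
                    prob = config$class_proportions)
  grid <- config$grid
  max_dose <- max(grid)

  sample_hm <- function() {
    repeat {
      k <- .rlnorm_med_iqr(1, config$k_median, config$k_iqr)
      n <- .rlnorm_med_iqr(1, config$n_median, config$n_iqr,
                           support = config$n_support)
      if (!config$exclude_high_k_high_n || !(k > 1 && n > 5)) {
        return(c(k = k, n = n))
      }
    }
  }

  truth <- vector("list", ng)
  curves <- vector("list", ng)
  ids <- sprintf("gene_%04d", seq_len(ng))
  for (i in seq_len(ng)) {
    cl <- classes[i]
    if (cl == "HM") {
      kn <- sample_hm()
      emax <- .rlnorm_trunc(1, config$emax_meanlog, config$emax_sdlog,
                            config$emax_min)
      pars <- list(b0 = 1, k = unname(kn["k"]), n = unname(kn["n"]),
                   emax = emax)
      base <- evaluate_model("HM", pars, grid)
      tr <- tibble::tibble(gene_id = ids[i], class = cl,
                           b0 = 1, k = pars$k, n = pars$n, emax = pars$emax,
                           m = NA_real_, nm_height = NA_real_,
                           nm_peak = NA_real_)
    } else if (cl == "LM") {
      linear <- stats::runif(1) < 0.5
      n <- if (linear) 1 else stats::runif(1, 1.2, 2.2)
      rise <- stats::rlnorm(1, log(5), 0.4)
      m <- rise / max_dose^n
      pars <- list(b0 = 1, m = m, n = n)
      base <- evaluate_model("NONSAT", pars, grid)
      tr <- tibble::tibble(gene_id = ids[i], class = cl,
                           b0 = 1, k = NA_real_, n = n, emax = NA_real_,
                           m = m, nm_height = NA_real_, nm_peak = NA_real_)
    } else if (cl == "NR") {
      base <- rep(1, length(grid))
      tr <- tibble::tibble(gene_id = ids[i], class = cl,
                           b0 = 1, k = NA_real_, n = NA_real_,
                           emax = NA_real_, m = NA_real_,
                           nm_height = NA_real_, nm_peak = NA_real_)
    } else { # NM
      height <- .rlnorm_trunc(1, log(3), 0.3, 1.5)
      peak <- stats::runif(1, 0.5, 1.0)
      base <- nm_template(grid, height = height, peak_dose = peak,
                          max_dose = max_dose)
      tr <- tibble::tibble(gene_id = ids[i], class = cl,
                           b0 = 1, k = NA_real_, n = NA_real_,
                           emax = NA_real_, m = NA_real_,
                           nm_height = height, nm_peak = peak)
    }
    fc <- base
    if (config$noise_cv > 0) {
      s <- sqrt(log(1 + config$noise_cv^2))
      noise <- stats::rlnorm(length(grid), meanlog = -s^2 / 2, sdlog = s)
      fc <- base * noise
    }
    fc[grid == 0] <- 1
    curves[[i]] <- tibble::tibble(gene_id = ids[i], dose = grid,
                                  fold_change = fc)
    truth[[i]] <- tr
  }
  list(curves = purrr::list_rbind(curves), truth = purrr::list_rbind(truth))
}

#' Configuration for synthetic ChIP coverage tracks
#'
#' @param genome_length track length (bp).
#' @param background_rate mean test-sample read depth (reads/bp) away from
#'   peaks.
#' @param input_rate mean input-sample read depth (reads/bp).
#' @param peaks tibble with columns `center` (bp), `width` (Gaussian sd,
#'   bp) and `fold` (enrichment at the peak center over background).
#' @param seed integer seed.
#' @return list of class `track_config`.
#' @export
track_config <- function(genome_length = 50000, background_rate = 5,
                         input_rate = 5,
                         peaks = tibble::tibble(center = numeric(0),
                                                width = numeric(0),
                                                fold = numeric(0)),
                         seed = 1L) {
  if (background_rate <= 0 || input_rate <= 0) {
    stop("rates must be positive", call. = FALSE)
  }
  peaks <- tibble::as_tibble(peaks)
  if (nrow(peaks) > 0) {
    if (any(peaks$width <= 0)) stop("peak widths must be positive", call. = FALSE)
    if (any(peaks$center < 0 | peaks$center >= genome_length)) {
      stop("peaks must lie within the genome", call. = FALSE)
    }
  }
  structure(list(genome_length = as.integer(genome_length),
                 background_rate = background_rate, input_rate = input_rate,
                 peaks = peaks, seed = as.integer(seed)),
            class = "track_config")
}

#' Generate synthetic test/input coverage tracks with planted peaks
#'
#' Per-base counts: the input track is Poisson with the configured flat
#' rate; the test track is Poisson with rate `background_rate * profile`,
#' where the enrichment profile is 1 plus a Gaussian bump of amplitude
#' `fold - 1` at each planted peak (overlapping bumps add).
#'
#' @param config a [track_config()].
#' @return list with `test` and `input` coverage tibbles (`pos` 0-based,
#'   `depth`) and `truth` (the peak table).
#' @export
generate_tracks <- function(config = track_config()) {
  stopifnot(inherits(config, "track_config"))
  set.seed(config$seed)
  L <- config$genome_length
  pos <- seq_len(L) - 1L
  profile <- rep(1, L)
  if (nrow(config$peaks) > 0) {
    for (j in seq_len(nrow(config$peaks))) {
      pk <- config$peaks[j, ]
      profile <- profile +
        (pk$fold - 1) * exp(-(pos - pk$center)^2 / (2 * pk$width^2))
    }
  }
  test <- stats::rpois(L, config$background_rate * profile)
  input <- stats::rpois(L, config$input_rate)
  list(
    test = tibble::tibble(pos = pos, depth = as.numeric(test)),
    input = tibble::tibble(pos = pos, depth = as.numeric(input)),
    truth = config$peaks
  )
}
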