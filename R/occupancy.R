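#' Mode-normalize a coverage track
#'
#' Internal normalization of ChIP coverage: every per-base depth is divided
#' by the mode of the depth distribution, so the genome-wide background maps
#' to about 1. The mode is computed over strictly positive depths after
#' integer rounding; ties are broken toward the smaller depth.
#'
#' @param track tibble with columns `pos` and `depth` (reads/bp), or a bare
#'   numeric depth vector.
#' @return same shape as the input with `depth` divided by the mode.
#' @export
#' @examples
#' mode_normalize(c(4, 4, 4, 8))
mode_normalize <- function(track) {
  depth <- if (is.data.frame(track)) track$depth else track
  pos_depth <- round(depth[depth > 0])
  if (length(pos_depth) == 0) {
    stop("cannot normalize an all-zero track", call. = FALSE)
  }
  tab <- table(pos_depth)
  m <- as.numeric(names(tab)[which.max(tab)])  # which.max: first = smallest
  if (is.data.frame(track)) {
    track$depth <- track$depth / m
    track
  } else {
    depth / m
  }
}

#' Per-base enrichment ratio of test over input
#'
#' @param test_norm,input_norm equal-length normalized tracks (tibbles with
#'   `pos`/`depth`, or numeric vectors).
#' @param pseudocount added to both numerator and denominator so zero-input
#'   bases stay finite.
#' @return tibble with `pos` and `signal` (or a numeric vector for vector
#'   input).
#' @export
enrichment_ratio <- function(test_norm, input_norm, pseudocount = 0.5) {
  t_d <- if (is.data.frame(test_norm)) test_norm$depth else test_norm
  i_d <- if (is.data.frame(input_norm)) input_norm$depth else input_norm
  if (length(t_d) != length(i_d)) {
    stop("test and input tracks differ in length", call. = FALSE)
  }
  sig <- (t_d + pseudocount) / (i_d + pseudocount)
  if (is.data.frame(test_norm)) {
    tibble::tibble(pos = test_norm$pos, signal = sig)
  } else {
    sig
  }
}

#' Smooth a signal track by local regression
#'
#' Removes spurious single-base spikes with locally weighted linear
#' regression (tricube weights, [stats::lowess()] with no robustness
#' iterations) along the coordinate axis. A constant signal is returned
#' unchanged.
#'
#' @param signal tibble with `pos` and `signal`, or a numeric vector.
#' @param span fraction of the track used per local fit, in (0, 1]. The
#'   default corresponds to a few hundred bp on a genome-scale track.
#' @param delta interpolation stride passed to [stats::lowess()]; 0 (the
#'   default) evaluates the local fit at every base, which narrow promoter
#'   peaks require — the lowess default of 1% of the coordinate range
#'   flattens features narrower than the stride.
#' @return same shape as input, smoothed.
#' @export
smooth_signal <- function(signal, span = 0.0005, delta = 0) {
  if (span <= 0 || span > 1) stop("span must be in (0, 1]", call. = FALSE)
  sig <- if (is.data.frame(signal)) signal$signal else signal
  pos <- if (is.data.frame(signal)) signal$pos else seq_along(sig) - 1
  if (stats::sd(sig) == 0) {
    sm <- sig
  } else {
    sm <- stats::lowess(pos, sig, f = span, iter = 0, delta = delta)$y
  }
  if (is.data.frame(signal)) {
    tibble::tibble(pos = pos, signal = sm)
  } else {
    sm
  }
}

#' Promoter windows from a gene annotation
#'
#' The binding region of a gene is the window from 200 bp upstream to 50 bp
#' downstream of its transcription start, along the coding strand
#' (strand-aware; 0-based half-open coordinates, 251 bp total including the
#' start base).
#'
#' @param annotation tibble with `gene_id`, `start`, `end` (0-based
#'   half-open), `strand` (`"+"`/`"-"`), and optionally `operon_id`.
#' @param upstream,downstream window extent around the start (bp).
#' @return tibble with `gene_id`, `win_start`, `win_end`, `strand`,
#'   `operon_id`.
#' @export
promoter_windows <- function(annotation, upstream = 200, downstream = 50) {
  stopifnot(all(c("gene_id", "start", "end", "strand") %in% names(annotation)))
  if (!"operon_id" %in% names(annotation)) {
    annotation$operon_id <- annotation$gene_id
  }
  tss <- ifelse(annotation$strand == "+", annotation$start,
                annotation$end - 1)
  win_start <- ifelse(annotation$strand == "+", tss - upstream,
                      tss - downstream)
  win_end <- ifelse(annotation$strand == "+", tss + downstream + 1,
                    tss + upstream + 1)
  tibble::tibble(gene_id = annotation$gene_id,
                 win_start = win_start, win_end = win_end,
                 strand = annotation$strand,
                 operon_id = annotation$operon_id,
                 tss = tss)
}

#' Score promoter occupancy from a smoothed signal track
#'
#' The occupancy of a promoter is the maximum smoothed enrichment signal
#' within its window. For operons, only the first gene (the most upstream
#' in the direction of transcription) carries the operon's promoter and is
#' scored; the score is propagated as that operon's representative row.
#' Windows extending beyond the track are clipped with a warning; windows
#' entirely outside are scored `NA`.
#'
#' @param smoothed tibble with `pos` and `signal` (see [smooth_signal()]).
#' @param annotation gene annotation (see [promoter_windows()]).
#' @param upstream,downstream window extent (bp).
#' @return tibble with one row per operon representative: `gene_id`,
#'   `operon_id`, `occupancy`.
#' @export
score_promoters <- function(smoothed, annotation, upstream = 200,
                            downstream = 50) {
  win <- promoter_windows(annotation, upstream, downstream)
  # operon representative: most upstream gene along transcription direction
  rep_rows <- dplyr::slice(
    dplyr::group_by(win, .data$operon_id),
    if (dplyr::first(.data$strand) == "+") which.min(.data$tss)
    else which.max(.data$tss))
  rep_rows <- dplyr::ungroup(rep_rows)
  lo <- min(smoothed$pos); hi <- max(smoothed$pos)
  clipped <- FALSE
  occ <- purrr::pmap_dbl(
    rep_rows[, c("win_start", "win_end")],
    function(win_start, win_end) {
      s <- max(win_start, lo); e <- min(win_end, hi + 1)
      if (s < win_start || e > win_end) clipped <<- TRUE
      if (s >= e) return(NA_real_)
      sel <- smoothed$pos >= s & smoothed$pos < e
      max(smoothed$signal[sel])
    })
  if (clipped) warning("some promoter windows were clipped to the track range")
  tibble::tibble(gene_id = rep_rows$gene_id, operon_id = rep_rows$operon_id,
                 occupancy = occ)
}

#' Bin promoters as direct or indirect targets
#'
#' Curated direct targets define an occupancy cutoff — by default the
#' bottom quartile (Q1, linear-interpolation quantile) of their occupancy
#' scores. The direct set is the union of the curated genes and every
#' scored gene whose occupancy exceeds the cutoff; the curated set is
#' always contained in the direct set.
#'
#' @param occupancy a [score_promoters()] table.
#' @param curated_direct_ids character vector of curated direct gene ids;
#'   ids absent from the table are dropped with a warning.
#' @param quantile quantile of curated occupancy used as cutoff.
#' @return the occupancy table with added `curated` and `label`
#'   (`"direct"`/`"indirect"`) columns; the numeric cutoff is attached as
#'   attribute `"cutoff"` (also via [direct_cutoff()]).
#' @export
bin_direct_indirect <- function(occupancy, curated_direct_ids,
                                quantile = 0.25) {
  if (length(curated_direct_ids) == 0) {
    stop("curated direct set is empty", call. = FALSE)
  }
  missing <- setdiff(curated_direct_ids, occupancy$gene_id)
  if (length(missing) > 0) {
    warning(length(missing), " curated id(s) not in the occupancy table")
  }
  curated <- occupancy$gene_id %in% curated_direct_ids
  if (!any(curated)) stop("no curated gene has an occupancy score", call. = FALSE)
  cutoff <- stats::quantile(occupancy$occupancy[curated], probs = quantile,
                            na.rm = TRUE, type = 7, names = FALSE)
  occupancy$curated <- curated
  occupancy$label <- ifelse(
    curated | (!is.na(occupancy$occupancy) & occupancy$occupancy > cutoff),
    "direct", "indirect")
  attr(occupancy, "cutoff") <- cutoff
  occupancy
}

#' @rdname bin_direct_indirect
#' @param binned a [bin_direct_indirect()] result.
#' @export
direct_cutoff <- function(binned) attr(binned, "cutoff")
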