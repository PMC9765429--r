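#' Read a dose-response curves table
#'
#' Wide TSV dialect: a `gene_id` column followed by one column per dose,
#' column names being the doses in mM, values linear fold change relative
#' to the zero-dose reference. With `log2 = TRUE` the values are read as
#' log2 fold changes and exponentiated on load (log scale distorts trend
#' shapes and magnitudes, so all downstream analysis is on the linear
#' scale).
#'
#' @param path TSV file path.
#' @param log2 values are log2 fold changes.
#' @return long tibble `gene_id`, `dose`, `fold_change` (validated).
#' @export
read_curves <- function(path, log2 = FALSE) {
  wide <- readr::read_tsv(path, show_col_types = FALSE)
  if (names(wide)[1] != "gene_id") {
    stop("curves TSV must start with a gene_id column (", path, ")",
         call. = FALSE)
  }
  doses <- suppressWarnings(as.numeric(names(wide)[-1]))
  if (anyNA(doses)) {
    bad <- names(wide)[-1][is.na(doses)]
    stop("non-numeric dose column name(s): ", paste(bad, collapse = ", "),
         " (", path, ")", call. = FALSE)
  }
  long <- tidyr::pivot_longer(wide, -"gene_id", names_to = "dose",
                              values_to = "fold_change")
  long$dose <- as.numeric(long$dose)
  if (log2) long$fold_change <- 2^long$fold_change
  long <- long[order(match(long$gene_id, wide$gene_id), long$dose), ]
  validate_curves(long)
  long
}

#' Write a dose-response curves table
#'
#' @param curves long curves tibble.
#' @param path output TSV path.
#' @return `path`, invisibly.
#' @export
write_curves <- function(curves, path) {
  validate_curves(curves)
  wide <- tidyr::pivot_wider(curves, id_cols = "gene_id",
                             names_from = "dose", values_from = "fold_change")
  readr::write_tsv(wide, path)
  invisible(path)
}

#' Read or write a bedGraph coverage track
#'
#' bedGraph (4 columns: chrom, start, end, value; 0-based half-open) via
#' rtracklayer, expanded to a per-base depth tibble over the contiguous
#' covered range.
#'
#' @param path bedGraph file path.
#' @return tibble with `pos` (0-based) and `depth`.
#' @export
read_bedgraph <- function(path) {
  if (!requireNamespace("rtracklayer", quietly = TRUE)) {
    stop("rtracklayer is required for bedGraph IO", call. = FALSE)
  }
  gr <- rtracklayer::import(path, format = "bedGraph")
  starts <- BiocGenerics::start(gr) - 1L  # GRanges is 1-based
  ends <- BiocGenerics::end(gr)           # inclusive -> half-open end
  vals <- gr$score
  pos <- unlist(Map(seq, starts, ends - 1L))
  depth <- rep(vals, ends - starts)
  ord <- order(pos)
  tibble::tibble(pos = as.integer(pos[ord]), depth = as.numeric(depth[ord]))
}

#' @rdname read_bedgraph
#' @param track per-base tibble (`pos`, `depth`).
#' @param chrom chromosome name to write.
#' @return `path`, invisibly.
#' @export
write_bedgraph <- function(track, path, chrom = "chr") {
  # run-length encode equal-depth stretches into bedGraph intervals
  r <- rle(track$depth)
  ends <- cumsum(r$lengths)
  starts <- c(0L, ends[-length(ends)])
  df <- data.frame(chrom = chrom, start = track$pos[1] + starts,
                   end = track$pos[1] + ends, value = r$values)
  utils::write.table(df, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = FALSE)
  invisible(path)
}

#' Read a gene/operon annotation table
#'
#' TSV with columns `gene_id`, `start`, `end`, `strand` and optionally
#' `operon_id` (0-based half-open coordinates).
#'
#' @param path TSV path.
#' @return annotation tibble.
#' @export
read_annotation <- function(path) {
  ann <- readr::read_tsv(path, show_col_types = FALSE)
  need <- c("gene_id", "start", "end", "strand")
  missing <- setdiff(need, names(ann))
  if (length(missing) > 0) {
    stop("annotation is missing column(s): ",
         paste(missing, collapse = ", "), " (", path, ")", call. = FALSE)
  }
  ann
}

#' Read a curated gene list (one id per line)
#'
#' @param path plain-text path.
#' @return character vector of gene ids.
#' @export
read_gene_list <- function(path) {
  ids <- readr::read_lines(path)
  ids[nzchar(trimws(ids))]
}

#' Read a per-gene fit table
#'
#' Reads back the per-gene winning-fit TSV written by [run_pipeline()] (or
#' an externally assembled table in the same dialect): one row per gene
#' with at least `gene_id` and `class`, plus whichever estimate columns
#' (`k`, `n`, `emax`, ...) are present.
#'
#' @param path TSV path.
#' @return tibble.
#' @export
read_fit_table <- function(path) {
  tb <- readr::read_tsv(path, show_col_types = FALSE)
  if (!all(c("gene_id", "class") %in% names(tb))) {
    stop("fit table needs gene_id and class columns (", path, ")",
         call. = FALSE)
  }
  tb
}
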