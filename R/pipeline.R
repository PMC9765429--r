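#' Run the full synthetic-data analysis pipeline
#'
#' End-to-end chain: generate a synthetic regulon with known ground truth,
#' fit all four response models to every gene, classify, cluster the
#' z-scored trends (k-means at `cluster_k` plus optimum-k diagnostics),
#' cross-tabulate clusters against model-fit classes, and summarize the
#' fitted Hill parameters. All artifacts are written as TSV/JSON next to a
#' resolved-config YAML and a run manifest (input checksums, stage
#' timings, warning counts), so a run is reproducible from its output
#' directory alone.
#'
#' @param out_dir output directory (created if needed).
#' @param config a [regulon_config()]; its seed drives every stage.
#' @param thresholds a [selection_thresholds()].
#' @param cluster_k cluster count for the trend k-means.
#' @param write write artifacts to `out_dir` (set `FALSE` to only return
#'   objects).
#' @return invisibly, a list with `curves`, `truth`, `fits`,
#'   `classification`, `kmeans`, `diagnostics`, `crosstab`, `summaries`,
#'   and `paths` of written artifacts.
#' @export
run_pipeline <- function(out_dir = ".", config = regulon_config(),
                         thresholds = selection_thresholds(),
                         cluster_k = 4, write = TRUE) {
  timings <- list()
  warn_count <- 0L
  step <- function(name, expr) {
    t0 <- Sys.time()
    res <- withCallingHandlers(expr, warning = function(w) {
      warn_count <<- warn_count + 1L
      invokeRestart("muffleWarning")
    })
    timings[[name]] <<- as.numeric(difftime(Sys.time(), t0, units = "secs"))
    res
  }

  synth <- step("synth", generate_regulon(config))
  fits <- step("fit", fit_models(synth$curves))
  cls <- step("classify",
              classify_regulon(synth$curves, thresholds, fits = fits))
  z <- step("zscore", zscore_trends(synth$curves))
  km <- step("kmeans", kmeans_trends(z, cluster_k, seed = config$seed))
  diag <- step("choose_k",
               choose_k(z, k_range = 2:min(8, nrow(z) - 1),
                        seed = config$seed))
  ct <- step("crosstab", crosstab(
    km$assignment,
    tibble::tibble(gene_id = cls$gene_id, class = cls$class)))
  hm <- cls[cls$class == "HM", ]
  summaries <- step("summarize", purrr::list_rbind(list(
    summarize_parameter(hm$k, "k"),
    summarize_parameter(hm$n, "n"),
    summarize_parameter(hm$emax, "emax"),
    summarize_parameter(hm$b0, "b0"))))

  paths <- character(0)
  if (write) {
    dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
    pth <- function(f) file.path(out_dir, f)
    write_curves(synth$curves, pth("curves.tsv"))
    readr::write_tsv(synth$truth, pth("truth.tsv"))
    readr::write_tsv(fits, pth("fits.tsv"))
    cls_out <- dplyr::select(tibble::as_tibble(cls), -"rejection_log")
    readr::write_tsv(cls_out, pth("classification.tsv"))
    readr::write_tsv(km$assignment, pth("kmeans_assignment.tsv"))
    readr::write_tsv(tibble::as_tibble(diag), pth("cluster_diagnostics.tsv"))
    readr::write_tsv(summaries, pth("parameter_summaries.tsv"))
    jsonlite::write_json(
      list(class_counts = class_counts(cls),
           thresholds = unclass(thresholds),
           crosstab_matching = ct$matching),
      pth("summary.json"), auto_unbox = TRUE, digits = NA)
    cfg <- unclass(config)
    cfg$class_proportions <- as.list(cfg$class_proportions)
    yaml::write_yaml(cfg, pth("config.yaml"))
    data_files <- c("curves.tsv", "truth.tsv", "fits.tsv",
                    "classification.tsv", "kmeans_assignment.tsv",
                    "cluster_diagnostics.tsv", "parameter_summaries.tsv")
    manifest <- list(
      tool = paste("trendfit",
                   as.character(utils::packageVersion("trendfit"))),
      seed = config$seed,
      checksums = as.list(tools::md5sum(file.path(out_dir, data_files))),
      timings_sec = timings,
      n_warnings = warn_count)
    # manifest written last, atomically (write to temp then rename)
    tmp <- tempfile(tmpdir = out_dir)
    jsonlite::write_json(manifest, tmp, auto_unbox = TRUE, digits = NA)
    file.rename(tmp, pth("manifest.json"))
    paths <- file.path(out_dir, c(data_files, "summary.json", "config.yaml",
                                  "manifest.json"))
  }

  invisible(list(curves = synth$curves, truth = synth$truth, fits = fits,
                 classification = cls, kmeans = km, diagnostics = diag,
                 crosstab = ct, summaries = summaries, paths = paths))
}
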