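test_that("mode normalization divides by the modal depth", {
  expect_equal(mode_normalize(c(4, 4, 4, 8)), c(1, 1, 1, 2))
  tr <- tibble::tibble(pos = 0:4, depth = c(10, 10, 10, 35, 0))
  out <- mode_normalize(tr)
  expect_equal(out$depth, c(1, 1, 1, 3.5, 0))
  expect_error(mode_normalize(c(0, 0, 0)), "all-zero")
  # scale equivariance on integer-scaled tracks
  base <- c(3, 3, 3, 6, 9, 3)
  expect_equal(mode_normalize(base * 7L), mode_normalize(base))
  # ties broken toward the smaller depth
  expect_equal(mode_normalize(c(2, 2, 5, 5)), c(1, 1, 2.5, 2.5))
})

test_that("enrichment ratio honors the pseudocount contract", {
  expect_equal(enrichment_ratio(c(1, 2, 3), c(1, 2, 3), 0), c(1, 1, 1))
  expect_equal(enrichment_ratio(c(2, 4), c(1, 2), 0), c(2, 2))
  r <- enrichment_ratio(c(5), c(0), 0.5)
  expect_true(is.finite(r))
  expect_equal(r, 5.5 / 0.5)
  expect_error(enrichment_ratio(1:3, 1:4), "length")
})

test_that("smoothing attenuates spikes, keeps peaks in place, preserves constants", {
  n <- 2000
  const <- rep(2, n)
  expect_equal(smooth_signal(const, span = 0.05), const)
  spike <- rep(1, n); spike[1000] <- 100
  sm <- smooth_signal(spike, span = 0.05)  # span covers ~100 bases
  expect_lt(max(sm), 100)
  expect_gt(max(sm), 1)
  x <- seq_len(n)
  bump <- 1 + 5 * exp(-(x - 800)^2 / (2 * 85^2))  # ~200 bp wide bump
  smb <- smooth_signal(bump, span = 0.05)
  expect_lt(abs(which.max(smb) - 800), 5)
  expect_error(smooth_signal(bump, span = 0), "span")
})

test_that("promoter windows are strand-aware, 251 bp, and operon-deduplicated", {
  ann <- tibble::tibble(
    gene_id = c("gA", "gB", "gC"),
    start = c(1000, 2000, 5000), end = c(1600, 2900, 5800),
    strand = c("+", "+", "-"),
    operon_id = c("op1", "op1", "op2"))
  win <- promoter_windows(ann)
  expect_true(all(win$win_end - win$win_start == 251))
  expect_equal(win$win_start[1], 800)   # plus strand: start - 200
  expect_equal(win$win_end[1], 1051)
  expect_equal(win$win_start[3], 5749)  # minus strand: tss at end - 1
  expect_equal(win$win_end[3], 6000)

  sig <- tibble::tibble(pos = 0:9999, signal = 1)
  occ <- score_promoters(sig, ann)
  expect_equal(nrow(occ), 2)  # one promoter per operon
  expect_true("gA" %in% occ$gene_id)   # first gene of op1 on + strand
  expect_false("gB" %in% occ$gene_id)
  expect_equal(occ$occupancy, c(1, 1))
})

test_that("planted peaks are recovered and ranked by fold", {
  peaks <- tibble::tibble(center = c(5000, 15000, 25000, 35000),
                          width = rep(120, 4),
                          fold = c(12, 3, 7, 20))
  cfg <- track_config(genome_length = 42000, background_rate = 8,
                      input_rate = 8, peaks = peaks, seed = 4)
  tracks <- generate_tracks(cfg)
  sig <- enrichment_ratio(mode_normalize(tracks$test),
                          mode_normalize(tracks$input))
  sm <- smooth_signal(sig, span = 500 / 42000)
  ann <- tibble::tibble(
    gene_id = paste0("g", 1:4),
    start = peaks$center + 100,  # peak sits inside [-200, +50) window
    end = peaks$center + 1100,
    strand = "+", operon_id = paste0("op", 1:4))
  occ <- score_promoters(sm, ann)
  expect_equal(nrow(occ), 4)
  # score ranking matches planted fold ranking exactly
  expect_equal(stats::cor(occ$occupancy, peaks$fold, method = "spearman"), 1)
  # peak heights roughly match the planted enrichment
  expect_gt(occ$occupancy[4], occ$occupancy[1])
  expect_gt(occ$occupancy[1], 5)
})

test_that("null tracks give promoter scores concentrated near one", {
  cfg <- track_config(genome_length = 30000, background_rate = 6,
                      input_rate = 6, seed = 9)
  tracks <- generate_tracks(cfg)
  sig <- enrichment_ratio(mode_normalize(tracks$test),
                          mode_normalize(tracks$input))
  sm <- smooth_signal(sig, span = 500 / 30000)
  starts <- seq(500, 29000, by = 1000)
  ann <- tibble::tibble(gene_id = paste0("g", seq_along(starts)),
                        start = starts, end = starts + 500, strand = "+",
                        operon_id = paste0("op", seq_along(starts)))
  occ <- score_promoters(sm, ann)
  expect_lt(stats::quantile(abs(occ$occupancy - 1), 0.95), 0.25)
})

test_that("direct/indirect binning uses the curated quantile cutoff", {
  occ <- tibble::tibble(
    gene_id = paste0("g", 1:8), operon_id = paste0("g", 1:8),
    occupancy = c(2.8, 3.0, 4.0, 10.0, 1.0, 3.5, 2.0, 0.5))
  curated <- paste0("g", 1:4)
  binned <- bin_direct_indirect(occ, curated, quantile = 0.25)
  expect_equal(direct_cutoff(binned),
               stats::quantile(c(2.8, 3, 4, 10), 0.25, type = 7,
                               names = FALSE))
  # curated genes always direct, even below cutoff
  expect_true(all(binned$label[binned$curated] == "direct"))
  expect_equal(binned$label[binned$gene_id == "g6"], "direct")   # 3.5 > 2.85
  expect_equal(binned$label[binned$gene_id == "g7"], "indirect") # 2.0
  # quantile = 0: cutoff is the curated minimum
  b0 <- bin_direct_indirect(occ, curated, quantile = 0)
  expect_equal(direct_cutoff(b0), 2.8)
  # all non-curated below cutoff: direct set equals the curated set
  occ2 <- occ; occ2$occupancy[5:8] <- 0.1
  b2 <- bin_direct_indirect(occ2, curated)
  expect_setequal(b2$gene_id[b2$label == "direct"], curated)
  expect_error(bin_direct_indirect(occ, character(0)), "empty")
  expect_warning(bin_direct_indirect(occ, c(curated, "nope")),
                 "not in the occupancy")
})
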