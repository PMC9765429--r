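test_that("parameter summaries match direct arithmetic", {
  s <- summarize_parameter(c(1, 2, 3, 4, 5), "k")
  expect_equal(s$median, 3)
  expect_equal(s$iqr, 2)
  expect_equal(s$madm_pct, 100 * 1 / 3)
  expect_equal(s$min, 1)
  expect_equal(s$max, 5)
  expect_equal(s$iqr_over_range_pct, 50)
  eq <- summarize_parameter(rep(2, 5))
  expect_equal(eq$iqr, 0)
  expect_equal(eq$madm_pct, 0)
  expect_error(summarize_parameter(numeric(0)), "at least 2")
  # invariances: reordering changes nothing; MADM is scale-free, IQR scales
  x <- c(2.3, 0.7, 1.9, 4.4, 0.9, 3.1)
  expect_equal(summarize_parameter(sample(x)), summarize_parameter(x))
  expect_equal(summarize_parameter(10 * x)$madm_pct,
               summarize_parameter(x)$madm_pct)
  expect_equal(summarize_parameter(10 * x)$iqr, 10 * summarize_parameter(x)$iqr)
})

test_that("rank-sum p matches exhaustive enumeration for small groups", {
  r <- compare_groups(c(1, 2, 3), c(101, 102, 103))
  expect_equal(r$p_value, 0.1)  # most extreme of the C(6,3)=20 orderings
  expect_equal(r$p_value, oracle_ranksum_p(c(1, 2, 3), c(101, 102, 103)))
  set.seed(6)
  for (sizes in list(c(3, 3), c(4, 5), c(6, 6), c(2, 6))) {
    x <- rnorm(sizes[1]); y <- rnorm(sizes[2], 0.5)
    expect_equal(compare_groups(x, y)$p_value, oracle_ranksum_p(x, y),
                 tolerance = 1e-10)
  }
  same <- compare_groups(c(1, 3, 5), c(2, 4, 6))
  expect_lte(same$p_value, 1)
  expect_error(compare_groups(numeric(0), 1:3), "nonempty")
})

test_that("identical distributions give p = 1 and shifts are detected", {
  p_id <- compare_groups(c(1, 4, 9), c(2, 5, 10))  # interleaved, symmetric W
  expect_gt(p_id$p_value, 0.5)
  set.seed(10)
  a <- rnorm(100); b <- rnorm(100, 1)
  expect_lt(compare_groups(a, b)$p_value, 0.01)
})

test_that("correlations behave for monotone, exact, and null relations", {
  x <- c(1, 2, 3, 4, 5)
  expect_equal(correlate(x, x, "pearson")$estimate, 1)
  expect_equal(correlate(x, x, "spearman")$estimate, 1)
  ex <- correlate(x, exp(x), "spearman")
  expect_equal(ex$estimate, 1)
  expect_lt(correlate(x, exp(x), "pearson")$estimate, 1)
  set.seed(8)
  nullr <- correlate(rnorm(1000), rnorm(1000), "spearman")
  expect_lt(abs(nullr$estimate), 0.1)
  expect_true(is.na(correlate(rep(1, 5), x, "pearson")$estimate))
  expect_error(correlate(1:3, 1:4), "length")
})

test_that("Fisher enrichment matches hypergeometric enumeration for all small tables", {
  # every 2x2 table with all four margins at most 12
  checked <- 0L
  worst <- 0
  for (a in 0:12) for (b in 0:(12 - a)) for (cc in 0:(12 - a)) {
    for (d in 0:(min(12 - cc, 12 - b))) {
      if (a + b + cc + d == 0) next
      p_impl <- stats::fisher.test(matrix(c(a, b, cc, d), 2,
                                          byrow = TRUE))$p.value
      worst <- max(worst, abs(p_impl - oracle_fisher_p(a, b, cc, d)))
      checked <- checked + 1L
    }
  }
  expect_lt(worst, 1e-9)
  expect_gt(checked, 5000)
})

test_that("enrichment builds the right table from gene sets", {
  universe <- paste0("g", 1:20)
  class_m <- paste0("g", 1:10)
  cat_m <- paste0("g", c(1:8, 11, 12))
  e <- enrichment(cat_m, class_m, universe)
  expect_equal(c(e$a, e$b, e$c, e$d), c(8, 2, 2, 8))
  expect_equal(e$p_value, oracle_fisher_p(8, 2, 2, 8))
  bal <- enrichment(paste0("g", c(1:5, 11:15)), class_m, universe)
  expect_equal(c(bal$a, bal$b, bal$c, bal$d), c(5, 5, 5, 5))
  expect_equal(bal$p_value, 1)
  ident <- enrichment(class_m, class_m, universe)
  expect_true(is.infinite(ident$odds_ratio))
  expect_error(enrichment(cat_m, class_m, character(0)), "empty")
})

test_that("enrichment_table adjusts p across categories within class", {
  classes <- tibble::tibble(gene_id = paste0("g", 1:20),
                            class = rep(c("HM", "LM"), each = 10))
  cats <- tibble::tibble(gene_id = paste0("g", c(1:8, 11, 12)),
                         category = "respiration")
  et <- enrichment_table(cats, classes)
  expect_equal(nrow(et), 2)
  expect_true(all(et$p_adjusted >= et$p_value))
})

test_that("quartile bins use type-7 quantiles with lower-bin ties", {
  expect_equal(as.character(quartile_bins(1:8)),
               c("Q1", "Q1", "Q2", "Q2", "Q3", "Q3", "Q4", "Q4"))
  expect_equal(as.character(quartile_bins(rep(3, 6))), rep("Q1", 6))
  set.seed(2)
  for (i in 1:5) {
    v <- rnorm(40 + i)
    sizes <- table(quartile_bins(v))
    expect_lte(max(sizes) - min(sizes), 1)
  }
  expect_error(quartile_bins(1:3), "at least 4")
})

test_that("vocabulary bins follow the field thresholds", {
  v <- parameter_vocabulary(n = c(2, 4, 6), k = c(0.5, 0.8, 1.2))
  expect_equal(as.character(v$n_label), c("low", "moderate", "high"))
  expect_equal(as.character(v$k_label), c("low", "moderate", "high"))
})
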