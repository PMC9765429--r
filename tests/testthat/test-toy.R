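test_that("two first-order edges compose to the exact algebraic Hill curve", {
  grid <- exp(seq(log(0.001), log(100), length.out = 80))
  ch <- compose_chain(c(0.5, 0.5), edge_n = 1, grid = grid)
  r2 <- ch$response[ch$level == 2]
  # Emax' = 1/(1+k2) = 2/3, k' = k1*k2/(1+k2) = 1/6
  expected <- (2 / 3) * grid / (1 / 6 + grid)
  expect_equal(r2, expected, tolerance = 1e-12)
})

test_that("chains vanish at dose zero and a single edge is its own Hill curve", {
  grid <- c(0, 0.1, 1, 10)
  ch <- compose_chain(c(0.7, 0.3, 0.9), edge_n = 2, grid = grid)
  expect_true(all(ch$response[ch$dose == 0] == 0))
  one <- compose_chain(0.7, edge_n = 2, grid = grid)
  expect_equal(one$response, grid^2 / (0.7^2 + grid^2))
  expect_true(all(ch$response >= 0 & ch$response < 1))
  expect_error(compose_chain(c(0.5, -1), 2, grid), "positive")
})

test_that("first-order chain recursion matches brute-force evaluation and the fit", {
  set.seed(11)
  grid <- exp(seq(log(1e-4), log(1e3), length.out = 60))
  for (i in 1:5) {
    ks <- runif(3, 0.3, 1.5)
    oracle <- oracle_first_order_chain(ks)
    ch <- compose_chain(ks, edge_n = 1, grid = grid)
    r3 <- ch$response[ch$level == 3]
    # the recursion itself is checked against brute-force composition
    expect_equal(r3, oracle$emax * grid / (oracle$k + grid),
                 tolerance = 1e-10)
    ap <- apparent_parameters(r3, grid)
    expect_equal(ap$apparent_k, oracle$k, tolerance = 1e-3)
    expect_equal(ap$apparent_n, 1, tolerance = 1e-3)
    expect_equal(ap$apparent_emax, oracle$emax, tolerance = 1e-3)
  }
})

test_that("apparent parameters recover an exact Hill input", {
  grid <- exp(seq(log(0.005), log(50), length.out = 60))
  resp <- grid^2 / (0.7^2 + grid^2)
  ap <- apparent_parameters(resp, grid)
  expect_equal(ap$apparent_k, 0.7, tolerance = 1e-4)
  expect_equal(ap$apparent_n, 2, tolerance = 1e-4)
  expect_equal(ap$apparent_emax, 1, tolerance = 1e-4)
  expect_true(ap$reliable)
})

test_that("two-edge n=2 apparent midpoint matches the brute-force half-max", {
  for (ks in list(c(0.8, 0.3), c(0.7, 0.4), c(1.2, 0.5))) {
    half <- oracle_half_max(ks, n = 2)
    grid <- exp(seq(log(min(ks) / 100), log(max(ks) * 100),
                    length.out = 60))
    ch <- compose_chain(ks, edge_n = 2, grid = grid)
    ap <- apparent_parameters(ch$response[ch$level == 2], grid)
    expect_equal(ap$apparent_k, half, tolerance = 0.02)
  }
})

test_that("a non-plateaued response is flagged unreliable, not raised", {
  grid <- seq(0.01, 0.5, length.out = 20)  # well below k
  resp <- grid^2 / (5^2 + grid^2)
  ap <- apparent_parameters(resp, grid)
  expect_false(ap$reliable)
})

test_that("ensemble summaries behave per the cascade null model", {
  ens <- simulate_ensemble(chain_config(n_trials = 150, seed = 7))
  td <- tidy(ens)
  expect_equal(td$level, 1:3)
  # level-1 apparent values equal the sampled edge values up to fit tolerance
  tb <- tibble::as_tibble(ens)
  l1 <- tb[tb$level == 1 & tb$converged, ]
  expect_equal(l1$apparent_k, l1$edge_k, tolerance = 1e-3)
  expect_equal(l1$apparent_n, rep(2, nrow(l1)), tolerance = 1e-3)
  # mean and variance of apparent k and n increase along the chain
  expect_true(all(diff(td$mean_k) > 0))
  expect_true(all(diff(td$var_k) > 0))
  expect_true(all(diff(td$mean_n) > 0))
  expect_true(all(diff(td$var_n) > 0))
  # apparent saturation decays along the chain
  expect_true(all(diff(td$mean_emax) < 0))
  # some trials show apparent k2 below that trial's k1
  gl <- glance(ens)
  expect_gt(gl$frac_k2_lt_k1, 0)
  # reproducibility
  ens2 <- simulate_ensemble(chain_config(n_trials = 150, seed = 7))
  expect_equal(tibble::as_tibble(ens2), tb)
})

test_that("a single fixed-k trial equals compose + fit", {
  cfg <- chain_config(n_trials = 1, k_sampler = function(n) rep(0.8, n),
                      seed = 1)
  ens <- simulate_ensemble(cfg)
  tb <- tibble::as_tibble(ens)
  grid <- exp(seq(log(0.8 / 100), log(0.8 * 100), length.out = 60))
  ch <- compose_chain(rep(0.8, 3), 2, grid)
  for (j in 1:3) {
    ap <- apparent_parameters(ch$response[ch$level == j], grid)
    expect_equal(tb$apparent_k[tb$level == j], ap$apparent_k)
    expect_equal(tb$apparent_n[tb$level == j], ap$apparent_n)
  }
})

test_that("empirical k sampler resamples the supplied values", {
  s <- empirical_k_sampler(c(0.5, 0.9, 1.3))
  set.seed(1)
  draws <- s(200)
  expect_true(all(draws %in% c(0.5, 0.9, 1.3)))
  expect_error(empirical_k_sampler(c(0.5, -1)))
})
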