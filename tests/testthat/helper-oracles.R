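# Independent oracles, kept free of the implementation paths they check.

# Two-sided Fisher exact p by direct hypergeometric enumeration over all
# tables with the observed margins.
oracle_fisher_p <- function(a, b, c, d) {
  K <- a + b            # row 1 total
  n <- a + c            # column 1 total
  N <- a + b + c + d
  xs <- max(0, n - (N - K)):min(K, n)
  probs <- stats::dhyper(xs, K, N - K, n)
  p_obs <- stats::dhyper(a, K, N - K, n)
  sum(probs[probs <= p_obs * (1 + 1e-7)])
}

# Two-sided exact rank-sum p by enumerating every assignment of ranks to
# group A.
oracle_ranksum_p <- function(x, y) {
  n1 <- length(x); n2 <- length(y)
  r <- rank(c(x, y))
  w_obs <- sum(r[seq_len(n1)]) - n1 * (n1 + 1) / 2
  all_w <- apply(utils::combn(n1 + n2, n1), 2, function(idx) {
    sum(seq_len(n1 + n2)[idx]) - n1 * (n1 + 1) / 2
  })
  pl <- mean(all_w <= w_obs); pg <- mean(all_w >= w_obs)
  min(1, 2 * min(pl, pg))
}

# Exact parameters of a first-order (n = 1) Hill chain: each edge has
# b0 = 0, emax = 1, midpoint ks[j]; the composition is again first-order
# Hill with these parameters.
oracle_first_order_chain <- function(ks) {
  kp <- ks[1]; ep <- 1
  for (j in seq_along(ks)[-1]) {
    kp_new <- kp * ks[j] / (ep + ks[j])
    ep <- ep / (ep + ks[j])
    kp <- kp_new
  }
  list(k = kp, emax = ep)
}

# Brute-force half-saturation dose of a composed chain (any n): the dose
# where the response crosses half its plateau.
oracle_half_max <- function(ks, n) {
  f <- function(cc) {
    r <- cc
    for (k in ks) r <- r^n / (k^n + r^n)
    r
  }
  plateau <- f(1e9)
  stats::uniroot(function(cc) f(cc) - plateau / 2,
                 c(1e-9, 1e9), tol = 1e-12)$root
}

# Best label agreement between a clustering and ground-truth classes,
# maximized over all cluster -> class bijections (exact Hungarian
# equivalent at small k).
oracle_label_agreement <- function(clusters, classes) {
  cl_lev <- unique(clusters); cls_lev <- unique(classes)
  k <- length(cl_lev)
  perms <- function(v) {
    if (length(v) <= 1) return(list(v))
    out <- list()
    for (i in seq_along(v)) {
      for (p in perms(v[-i])) out[[length(out) + 1]] <- c(v[i], p)
    }
    out
  }
  if (length(cls_lev) < k) cls_lev <- c(cls_lev, rep(NA, k - length(cls_lev)))
  best <- 0
  for (p in perms(cls_lev)) {
    mapped <- p[match(clusters, cl_lev)]
    best <- max(best, mean(mapped == classes, na.rm = FALSE))
  }
  best
}

# Noiseless curve construction helpers.
make_curve <- function(model_id, params, gene_id = "g1",
                       grid = default_dose_grid()) {
  tibble::tibble(gene_id = gene_id, dose = grid,
                 fold_change = evaluate_model(model_id, params, grid))
}

# Deterministic inverted-U curve used across classification tests: rises to
# about 3-fold near 0.6 mM and falls back to 1 by 4 mM.
make_inverted_u <- function(gene_id = "nm1", grid = default_dose_grid()) {
  tibble::tibble(gene_id = gene_id, dose = grid,
                 fold_change = nm_template(grid, height = 3,
                                           peak_dose = 0.6))
}
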