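# Small planted-archetype regulon shared by clustering and acceptance tests.
planted_curves <- function(n_per = 12, cv = 0.04, seed = 31) {
  set.seed(seed)
  grid <- default_dose_grid()
  shapes <- list(
    S = evaluate_model("HM", list(b0 = 1, k = 0.6, n = 6, emax = 8), grid),
    L = evaluate_model("LIN", list(b0 = 1, m = 1.2), grid),
    NMb = nm_template(grid, height = 3, peak_dose = 0.7),
    # gentle repression: monotone decline, opposite direction to L
    F = 1 - 0.35 * grid^2 / (0.5^2 + grid^2))
  purrr::imap(shapes, function(base, nm) {
    purrr::map(seq_len(n_per), function(i) {
      fc <- base * exp(rnorm(10, 0, cv)); fc[1] <- base[1]
      tibble::tibble(gene_id = paste0(nm, "_", i), archetype = nm,
                     dose = grid, fold_change = fc)
    }) |> purrr::list_rbind()
  }) |> purrr::list_rbind()
}

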