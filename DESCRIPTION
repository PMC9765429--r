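Package: trendfit
Title: Phenomenological Model Fitting for Genome-Wide Dose-Response Trends
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Fits and selects among phenomenological response models (Hill,
    nonsaturating power, linear, and null) for genome-wide dose-response
    curves such as the transcriptional response of a bacterial regulon to a
    titrated effector. Provides the custom goodness-of-fit panel used for
    nonlinear fits (predicted-versus-observed R-squared, slope and relative
    standard errors), cascading model-selection rules, a Hill-cascade null
    model for apparent cooperativity of indirectly regulated genes, ChIP
    coverage promoter-occupancy scoring, trend clustering diagnostics, robust
    parameter summaries, and a synthetic-data generator with known ground
    truth for end-to-end validation.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    cluster,
    dplyr,
    generics,
    ggplot2,
    jsonlite,
    minpack.lm,
    purrr,
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    tools,
    utils,
    yaml
Suggests:
    BiocGenerics,
    withr,
    rtracklayer,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
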