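# trendfit

Phenomenological model fitting for genome-wide dose-response trends.

## The problem

When a global transcription factor is titrated over a concentration
gradient — for example the cAMP–CRP system of *E. coli* driven across
ten extracellular cAMP doses from 0 to 4 mM — every regulated gene traces
its own dose-response curve. Clustering such curves shows broad shape
families but little more. `trendfit` instead summarizes each gene's curve
with one of four phenomenological models and selects among them, turning a
regulon-scale expression data set into a table of interpretable constants:

* **HM** (Hill): `E(c) = b0 + (Emax − b0) · c^n / (k^n + c^n)` — a sigmoid
  with basal level `b0` (fold change), half-saturation midpoint `k` (mM),
  steepness `n`, and saturating fold change `Emax`;
* **LM** (linear / nonsaturating): `E(c) = b0 + m·c^n` or `b0 + m·c`, for
  genes whose saturation lies beyond the tested range;
* **NR** (null): `E(c) = b0`, no response;
* **NM** (nonmonotonic): rise-then-fall curves that fit none of the
  monotone models.

Because classical R² is not meaningful for nonlinear fits, fit quality is
judged by regressing observed on model-predicted values (`R²_NLfit`,
`slope_NLfit`, and its p-value), alongside the residual variance
`σ² = SSE/(N − p)` used to compare competing models and relative standard
errors (RSE) of the estimates. A gene is accepted as sigmoid only when the
Hill fit has the strictly smallest σ², `R²_NLfit > 0.8` (p < 0.05),
`slope_NLfit = 1 ± 0.2`, and RSE(k), RSE(Emax) < 20%.

The package also provides the surrounding analyses such a study needs: a
synthetic-regulon generator with known ground truth, a Hill-cascade null
model (what apparent `k` and `n` should look like for genes regulated
indirectly through a chain of Hill edges), ChIP coverage promoter-occupancy
scoring with direct/indirect binning, trend clustering diagnostics
(k-means, average-linkage, silhouette/WSS/gap, PCA), and robust parameter
summaries (median, IQR, MADM) with rank-sum, correlation and Fisher-exact
group comparisons.

It is aimed at computational biologists analyzing dose-titration
expression data for any continuously variable regulator, not only cAMP.

## Worked example

```r
library(trendfit)

# a noiseless sigmoid gene on the default 10-dose grid
curve <- tibble::tibble(
  gene_id = "gatB-like", dose = default_dose_grid(),
  fold_change = evaluate_model("HM", list(b0 = 1, k = 0.8, n = 4, emax = 10),
                               default_dose_grid()))
fit <- fit_curve(curve, "HM")
tidy(fit)
#> # A tibble: 4 x 4
#>   term  estimate std.error   rse
#>   <chr>    <dbl>     <dbl> <dbl>
#> 1 b0         1           0     0
#> 2 k          0.8         0     0
#> 3 n          4           0     0
#> 4 emax      10           0     0
```

The fit recovers the generating parameters exactly (σ² ≈ 0, R²_NLfit = 1).
A full synthetic regulon — 305 genes, 74/9/6/11% HM/LM/NR/NM, Hill
midpoints log-normal around 0.79 mM, 10% multiplicative noise — runs
end-to-end in under a minute:

```r
synth <- generate_regulon(regulon_config(seed = 1))
cls <- classify_regulon(synth$curves)
glance(cls)
#> # A tibble: 1 x 6
#>      HM    LM    NR    NM n_genes n_b0_flagged
#>   <int> <int> <int> <int>   <int>        <int>
#> 1   228    22    10    45     305            8

hm <- cls[cls$class == "HM", ]
summarize_parameter(hm$k, "k")
#> # A tibble: 1 x 8
#>   parameter     n median   iqr madm_pct   min   max iqr_over_range_pct
#>   <chr>     <int>  <dbl> <dbl>    <dbl> <dbl> <dbl>              <dbl>
#> 1 k           228  0.812 0.314     19.5 0.374  3.05               11.8
```

The recovered midpoint distribution (median 0.81 mM) matches the
generating configuration (0.79 mM): the fit-and-select pipeline is close
to unbiased for sigmoid genes at this noise level. `run_pipeline()` chains
generation, fitting, classification, clustering and summaries and writes
a TSV/JSON artifact tree with a resolved config and run manifest.

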