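---
title: "Models, selection rules and design choices in trendfit"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models, selection rules and design choices in trendfit}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(trendfit)
```

## The model set and its assumptions

`trendfit` describes a gene's dose-response to a titrated effector
(concentration `c`, mM) with four nested phenomenological models:

| model | form | parameters |
|---|---|---|
| HM | `b0 + (Emax − b0)·c^n/(k^n + c^n)` | `b0`, `k`, `n`, `Emax` |
| NONSAT | `b0 + m·c^n` | `b0`, `m`, `n` |
| LIN | `b0 + m·c` | `b0`, `m` |
| NR | `b0` | `b0` |

Responses are linear fold changes relative to the zero-dose reference, so
the dose-0 point is 1 by construction and is included as a fitted point —
it anchors the basal level `b0` near 1, which is also where a
well-behaved titration experiment should place it. The nonsaturating
power law is the Hill limit for `k` far above the tested range; the
linear model is its `n = 1` special case. Units: `b0` and `Emax` in fold
change, `k` in mM, `n` dimensionless, `m` in fold change per mM^n.

Assumptions worth keeping in mind: each dose contributes one fold-change
value (replicate collapse happens upstream, in differential-expression
calling), all doses are weighted equally, and the response is assumed to
be an equilibrium property of the dose, with no dynamics.

## Fitting

Fits are bounded nonlinear least squares (Levenberg–Marquardt,
`minpack.lm::nlsLM`). Start values follow a fixed recipe: `b0` is the
mean fold change at the three lowest nonzero doses, `Emax` the mean at
the doses nearest 1–2 mM, `n = 2`, `k = 0.6` mM, `m = 1`. Because a
single start can strand the optimizer in a shallow basin on steep or
noisy curves, the Hill and power-law models also try a small
deterministic set of data-driven starts (midpoint at the observed
half-rise crossing, saturation at the top-dose response, and a steep
`n = 6` variant); the converged candidate with the smallest SSE wins.
Selection among starts sees only the least-squares objective, never the
downstream acceptance criteria.

Bounds keep the solver in the biologically meaningful region: positive
levels, `k` at most 10× the maximum dose (a midpoint beyond that is
unidentifiable from the data), `n` in (0.1, 20]. The null model is solved
in closed form (`b0 = mean`, `se = sqrt(σ²/N)`).

Standard errors come from the linearized covariance at the optimum. When
an estimate is pinned at a bound — typically `n` at its ceiling for genes
whose transition falls between two grid doses — that covariance is
singular and its standard errors meaningless; `trendfit` then reports the
pinned parameter's standard error as undefined and computes the remaining
ones from the Jacobian restricted to the interior parameters. Without
this, boundary-pinned sigmoid fits show inflated RSE(k) (in simulation,
reported relative errors of 0.5–24 where the Monte Carlo sampling error
is ~0.1) and are spuriously rejected.

Non-convergence is recorded in a flag, never raised: a gene whose Hill
fit diverges can still be classified by the remaining models.

## Goodness of fit and model selection

For nonlinear fits the package uses the predicted-versus-observed panel:
`R²_NLfit` (squared Pearson correlation of predicted and observed),
`slope_NLfit` (OLS slope of observed on predicted; 1 for an unbiased
fit), its two-sided p-value, and `σ² = SSE/(N − p)` with `N` = number of
doses and `p` = parameter count. The slope regresses observed on
predicted; the opposite direction differs only in degenerate cases and
can be judged from the same panel.

Selection is a σ² contest followed by class-specific acceptance rules.
Converged models compete on σ²; the strict minimum wins, with exact ties
broken by parsimony. The winner must then pass:

* **HM**: `R²_NLfit > 0.80`, `p < 0.05`, `slope_NLfit ∈ [0.8, 1.2]`,
  RSE(k) and RSE(Emax) < 20%. RSEs of `b0` and `n` are deliberately not
  filtered: the sparse sampling around the transition makes `n` poorly
  determined even for clean sigmoid curves, and `b0` is anchored by
  construction.
* **LM** (NONSAT or LIN winning): `R²_NLfit > 0.70`, `p < 0.05`,
  `slope_NLfit ∈ [0.8, 1.2]`. If both variants pass, the lower-σ² one is
  stored and the gene is labeled LM.
* **NR**: the R²/slope criteria are undefined for a constant predictor
  and are skipped. Instead NR requires flatness in an absolute sense: no
  dose may show a fold change of 2 or more (or 0.5 or less) — the same
  2-fold cutoff that defines differential expression. Without this gate a
  strong rise-and-fall gene, which no monotone model tracks, hands the
  flat model the smallest σ² purely through its larger denominator
  (`N − 1` versus `N − 4`) and is mislabeled nonresponsive.
* **NM** is pure exclusion: no converged model passed. The per-model
  rejection log is kept on every gene to support manual review.

A winning fit with `b0` outside [0.8, 1.2] is flagged but not rejected.

Note a structural property of σ²-based selection with one value per dose:
for a true power-law gene, the Hill model's extra parameter absorbs
roughly one noise degree of freedom, so `σ²_HM < σ²_NONSAT` is close to a
coin flip; such genes then usually fail the Hill RSE filter and land in
NM. The same applies to truly flat genes versus the noise-absorbing
nonlinear models. Classification accuracy for LM- and NR-truth genes is
therefore intrinsically limited (~60–70% in simulation at 10% noise),
while sigmoid-truth genes classify at ~95%.

## The synthetic regulon

`generate_regulon()` emulates the statistical structure the analysis
assumes: ~305 genes in proportions 74/9/6/11% (HM/LM/NR/NM); Hill
midpoints log-normal with median 0.79 mM and IQR 0.26 mM; steepness
log-normal with median 3.9 and IQR 2, truncated to (1, 20]; saturating
fold changes log-normal truncated below at 1.2-fold with median ~8.9 (the
geometric midpoint of the 1.2–66.5-fold range it emulates) and `sdlog`
0.77, which reproduces a median-absolute-deviation-from-median of ~48% of
the median. Only medians and IQRs are constrained by observation; the
log-normal forms are a modelling choice, with the scale parameter in
closed form: `sdlog = asinh(IQR/(2·median))/qnorm(0.75)`.

Noise is multiplicative log-normal per dose, mean-one, with CV 0.10 by
default; the zero-dose anchor is exact. Nonmonotonic genes use a
unimodal beta-shaped bump (height log-normal around 3-fold, truncated at
1.5; peak position uniform in 0.5–1.0 mM). LM-truth genes split evenly
between linear and power-law (`n` uniform in 1.2–2.2) with the top-dose
rise log-normal around 5-fold. An option rejects sampled (k, n) pairs
with `k > 1` and `n > 5`, mimicking the empirically empty
high-k/high-n region; it is off by default.

What the generator does *not* emulate: replicate-level dispersion,
library-size effects, dose-dependent noise, operon-correlated noise, or
curve shapes that superpose several archetypes. Passing tests on this
generator therefore demonstrate correctness of the estimation machinery
under the stated noise model, not performance on any real library.

## The cascade null model

For indirect regulation, `simulate_ensemble()` composes a feed-forward
chain of Hill edges (`b0 = 0`, `Emax = 1`, shared `n = 2` by default,
per-edge `k` drawn independently per trial from the observed-midpoint
distribution) and refits each node's response against the input dose with
`b0` fixed at 0 and `k`, `n`, `Emax` free — `Emax` must stay free because
the composed plateau is below 1 even though every edge saturates at 1.
The evaluation grid is 60 log-spaced doses spanning [min(k)/100,
max(k)·100] per trial, so transition and plateau are always resolved; a
response whose last two grid values differ by more than 1% relative is
flagged unreliable rather than dropped.

Two exact oracles guard the machinery: first-order chains compose to a
first-order Hill curve with `k' = k'_{prev}·k_j/(E'_{prev}+k_j)` and
`E' = E'_{prev}/(E'_{prev}+k_j)`, and for any chain the half-saturation
dose can be found by brute-force root finding on the composed response.
The fitted apparent `k` tracks that half-max crossing to within ~2% when
downstream midpoints are moderate (`k₂ ≲ 0.8`); the discrepancy grows as
`k₂` approaches 1 because the composed curve departs further from a pure
Hill shape — the fitted midpoint and the half-max crossing are then
genuinely different functionals. The defaults use 10⁴ trials
(10⁶ supported); summaries are invariant to trial order.

## Occupancy scoring

Coverage tracks are mode-normalized (per-base depth divided by the modal
strictly-positive integer depth, ties to the smaller value), ratioed
(test/input with pseudocount 0.5 on both sides), and smoothed by local
linear regression (tricube weights, `lowess` with no robustness
iterations). The smoothing stride (`delta`) is 0 — evaluating the local
fit at every base — because the lowess default of 1% of the coordinate
range flattens promoter-scale peaks narrower than the stride. The default
span corresponds to a few hundred bases; the exact span any given study
used is rarely stated, so it is configurable.

A promoter's occupancy is the maximum smoothed signal in the window from
200 bp upstream to 50 bp downstream of the gene start, strand-aware, in
0-based half-open coordinates (251 bp including the start base). For
operons only the first gene in the direction of transcription is scored.
Direct targets are the union of a curated list and all genes whose
occupancy exceeds the bottom-quartile (type-7 quantile) occupancy of the
curated set — so the curated set is always contained in the direct set,
and the cutoff is reported. Quantiles of small curated sets are
definition-sensitive, hence the explicit type-7 choice.

## Clustering

Trends are row-wise z-scored with the sample (n−1) standard deviation;
constant rows are excluded with a warning. The zero-dose column is
included by default (it carries the anchor's shape information), with an
option to drop it. Hierarchical clustering uses Pearson distance
(`1 − r`) with average linkage; k-means uses 50 restarts and 300
iterations with an explicit seed. Optimum-k diagnostics report WSS
(elbow by largest second difference), mean silhouette width (Euclidean),
and the gap statistic (uniform-reference resampling, B = 50,
first-SE-max rule) separately, with no forced consensus — continuous
trend data need not have a well-defined cluster count. PCA fixes
component signs by making each component's largest-magnitude loading
positive. Cluster-to-class naming uses maximum cross-tab overlap.

## Statistical summaries

MADM is defined as `100·median(|x − median|)/median` — a percentage of
the median, the only convention under which robust dispersions of
saturation levels (~48%) and midpoints (~16%) are directly comparable.
Quantiles are linear-interpolation (type 7) throughout; quartile bins
assign boundary ties to the lower bin. Rank-sum comparisons are exact for
small tie-free samples and normal-approximated with tie correction
otherwise; Fisher's exact test and rank-sum p-values are cross-checked in
the test suite against exhaustive enumeration. Category enrichment
adjusts p-values across categories within each class (Holm by default,
recorded in the output).

## Problem sizes and determinism

The test suite and the acceptance script use a 305-gene regulon for the
full round trip, 1,000 pure-sigmoid genes for recovery error, 5,000
cascade trials, 52-kb coverage tracks with five planted peaks, and 60
planted-archetype curves for clustering — sizes at which every
distributional claim the package makes about itself is stable across
seeds while a complete run stays in the minutes range. All randomness
flows from explicit integer seeds; identical configurations produce
byte-identical artifacts.

## Known limitations

* With one fold-change value per dose, σ²-based selection between nested
  models is noise-limited (see above); the NM class absorbs the
  ambiguous cases, as its rejection-log design intends.
* `n` is the least identifiable Hill parameter on a 10-dose grid — its
  RSE is rightly excluded from the filters, and recovered `n` medians are
  biased slightly upward by selection.
* The occupancy module assumes single-peak promoter windows; overlapping
  divergent promoters are scored by whichever signal is larger.
* Apparent-parameter fits summarize composed curves that are not exactly
  Hill; reported apparent `k`/`n` are best-fit projections, not
  mechanistic constants.
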