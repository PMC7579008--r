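---
title: "Methods: random-forest hazard mapping of groundwater arsenic exceedance"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: random-forest hazard mapping of groundwater arsenic exceedance}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

## The problem and the modeling strategy

Chronic exposure to geogenic arsenic through untreated groundwater is a major
public-health hazard across the Indo-Gangetic floodplains. Concentration
measurements from wells are abundant in a few intensively surveyed districts
and sparse elsewhere, while the environmental drivers of arsenic mobilisation
(climate, soil chemistry, lithology, topography) are available as continuous
1-km rasters. `ashazard` implements the standard geostatistical-learning
response to this situation:

1. **Spatial averaging.** All measurements falling in one 30 arc-second
   (~1 km) grid cell are averaged, so a cell sampled 300 times counts once.
   This tempers the influence of densely surveyed hotspots on the model.
2. **Binary recoding.** The cell-mean concentration is recoded against the
   10 µg/L WHO guideline: label 1 if the mean exceeds 10 µg/L, 0 otherwise
   (a value of exactly 10 maps to 0). Averaging precedes recoding; a cell
   with members {0, 30} µg/L has mean 15 and is labelled exceeding.
   Modeling a binary target absorbs much of the measurement-precision and
   depth-aggregation uncertainty of compiled field data.
3. **Random forest.** A bootstrap ensemble of classification trees predicts
   the probability of exceedance (the fraction of trees voting class 1) from
   the predictor values of a cell. The per-split candidate-variable count
   `mtry` is tuned over `1..p` by out-of-bag (OOB) accuracy; the stratified
   80/20 train/test split preserves class prevalence to within one row per
   class.
4. **Cutoff selection.** Sensitivity and specificity (and, separately, PPV
   and NPV) are evaluated on a grid of 100 probabilities spanning [0, 1];
   the cutoff where the paired curves intersect is the operating point that
   classifies low and high cells equally well. Following the study design
   this is computed on predictions for *all* available data (train + test).
5. **Exposure.** Cells whose probability exceeds a cutoff form the hazard
   map. The exposed population is
   `probability x population x use-rate`, summed over hazard cells, with
   untreated-groundwater use rates of 0.637 (rural) and 0.238 (urban).
   Running this at both cutoffs brackets the estimate as a low–high range;
   monotonicity guarantees the low end comes from the higher cutoff.

## The synthetic study region

The real compiled measurement dataset and predictor rasters are not
redistributable, so the package ships a generator that reproduces the
*structure* of the problem with a known ground truth:

- **Continuous predictors** are stationary Gaussian random fields: white
  noise convolved on the torus with a Gaussian kernel of scale
  `correlation_length` cells (FFT convolution), standardised to mean 0 and
  sd 1. The method was fixed once (filtered noise, not spectral synthesis);
  tests assert only the measured lag-1 autocorrelation, which is ~0 at
  `correlation_length = 0` and >0.8 at 20 cells.
- **Categorical predictors** (lithology / land-cover stand-ins) are
  contiguous nearest-seed patches labelled by cycling through the category
  levels.
- **Population** is the exponential of a smoothed field — heavy-tailed,
  non-negative counts; the **urban mask** is the top decile of population,
  mirroring a rural/urban classification without external data.
- **Regions** are a rectangular tiling of the grid; zonal summaries assign
  each cell to exactly one region.
- **Sampling** emulates clustered well surveys: points are drawn from a
  restricted set of sites (about `n_points / (1 + clustering_factor)` of
  them), with 35% of sites in a small hotspot window, so many points share
  a cell and the aggregation step has real work to do.
- **Exceedance mechanism.** The per-cell probability is
  `plogis(b0 + Σ βk xk + Σ peaked terms)`; peaked terms are Gaussian bumps
  emulating optimum-range (non-monotone) predictor effects. Each point's
  indicator is Bernoulli at its cell's probability, and a concentration
  consistent with the indicator is attached: `10 + Y` µg/L
  (Y ~ lognormal, meanlog 3, sdlog 1.2) above, `10 − min(Y′, 9.9)` below.
  The heavy right tail matches the means ± SDs typical of arsenic survey
  compilations; only the binary side of the threshold matters downstream.

### The study-like scenario and its calibration

`paper_like_scenario()` fixes the scenario used by the acceptance checks and
the analysis scripts: a 250 × 250 cell grid, 18 continuous + 2 categorical
predictors (20 predictor columns), 150,000 points aggregating to roughly
21,500 occupied cells (the same ~6–7× reduction seen in heavily clustered
national compilations), five linear effects (β = 1.5, −1.2, 1.0, −0.8, 0.6
on `cont_01..05`) and one peaked effect on `cont_06`. β was chosen so one
predictor is clearly dominant and the weakest detectable effect sits at
|β| = 0.6 — the documented detectability threshold for the sign-recovery
property of the binned correlation diagnostic.

The intercept is calibrated by bisection so that the **aggregated**
exceedance fraction equals 0.42, the study-like prevalence. Calibrating on
the aggregated rather than the point-level rate matters: with a heavy-tailed
concentration marginal, a single large exceedance can tip a multi-point
cell's mean over 10 µg/L, so the cell-level rate sits well above the mean
Bernoulli probability. The bisection evaluates the simulated aggregated rate
(deterministic given the sampling seed) and converges in 20 steps.

### What the generator does *not* emulate

Real predictor rasters are cross-correlated (climate drives soils) and
anisotropic; real measurement error, field-kit/lab mixtures, well depth and
temporal drift are absent; regions here are rectangles, not administrative
polygons; the grid is treated as equal-area (cell counting, no latitude
cosine — an optional weighting hook was considered and left out because the
study grid spans latitudes where the distortion is a second-order effect
relative to model uncertainty). Passing tests therefore demonstrate the
correctness of the machinery and its statistical behaviour under a known
mechanism, not predictive skill on real Indian data.

## Statistical components, from first principles

- **Confusion statistics.** Accuracy, NIR (larger reference-class share),
  one-sided *exact* binomial p-value for accuracy > NIR (`pbinom`, no
  normal approximation), Cohen's kappa from row × column marginals,
  sensitivity/specificity/PPV/NPV with exceedance as the positive class,
  prevalence and balanced accuracy. The positive-class convention is pinned
  by a test reproducing a published statistic set to 4 decimal places. Zero
  denominators yield `NA` plus an `undefined` attribute, never silent NaN.
- **AUC** is pairwise concordance with ties counted ½, computed by the
  Mann-Whitney rank identity; a test checks exact agreement with explicit
  pair enumeration and with an established ROC package.
- **Cutoff search** evaluates both curves at each grid probability and takes
  the grid point minimising |ΔCurve| (nearest-grid, not interpolated — the
  plotted 100-point curve is the object of interest), ties to the lowest
  cutoff. The endpoint probabilities 0 and 1 are excluded from the search:
  prediction uses the strict rule `p > cutoff`, so the endpoints force
  degenerate one-class predictions for generic scores (and in perfectly
  separated data cutoff 0 would trivially tie the interior optimum).
- **Binned correlation.** Values are stably sorted into `ceil(1 + log2 n)`
  (Sturges) equal-count bins, sizes differing by at most one with the
  remainder on the first bins; identical values may straddle a boundary
  (equal-count priority over tie integrity). Kendall tau-b between bin mean
  and bin exceedance proportion is the default report, with the Pearson
  correlation over the same summaries returned alongside — both are
  provided because either convention appears in applied work of this kind.
  A constant predictor is flagged `undefined`. Note that a 0/1 step in the
  bin proportions cannot reach |tau-b| = 1: the tied proportions enter the
  tie correction (8 zeros + 8 ones over 16 bins give tau-b = 0.730), which
  is asserted by hand enumeration in the tests.
- **Permutation importance** shuffles one predictor column at a time and
  measures the mean accuracy drop at the 0.5 cutoff over `n_repeats`
  shuffles, by default on the held-out test set; `method = "oob"` returns
  the forest's own OOB permutation importance instead. Gini importance
  comes from the forest's recorded impurity decreases.
  `normalize_importance()` divides each measure by its maximum (max = 1,
  signs preserved).

## Numerical and design choices

- **Cell membership** is half-open: `col = floor((lon − lon0)/cellsize) + 1`,
  with points on the northern/eastern boundary assigned to the last
  row/column, so every in-extent point belongs to exactly one cell.
  Representative points sit at cell centers. Cells are pure geographic
  30 arc-second squares; no projection.
- **Categorical predictors** enter the forest as R factors, i.e. native
  categorical splits, rather than one-hot dummies — the backend supports
  them directly and they match how such models are fitted in practice.
  Prediction inputs are validated against the recorded training schema and
  unseen categories are refused by name.
- **Tree counts.** The configured default is 10,001 trees (odd, so votes
  cannot tie). Vote-fraction probabilities stabilise well before that, so
  tuning forests use 501 trees by default and the test suite and
  acceptance script run 151–601 trees at the full ~21,500-cell problem
  size; the tree count trades runtime for Monte-Carlo smoothness of the
  probability estimates, not for fidelity of the pipeline.
- **Seeds.** One master seed derives per-stage seeds through an arithmetic
  hash of the stage name (kept below 2^31); identical configurations are
  bit-reproducible end to end.
- **Nodata** propagates: any cell with a missing predictor yields a nodata
  probability; rows hitting nodata during extraction are dropped and
  counted in the manifest. Misregistered rasters are refused with the
  offending layer named.
- **Rasters as text.** Grids are carried by a lightweight in-package
  `grid_raster` class and serialised as ESRI ASCII grids — a plain-text
  interchange format readable by any GIS — with points as CSV, regions as
  a region-index raster plus a name table, and the scenario as YAML.

## Known limitations

Accuracy measured at the intersection cutoff on the *full* dataset is
optimistic: most rows were in the training sample, which the forest partly
memorises. The package reproduces that computation as part of the pipeline
because the cutoffs themselves are defined on all available data, but the
honest generalisation figures are the held-out test statistics and the OOB
accuracy. Exposure estimates count only cells above the cutoff, so
localised contamination below it contributes nothing — an underestimation
by construction. Use rates are single national constants; sub-national
rates and demographic disaggregation are out of scope.
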