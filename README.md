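# ashazard

Geospatial random-forest hazard mapping of groundwater arsenic exceedance.

## The problem

Millions of people in South Asia drink untreated groundwater containing
geogenic arsenic above the WHO guideline of 10 µg/L. Well measurements are
plentiful in a handful of intensively surveyed districts and nearly absent
elsewhere, while environmental proxies for arsenic mobilisation — climate,
soil chemistry, lithology, land cover, topography, water-table depth — exist
as wall-to-wall 1-km rasters. `ashazard` is for epidemiologists and
hydrogeologists who need to turn that combination into a defensible hazard
map and a population-at-risk estimate.

The pipeline is:

1. **Aggregate**: average all measurements inside each 30 arc-second
   (~1 km) cell, so oversampled hotspots count once
   (`aggregate_to_grid()`).
2. **Recode**: label a cell 1 if its *mean* concentration exceeds 10 µg/L,
   0 otherwise (exactly 10 → 0); averaging precedes recoding
   (`recode_binary()`).
3. **Model**: a stratified 80/20 split (`stratified_split()`), `mtry` tuned
   over `1..p` by out-of-bag accuracy (`tune_mtry()`), a 10,001-tree random
   forest `P(As > 10 µg/L | predictors)` (`fit_forest()`), and a
   probability map over the full raster stack (`predict_prob()`).
4. **Evaluate**: the complete confusion-statistic set — accuracy, NIR with
   an exact binomial p-value, Cohen's kappa, sensitivity, specificity,
   PPV/NPV, prevalence, balanced accuracy (`confusion_stats()`) — plus
   pairwise-concordance AUC (`roc_auc()`), and two operating cutoffs where
   the sensitivity/specificity and PPV/NPV curves intersect over a
   100-point probability grid (`find_cutoff()`).
5. **Explain**: permutation and Gini variable importance
   (`permutation_importance()`, `importance_table()`) and the binned
   Kendall tau-b diagnostic — Sturges `ceil(1 + log2 n)` equal-count bins of
   each predictor against the bin-wise exceedance proportion
   (`binned_exceedance_correlation()`).
6. **Expose**: hazard maps at both cutoffs (`hazard_map()`) and the exposed
   population `Σ p × pop × use-rate` over high-hazard cells, with
   rural/urban untreated-groundwater use rates 0.637/0.238, reported
   per region as a low–high range (`exposed_population()`,
   `regional_summary()`).

Because the compiled national measurement datasets are not redistributable,
the package includes a first-class synthetic-landscape generator
(`generate_landscape()`, `sample_arsenic_points()`,
`paper_like_scenario()`) with spatially autocorrelated predictor fields,
clustered well sampling, and a known logistic exceedance mechanism, so the
entire pipeline is testable against ground truth. See the methods vignette
(`vignettes/hazard-mapping-methods.Rmd`) for the model, its assumptions,
and all numerical choices.

## Worked example

```r
library(ashazard)

scen  <- paper_like_scenario(seed = 1)           # synthetic study region
table <- build_modeling_table(scen$points, scen$landscape$predictors)
mean(table$label)                                 # 0.4200037  (42% exceedance)
nrow(table)                                       # 21576 aggregated cells

split <- stratified_split(table, 0.8, seed = 2)
fit   <- fit_forest(split$train, forest_spec(n_trees = 300, seed = 3))
fit$oob_accuracy                                  # 0.8331499
ev    <- evaluate_model(fit, split$test)
ev$auc                                            # 0.9088547

p_all <- predict_prob(fit, table)                 # cutoffs use ALL data
find_cutoff(p_all, table$label, "sens_spec")$cutoff
```

The exceedance fraction says 42% of the 1-km cells have a mean
concentration above the guideline; the OOB accuracy (0.83) and held-out AUC
(0.91) say the forest separates exceeding from non-exceeding cells far
better than the no-information rate; the cutoff is the probability at which
the model classifies both classes equally well, and it thresholds the
probability map into the hazard map that drives the exposure estimate.

The `analysis/` directory runs the same workflow as a narrated sequence of
stages writing plain-text artifacts under `results/`:

```sh
Rscript analysis/01_simulate.R     # landscape + 150,000 sample points
Rscript analysis/02_prepare.R      # modeling table (aggregation + labels)
Rscript analysis/03_fit_model.R    # tuning, fit, CV stats, cutoffs, importance, map
Rscript analysis/04_exposure.R     # hazard maps + regional exposure report
Rscript analysis/05_figures.R      # importance / correlation / cutoff figures
```

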