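#' Pipeline configuration
#'
#' Collects every tunable of the end-to-end analysis, with defaults fixed
#' at the study's stated values: 10 ug/L guideline threshold, 80/20
#' stratified split, 10,001-tree final forest, mtry tuned on out-of-bag
#' accuracy (501-tree tuning forests), 100-point cutoff grids, and
#' rural/urban groundwater-use rates 0.637/0.238.
#'
#' @param threshold guideline concentration, ug/L.
#' @param train_fraction training share of the stratified split.
#' @param n_trees trees in the final forest.
#' @param n_trees_tuning trees per tuning forest.
#' @param mtry fixed mtry, or `NULL` to tune over 1..p.
#' @param tune logical; tune mtry when `mtry` is `NULL`.
#' @param grid_size cutoff-grid resolution.
#' @param rural_use_rate,urban_use_rate groundwater-use rates.
#' @param n_repeats_importance permutation-importance repeats.
#' @param seed master seed; every stage seed is derived from it.
#' @param scenario list of overrides passed to [paper_like_scenario()]
#'   (`n_points`, `nrow`, `ncol`) for the synthetic scenario.
#' @return a `pipeline_config` list.
#' @export
pipeline_config <- function(threshold = 10, train_fraction = 0.8,
                            n_trees = 10001L, n_trees_tuning = 501L,
                            mtry = NULL, tune = TRUE,
                            grid_size = 100L,
                            rural_use_rate = 0.637, urban_use_rate = 0.238,
                            n_repeats_importance = 5L,
                            seed = 1L, scenario = list()) {
  structure(list(threshold = threshold, train_fraction = train_fraction,
                 n_trees = as.integer(n_trees),
                 n_trees_tuning = as.integer(n_trees_tuning),
                 mtry = if (is.null(mtry)) NULL else as.integer(mtry),
                 tune = isTRUE(tune), grid_size = as.integer(grid_size),
                 rural_use_rate = rural_use_rate,
                 urban_use_rate = urban_use_rate,
                 n_repeats_importance = as.integer(n_repeats_importance),
                 seed = as.integer(seed), scenario = scenario),
            class = "pipeline_config")
}

#' Derive a stage seed from the master seed
#'
#' Deterministic arithmetic hash of the stage name folded into the master
#' seed, kept within 32-bit integer range so each stage draws from an
#' independent, reproducible stream.
#'
#' @param master master seed (integer).
#' @param stage stage name.
#' @return integer seed.
#' @export
derive_seed <- function(master, stage) {
  h <- sum(utf8ToInt(stage) * seq_along(utf8ToInt(stage)))
  as.integer((as.numeric(master) * 7919 + h * 104729) %% 2147483647)
}

#' Write / read a scenario file
#'
#' Serialises a [pipeline_config()] to YAML so a run is fully captured by
#' one plain-text file.
#'
#' @param config a `pipeline_config`.
#' @param path file path.
#' @return `read_scenario` returns a `pipeline_config`.
#' @export
write_scenario <- function(config, path) {
  yaml::write_yaml(unclass(config), path)
  invisible(path)
}

#' @rdname write_scenario
#' @export
read_scenario <- function(path) {
  raw <- yaml::read_yaml(path)
  do.call(pipeline_config, raw)
}

#' Run the full synthetic-scenario pipeline
#'
#' Sequences every stage on the study-like synthetic landscape: simulate,
#' aggregate and label, extract predictors, stratified split, (optionally)
#' tune mtry, fit the forest, cross-validate on the held-out test set,
#' solve both probability cutoffs on the full dataset's predictions,
#' compute variable importance and binned correlations, predict the
#' probability map, and derive hazard maps and the regional exposure
#' report. A manifest of seeds and row/cell counts is assembled and, when
#' `out_dir` is given, all artifacts are written there as plain-text files
#' (CSV tables, .asc rasters, JSON manifest and statistics).
#'
#' @param config a [pipeline_config()].
#' @param out_dir optional output directory for artifacts.
#' @return (invisibly) a list with every stage result and the `manifest`.
#' @export
run_pipeline <- function(config = pipeline_config(), out_dir = NULL) {
  stopifnot(inherits(config, "pipeline_config"))
  manifest <- list(package_version = as.character(utils::packageVersion("ashazard")),
                   master_seed = config$seed)
  stage <- function(nm) derive_seed(config$seed, nm)

  # -- simulate ------------------------------------------------------------
  sc_args <- utils::modifyList(list(seed = stage("simulate")), config$scenario)
  scen <- do.call(paper_like_scenario, sc_args)
  points <- scen$points
  manifest$n_points_raw <- nrow(points)

  # -- prepare -------------------------------------------------------------
  table <- build_modeling_table(points[c("lon", "lat", "as_ugL")],
                                scen$landscape$predictors,
                                threshold = config$threshold)
  manifest$n_aggregated <- attr(table, "n_aggregated")
  manifest$n_dropped_nodata <- attr(table, "n_dropped")
  manifest$n_modeling_rows <- nrow(table)
  manifest$exceedance_fraction <- mean(table$label)

  # -- split / tune / fit --------------------------------------------------
  split <- stratified_split(table, config$train_fraction, seed = stage("split"))
  manifest$n_train <- nrow(split$train)
  manifest$n_test <- nrow(split$test)

  tuning <- NULL
  mtry <- config$mtry
  if (is.null(mtry) && config$tune) {
    tuning <- tune_mtry(split$train, n_trees = config$n_trees_tuning,
                        seed = stage("tune"))
    mtry <- tuning$mtry
  }
  manifest$mtry <- if (is.null(mtry)) NA_integer_ else mtry

  model <- fit_forest(split$train,
                      forest_spec(n_trees = config$n_trees, mtry = mtry,
                                  seed = stage("fit")))
  manifest$oob_accuracy <- model$oob_accuracy

  # -- evaluate ------------------------------------------------------------
  eval_test <- evaluate_model(model, split$test)
  manifest$test_accuracy <- eval_test$stats$accuracy
  manifest$test_auc <- eval_test$auc

  # cutoffs are solved on predictions for ALL available data (train + test)
  p_all <- predict_prob(model, table)
  cut_ss <- find_cutoff(p_all, table$label, "sens_spec", config$grid_size)
  cut_pn <- find_cutoff(p_all, table$label, "ppv_npv", config$grid_size)
  manifest$cutoff_sens_spec <- cut_ss$cutoff
  manifest$cutoff_ppv_npv <- cut_pn$cutoff

  # -- importance & correlations -------------------------------------------
  importance <- importance_table(model, split$test,
                                 n_repeats = config$n_repeats_importance,
                                 seed = stage("importance"))
  importance_norm <- normalize_importance(importance)
  correlations <- correlation_table(table)

  # -- probability map, hazard, exposure -----------------------------------
  prob_map <- predict_prob(model, scen$landscape$predictors)
  expo_cfg <- exposure_config(config$rural_use_rate, config$urban_use_rate,
                              cutoffs = c(cut_ss$cutoff, cut_pn$cutoff))
  report <- regional_summary(prob_map, scen$landscape$population,
                             scen$landscape$urban, scen$landscape$regions,
                             scen$landscape$region_names, expo_cfg)
  tot <- report[report$region == "Total", ]
  manifest$pop_exposed_low <- tot$pop_low
  manifest$pop_exposed_high <- tot$pop_high
  manifest$pct_area_low <- tot$pct_area_low
  manifest$pct_area_high <- tot$pct_area_high

  res <- list(scenario = scen, table = table, split = split, tuning = tuning,
              model = model, eval_test = eval_test,
              cutoff_sens_spec = cut_ss, cutoff_ppv_npv = cut_pn,
              importance = importance, importance_norm = importance_norm,
              correlations = correlations, prob_map = prob_map,
              report = report, manifest = manifest)

  if (!is.null(out_dir)) write_artifacts(res, out_dir)
  invisible(res)
}

# Plain-text artifact dump: CSV tables, .asc rasters, JSON manifest.
write_artifacts <- function(res, out_dir) {
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  w <- function(df, nm) utils::write.csv(df, file.path(out_dir, nm),
                                         row.names = FALSE)
  w(res$table, "modeling_table.csv")
  if (!is.null(res$tuning)) w(res$tuning$trace, "mtry_tuning.csv")
  w(res$importance, "importance.csv")
  w(res$importance_norm, "importance_normalized.csv")
  w(res$correlations, "correlations.csv")
  w(res$cutoff_sens_spec$curves, "cutoff_curves.csv")
  w(as.data.frame(res$report), "exposure_report.csv")
  write_ascii_grid(res$prob_map, file.path(out_dir, "probability_map.asc"))
  for (ct in c(res$cutoff_sens_spec$cutoff, res$cutoff_ppv_npv$cutoff))
    write_ascii_grid(hazard_map(res$prob_map, ct),
                     file.path(out_dir, sprintf("hazard_map_%g.asc", ct)))
  s <- res$eval_test$stats
  stats_out <- s[setdiff(names(s), "matrix")]
  stats_out$confusion <- as.vector(s$matrix)
  jsonlite::write_json(stats_out, file.path(out_dir, "test_statistics.json"),
                       auto_unbox = TRUE, digits = NA)
  jsonlite::write_json(res$manifest, file.path(out_dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA)
  invisible(out_dir)
}
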