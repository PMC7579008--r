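#' Stratified train/test split
#'
#' Partitions the modeling table per class so the exceedance prevalence is
#' preserved (up to one row per class) in both parts.
#'
#' @param table modeling table with an integer 0/1 `label` column.
#' @param train_fraction fraction assigned to training (default 0.8).
#' @param seed RNG seed.
#' @return list of class `split_result` with `train`, `test`, `seed`.
#' @export
stratified_split <- function(table, train_fraction = 0.8, seed = 1L) {
  if (!"label" %in% names(table)) stop("table needs a 'label' column", call. = FALSE)
  if (length(unique(table$label)) < 2L)
    stop("stratified_split: both classes must be present", call. = FALSE)
  set.seed(seed)
  in_train <- logical(nrow(table))
  for (cl in sort(unique(table$label))) {
    rows <- which(table$label == cl)
    n_tr <- round(train_fraction * length(rows))
    in_train[sample(rows, n_tr)] <- TRUE
  }
  structure(list(train = table[in_train, , drop = FALSE],
                 test = table[!in_train, , drop = FALSE],
                 seed = as.integer(seed)),
            class = "split_result")
}

#' Forest hyperparameters
#'
#' @param n_trees number of trees (study default 10,001).
#' @param mtry predictors made available at each split; `NULL` requests
#'   tuning via [tune_mtry()].
#' @param seed RNG seed for fitting.
#' @return a `forest_spec` list.
#' @export
forest_spec <- function(n_trees = 10001L, mtry = NULL, seed = 1L) {
  if (n_trees < 1) stop("n_trees must be >= 1", call. = FALSE)
  structure(list(n_trees = as.integer(n_trees),
                 mtry = if (is.null(mtry)) NULL else as.integer(mtry),
                 seed = as.integer(seed)),
            class = "forest_spec")
}

rf_design <- function(table) {
  cols <- predictor_columns(table)
  if (!length(cols)) stop("modeling table has no predictor columns", call. = FALSE)
  x <- table[cols]
  y <- factor(table$label, levels = c(0L, 1L))
  list(x = x, y = y)
}

#' Tune mtry on out-of-bag accuracy
#'
#' Fits one forest per candidate value of `mtry` (variables available at
#' each split) and selects the candidate with the highest out-of-bag
#' accuracy; ties go to the smallest candidate (parsimony).
#'
#' @param train training modeling table.
#' @param candidates integer candidates; default `1:p` over all predictors.
#' @param n_trees trees per tuning forest (reduced relative to the final
#'   fit; tuning needs stability, not the full ensemble).
#' @param seed RNG seed (re-seeded per candidate for comparability).
#' @return list with `mtry` (selected) and `trace` (data.frame of candidate
#'   and OOB accuracy).
#' @export
tune_mtry <- function(train, candidates = NULL, n_trees = 501L, seed = 1L) {
  d <- rf_design(train)
  p <- ncol(d$x)
  if (is.null(candidates)) candidates <- seq_len(p)
  if (any(candidates < 1 | candidates > p))
    stop("mtry candidates must lie in 1..p", call. = FALSE)
  acc <- vapply(candidates, function(m) {
    set.seed(seed + m)
    fit <- randomForest::randomForest(x = d$x, y = d$y, ntree = n_trees, mtry = m)
    unname(1 - fit$err.rate[n_trees, "OOB"])
  }, numeric(1L))
  best <- candidates[which.max(acc)]  # which.max takes the first (smallest) tie
  list(mtry = as.integer(best),
       trace = data.frame(mtry = candidates, oob_accuracy = acc))
}

#' Fit the exceedance random forest
#'
#' Bootstrap-aggregated classification trees with restricted random
#' predictor choice at each split; class probabilities are tree-vote
#' fractions. Categorical predictors enter as factors (native categorical
#' splits). The schema of the training columns is recorded so prediction
#' inputs can be validated.
#'
#' @param train training modeling table (both classes present).
#' @param spec a [forest_spec()]; if `spec$mtry` is `NULL` the backend
#'   default (sqrt(p)) is used.
#' @return object of class `fitted_forest`: the backend fit, the training
#'   schema, and the out-of-bag accuracy.
#' @export
fit_forest <- function(train, spec = forest_spec()) {
  d <- rf_design(train)
  if (nlevels(droplevels(d$y)) < 2L)
    stop("fit_forest: training data must contain both classes", call. = FALSE)
  set.seed(spec$seed)
  args <- list(x = d$x, y = d$y, ntree = spec$n_trees, importance = TRUE)
  if (!is.null(spec$mtry)) args$mtry <- spec$mtry
  rf <- do.call(randomForest::randomForest, args)
  schema <- lapply(d$x, function(col)
    if (is.factor(col)) list(type = "factor", levels = levels(col))
    else list(type = "numeric", levels = NULL))
  structure(list(rf = rf, schema = schema, spec = spec,
                 oob_accuracy = unname(1 - rf$err.rate[spec$n_trees, "OOB"])),
            class = "fitted_forest")
}

#' @export
print.fitted_forest <- function(x, ...) {
  cat(sprintf("fitted_forest: %d trees, mtry %d, %d predictors, OOB accuracy %.4f\n",
              x$rf$ntree, x$rf$mtry, length(x$schema), x$oob_accuracy))
  invisible(x)
}

check_schema <- function(model, data) {
  need <- names(model$schema)
  missing <- setdiff(need, names(data))
  if (length(missing))
    stop(sprintf("prediction input is missing predictor column(s): %s",
                 paste(missing, collapse = ", ")), call. = FALSE)
  for (nm in need) {
    sc <- model$schema[[nm]]
    if (sc$type == "factor") {
      if (!is.factor(data[[nm]]))
        data[[nm]] <- factor(data[[nm]], levels = sc$levels)
      extra <- setdiff(levels(droplevels(data[[nm]])), sc$levels)
      if (length(extra))
        stop(sprintf("column '%s' has unseen categor%s: %s", nm,
                     if (length(extra) > 1) "ies" else "y",
                     paste(extra, collapse = ", ")), call. = FALSE)
      data[[nm]] <- factor(as.character(data[[nm]]), levels = sc$levels)
    } else if (!is.numeric(data[[nm]])) {
      stop(sprintf("column '%s' must be numeric", nm), call. = FALSE)
    }
  }
  data[need]
}

#' Predict exceedance probabilities
#'
#' For a data.frame, returns the per-row probability (fraction of trees
#' voting for exceedance); rows with any missing predictor get `NA`. For a
#' [raster_stack()], returns a probability `grid_raster` where any cell
#' with a nodata predictor propagates to nodata.
#'
#' @param model a [fit_forest()] result.
#' @param input modeling table rows or a co-registered predictor stack.
#' @return numeric vector of probabilities, or a probability `grid_raster`.
#' @export
predict_prob <- function(model, input) {
  stopifnot(inherits(model, "fitted_forest"))
  if (inherits(input, "raster_stack")) {
    check_coregistered(input)
    g <- grid_spec(input)
    df <- data.frame(row.names = seq_len(g$nrow * g$ncol))
    for (nm in names(input)) {
      lay <- input[[nm]]
      v <- as.vector(lay$values)  # column-major; consistent for re-fold below
      if (!is.null(lay$levels))
        v <- factor(lay$levels[as.integer(v)], levels = lay$levels)
      df[[nm]] <- v
    }
    p <- predict_prob(model, df)
    return(grid_raster(matrix(p, g$nrow, g$ncol),
                       xll = g$xll, yll = g$yll, cellsize = g$cellsize))
  }
  x <- check_schema(model, input)
  out <- rep(NA_real_, nrow(x))
  ok <- stats::complete.cases(x)
  if (any(ok))
    out[ok] <- stats::predict(model$rf, x[ok, , drop = FALSE], type = "prob")[, "1"]
  out
}
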