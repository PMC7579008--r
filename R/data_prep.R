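#' Spatially average sample points to a prediction grid
#'
#' Concentration measurements falling in the same grid cell are averaged to
#' a single point at the cell center, so that densely sampled areas do not
#' dominate the model. Averaging precedes any binary recoding: a cell with
#' concentrations {0, 30} ug/L averages to 15 and is later labelled as
#' exceeding.
#'
#' @param points data.frame with columns `lon`, `lat`, `as_ugL`.
#' @param grid a `grid_raster` or grid spec list defining the target grid.
#' @return data.frame with one row per occupied cell, ordered by (row, col):
#'   `cell_row`, `cell_col`, `lon`, `lat` (cell center), `as_ugL` (arithmetic
#'   mean), `n_obs` (member count). Points outside the grid extent are
#'   dropped; their count is attached as attribute `n_dropped` and reported
#'   with a message.
#' @export
aggregate_to_grid <- function(points, grid) {
  req <- c("lon", "lat", "as_ugL")
  if (!all(req %in% names(points)))
    stop("points must have columns lon, lat, as_ugL", call. = FALSE)
  if (nrow(points) == 0L) {
    warning("aggregate_to_grid: empty input, returning empty output")
    out <- data.frame(cell_row = integer(), cell_col = integer(),
                      lon = numeric(), lat = numeric(),
                      as_ugL = numeric(), n_obs = integer())
    attr(out, "n_dropped") <- 0L
    return(out)
  }
  idx <- cell_index(grid, points$lon, points$lat)
  n_drop <- sum(!idx$inside)
  if (n_drop > 0)
    message(sprintf("aggregate_to_grid: dropped %d point(s) outside the grid extent", n_drop))
  keep <- idx$inside
  if (!any(keep)) stop("aggregate_to_grid: no points inside the grid extent", call. = FALSE)
  g <- if (is.list(grid) && !inherits(grid, "grid_raster")) grid else grid_spec(grid)
  key <- (idx$row[keep] - 1) * g$ncol + idx$col[keep]
  conc <- points$as_ugL[keep]
  sums <- rowsum(cbind(conc, 1), key)          # ordered by key = (row, col)
  cells <- as.numeric(rownames(sums))
  cell_row <- as.integer((cells - 1) %/% g$ncol + 1)
  cell_col <- as.integer((cells - 1) %% g$ncol + 1)
  ctr <- cell_center(g, cell_row, cell_col)
  out <- data.frame(cell_row = cell_row, cell_col = cell_col,
                    lon = ctr$lon, lat = ctr$lat,
                    as_ugL = sums[, 1L] / sums[, 2L],
                    n_obs = as.integer(sums[, 2L]))
  rownames(out) <- NULL
  attr(out, "n_dropped") <- n_drop
  attr(out, "n_input") <- nrow(points)
  out
}

#' Recode concentrations to binary exceedance labels
#'
#' @param concentrations non-negative concentrations in ug/L.
#' @param threshold guideline value in ug/L (default 10).
#' @return integer vector: 0 where value <= threshold, 1 where value >
#'   threshold. Exactly-at-threshold values map to 0.
#' @export
recode_binary <- function(concentrations, threshold = 10) {
  if (any(!is.finite(concentrations)) || any(concentrations < 0))
    stop("concentrations must be finite and >= 0", call. = FALSE)
  as.integer(concentrations > threshold)
}

#' Join predictor-raster values onto points
#'
#' Each point receives the value of every predictor layer at its location
#' (point-in-cell lookup per raster). Rows hitting nodata in any layer, or
#' falling outside a layer's extent, are dropped and counted.
#'
#' @param points data.frame with `lon`, `lat` (other columns carried along).
#' @param predictors a [raster_stack()]; layers with a `levels` attribute
#'   become factor columns.
#' @return `points` with one added column per layer; attribute `n_dropped`
#'   counts removed rows.
#' @export
extract_predictors <- function(points, predictors) {
  stopifnot(inherits(predictors, "raster_stack"))
  check_coregistered(predictors)
  out <- points
  for (nm in names(predictors)) {
    lay <- predictors[[nm]]
    v <- extract_at(lay, points$lon, points$lat)
    if (!is.null(lay$levels))
      v <- factor(lay$levels[as.integer(v)], levels = lay$levels)
    out[[nm]] <- v
  }
  ok <- stats::complete.cases(out[names(predictors)])
  n_drop <- sum(!ok)
  if (n_drop > 0)
    message(sprintf("extract_predictors: dropped %d row(s) with nodata or out-of-extent predictors", n_drop))
  out <- out[ok, , drop = FALSE]
  if (nrow(out) == 0L)
    stop("extract_predictors: no rows survive predictor extraction", call. = FALSE)
  rownames(out) <- NULL
  attr(out, "n_dropped") <- n_drop
  out
}

#' Assemble the modeling table
#'
#' Aggregates raw sample points to the predictor grid, recodes the mean
#' concentration at the guideline threshold, and joins all predictor values:
#' one row per aggregated cell with a binary `label` and one column per
#' predictor.
#'
#' @param points raw sample points (`lon`, `lat`, `as_ugL`).
#' @param predictors a [raster_stack()] (also defines the aggregation grid).
#' @param threshold guideline concentration in ug/L.
#' @return the modeling table data.frame; attributes `n_input`,
#'   `n_aggregated`, `n_dropped` record the bookkeeping.
#' @export
build_modeling_table <- function(points, predictors, threshold = 10) {
  agg <- aggregate_to_grid(points[c("lon", "lat", "as_ugL")], predictors[[1L]])
  tab <- extract_predictors(agg, predictors)
  tab$label <- recode_binary(tab$as_ugL, threshold)
  attr(tab, "n_input") <- nrow(points)
  attr(tab, "n_aggregated") <- nrow(agg)
  tab
}

#' Names of the predictor columns of a modeling table
#'
#' @param table a modeling table.
#' @return character vector: every column except the positional and response
#'   bookkeeping columns.
#' @export
predictor_columns <- function(table) {
  setdiff(names(table),
          c("cell_row", "cell_col", "lon", "lat", "as_ugL", "n_obs",
            "label", "true_prob", "exceed"))
}
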