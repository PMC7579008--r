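#' Configuration of a synthetic study landscape
#'
#' Describes a fully synthetic study region: a regular 30 arc-second grid
#' carrying spatially autocorrelated continuous predictor fields, patchy
#' categorical predictors (stand-ins for lithology / land cover), a
#' population-count surface, an urban mask, and a rectangular tiling of
#' named regions.
#'
#' @param nrow,ncol grid dimensions in cells.
#' @param xll,yll lower-left corner (degrees).
#' @param cellsize degrees per cell; default 1/120 (30 arc-seconds).
#' @param n_continuous number of continuous predictor fields.
#' @param categorical_levels integer vector: one entry per categorical
#'   predictor, giving its number of categories (each >= 2).
#' @param correlation_length spatial autocorrelation scale of the continuous
#'   fields, in cells (Gaussian smoothing scale); 0 gives white noise.
#' @param region_tiles c(rows, cols) of the rectangular region tiling.
#' @param urban_quantile population quantile above which a cell is urban.
#' @param seed integer RNG seed.
#' @return a `landscape_config` list.
#' @export
landscape_config <- function(nrow = 100, ncol = 100, xll = 68, yll = 8,
                             cellsize = 1 / 120, n_continuous = 8,
                             categorical_levels = c(6L, 5L),
                             correlation_length = 10,
                             region_tiles = c(2L, 2L),
                             urban_quantile = 0.9,
                             seed = 1L) {
  if (nrow < 1 || ncol < 1) stop("grid dimensions must be positive", call. = FALSE)
  if (cellsize <= 0) stop("cellsize must be > 0", call. = FALSE)
  if (correlation_length < 0) stop("correlation_length must be >= 0", call. = FALSE)
  if (length(categorical_levels) && any(categorical_levels < 2))
    stop("categorical predictors need >= 2 categories", call. = FALSE)
  structure(list(nrow = as.integer(nrow), ncol = as.integer(ncol),
                 xll = xll, yll = yll, cellsize = cellsize,
                 n_continuous = as.integer(n_continuous),
                 categorical_levels = as.integer(categorical_levels),
                 correlation_length = correlation_length,
                 region_tiles = as.integer(region_tiles),
                 urban_quantile = urban_quantile,
                 seed = as.integer(seed)),
            class = "landscape_config")
}

# Stationary Gaussian random field: white noise convolved (via FFT, on the
# torus) with a Gaussian kernel of scale `corr_len` cells, then standardised
# to mean 0, sd 1. corr_len = 0 returns the raw white noise.
gaussian_random_field <- function(nrow, ncol, corr_len) {
  z <- matrix(stats::rnorm(nrow * ncol), nrow, ncol)
  if (corr_len <= 0) return(z)
  dr <- pmin(0:(nrow - 1), nrow - (0:(nrow - 1)))
  dc <- pmin(0:(ncol - 1), ncol - (0:(ncol - 1)))
  k <- exp(-outer(dr^2, dc^2, `+`) / (2 * corr_len^2))
  sm <- Re(stats::fft(stats::fft(z) * stats::fft(k), inverse = TRUE)) / (nrow * ncol)
  (sm - mean(sm)) / stats::sd(sm)
}

# Contiguous categorical patches: nearest-seed (Voronoi) assignment of
# `n_patches` random seed cells, each labelled by cycling through the levels.
categorical_patches <- function(nrow, ncol, n_levels, n_patches = 3L * n_levels) {
  sr <- stats::runif(n_patches, 0.5, nrow + 0.5)
  sc <- stats::runif(n_patches, 0.5, ncol + 0.5)
  lev <- rep_len(seq_len(n_levels), n_patches)
  rows <- matrix(seq_len(nrow), nrow, ncol)
  cols <- matrix(seq_len(ncol), nrow, ncol, byrow = TRUE)
  best <- matrix(Inf, nrow, ncol)
  out <- matrix(1L, nrow, ncol)
  for (i in seq_len(n_patches)) {
    d <- (rows - sr[i])^2 + (cols - sc[i])^2
    upd <- d < best
    best[upd] <- d[upd]
    out[upd] <- lev[i]
  }
  out
}

#' Generate a synthetic landscape
#'
#' Builds the full co-registered set of study rasters from a
#' [landscape_config()]: continuous predictors (`cont_01`, ...) as
#' standardised Gaussian random fields, categorical predictors
#' (`cat_01`, ...) as contiguous nearest-seed patches, a heavy-tailed
#' population surface (exp of a smoothed field), an urban mask (top
#' `urban_quantile` of population), and a rectangular region tiling.
#'
#' @param config a [landscape_config()].
#' @return a `landscape` list with elements `predictors` (a
#'   [raster_stack()]), `population`, `urban`, `regions` (region-index
#'   raster), `region_names` (data.frame id/name), and `config`.
#' @export
generate_landscape <- function(config) {
  stopifnot(inherits(config, "landscape_config"))
  set.seed(config$seed)
  nr <- config$nrow; nc <- config$ncol
  mk <- function(v, levels = NULL)
    grid_raster(v, xll = config$xll, yll = config$yll,
                cellsize = config$cellsize, levels = levels)

  layers <- list()
  for (i in seq_len(config$n_continuous))
    layers[[sprintf("cont_%02d", i)]] <-
      mk(gaussian_random_field(nr, nc, config$correlation_length))
  for (i in seq_along(config$categorical_levels)) {
    nl <- config$categorical_levels[i]
    layers[[sprintf("cat_%02d", i)]] <-
      mk(categorical_patches(nr, nc, nl), levels = paste0("class", seq_len(nl)))
  }

  pop_field <- gaussian_random_field(nr, nc, max(config$correlation_length, 5))
  population <- mk(exp(3 + 1.5 * pop_field))  # heavy-tailed counts per cell
  urb_thr <- stats::quantile(population$values, config$urban_quantile)
  urban <- mk((population$values >= urb_thr) * 1)

  tiles <- config$region_tiles
  ri <- ceiling(tiles[1L] * (row(matrix(0, nr, nc))) / nr)
  ci <- ceiling(tiles[2L] * (col(matrix(0, nr, nc))) / nc)
  regions <- mk((ri - 1L) * tiles[2L] + ci)
  n_reg <- tiles[1L] * tiles[2L]
  region_names <- data.frame(id = seq_len(n_reg),
                             name = sprintf("Region %02d", seq_len(n_reg)))

  structure(list(predictors = raster_stack(layers),
                 population = population, urban = urban,
                 regions = regions, region_names = region_names,
                 config = config),
            class = "landscape")
}

#' @export
print.landscape <- function(x, ...) {
  cat(sprintf("synthetic landscape: %d x %d cells, %d predictors (%d continuous, %d categorical)\n",
              x$config$nrow, x$config$ncol, length(x$predictors),
              x$config$n_continuous, length(x$config$categorical_levels)))
  invisible(x)
}

#' Specify the true exceedance mechanism
#'
#' The probability that groundwater arsenic exceeds the guideline at a cell
#' is `plogis(intercept + sum(linear terms) + sum(peaked terms))` evaluated
#' on the landscape's predictor fields. Peaked terms are Gaussian bumps
#' `height * exp(-((x - center)/width)^2)` that emulate non-monotone
#' (optimum-range) predictor effects.
#'
#' @param intercept logit-scale intercept.
#' @param linear named numeric vector of coefficients on continuous
#'   predictors.
#' @param peaked named list; each element `c(center=, width=, height=)`
#'   (height defaults to 1) keyed by predictor name.
#' @param concentration_scale lognormal sdlog of the magnitude by which a
#'   drawn concentration sits above/below the 10 ug/L threshold.
#' @return an `exceedance_model_spec` list.
#' @export
exceedance_model_spec <- function(intercept = 0, linear = numeric(),
                                  peaked = list(),
                                  concentration_scale = 1) {
  if (length(linear) && is.null(names(linear)))
    stop("linear coefficients must be named by predictor", call. = FALSE)
  for (nm in names(peaked)) {
    p <- peaked[[nm]]
    if (!("center" %in% names(p)) || !("width" %in% names(p)) || p[["width"]] <= 0)
      stop(sprintf("peaked term '%s' needs center and width > 0", nm), call. = FALSE)
  }
  structure(list(intercept = intercept, linear = linear, peaked = peaked,
                 concentration_scale = concentration_scale),
            class = "exceedance_model_spec")
}

# Logit-scale linear predictor over all landscape cells (matrix).
logit_field <- function(landscape, model) {
  nms <- c(names(model$linear), names(model$peaked))
  missing <- setdiff(nms, names(landscape$predictors))
  if (length(missing))
    stop(sprintf("exceedance model names unknown predictors: %s",
                 paste(missing, collapse = ", ")), call. = FALSE)
  g <- landscape$config
  eta <- matrix(model$intercept, g$nrow, g$ncol)
  for (nm in names(model$linear))
    eta <- eta + model$linear[[nm]] * landscape$predictors[[nm]]$values
  for (nm in names(model$peaked)) {
    p <- model$peaked[[nm]]
    h <- if ("height" %in% names(p)) p[["height"]] else 1
    x <- landscape$predictors[[nm]]$values
    eta <- eta + h * exp(-((x - p[["center"]]) / p[["width"]])^2)
  }
  eta
}

#' True exceedance-probability surface
#'
#' @param landscape a [generate_landscape()] result.
#' @param model an [exceedance_model_spec()].
#' @return a `grid_raster` of `plogis(eta)` per cell.
#' @export
exceedance_probability <- function(landscape, model) {
  g <- landscape$config
  grid_raster(stats::plogis(logit_field(landscape, model)),
              xll = g$xll, yll = g$yll, cellsize = g$cellsize)
}

#' Calibrate the intercept to a target exceedance rate
#'
#' Solves for the logit intercept at which the mean exceedance probability
#' over a set of cells (by default all cells) equals `target`; used to pin
#' the synthetic scenario at the study-like aggregate exceedance rate.
#'
#' @param landscape a landscape.
#' @param model an [exceedance_model_spec()]; its intercept is replaced.
#' @param target desired mean exceedance probability.
#' @param cells optional two-column matrix (row, col) of cells to average
#'   over (e.g. the sampled cells).
#' @return the model spec with the calibrated intercept.
#' @export
calibrate_intercept <- function(landscape, model, target = 0.42, cells = NULL) {
  eta0 <- logit_field(landscape, model) - model$intercept
  if (!is.null(cells)) eta0 <- eta0[cells]
  f <- function(b0) mean(stats::plogis(eta0 + b0)) - target
  model$intercept <- stats::uniroot(f, c(-50, 50), tol = 1e-10)$root
  model
}

#' Configuration of the clustered well-sampling process
#'
#' Emulates measurement campaigns whose samples concentrate heavily in a few
#' areas: points are drawn from a restricted set of "well sites" so that many
#' points share a 1-km cell, and a fraction of sites falls in a small
#' hotspot sub-region.
#'
#' @param n_points number of sample points.
#' @param clustering_factor >= 0; the number of distinct candidate sites is
#'   about `n_points / (1 + clustering_factor)`, so larger values put more
#'   points in the same cells.
#' @param hotspot_fraction fraction of sites placed inside a hotspot window
#'   covering ~4% of the grid.
#' @param seed integer RNG seed.
#' @return a `sampling_config` list.
#' @export
sampling_config <- function(n_points = 10000, clustering_factor = 5,
                            hotspot_fraction = 0.35, seed = 1L) {
  if (n_points < 1) stop("n_points must be >= 1", call. = FALSE)
  if (clustering_factor < 0) stop("clustering_factor must be >= 0", call. = FALSE)
  if (hotspot_fraction < 0 || hotspot_fraction > 1)
    stop("hotspot_fraction must be in [0, 1]", call. = FALSE)
  structure(list(n_points = as.integer(n_points),
                 clustering_factor = clustering_factor,
                 hotspot_fraction = hotspot_fraction,
                 seed = as.integer(seed)),
            class = "sampling_config")
}

#' Draw clustered arsenic sample points with known exceedance mechanism
#'
#' Each point's exceedance indicator is Bernoulli with probability
#' `plogis(eta)` at its cell; the attached concentration is consistent with
#' the indicator and has the heavy right tail typical of arsenic survey
#' compilations: `10 + Y` ug/L when exceeding, with `Y` lognormal(meanlog 3,
#' sdlog 1.2 * `concentration_scale`), and `10 - min(Y', 9.9)` otherwise,
#' with `Y'` lognormal(meanlog 1.5, sdlog `concentration_scale`). Only the
#' binary side of the threshold matters downstream.
#'
#' @param landscape a [generate_landscape()] result.
#' @param model an [exceedance_model_spec()].
#' @param sampling a [sampling_config()].
#' @return data.frame with `lon`, `lat`, `as_ugL`, plus bookkeeping columns
#'   `true_prob` and `exceed`.
#' @export
sample_arsenic_points <- function(landscape, model, sampling) {
  stopifnot(inherits(sampling, "sampling_config"))
  eta <- logit_field(landscape, model)  # validates predictor names
  g <- landscape$config
  set.seed(sampling$seed)
  n <- sampling$n_points

  n_sites <- max(1L, round(n / (1 + sampling$clustering_factor)))
  n_hot <- round(sampling$hotspot_fraction * n_sites)
  # hotspot: a 20% x 20% window, position drawn once
  hr0 <- sample.int(max(1L, g$nrow - ceiling(0.2 * g$nrow)), 1L)
  hc0 <- sample.int(max(1L, g$ncol - ceiling(0.2 * g$ncol)), 1L)
  site_r <- c(stats::runif(n_hot, hr0, hr0 + 0.2 * g$nrow),
              stats::runif(n_sites - n_hot, 0, g$nrow))
  site_c <- c(stats::runif(n_hot, hc0, hc0 + 0.2 * g$ncol),
              stats::runif(n_sites - n_hot, 0, g$ncol))
  pick <- sample.int(n_sites, n, replace = TRUE)
  # jitter each point within its site's cell
  cell_r <- pmin(floor(site_r[pick]), g$nrow - 1L)
  cell_c <- pmin(floor(site_c[pick]), g$ncol - 1L)
  fr <- cell_r + stats::runif(n)   # row offset from the north edge, cells
  fc <- cell_c + stats::runif(n)

  lon <- g$xll + fc * g$cellsize
  lat <- g$yll + (g$nrow - fr) * g$cellsize
  row <- as.integer(cell_r) + 1L
  col <- as.integer(cell_c) + 1L

  p <- stats::plogis(eta[cbind(row, col)])
  exceed <- stats::rbinom(n, 1L, p)
  y_hi <- stats::rlnorm(n, meanlog = 3, sdlog = 1.2 * model$concentration_scale)
  y_lo <- stats::rlnorm(n, meanlog = 1.5, sdlog = model$concentration_scale)
  conc <- ifelse(exceed == 1L, 10 + y_hi, 10 - pmin(y_lo, 9.9))

  data.frame(lon = lon, lat = lat, as_ugL = conc,
             true_prob = p, exceed = exceed)
}

#' The study-like synthetic scenario
#'
#' A fixed scenario mirroring the structure of the real study at reduced
#' scale: a 250 x 250 cell (30 arc-second) landscape with 20 predictors
#' (18 continuous autocorrelated fields + 2 categorical patch layers),
#' heavy clustered sampling that aggregates to roughly 20,000 occupied
#' 1-km cells, and an exceedance mechanism with five linear effects, one
#' peaked (non-monotone) effect, and an intercept calibrated so the mean
#' sampled-cell exceedance probability is 0.42.
#'
#' @param seed master seed for landscape and sampling.
#' @param n_points number of raw sample points before aggregation.
#' @param nrow,ncol grid dimensions.
#' @return list with `landscape`, `model`, `sampling`, and `points`
#'   (the sampled data.frame).
#' @export
paper_like_scenario <- function(seed = 1L, n_points = 150000L,
                                nrow = 250L, ncol = 250L) {
  cfg <- landscape_config(nrow = nrow, ncol = ncol, n_continuous = 18,
                          categorical_levels = c(6L, 5L),
                          correlation_length = 12,
                          region_tiles = c(2L, 3L),
                          seed = seed)
  land <- generate_landscape(cfg)
  model <- exceedance_model_spec(
    intercept = 0,
    linear = c(cont_01 = 1.5, cont_02 = -1.2, cont_03 = 1.0,
               cont_04 = -0.8, cont_05 = 0.6),
    peaked = list(cont_06 = c(center = 0, width = 0.7, height = 1.5)),
    concentration_scale = 1
  )
  samp <- sampling_config(n_points = n_points, clustering_factor = 3,
                          hotspot_fraction = 0.35,
                          seed = seed + 1000L)
  # The 0.42 target refers to the rate AFTER spatial averaging, where the
  # heavy-tailed concentration marginal lets one large value tip a mixed
  # cell's mean over the threshold, so calibrate the intercept against the
  # simulated aggregated rate (deterministic given the sampling seed; the
  # rate is monotone in the intercept, so bisection suffices).
  grid <- land$predictors[[1L]]
  agg_rate <- function(b0) {
    model$intercept <- b0
    pts <- sample_arsenic_points(land, model, samp)
    mean(aggregate_to_grid(pts[c("lon", "lat", "as_ugL")], grid)$as_ugL > 10)
  }
  lo <- -8; hi <- 8
  for (i in 1:20) {
    mid <- (lo + hi) / 2
    if (agg_rate(mid) < 0.42) lo <- mid else hi <- mid
  }
  model$intercept <- (lo + hi) / 2
  pts <- sample_arsenic_points(land, model, samp)
  list(landscape = land, model = model, sampling = samp, points = pts)
}
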