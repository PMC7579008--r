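#' Exposure-estimation configuration
#'
#' Nationwide usage rates of untreated groundwater: 0.637 of the rural and
#' 0.238 of the urban population draw drinking water from untreated
#' groundwater (2016 estimates), and two probability cutoffs bracketing the
#' hazard classification.
#'
#' @param rural_use_rate,urban_use_rate fractions in [0, 1].
#' @param cutoffs numeric vector (typically length 2) of probability
#'   cutoffs.
#' @return an `exposure_config` list.
#' @export
exposure_config <- function(rural_use_rate = 0.637, urban_use_rate = 0.238,
                            cutoffs = c(0.49, 0.55)) {
  if (any(c(rural_use_rate, urban_use_rate) < 0) ||
      any(c(rural_use_rate, urban_use_rate) > 1))
    stop("use rates must lie in [0, 1]", call. = FALSE)
  if (any(cutoffs < 0 | cutoffs > 1))
    stop("cutoffs must lie in [0, 1]", call. = FALSE)
  structure(list(rural_use_rate = rural_use_rate,
                 urban_use_rate = urban_use_rate,
                 cutoffs = cutoffs),
            class = "exposure_config")
}

#' Binary hazard map from a probability raster
#'
#' @param prob_raster exceedance-probability `grid_raster` (values in
#'   [0, 1] or nodata).
#' @param cutoff probability cutoff in [0, 1].
#' @return `grid_raster` with 1 where probability > cutoff, 0 otherwise;
#'   nodata propagates.
#' @export
hazard_map <- function(prob_raster, cutoff) {
  stopifnot(inherits(prob_raster, "grid_raster"))
  if (length(cutoff) != 1L || !is.finite(cutoff) || cutoff < 0 || cutoff > 1)
    stop("cutoff must be a single value in [0, 1]", call. = FALSE)
  out <- prob_raster
  out$values <- (prob_raster$values > cutoff) * 1
  out$levels <- NULL
  out
}

#' Population exposed to high-hazard groundwater
#'
#' For every cell classified high-hazard (probability > cutoff), the
#' resident population is weighted by the modeled exceedance probability
#' and by the groundwater-use rate of its rural/urban class; cells at or
#' below the cutoff contribute nothing.
#'
#' @param prob_raster exceedance-probability raster.
#' @param cutoff hazard cutoff in [0, 1].
#' @param population_raster population counts per cell.
#' @param urban_mask 0/1 raster (1 = urban).
#' @param config an [exposure_config()].
#' @return list with `total` (people) and `raster` (per-cell exposure;
#'   nodata where the probability is nodata).
#' @export
exposed_population <- function(prob_raster, cutoff, population_raster,
                               urban_mask, config = exposure_config()) {
  check_coregistered(prob = prob_raster, population = population_raster,
                     urban = urban_mask)
  if (length(cutoff) != 1L || cutoff < 0 || cutoff > 1)
    stop("cutoff must lie in [0, 1]", call. = FALSE)
  p <- prob_raster$values
  rate <- ifelse(urban_mask$values == 1, config$urban_use_rate,
                 config$rural_use_rate)
  expo <- ifelse(!is.na(p) & p > cutoff,
                 p * population_raster$values * rate, 0)
  expo[is.na(p)] <- NA_real_
  out <- prob_raster
  out$values <- expo
  list(total = sum(expo, na.rm = TRUE), raster = out)
}

#' Per-region exposure report
#'
#' Zonal summary of the hazard classification: for each region and each
#' cutoff, the percentage of the region's valid cells classified
#' high-hazard and the summed probability- and use-rate-weighted exposed
#' population; a national totals row is appended. With two cutoffs the
#' columns are assembled as a low-high range — monotonicity guarantees the
#' low end comes from the higher cutoff.
#'
#' @param prob_raster exceedance-probability raster.
#' @param population_raster,urban_mask co-registered population and urban
#'   rasters.
#' @param regions region-index `grid_raster` (integer ids).
#' @param region_names data.frame with `id`, `name` (optional; ids used
#'   otherwise).
#' @param config an [exposure_config()] carrying the two cutoffs.
#' @return data.frame of class `exposure_report`: `region`,
#'   `pct_area_low`, `pct_area_high`, `pop_low`, `pop_high`, plus per-cutoff
#'   columns `pct_area_at_<cutoff>` / `pop_at_<cutoff>`, with a final
#'   `Total` row. Regions with no flagged cells report zeros.
#' @export
regional_summary <- function(prob_raster, population_raster, urban_mask,
                             regions, region_names = NULL,
                             config = exposure_config()) {
  check_coregistered(prob = prob_raster, population = population_raster,
                     urban = urban_mask, regions = regions)
  cutoffs <- sort(config$cutoffs)
  ids <- sort(unique(as.vector(regions$values)))
  ids <- ids[!is.na(ids)]
  nm <- if (!is.null(region_names))
    region_names$name[match(ids, region_names$id)] else as.character(ids)

  per_cut <- lapply(cutoffs, function(ct) {
    hz <- hazard_map(prob_raster, ct)
    ex <- exposed_population(prob_raster, ct, population_raster, urban_mask,
                             config)
    t(vapply(ids, function(id) {
      sel <- regions$values == id & !is.na(hz$values)
      n_valid <- sum(sel)
      c(pct = if (n_valid > 0) 100 * sum(hz$values[sel] == 1) / n_valid else 0,
        pop = sum(ex$raster$values[sel], na.rm = TRUE))
    }, numeric(2L)))
  })

  out <- data.frame(region = nm)
  for (k in seq_along(cutoffs)) {
    out[[sprintf("pct_area_at_%g", cutoffs[k])]] <- per_cut[[k]][, "pct"]
    out[[sprintf("pop_at_%g", cutoffs[k])]] <- per_cut[[k]][, "pop"]
  }
  lo <- length(cutoffs); hi <- 1L  # higher cutoff flags fewer cells
  out$pct_area_low <- per_cut[[lo]][, "pct"]
  out$pct_area_high <- per_cut[[hi]][, "pct"]
  out$pop_low <- per_cut[[lo]][, "pop"]
  out$pop_high <- per_cut[[hi]][, "pop"]

  tot <- out[1L, ]
  tot$region <- "Total"
  n_valid_all <- sum(!is.na(prob_raster$values))
  for (k in seq_along(cutoffs)) {
    hz <- hazard_map(prob_raster, cutoffs[k])
    tot[[sprintf("pct_area_at_%g", cutoffs[k])]] <-
      100 * sum(hz$values == 1, na.rm = TRUE) / n_valid_all
    tot[[sprintf("pop_at_%g", cutoffs[k])]] <- sum(per_cut[[k]][, "pop"])
  }
  tot$pct_area_low <- tot[[sprintf("pct_area_at_%g", cutoffs[lo])]]
  tot$pct_area_high <- tot[[sprintf("pct_area_at_%g", cutoffs[hi])]]
  tot$pop_low <- tot[[sprintf("pop_at_%g", cutoffs[lo])]]
  tot$pop_high <- tot[[sprintf("pop_at_%g", cutoffs[hi])]]
  out <- rbind(out, tot)
  rownames(out) <- NULL
  class(out) <- c("exposure_report", class(out))
  out
}
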