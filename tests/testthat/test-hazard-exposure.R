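rand_rasters <- function(seed = 161, nr = 20, nc = 25, na_frac = 0.05) {
  set.seed(seed)
  p <- matrix(runif(nr * nc), nr, nc)
  p[sample(length(p), round(na_frac * length(p)))] <- NA
  list(prob = grid_raster(p, 0, 0, cellsize = 1),
       pop = grid_raster(matrix(rpois(nr * nc, 50), nr, nc), 0, 0, cellsize = 1),
       urban = grid_raster(matrix(rbinom(nr * nc, 1, 0.2), nr, nc), 0, 0,
                           cellsize = 1))
}

test_that("hazard maps threshold strictly and propagate nodata", {
  r <- rand_rasters()
  h0 <- hazard_map(r$prob, 0)
  expect_equal(h0$values == 1, r$prob$values > 0)
  h1 <- hazard_map(r$prob, 1)
  expect_equal(sum(h1$values, na.rm = TRUE), 0)
  expect_equal(is.na(h1$values), is.na(r$prob$values))
  for (ct in c(0.2, 0.5, 0.8)) {
    h <- hazard_map(r$prob, ct)
    expect_equal(sum(h$values == 1, na.rm = TRUE),
                 sum(r$prob$values > ct, na.rm = TRUE))  # brute-force count
  }
  expect_error(hazard_map(r$prob, 1.5), "cutoff")
})

test_that("a single rural cell gives the hand-computed exposure", {
  prob <- grid_raster(matrix(0.6, 1, 1), 0, 0, cellsize = 1)
  pop <- grid_raster(matrix(1000, 1, 1), 0, 0, cellsize = 1)
  rural <- grid_raster(matrix(0, 1, 1), 0, 0, cellsize = 1)
  ex <- exposed_population(prob, 0.49, pop, rural, exposure_config())
  expect_equal(ex$total, 0.6 * 1000 * 0.637)  # = 382.2
  # urban cell instead
  urban <- grid_raster(matrix(1, 1, 1), 0, 0, cellsize = 1)
  expect_equal(exposed_population(prob, 0.49, pop, urban)$total,
               0.6 * 1000 * 0.238)
  # below the cutoff: contributes nothing
  expect_equal(exposed_population(prob, 0.7, pop, rural)$total, 0)
})

test_that("exposure equals a brute-force per-cell sum and is monotone in the cutoff", {
  r <- rand_rasters(seed = 162)
  cfg <- exposure_config()
  totals <- vapply(seq(0, 1, by = 0.1), function(ct) {
    ex <- exposed_population(r$prob, ct, r$pop, r$urban, cfg)
    # independent brute force over every cell
    brute <- 0
    for (i in seq_len(nrow(r$prob$values))) for (j in seq_len(ncol(r$prob$values))) {
      p <- r$prob$values[i, j]
      if (!is.na(p) && p > ct) {
        rate <- if (r$urban$values[i, j] == 1) cfg$urban_use_rate else cfg$rural_use_rate
        brute <- brute + p * r$pop$values[i, j] * rate
      }
    }
    expect_equal(ex$total, brute, tolerance = 1e-12)
    ex$total
  }, numeric(1))
  expect_true(all(diff(totals) <= 1e-12))  # non-increasing in the cutoff
})

test_that("degenerate rates and populations behave exactly", {
  r <- rand_rasters(seed = 163, na_frac = 0)
  zero_pop <- grid_raster(matrix(0, 20, 25), 0, 0, cellsize = 1)
  expect_equal(exposed_population(r$prob, 0.3, zero_pop, r$urban)$total, 0)
  all1 <- grid_raster(matrix(1, 20, 25), 0, 0, cellsize = 1)
  cfg1 <- exposure_config(rural_use_rate = 1, urban_use_rate = 1,
                          cutoffs = c(0.4, 0.6))
  ex <- exposed_population(all1, 0.5, r$pop, r$urban, cfg1)
  expect_equal(ex$total, sum(r$pop$values))
  # misregistered rasters are refused with the mismatch named
  small_pop <- grid_raster(matrix(1, 5, 5), 0, 0, cellsize = 1)
  expect_error(exposed_population(r$prob, 0.5, small_pop, r$urban),
               "population")
})

test_that("regional summaries conserve totals and honour range semantics", {
  r <- rand_rasters(seed = 164)
  cfg <- exposure_config(cutoffs = c(0.4, 0.7))
  whole <- grid_raster(matrix(1L, 20, 25), 0, 0, cellsize = 1)
  rep1 <- regional_summary(r$prob, r$pop, r$urban, whole,
                           data.frame(id = 1, name = "All"), cfg)
  expect_equal(unlist(rep1[rep1$region == "All", -1]),
               unlist(rep1[rep1$region == "Total", -1]))
  # split into two halves: regional exposures sum to the national total
  halves <- grid_raster(cbind(matrix(1L, 20, 12), matrix(2L, 20, 13)),
                        0, 0, cellsize = 1)
  rep2 <- regional_summary(r$prob, r$pop, r$urban, halves, config = cfg)
  tot <- rep2[rep2$region == "Total", ]
  parts <- rep2[rep2$region != "Total", ]
  expect_equal(sum(parts$pop_low), tot$pop_low)
  expect_equal(sum(parts$pop_high), tot$pop_high)
  # low end comes from the higher cutoff
  expect_equal(tot$pop_low, tot[["pop_at_0.7"]])
  expect_equal(tot$pop_high, tot[["pop_at_0.4"]])
  expect_true(all(parts$pop_low <= parts$pop_high + 1e-12))
  expect_true(all(parts$pct_area_low <= parts$pct_area_high + 1e-12))
  expect_true(all(parts$pct_area_low >= 0 & parts$pct_area_high <= 100))
})

test_that("exposure is bounded by probability-weighted and total population", {
  r <- rand_rasters(seed = 165)
  ct <- 0.3
  ex <- exposed_population(r$prob, ct, r$pop, r$urban)$total
  hz <- !is.na(r$prob$values) & r$prob$values > ct
  pw <- sum(r$prob$values[hz] * r$pop$values[hz])
  expect_lte(ex, pw + 1e-9)
  expect_lte(pw, sum(r$pop$values[hz]) + 1e-9)
})
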