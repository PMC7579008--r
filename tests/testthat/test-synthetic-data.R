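test_that("generation is bit-identical under the same seed and config", {
  cfg <- landscape_config(nrow = 40, ncol = 40, n_continuous = 3, seed = 5)
  l1 <- generate_landscape(cfg)
  l2 <- generate_landscape(cfg)
  expect_identical(l1$predictors[["cont_01"]]$values,
                   l2$predictors[["cont_01"]]$values)
  expect_identical(l1$population$values, l2$population$values)
  m <- exceedance_model_spec(intercept = -0.5, linear = c(cont_01 = 1))
  s <- sampling_config(n_points = 500, seed = 9)
  expect_identical(sample_arsenic_points(l1, m, s),
                   sample_arsenic_points(l2, m, s))
})

test_that("correlation length controls measured spatial autocorrelation", {
  set.seed(42)
  f0 <- ashazard:::gaussian_random_field(200, 200, 0)
  expect_lt(abs(lag1_autocor(f0)), 0.05)
  f20 <- ashazard:::gaussian_random_field(200, 200, 20)
  expect_gt(lag1_autocor(f20), 0.8)
  expect_equal(mean(f20), 0, tolerance = 1e-8)
  expect_equal(sd(f20), 1, tolerance = 1e-8)
})

test_that("generated rasters are co-registered, population non-negative, urban binary", {
  cfg <- landscape_config(nrow = 30, ncol = 50, n_continuous = 2,
                          categorical_levels = c(3L), seed = 2)
  land <- generate_landscape(cfg)
  expect_silent(check_coregistered(c(unclass(land$predictors),
                                     list(pop = land$population,
                                          urban = land$urban,
                                          regions = land$regions))))
  expect_true(all(land$population$values >= 0))
  expect_true(all(land$urban$values %in% c(0, 1)))
  # regions partition the grid
  expect_true(all(land$regions$values %in% land$region_names$id))
  # categorical layer holds valid integer categories
  cat1 <- land$predictors[["cat_01"]]
  expect_true(all(cat1$values %in% seq_along(cat1$levels)))
  # every sampled point falls in exactly one cell
  m <- exceedance_model_spec(linear = c(cont_01 = 1))
  pts <- sample_arsenic_points(land, m, sampling_config(n_points = 2000, seed = 3))
  idx <- cell_index(land$population, pts$lon, pts$lat)
  expect_true(all(idx$inside))
})

test_that("degenerate logistic settings behave as specified", {
  cfg <- landscape_config(nrow = 30, ncol = 30, n_continuous = 1, seed = 4)
  land <- generate_landscape(cfg)
  # huge negative intercept: nothing exceeds
  m <- exceedance_model_spec(intercept = -40)
  pts <- sample_arsenic_points(land, m, sampling_config(n_points = 1000, seed = 5))
  expect_true(all(pts$as_ugL <= 10))
  # intercept 0, no covariates: exceedance fraction 0.5 +/- 0.02 at n = 10,000
  m0 <- exceedance_model_spec(intercept = 0)
  pts0 <- sample_arsenic_points(land, m0, sampling_config(n_points = 10000, seed = 6))
  expect_equal(mean(pts0$exceed), 0.5, tolerance = 0.02)
  # concentrations are consistent with the indicator and positive
  expect_true(all(pts0$as_ugL > 0))
  expect_identical(as.integer(pts0$as_ugL > 10), pts0$exceed)
})

test_that("clustering concentrates many points into few cells", {
  cfg <- landscape_config(nrow = 100, ncol = 100, n_continuous = 1, seed = 7)
  land <- generate_landscape(cfg)
  m <- exceedance_model_spec(linear = c(cont_01 = 1))
  pts <- sample_arsenic_points(land, m,
    sampling_config(n_points = 10000, clustering_factor = 50, seed = 8))
  idx <- cell_index(land$population, pts$lon, pts$lat)
  n_cells <- nrow(unique(cbind(idx$row, idx$col)))
  expect_lt(n_cells, 1000)  # far fewer occupied cells than points
})

test_that("empirical exceedance converges to the specified logistic probabilities", {
  cfg <- landscape_config(nrow = 50, ncol = 50, n_continuous = 2,
                          correlation_length = 6, seed = 10)
  land <- generate_landscape(cfg)
  m <- exceedance_model_spec(intercept = -0.3,
                             linear = c(cont_01 = 0.8, cont_02 = -0.5),
                             peaked = list(cont_02 = c(center = 0, width = 1,
                                                       height = 0.5)))
  pts <- sample_arsenic_points(land, m, sampling_config(n_points = 20000, seed = 11))
  # binomial error bound: 4 sd of the mean of heterogeneous Bernoullis
  tol <- 4 * sqrt(mean(pts$true_prob * (1 - pts$true_prob)) / nrow(pts))
  expect_equal(mean(pts$exceed), mean(pts$true_prob), tolerance = tol)
})

test_that("configuration errors are caught", {
  expect_error(landscape_config(nrow = 0), "positive")
  expect_error(landscape_config(correlation_length = -1), ">= 0")
  expect_error(landscape_config(categorical_levels = c(1L)), "categories")
  expect_error(sampling_config(n_points = 0), "n_points")
  expect_error(sampling_config(hotspot_fraction = 1.2), "hotspot")
  expect_error(exceedance_model_spec(peaked = list(a = c(center = 0, width = 0))),
               "width")
  land <- generate_landscape(landscape_config(nrow = 10, ncol = 10,
                                              n_continuous = 1, seed = 1))
  bad <- exceedance_model_spec(linear = c(no_such = 1))
  expect_error(sample_arsenic_points(land, bad, sampling_config(n_points = 10)),
               "no_such")
})

test_that("intercept calibration hits the requested mean probability", {
  cfg <- landscape_config(nrow = 40, ncol = 40, n_continuous = 2, seed = 12)
  land <- generate_landscape(cfg)
  m <- exceedance_model_spec(linear = c(cont_01 = 2, cont_02 = -1))
  m42 <- calibrate_intercept(land, m, target = 0.42)
  expect_equal(mean(exceedance_probability(land, m42)$values), 0.42,
               tolerance = 1e-6)
})
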