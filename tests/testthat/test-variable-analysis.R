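test_that("Sturges' rule gives the expected bin counts", {
  expect_equal(sturges_bins(23799), 16L)
  expect_equal(sturges_bins(2), 2L)
  expect_equal(sturges_bins(1000), 11L)
  expect_equal(sturges_bins(1), 1L)
  expect_error(sturges_bins(0), ">= 1")
})

test_that("equal-count binning is balanced and reproduces the sorted input", {
  for (n in c(16, 100, 1003, 23799)) {
    nb <- sturges_bins(n)
    a <- ashazard:::equal_count_assignment(n, nb)
    sizes <- tabulate(a, nb)
    expect_equal(sum(sizes), n)
    expect_lte(diff(range(sizes)), 1L)
    expect_true(!is.unsorted(a))  # concatenated bins = sorted order
  }
})

test_that("monotone predictor-label relationships give extreme tau_b values", {
  # bin proportions strictly increasing: tau_b exactly 1
  x <- seq_len(320)
  lab <- unlist(lapply(1:16, function(k) rep(c(1L, 0L), c(k - 1L, 21L - k))))
  bc <- binned_exceedance_correlation(x, lab, n_bins = 16)
  expect_equal(bc$tau_b, 1)
  expect_true(bc$significant)
  expect_equal(sum(bc$bins$n), 320L)
  expect_equal(bc$bins$prop_exceed, (0:15) / 20)
  # decreasing relationship flips the sign
  bc2 <- binned_exceedance_correlation(-x, lab, n_bins = 16)
  expect_equal(bc2$tau_b, -1)
  # label = (predictor > median): a 0/1 step in the bin proportions, whose
  # y-ties enter the tau-b tie correction. Hand enumeration over the 16 bins:
  # 64 concordant pairs, 0 discordant, 56 tied-in-y pairs, so
  # tau_b = 64 / sqrt(120 * (120 - 56)).
  step <- as.integer(x > stats::median(x))
  bs <- binned_exceedance_correlation(x, step, n_bins = 16)
  expect_equal(bs$tau_b, 64 / sqrt(120 * 64))
})

test_that("binned tau_b is invariant under strictly monotone predictor transforms", {
  set.seed(131)
  x <- rnorm(2000)
  lab <- rbinom(2000, 1, plogis(1.2 * x))
  b1 <- binned_exceedance_correlation(x, lab, 16)
  b2 <- binned_exceedance_correlation(exp(x), lab, 16)
  expect_equal(b2$tau_b, b1$tau_b)
  expect_equal(b2$bins$prop_exceed, b1$bins$prop_exceed)
})

test_that("a constant predictor is flagged undefined, not silently zero", {
  bc <- binned_exceedance_correlation(rep(2.5, 100), rbinom(100, 1, 0.4), 5)
  expect_true(bc$undefined)
  expect_true(is.na(bc$tau_b))
})

test_that("permutation importance separates dominant and null predictors", {
  set.seed(141)
  n <- 2000
  tab <- data.frame(lon = runif(n), lat = runif(n),
                    signal = rnorm(n), noise1 = rnorm(n), noise2 = rnorm(n))
  tab$label <- as.integer(tab$signal > 0)  # label perfectly determined
  sp <- stratified_split(tab, seed = 142)
  fit <- fit_forest(sp$train, forest_spec(n_trees = 201, seed = 143))
  imp <- permutation_importance(fit, sp$test, n_repeats = 10, seed = 144)
  expect_equal(imp$predictor[which.max(imp$mean_decrease_accuracy)], "signal")
  nulls <- imp$mean_decrease_accuracy[imp$predictor != "signal"]
  expect_true(all(abs(nulls) < 0.02))
  # fixed seed -> reproducible shuffles
  imp2 <- permutation_importance(fit, sp$test, n_repeats = 10, seed = 144)
  expect_identical(imp, imp2)
  expect_error(permutation_importance(fit, sp$test, n_repeats = 0), "n_repeats")
})

test_that("OOB-mode importance exposes the forest's recorded measures", {
  tab <- make_table(500, p = 4, seed = 151)
  fit <- fit_forest(tab, forest_spec(n_trees = 201, seed = 152))
  imp <- importance_table(fit, tab, method = "oob")
  expect_setequal(imp$predictor, sprintf("x%d", 1:4))
  expect_true(all(is.finite(imp$mean_decrease_gini)))
  # informative predictor dominates both measures
  expect_equal(imp$predictor[which.max(imp$mean_decrease_gini)], "x1")
})

test_that("normalization divides by the per-measure maximum and keeps signs", {
  tbl <- data.frame(predictor = c("a", "b", "c"),
                    mean_decrease_accuracy = c(2, 4, 1),
                    mean_decrease_gini = c(10, 5, -2))
  nt <- normalize_importance(tbl)
  expect_equal(nt$mean_decrease_accuracy, c(0.5, 1.0, 0.25))
  expect_equal(nt$mean_decrease_gini, c(1.0, 0.5, -0.2))
  expect_equal(max(nt$mean_decrease_accuracy), 1)
  one <- normalize_importance(data.frame(predictor = "a",
                                         mean_decrease_accuracy = 3))
  expect_equal(one$mean_decrease_accuracy, 1)
  bad <- data.frame(predictor = c("a", "b"), mean_decrease_accuracy = c(-1, 0))
  expect_error(normalize_importance(bad), "positive")
  set.seed(153)
  for (i in 1:10) {
    v <- rnorm(6); v[1] <- abs(v[1]) + 0.1
    tb <- data.frame(predictor = letters[1:6], mean_decrease_accuracy = v)
    expect_equal(sign(normalize_importance(tb)$mean_decrease_accuracy), sign(v))
  }
})
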