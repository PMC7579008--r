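# Shared fixtures and independent oracles for the test suite.

# A small landscape + points, cheap enough to rebuild per test file.
small_scene <- function(seed = 11L, nrow = 60L, ncol = 60L,
                        n_points = 4000L, clustering_factor = 3,
                        betas = c(cont_01 = 1.5, cont_02 = -1.0)) {
  cfg <- landscape_config(nrow = nrow, ncol = ncol, n_continuous = 4,
                          categorical_levels = c(4L), correlation_length = 8,
                          seed = seed)
  land <- generate_landscape(cfg)
  model <- exceedance_model_spec(intercept = 0, linear = betas)
  samp <- sampling_config(n_points = n_points,
                          clustering_factor = clustering_factor,
                          hotspot_fraction = 0.3, seed = seed + 1L)
  list(landscape = land, model = model, sampling = samp,
       points = sample_arsenic_points(land, model, samp))
}

# A synthetic modeling table without any raster plumbing: numeric predictors
# x1..xp, the label driven by a logistic model on the first few.
make_table <- function(n, p = 5L, betas = c(2, -1.5), seed = 1L) {
  set.seed(seed)
  x <- matrix(rnorm(n * p), n, p, dimnames = list(NULL, sprintf("x%d", 1:p)))
  eta <- x[, seq_along(betas), drop = FALSE] %*% betas
  lab <- rbinom(n, 1L, plogis(eta))
  cbind(data.frame(lon = runif(n), lat = runif(n)), as.data.frame(x),
        data.frame(label = as.integer(lab)))
}

# Brute-force AUC: enumerate every positive-negative pair, ties count 1/2.
auc_by_enumeration <- function(scores, labels) {
  pos <- scores[labels == 1]; neg <- scores[labels == 0]
  cmp <- outer(pos, neg, function(a, b) (a > b) + 0.5 * (a == b))
  mean(cmp)
}

# Label-level recomputation of the confusion statistics.
stats_from_labels <- function(pred, ref) {
  list(accuracy = mean(pred == ref),
       sensitivity = mean(pred[ref == 1] == 1),
       specificity = mean(pred[ref == 0] == 0),
       ppv = mean(ref[pred == 1] == 1),
       npv = mean(ref[pred == 0] == 0),
       prevalence = mean(ref == 1))
}

# Empirical lag-1 spatial autocorrelation of a matrix (row direction).
lag1_autocor <- function(m) {
  a <- as.vector(m[-nrow(m), ]); b <- as.vector(m[-1, ])
  cor(a, b)
}
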