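test_that("the published cross-validation statistic set is reproduced to 4 d.p.", {
  m <- confusion_matrix(pred = c(rep(0, 2223 + 462), rep(1, 561 + 1514)),
                        ref = c(rep(0, 2223), rep(1, 462),
                                rep(0, 561), rep(1, 1514)))
  expect_equal(as.vector(m), c(2223L, 561L, 462L, 1514L))
  s <- confusion_stats(m)
  expect_equal(round(s$accuracy, 4), 0.7851)
  expect_equal(round(s$no_information_rate, 4), 0.5849)
  expect_lt(s$p_value_acc_gt_nir, 2.2e-16)
  expect_equal(round(s$kappa, 4), 0.5606)
  expect_equal(round(s$sensitivity, 4), 0.7662)
  expect_equal(round(s$specificity, 4), 0.7985)
  expect_equal(round(s$ppv, 4), 0.7296)
  expect_equal(round(s$npv, 4), 0.8279)
  expect_equal(round(s$prevalence, 4), 0.4151)
  expect_equal(round(s$balanced_accuracy, 4), 0.7823)
})

test_that("degenerate confusion matrices give the expected limits", {
  perfect <- matrix(c(30, 0, 0, 20), 2, 2)
  s <- confusion_stats(perfect)
  expect_equal(s$accuracy, 1)
  expect_equal(s$kappa, 1)
  all0 <- confusion_stats(matrix(c(25, 0, 15, 0), 2, 2))
  expect_equal(all0$kappa, 0)
  expect_equal(all0$accuracy, all0$no_information_rate)
  # zero denominators reported as undefined, never NaN
  expect_true(is.na(all0$ppv))
  expect_true("ppv" %in% attr(all0, "undefined"))
})

test_that("confusion statistics agree with label-level recomputation", {
  set.seed(101)
  for (i in 1:25) {
    n <- sample(20:200, 1)
    ref <- rbinom(n, 1, runif(1, 0.2, 0.8))
    pred <- ifelse(runif(n) < 0.7, ref, 1L - ref)
    if (length(unique(ref)) < 2 || length(unique(pred)) < 2) next
    s <- confusion_stats(confusion_matrix(pred, ref))
    o <- stats_from_labels(pred, ref)
    for (nm in names(o)) expect_equal(s[[nm]], o[[nm]])
    expect_lte(s$kappa, s$accuracy + 1e-12)
    expect_equal(s$balanced_accuracy, mean(c(s$sensitivity, s$specificity)))
  }
})

test_that("AUC equals exhaustive pair enumeration and known closed forms", {
  expect_equal(roc_auc(c(0.1, 0.4, 0.35, 0.8), c(0, 0, 1, 1)), 0.75)
  expect_equal(roc_auc(c(0.1, 0.2, 0.8, 0.9), c(0, 0, 1, 1)), 1.0)
  set.seed(111)
  for (i in 1:20) {
    n <- sample(10:50, 1)
    lab <- c(0L, 1L, rbinom(n - 2, 1, 0.5))
    sc <- round(runif(n), 1)  # coarse scores force ties
    expect_equal(roc_auc(sc, lab), auc_by_enumeration(sc, lab))
  }
  expect_error(roc_auc(runif(5), rep(1, 5)), "both classes")
})

test_that("AUC is invariant under strictly monotone score transforms and null at chance", {
  set.seed(112)
  sc <- runif(300); lab <- rbinom(300, 1, 0.5)
  a <- roc_auc(sc, lab)
  expect_equal(roc_auc(qlogis(sc * 0.98 + 0.01), lab), a)
  expect_equal(roc_auc(sc^3, lab), a)
  sc2 <- runif(10000); lab2 <- rbinom(10000, 1, 0.4)
  expect_equal(roc_auc(sc2, lab2), 0.5, tolerance = 0.02)
})

test_that("AUC matches an established independent implementation", {
  skip_if_not_installed("pROC")
  set.seed(113)
  sc <- runif(500); lab <- rbinom(500, 1, plogis(3 * (sc - 0.5)))
  ref <- as.numeric(pROC::auc(pROC::roc(lab, sc, quiet = TRUE)))
  expect_equal(roc_auc(sc, lab), ref, tolerance = 1e-12)
})

test_that("cutoff search finds the constructed sensitivity/specificity crossing", {
  set.seed(121)
  n <- 5000
  p <- c(runif(n / 2, 0, 0.5), runif(n / 2, 0.5, 1))
  lab <- rep(c(0L, 1L), each = n / 2)
  res <- find_cutoff(p, lab, "sens_spec", grid_size = 100)
  expect_equal(res$cutoff, 0.5, tolerance = 1 / 99 + 1e-9)
  expect_equal(nrow(res$curves), 100L)
  expect_true(all(c("sensitivity", "specificity", "ppv", "npv", "accuracy")
                  %in% names(res$curves)))
})

test_that("separable probabilities hit the tie rule: lowest interior cutoff, accuracy 1", {
  p <- c(rep(0, 40), rep(1, 60))
  lab <- c(rep(0L, 40), rep(1L, 60))
  res <- find_cutoff(p, lab, "sens_spec", grid_size = 100)
  expect_equal(res$cutoff, 1 / 99)  # first interior grid probability
  expect_equal(res$accuracy_at_cutoff, 1)
})

test_that("the two cutoff criteria agree within one grid step on symmetric data", {
  set.seed(122)
  n <- 4000
  p0 <- rbeta(n / 2, 2, 5)
  p <- c(p0, 1 - p0)  # mirrored score distributions, equal class sizes
  lab <- rep(c(0L, 1L), each = n / 2)
  c1 <- find_cutoff(p, lab, "sens_spec")
  c2 <- find_cutoff(p, lab, "ppv_npv")
  expect_lte(abs(c1$cutoff - c2$cutoff), 1 / 99 + 1e-9)
  expect_error(find_cutoff(p, rep(1L, n)), "both classes")
})
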