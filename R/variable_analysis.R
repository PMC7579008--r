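#' Sturges' rule bin count
#'
#' @param n number of observations (>= 1).
#' @return `ceiling(1 + log2(n))` bins.
#' @export
sturges_bins <- function(n) {
  if (length(n) != 1L || !is.finite(n) || n < 1)
    stop("sturges_bins: n must be a single value >= 1", call. = FALSE)
  as.integer(ceiling(1 + log2(n)))
}

# Equal-count bin assignment for n sorted values: sizes differ by at most 1,
# with the remainder spread over the first bins.
equal_count_assignment <- function(n, n_bins) {
  base <- n %/% n_bins
  rem <- n %% n_bins
  sizes <- rep(base, n_bins) + c(rep(1L, rem), rep(0L, n_bins - rem))
  rep(seq_len(n_bins), times = sizes)
}

#' Binned predictor-exceedance correlation
#'
#' The direction-of-effect diagnostic: predictor values are ordered (stable
#' sort, so ties keep input order and may straddle a bin boundary), split
#' into `n_bins` equal-count bins, and each bin is summarised by its mean
#' predictor value and its proportion of exceedance labels. The rank
#' correlation (Kendall tau-b, tie-corrected) between bin means and bin
#' exceedance proportions is reported with a two-sided p-value and a 95%
#' significance flag; the Pearson correlation over the same bin summaries is
#' returned alongside.
#'
#' @param values continuous predictor values.
#' @param labels binary exceedance labels (same length).
#' @param n_bins bin count; defaults to [sturges_bins()] of the sample size.
#' @return list of class `binned_correlation`: `n_bins`, `bins` (data.frame
#'   with mean_value, prop_exceed, n), `tau_b`, `p_value`, `significant`,
#'   `pearson_r`, `pearson_p`, `undefined` (TRUE for a constant predictor,
#'   whose correlation cannot be estimated).
#' @export
binned_exceedance_correlation <- function(values, labels,
                                          n_bins = sturges_bins(length(values))) {
  n <- length(values)
  if (n != length(labels)) stop("values and labels lengths differ", call. = FALSE)
  if (n < n_bins) stop("need at least n_bins observations", call. = FALSE)
  labels <- as.integer(labels)
  ord <- order(values)          # stable: ties keep input order
  v <- values[ord]; l <- labels[ord]
  bin <- factor(equal_count_assignment(n, n_bins), levels = seq_len(n_bins))
  bins <- data.frame(
    bin = seq_len(n_bins),
    mean_value = as.numeric(tapply(v, bin, mean)),
    prop_exceed = as.numeric(tapply(l, bin, mean)),
    n = as.integer(tabulate(bin, n_bins))
  )
  if (length(unique(v)) < 2L) {
    out <- list(n_bins = n_bins, bins = bins, tau_b = NA_real_,
                p_value = NA_real_, significant = NA,
                pearson_r = NA_real_, pearson_p = NA_real_, undefined = TRUE)
    class(out) <- "binned_correlation"
    return(out)
  }
  kt <- suppressWarnings(
    stats::cor.test(bins$mean_value, bins$prop_exceed, method = "kendall"))
  pr <- suppressWarnings(
    stats::cor.test(bins$mean_value, bins$prop_exceed, method = "pearson"))
  out <- list(n_bins = n_bins, bins = bins,
              tau_b = unname(kt$estimate), p_value = kt$p.value,
              significant = kt$p.value < 0.05,
              pearson_r = unname(pr$estimate), pearson_p = pr$p.value,
              undefined = FALSE)
  class(out) <- "binned_correlation"
  out
}

#' @export
print.binned_correlation <- function(x, ...) {
  if (x$undefined) {
    cat("binned_correlation: undefined (constant predictor)\n")
  } else {
    cat(sprintf("binned_correlation: %d bins, tau_b = %.3f (p = %.3g%s)\n",
                x$n_bins, x$tau_b, x$p_value,
                if (isTRUE(x$significant)) ", significant at 95%" else ""))
  }
  invisible(x)
}

#' Binned correlations for every continuous predictor
#'
#' @param table modeling table with a `label` column.
#' @param n_bins bin count; default Sturges on the row count.
#' @return data.frame with one row per continuous predictor: tau_b,
#'   p_value, significant, pearson_r.
#' @export
correlation_table <- function(table, n_bins = sturges_bins(nrow(table))) {
  cols <- predictor_columns(table)
  cols <- cols[vapply(table[cols], is.numeric, logical(1L))]
  rows <- lapply(cols, function(nm) {
    bc <- binned_exceedance_correlation(table[[nm]], table$label, n_bins)
    data.frame(predictor = nm, tau_b = bc$tau_b, p_value = bc$p_value,
               significant = bc$significant, pearson_r = bc$pearson_r,
               undefined = bc$undefined)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Permutation variable importance (accuracy decrease)
#'
#' For each predictor in turn, its column is randomly shuffled and the drop
#' in classification accuracy (at the 0.5 cutoff) relative to the unshuffled
#' baseline is measured and averaged over `n_repeats` shuffles. The default
#' evaluates on the supplied (held-out) data; `method = "oob"` instead
#' returns the forest's own out-of-bag permutation importance recorded at
#' fit time.
#'
#' @param model a [fit_forest()] result.
#' @param data labelled modeling table matching the training schema
#'   (ignored for `method = "oob"`).
#' @param n_repeats shuffles per predictor (>= 1).
#' @param seed RNG seed for the shuffles.
#' @param method `"test"` (permute on `data`) or `"oob"`.
#' @return data.frame with `predictor` and `mean_decrease_accuracy`.
#' @export
permutation_importance <- function(model, data, n_repeats = 10L, seed = 1L,
                                   method = c("test", "oob")) {
  method <- match.arg(method)
  stopifnot(inherits(model, "fitted_forest"))
  if (method == "oob") {
    imp <- randomForest::importance(model$rf, type = 1, scale = FALSE)
    return(data.frame(predictor = rownames(imp),
                      mean_decrease_accuracy = unname(imp[, 1L])))
  }
  if (n_repeats < 1) stop("n_repeats must be >= 1", call. = FALSE)
  preds <- names(model$schema)
  ref <- as.integer(data$label)
  acc <- function(d) {
    p <- predict_prob(model, d)
    mean(as.integer(p > 0.5) == ref, na.rm = TRUE)
  }
  baseline <- acc(data)
  set.seed(seed)
  drops <- vapply(preds, function(nm) {
    mean(vapply(seq_len(n_repeats), function(r) {
      d <- data
      d[[nm]] <- sample(d[[nm]])
      baseline - acc(d)
    }, numeric(1L)))
  }, numeric(1L))
  data.frame(predictor = preds, mean_decrease_accuracy = unname(drops))
}

#' Combined importance table
#'
#' Joins the permutation accuracy importance with the forest's recorded mean
#' decrease in Gini node impurity.
#'
#' @inheritParams permutation_importance
#' @return data.frame with `predictor`, `mean_decrease_accuracy`,
#'   `mean_decrease_gini`.
#' @export
importance_table <- function(model, data, n_repeats = 10L, seed = 1L,
                             method = c("test", "oob")) {
  perm <- permutation_importance(model, data, n_repeats, seed, method)
  gini <- randomForest::importance(model$rf, type = 2)
  perm$mean_decrease_gini <- unname(gini[perm$predictor, 1L])
  perm
}

#' Normalize importance measures by their maxima
#'
#' Each importance column is divided by its own greatest value so the most
#' important predictor scores exactly 1; negative entries keep their sign.
#'
#' @param table data.frame with `predictor` plus one or more numeric
#'   importance columns.
#' @return the table with each importance column rescaled.
#' @export
normalize_importance <- function(table) {
  cols <- setdiff(names(table), "predictor")
  cols <- cols[vapply(table[cols], is.numeric, logical(1L))]
  if (!length(cols)) stop("no numeric importance columns", call. = FALSE)
  for (nm in cols) {
    mx <- max(table[[nm]])
    if (!is.finite(mx) || mx <= 0)
      stop(sprintf("cannot normalize '%s': no positive values", nm), call. = FALSE)
    table[[nm]] <- table[[nm]] / mx
  }
  table
}
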