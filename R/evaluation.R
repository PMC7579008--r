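#' Build a 2x2 confusion matrix
#'
#' @param pred predicted 0/1 labels.
#' @param ref reference (observed) 0/1 labels.
#' @return 2x2 integer matrix; rows are predictions, columns reference,
#'   in class order 0, 1.
#' @export
confusion_matrix <- function(pred, ref) {
  if (length(pred) != length(ref)) stop("pred and ref lengths differ", call. = FALSE)
  m <- table(factor(pred, levels = c(0L, 1L)),
             factor(ref, levels = c(0L, 1L)))
  m <- matrix(as.integer(m), 2L, 2L,
              dimnames = list(pred = c("0", "1"), ref = c("0", "1")))
  m
}

#' Cross-validation statistics from a confusion matrix
#'
#' Computes, from first principles, the full statistic set of a binary
#' classification cross-validation with exceedance (class 1) as the positive
#' class: accuracy, no-information rate (NIR, the larger reference-class
#' share), a one-sided exact binomial p-value for accuracy > NIR, Cohen's
#' kappa, sensitivity, specificity, positive/negative predictive value,
#' prevalence, and balanced accuracy. Any statistic with a zero denominator
#' is reported as `NA` and named in the `undefined` attribute rather than
#' silently propagating NaN.
#'
#' @param m a 2x2 matrix as from [confusion_matrix()]: `m[pred, ref]` with
#'   classes ordered 0, 1.
#' @param positive_class the class treated as positive (default 1,
#'   exceedance).
#' @return named list of class `confusion_stats`.
#' @export
confusion_stats <- function(m, positive_class = 1L) {
  m <- as.matrix(m)
  if (!all(dim(m) == c(2L, 2L)) || any(m < 0))
    stop("confusion_stats: need a 2x2 matrix of non-negative counts", call. = FALSE)
  n <- sum(m)
  if (n < 1) stop("confusion_stats: empty matrix", call. = FALSE)
  pos <- if (identical(as.integer(positive_class), 1L)) 2L else 1L
  neg <- 3L - pos

  safe_div <- function(num, den) if (den > 0) num / den else NA_real_

  ref_pos <- m[1L, pos] + m[2L, pos]
  ref_neg <- m[1L, neg] + m[2L, neg]
  pred_pos <- m[pos, 1L] + m[pos, 2L]
  pred_neg <- m[neg, 1L] + m[neg, 2L]
  correct <- m[1L, 1L] + m[2L, 2L]

  accuracy <- correct / n
  nir <- max(ref_pos, ref_neg) / n
  # one-sided exact binomial: P(X >= correct | n, NIR)
  p_value <- stats::pbinom(correct - 1L, n, nir, lower.tail = FALSE)
  pe <- (pred_pos * ref_pos + pred_neg * ref_neg) / n^2
  kappa <- if (pe < 1) (accuracy - pe) / (1 - pe) else NA_real_

  sensitivity <- safe_div(m[pos, pos], ref_pos)
  specificity <- safe_div(m[neg, neg], ref_neg)
  ppv <- safe_div(m[pos, pos], pred_pos)
  npv <- safe_div(m[neg, neg], pred_neg)
  prevalence <- ref_pos / n
  balanced_accuracy <- mean(c(sensitivity, specificity))

  out <- list(accuracy = accuracy, no_information_rate = nir,
              p_value_acc_gt_nir = p_value, kappa = kappa,
              sensitivity = sensitivity, specificity = specificity,
              ppv = ppv, npv = npv, prevalence = prevalence,
              balanced_accuracy = balanced_accuracy,
              n = n, matrix = m)
  undef <- names(out)[vapply(out[1:10], function(v) is.na(v), logical(1L))]
  attr(out, "undefined") <- undef
  class(out) <- "confusion_stats"
  out
}

#' @export
print.confusion_stats <- function(x, ...) {
  cat("Confusion matrix (rows: prediction, cols: reference)\n")
  print(x$matrix)
  labels <- c(accuracy = "Accuracy (Acc)",
              no_information_rate = "No information rate (NIR)",
              p_value_acc_gt_nir = "p value (Acc > NIR)",
              kappa = "Cohen's kappa",
              sensitivity = "Sensitivity",
              specificity = "Specificity",
              ppv = "Positive predictive value",
              npv = "Negative predictive value",
              prevalence = "Prevalence",
              balanced_accuracy = "Balanced accuracy")
  for (nm in names(labels)) {
    v <- x[[nm]]
    txt <- if (is.na(v)) "undefined"
    else if (nm == "p_value_acc_gt_nir" && v < 2.2e-16) "<2.2e-16"
    else sprintf("%.4f", v)
    cat(sprintf("%-28s %s\n", labels[[nm]], txt))
  }
  invisible(x)
}

#' Area under the ROC curve
#'
#' Pairwise-concordance definition: the probability that a randomly chosen
#' positive scores above a randomly chosen negative, with ties counting
#' one half — computed via the rank (Mann-Whitney) identity, equivalent to
#' trapezoidal integration of the ROC curve.
#'
#' @param probabilities numeric scores.
#' @param labels 0/1 labels, both classes present.
#' @return AUC in [0, 1].
#' @export
roc_auc <- function(probabilities, labels) {
  if (length(probabilities) != length(labels))
    stop("probabilities and labels lengths differ", call. = FALSE)
  labels <- as.integer(labels)
  n1 <- sum(labels == 1L); n0 <- sum(labels == 0L)
  if (n1 == 0L || n0 == 0L)
    stop("roc_auc: both classes must be present", call. = FALSE)
  r <- rank(probabilities)  # mid-ranks give ties weight 1/2
  (sum(r[labels == 1L]) - n1 * (n1 + 1) / 2) / (n0 * n1)
}

#' Probability cutoff from curve intersection
#'
#' Evaluates sensitivity/specificity (or PPV/NPV) over a grid of candidate
#' probability cutoffs spanning [0, 1] and returns the grid cutoff at which
#' the two curves are closest — the operating point at which the model
#' classifies low and high values equally well. Ties go to the lowest
#' cutoff. Predictions at a cutoff are `probability > cutoff`. The two
#' endpoint cutoffs (0 and 1) force degenerate all-one-class predictions
#' for generic scores, so they are excluded from the intersection search;
#' the full curves are still returned over the whole grid.
#'
#' @param probabilities predicted exceedance probabilities.
#' @param labels observed 0/1 labels.
#' @param criterion `"sens_spec"` or `"ppv_npv"`.
#' @param grid_size number of evenly spaced cutoffs, endpoints included
#'   (default 100).
#' @return list of class `cutoff_result`: `cutoff`, `criterion`,
#'   `accuracy_at_cutoff`, and `curves` (data.frame over the full grid with
#'   sensitivity, specificity, ppv, npv, accuracy).
#' @export
find_cutoff <- function(probabilities, labels,
                        criterion = c("sens_spec", "ppv_npv"),
                        grid_size = 100L) {
  criterion <- match.arg(criterion)
  if (grid_size < 2L) stop("grid_size must be >= 2", call. = FALSE)
  labels <- as.integer(labels)
  if (length(unique(labels)) < 2L)
    stop("find_cutoff: both classes must be present", call. = FALSE)
  grid <- seq(0, 1, length.out = grid_size)
  n <- length(labels)
  np <- sum(labels == 1L); nn <- n - np
  curves <- do.call(rbind, lapply(grid, function(ct) {
    pred <- as.integer(probabilities > ct)
    tp <- sum(pred == 1L & labels == 1L)
    tn <- sum(pred == 0L & labels == 0L)
    predp <- sum(pred == 1L)
    data.frame(cutoff = ct,
               sensitivity = tp / np,
               specificity = tn / nn,
               ppv = if (predp > 0) tp / predp else NA_real_,
               npv = if (predp < n) tn / (n - predp) else NA_real_,
               accuracy = (tp + tn) / n)
  }))
  d <- if (criterion == "sens_spec") abs(curves$sensitivity - curves$specificity)
  else abs(curves$ppv - curves$npv)
  d[c(1L, grid_size)] <- NA_real_  # endpoint cutoffs are degenerate
  if (all(is.na(d)))
    stop("find_cutoff: criterion curves undefined over the whole grid", call. = FALSE)
  i <- which.min(d)  # first minimum = lowest cutoff on ties
  structure(list(cutoff = grid[i], criterion = criterion,
                 accuracy_at_cutoff = curves$accuracy[i],
                 curves = curves),
            class = "cutoff_result")
}

#' @export
print.cutoff_result <- function(x, ...) {
  cat(sprintf("cutoff_result (%s): cutoff %.4f, accuracy at cutoff %.4f\n",
              x$criterion, x$cutoff, x$accuracy_at_cutoff))
  invisible(x)
}

#' Evaluate a fitted forest on labelled data
#'
#' Predicts exceedance probabilities, thresholds them at `cutoff`, and
#' returns the full confusion-statistic set plus the AUC.
#'
#' @param model a [fit_forest()] result.
#' @param table labelled modeling table.
#' @param cutoff classification cutoff on the probability (default 0.5).
#' @return list with `stats` ([confusion_stats()]), `auc`, and
#'   `probabilities`.
#' @export
evaluate_model <- function(model, table, cutoff = 0.5) {
  p <- predict_prob(model, table)
  ok <- !is.na(p)
  pred <- as.integer(p[ok] > cutoff)
  ref <- as.integer(table$label[ok])
  list(stats = confusion_stats(confusion_matrix(pred, ref)),
       auc = roc_auc(p[ok], ref),
       probabilities = p)
}
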