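#' Bar chart of normalized variable importance
#'
#' One horizontal bar per predictor and importance measure, after
#' max-normalization, predictors ordered by permutation accuracy importance.
#'
#' @param importance table from [importance_table()] (normalized or not;
#'   normalized with [normalize_importance()] first if `normalize`).
#' @param normalize normalize before plotting (default TRUE).
#' @return a ggplot object.
#' @export
plot_importance <- function(importance, normalize = TRUE) {
  if (normalize) importance <- normalize_importance(importance)
  long <- rbind(
    data.frame(predictor = importance$predictor, measure = "Mean decrease accuracy",
               value = importance$mean_decrease_accuracy),
    data.frame(predictor = importance$predictor, measure = "Mean decrease Gini",
               value = importance$mean_decrease_gini)
  )
  ord <- importance$predictor[order(importance$mean_decrease_accuracy)]
  long$predictor <- factor(long$predictor, levels = ord)
  ggplot2::ggplot(long, ggplot2::aes(x = .data$value, y = .data$predictor,
                                     fill = .data$measure)) +
    ggplot2::geom_col(position = "dodge") +
    ggplot2::labs(x = "Importance (normalized to max = 1)", y = NULL,
                  fill = NULL) +
    ggplot2::theme_minimal()
}

#' Panel of binned predictor-exceedance relationships
#'
#' One facet per continuous predictor: binned mean predictor value against
#' the proportion of exceedances in the bin, annotated with Kendall tau-b
#' (bold when significant at 95%).
#'
#' @param table modeling table.
#' @param predictors predictor names (default: all continuous).
#' @param n_bins bin count (default Sturges).
#' @return a ggplot object.
#' @export
plot_binned_correlation <- function(table, predictors = NULL,
                                    n_bins = sturges_bins(nrow(table))) {
  cols <- predictor_columns(table)
  cols <- cols[vapply(table[cols], is.numeric, logical(1L))]
  if (!is.null(predictors)) cols <- intersect(cols, predictors)
  panels <- do.call(rbind, lapply(cols, function(nm) {
    bc <- binned_exceedance_correlation(table[[nm]], table$label, n_bins)
    lab <- if (bc$undefined) sprintf("%s (undefined)", nm)
    else sprintf("%s\ntau_b = %.2f%s", nm, bc$tau_b,
                 if (isTRUE(bc$significant)) " *" else "")
    cbind(bc$bins, predictor = lab)
  }))
  ggplot2::ggplot(panels, ggplot2::aes(x = .data$mean_value,
                                       y = .data$prop_exceed)) +
    ggplot2::geom_point() + ggplot2::geom_line(alpha = 0.5) +
    ggplot2::facet_wrap(~predictor, scales = "free_x") +
    ggplot2::labs(x = "Binned mean predictor value",
                  y = "Proportion exceeding threshold") +
    ggplot2::theme_minimal()
}

#' Cutoff-determination curves
#'
#' Sensitivity/specificity (or PPV/NPV) over the probability grid with the
#' selected intersection cutoff marked.
#'
#' @param cutoff_result a [find_cutoff()] result.
#' @return a ggplot object.
#' @export
plot_cutoff_curves <- function(cutoff_result) {
  cv <- cutoff_result$curves
  pair <- if (cutoff_result$criterion == "sens_spec")
    c("sensitivity", "specificity") else c("ppv", "npv")
  long <- rbind(
    data.frame(cutoff = cv$cutoff, curve = pair[1L], value = cv[[pair[1L]]]),
    data.frame(cutoff = cv$cutoff, curve = pair[2L], value = cv[[pair[2L]]])
  )
  ggplot2::ggplot(long, ggplot2::aes(x = .data$cutoff, y = .data$value,
                                     colour = .data$curve)) +
    ggplot2::geom_line() +
    ggplot2::geom_vline(xintercept = cutoff_result$cutoff, linetype = 2) +
    ggplot2::annotate("text", x = cutoff_result$cutoff, y = 0.05,
                      label = sprintf(" cutoff = %.2f", cutoff_result$cutoff),
                      hjust = 0) +
    ggplot2::labs(x = "Probability cutoff", y = "Value", colour = NULL) +
    ggplot2::theme_minimal()
}
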