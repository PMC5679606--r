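#' @importFrom ggplot2 autoplot ggplot aes geom_line geom_abline geom_tile
#'   geom_col labs scale_fill_viridis_c position_dodge theme_minimal
NULL

#' Plot an ROC or precision–recall curve
#'
#' @param object An `eval_curve` from [roc_curve()] or [pr_curve()].
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.eval_curve <- function(object, ...) {
  kind <- attr(object, "kind")
  if (identical(kind, "roc")) {
    ggplot(as_tibble(object), aes(x = .data$fpr, y = .data$tpr)) +
      geom_abline(slope = 1, intercept = 0, linetype = "dashed",
                  colour = "grey60") +
      geom_line() +
      labs(x = "False positive rate", y = "True positive rate",
           title = sprintf("ROC (AUC = %.3f)", attr(object, "auc"))) +
      theme_minimal()
  } else {
    ggplot(as_tibble(object), aes(x = .data$recall, y = .data$precision)) +
      geom_line() +
      labs(x = "Recall", y = "Precision", title = "Precision–recall") +
      theme_minimal()
  }
}

#' Heatmap of AUC over the beta/omega grid
#'
#' @param object A `sweep_result` from [parameter_sweep()].
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.sweep_result <- function(object, ...) {
  ggplot(as_tibble(object), aes(x = .data$beta, y = .data$omega,
                                fill = .data$auc)) +
    geom_tile() +
    scale_fill_viridis_c(name = "AUC") +
    labs(x = expression(beta), y = expression(omega),
         title = "AUC across the mixing-parameter grid") +
    theme_minimal()
}

#' Bar chart of essential hits in top-percent slices
#'
#' @param hits Tibble from [top_percent_hits()].
#' @param unique_only Plot the unique-hit counts instead of total hits.
#' @return A ggplot object.
#' @export
plot_top_percent <- function(hits, unique_only = FALSE) {
  ycol <- if (unique_only) "unique_hits" else "hits"
  ggplot(hits, aes(x = factor(.data$percent), y = .data[[ycol]],
                   fill = .data$method)) +
    geom_col(position = position_dodge()) +
    labs(x = "Top percent of ranking", fill = "Method",
         y = if (unique_only) "Unique essential proteins" else
           "Essential proteins") +
    theme_minimal()
}

#' @importFrom generics tidy glance
#' @export
generics::tidy

#' @export
generics::glance
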