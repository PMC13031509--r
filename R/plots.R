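#' Plot methods
#'
#' `autoplot()` methods give quick ggplot2 views of each result type:
#' attribution importances, the ensemble average-rank table, a selection
#' trace's score path, and the per-fold metric spread of an evaluation
#' report.
#'
#' @param object The result object.
#' @param ... Unused.
#' @return A ggplot object.
#' @name shapsel-autoplot
NULL

#' @rdname shapsel-autoplot
#' @method autoplot attribution_matrix
#' @export
autoplot.attribution_matrix <- function(object, ...) {
  imp <- global_importance(object)
  imp$feature <- factor(imp$feature,
                        levels = imp$feature[order(imp$importance)])
  ggplot2::ggplot(imp, ggplot2::aes(x = .data$importance,
                                    y = .data$feature)) +
    ggplot2::geom_col(fill = "#3070b0") +
    ggplot2::labs(x = "mean |Shapley value|", y = NULL,
                  title = "Global feature importance") +
    ggplot2::theme_minimal()
}

#' @rdname shapsel-autoplot
#' @method autoplot shapsel_art
#' @export
autoplot.shapsel_art <- function(object, ...) {
  df <- as_tibble(object)
  df$feature <- factor(df$feature, levels = rev(df$feature))
  ggplot2::ggplot(df, ggplot2::aes(x = .data$avg, y = .data$feature)) +
    ggplot2::geom_col(fill = "#b03030") +
    ggplot2::labs(x = "ensemble average rank (lower = more important)",
                  y = NULL, title = "Average rank table") +
    ggplot2::theme_minimal()
}

#' @rdname shapsel-autoplot
#' @method autoplot selection_trace
#' @export
autoplot.selection_trace <- function(object, ...) {
  df <- object$steps
  df$step <- seq_len(nrow(df))
  ggplot2::ggplot(df, ggplot2::aes(x = .data$step, y = .data$cv_score_with,
                                   colour = .data$action)) +
    ggplot2::geom_point(size = 2) +
    ggplot2::geom_line(ggplot2::aes(group = 1), colour = "grey60",
                       linewidth = 0.3) +
    ggplot2::scale_x_continuous(breaks = df$step, labels = df$feature) +
    ggplot2::labs(x = NULL, y = "CV accuracy of candidate subset",
                  title = "Forward-selection trace") +
    ggplot2::theme_minimal() +
    ggplot2::theme(axis.text.x = ggplot2::element_text(angle = 45,
                                                       hjust = 1))
}

#' @rdname shapsel-autoplot
#' @method autoplot eval_report
#' @export
autoplot.eval_report <- function(object, ...) {
  long <- tidyr::pivot_longer(object$per_fold, -"fold",
                              names_to = "metric", values_to = "value")
  ggplot2::ggplot(long, ggplot2::aes(x = .data$metric, y = .data$value)) +
    ggplot2::geom_boxplot(outlier.shape = NA, fill = "grey90") +
    ggplot2::geom_jitter(width = 0.1, alpha = 0.6, size = 1) +
    ggplot2::labs(x = NULL, y = "per-fold value",
                  title = "Cross-validated performance") +
    ggplot2::theme_minimal()
}
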