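#' Plot the best-fitness trajectory of a DE run
#'
#' @param object A `de_result`.
#' @param ... Unused.
#' @return A ggplot of best (and mean) fitness against generation.
#' @export
autoplot.de_result <- function(object, ...) {
  df <- tidyr::pivot_longer(object$history,
                            c("best_fitness", "mean_fitness"),
                            names_to = "series", values_to = "fitness")
  ggplot2::ggplot(df, ggplot2::aes(x = .data$generation, y = .data$fitness,
                                   colour = .data$series)) +
    ggplot2::geom_line() +
    ggplot2::labs(x = "Generation", y = "Fitness", colour = NULL,
                  title = "Differential-evolution fitness trajectory") +
    ggplot2::theme_minimal()
}

#' Plot per-feature selection frequency
#'
#' Bar plot of the probability of each feature being selected across the
#' search, optionally highlighting a set of reference (e.g. planted) indices.
#'
#' @param x A `de_result`, a list of them, or a [selection_frequency()]
#'   tibble.
#' @param highlight Optional integer feature indices to colour.
#' @return A ggplot.
#' @export
plot_selection_frequency <- function(x, highlight = integer(0)) {
  freq <- if (is.data.frame(x)) x else selection_frequency(x)
  freq$highlight <- freq$index %in% highlight
  p <- ggplot2::ggplot(freq, ggplot2::aes(x = .data$index, y = .data$frequency))
  p <- if (length(highlight)) {
    p + ggplot2::geom_col(ggplot2::aes(fill = .data$highlight)) +
      ggplot2::scale_fill_manual(values = c(`FALSE` = "grey60", `TRUE` = "firebrick"),
                                 labels = c("other", "highlighted"), name = NULL)
  } else {
    p + ggplot2::geom_col(fill = "grey40")
  }
  p + ggplot2::labs(x = "Feature index", y = "Selection frequency",
                    title = "Feature selection frequency") +
    ggplot2::theme_minimal()
}

#' Plot the confusion matrix of an evaluation report
#'
#' @param object An `evaluation_report`.
#' @param ... Unused.
#' @return A ggplot tile map of the confusion counts.
#' @export
autoplot.evaluation_report <- function(object, ...) {
  df <- as.data.frame(as.table(object$confusion))
  names(df) <- c("truth", "predicted", "count")
  ggplot2::ggplot(df, ggplot2::aes(x = .data$predicted, y = .data$truth,
                                   fill = .data$count)) +
    ggplot2::geom_tile() +
    ggplot2::geom_text(ggplot2::aes(label = .data$count), colour = "white") +
    ggplot2::scale_y_discrete(limits = rev) +
    ggplot2::labs(title = sprintf("Confusion matrix (%s)", object$classifier),
                  x = "Predicted", y = "True") +
    ggplot2::theme_minimal()
}
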