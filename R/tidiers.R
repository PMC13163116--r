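#' Tidy a DE feature-selection result
#'
#' One row per feature: whether the best mask selects it and how often it
#' was selected across the run's population history.
#'
#' @param x A `de_result`.
#' @param ... Unused.
#' @return A tibble with `feature`, `index`, `selected`, `frequency`.
#' @export
tidy.de_result <- function(x, ...) {
  freq <- selection_frequency(x)
  freq$selected <- x$best_mask == 1L
  freq[c("feature", "index", "selected", "frequency")]
}

#' One-row summary of a DE feature-selection result
#'
#' @param x A `de_result`.
#' @param ... Unused.
#' @return A tibble with `best_fitness`, `k`, `d`, `reduction_percentage`,
#'   `generations` and `n_evals`.
#' @export
glance.de_result <- function(x, ...) {
  tibble(
    best_fitness = x$best_fitness, k = x$best_k, d = x$d,
    reduction_percentage = reduction_percentage(x$d, x$best_k),
    generations = max(x$history$generation), n_evals = x$n_evals
  )
}

#' Per-class metrics of an evaluation report
#'
#' @param x An `evaluation_report`.
#' @param ... Unused.
#' @return The per-class tibble (precision, sensitivity, F1, specificity,
#'   support).
#' @export
tidy.evaluation_report <- function(x, ...) x$per_class

#' One-row overall metrics of an evaluation report
#'
#' @param x An `evaluation_report`.
#' @param ... Unused.
#' @return The overall one-row tibble.
#' @export
glance.evaluation_report <- function(x, ...) {
  dplyr::bind_cols(tibble(classifier = x$classifier), x$overall)
}
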