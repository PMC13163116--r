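#' End-to-end selection and classification pipeline
#'
#' Chains stratified splitting, binary-DE feature selection, classification
#' on both the full and the selected feature space, and the before/after
#' comparison table.
#'
#' By default the selector only ever sees the training + validation portion
#' (leakage-safe: the test partition plays no part in choosing features).
#' `paper_faithful = TRUE` instead runs the selector on the complete dataset
#' before splitting — the ordering used when a selected subset is evaluated
#' with a post-hoc split — which leaks test information into the selection
#' and is kept only for faithful reproduction of that protocol.
#'
#' @param data Labelled feature tibble.
#' @param de A [de_config()].
#' @param split A [split_spec()].
#' @param classifiers Named list of [classifier_spec()]s.
#' @param paper_faithful Run DE on all rows (including test) before the
#'   split instead of on train + validation only.
#' @param seed Optional seed for classifier training.
#' @return A `bdefs_pipeline` list: `split`, `de` (the `de_result`),
#'   `reports_full`, `reports_reduced`, `comparison`.
#' @export
run_pipeline <- function(data, de = de_config(), split = split_spec(),
                         classifiers = default_classifiers(),
                         paper_faithful = FALSE, seed = NULL) {
  parts <- stratified_split(data, split)
  de_input <- if (paper_faithful) data else
    dplyr::bind_rows(parts$train, parts$validation)
  de_res <- run_de(de_input, de)
  train_red <- apply_mask(parts$train, de_res)
  test_red <- apply_mask(parts$test, de_res)
  reports_full <- evaluate_classifiers(parts$train, parts$test, classifiers,
                                       seed = seed)
  reports_reduced <- evaluate_classifiers(train_red, test_red, classifiers,
                                          seed = seed)
  structure(list(
    split = parts, de = de_res,
    reports_full = reports_full, reports_reduced = reports_reduced,
    comparison = compare_reports(reports_full, reports_reduced),
    paper_faithful = paper_faithful
  ), class = "bdefs_pipeline")
}

#' @export
print.bdefs_pipeline <- function(x, ...) {
  cat(sprintf("<bdefs_pipeline> %d -> %d features (%.2f%% reduction)\n",
              x$de$d, x$de$best_k, reduction_percentage(x$de$d, x$de$best_k)))
  print(as.data.frame(x$comparison[c("classifier", "accuracy_before",
                                     "accuracy_after", "accuracy_difference",
                                     "speed_up_label")]),
        row.names = FALSE, digits = 4)
  invisible(x)
}

#' Serialize a DE result (mask, trajectory, config echo) as JSON
#'
#' @param result A `de_result`.
#' @param path Destination JSON path.
#' @return `path`, invisibly.
#' @export
write_mask_json <- function(result, path) {
  payload <- list(
    bits = result$best_mask,
    k = result$best_k,
    d = result$d,
    best_fitness = result$best_fitness,
    reduction_percentage = reduction_percentage(result$d, result$best_k),
    history = result$history,
    n_evals = result$n_evals,
    config = list(
      pop_size = result$config$pop_size, max_iter = result$config$max_iter,
      mutation_factor = result$config$mutation_factor,
      crossover_rate = result$config$crossover_rate,
      alpha = result$config$alpha, fitness_form = result$config$fitness_form,
      seed = result$config$seed
    )
  )
  jsonlite::write_json(payload, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}
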