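#' Evaluate a fitted classifier on a test set
#'
#' Produces the full multiclass report: accuracy from the confusion matrix,
#' per-class one-vs-rest precision/sensitivity/F1/specificity, macro
#' (unweighted mean) aggregate precision/recall/F1, macro one-vs-rest AUC
#' from class probabilities, balanced accuracy (macro sensitivity), Cohen's
#' kappa, the Wald 95% half-width `1.96 * sqrt(acc * (1 - acc) / n)`, and
#' wall-clock prediction time (informational only — hardware-dependent).
#'
#' The aggregate F1 is the macro mean of the per-class F1 values (not the
#' harmonic mean of macro precision and macro recall).
#'
#' @param model A `bdefs_model` from [fit_classifier()].
#' @param test Labelled feature tibble.
#' @return An `evaluation_report` with `overall` (one-row tibble),
#'   `per_class` tibble, the `confusion` matrix, `n_test` and a spec echo.
#'   Methods: [tidy()], [glance()], [autoplot()].
#' @export
evaluate_classifier <- function(model, test) {
  parts <- check_feature_data(test, "test")
  if (parts$n == 0L) abort("`test` must be non-empty.")
  t0 <- proc.time()[["elapsed"]]
  prob <- tryCatch(predict(model, test, type = "prob"), error = function(e) NULL)
  pred <- if (is.null(prob)) {
    predict(model, test, type = "class")
  } else {
    colnames(prob)[max.col(prob, ties.method = "first")]
  }
  pred_time <- proc.time()[["elapsed"]] - t0
  cm <- confusion_matrix(as.character(parts$y), pred, levels = model$classes)
  pc <- per_class_metrics(cm)
  n <- sum(cm)
  acc <- sum(diag(cm)) / n
  overall <- tibble(
    accuracy = acc,
    precision = mean(pc$precision),
    recall = mean(pc$sensitivity),
    f1 = mean(pc$f1),
    misclassification_rate = 1 - acc,
    auc = macro_auc(parts$y, prob),
    ci_halfwidth = 1.96 * sqrt(acc * (1 - acc) / n),
    balanced_accuracy = mean(pc$sensitivity),
    cohens_kappa = cohens_kappa(cm),
    prediction_time_s = pred_time,
    n_test = n
  )
  structure(list(overall = overall, per_class = pc, confusion = cm,
                 n_test = n, classifier = model$spec$family,
                 spec = model$spec),
            class = "evaluation_report")
}

#' @export
print.evaluation_report <- function(x, ...) {
  cat(sprintf("<evaluation_report> %s on %d test samples\n",
              x$classifier, x$n_test))
  print(as.data.frame(x$overall), row.names = FALSE, digits = 4)
  invisible(x)
}

#' Evaluate several classifier families on one split
#'
#' Fits each spec on `train` and evaluates on `test`, returning one report
#' per family.
#'
#' @param train,test Labelled feature tibbles.
#' @param specs A named list of [classifier_spec()]s (default all eight).
#' @param seed Optional training seed shared by every family.
#' @return A named list of `evaluation_report`s.
#' @export
evaluate_classifiers <- function(train, test, specs = default_classifiers(),
                                 seed = NULL) {
  reports <- purrr::imap(specs, function(sp, nm) {
    evaluate_classifier(fit_classifier(train, sp, seed = seed), test)
  })
  reports
}

#' Before/after comparison of classifier reports
#'
#' Pairs two report sets by classifier family (e.g. trained on the full
#' feature space versus on the selected subset) and tabulates the accuracy
#' difference (`after - before`) and the prediction-time speed-up
#' `before / after`, rendered as "N.NNx".
#'
#' @param before,after Named lists of `evaluation_report`s over the same
#'   families.
#' @return A tibble with one row per family: accuracies, their difference,
#'   prediction times, the numeric `speed_up` and its `speed_up_label`.
#' @export
compare_reports <- function(before, after) {
  fams <- names(before)
  if (!setequal(fams, names(after))) {
    abort("`before` and `after` must cover the same classifier families.")
  }
  purrr::map_dfr(fams, function(fm) {
    b <- before[[fm]]$overall
    a <- after[[fm]]$overall
    su <- b$prediction_time_s / a$prediction_time_s
    tibble(
      classifier = fm,
      accuracy_before = b$accuracy,
      accuracy_after = a$accuracy,
      accuracy_difference = a$accuracy - b$accuracy,
      time_before_s = b$prediction_time_s,
      time_after_s = a$prediction_time_s,
      speed_up = su,
      speed_up_label = sprintf("%.2fx", su)
    )
  })
}

#' Serialize a report (or comparison) to delimited text
#'
#' Writes the overall metrics of a set of reports as one CSV row per
#' classifier, mirroring the standard report column layout
#' (accuracy, precision, recall, F1, misclassification rate, AUC, CI
#' half-width, balanced accuracy, Cohen's kappa).
#'
#' @param reports A named list of `evaluation_report`s or a comparison
#'   tibble from [compare_reports()].
#' @param path Destination CSV path.
#' @return `path`, invisibly.
#' @export
write_report_table <- function(reports, path) {
  tab <- if (is.data.frame(reports)) {
    reports
  } else {
    purrr::map_dfr(reports, ~ .x$overall, .id = "classifier")
  }
  readr::write_csv(tab, path, progress = FALSE)
  invisible(path)
}
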