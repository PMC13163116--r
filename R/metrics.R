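#' Multiclass confusion matrix
#'
#' Entry `(i, j)` counts samples of true class `i` predicted as class `j`;
#' rows therefore sum to the per-class truth counts.
#'
#' @param truth,predicted Equal-length label vectors.
#' @param levels Optional class set; defaults to the union of observed
#'   labels. Predicted labels outside the set are an error.
#' @return A `K x K` integer matrix with class dimnames (truth x predicted).
#' @export
confusion_matrix <- function(truth, predicted, levels = NULL) {
  if (length(truth) != length(predicted)) {
    abort("`truth` and `predicted` must have equal length.")
  }
  truth <- as.character(truth)
  predicted <- as.character(predicted)
  levels <- levels %||% sort(unique(c(truth, predicted)))
  bad <- setdiff(unique(c(truth, predicted)), levels)
  if (length(bad)) {
    abort(sprintf("Label(s) outside the declared class set: %s.",
                  paste(bad, collapse = ", ")))
  }
  tab <- table(factor(truth, levels = levels), factor(predicted, levels = levels))
  m <- matrix(as.integer(tab), nrow = length(levels),
              dimnames = list(truth = levels, predicted = levels))
  m
}

#' Per-class one-vs-rest metrics from a confusion matrix
#'
#' Computes precision `TP/(TP+FP)`, sensitivity (recall) `TP/(TP+FN)`, their
#' harmonic-mean F1, and specificity `TN/(TN+FP)` for each class, treating
#' that class as positive and all others as negative. Undefined 0/0 ratios
#' are reported as 0.
#'
#' @param cm A confusion matrix from [confusion_matrix()].
#' @return A tibble with `class`, `precision`, `sensitivity`, `f1`,
#'   `specificity` and `support`.
#' @export
per_class_metrics <- function(cm) {
  n <- sum(cm)
  tp <- diag(cm)
  fp <- colSums(cm) - tp
  fn <- rowSums(cm) - tp
  tn <- n - tp - fp - fn
  safe_div <- function(a, b) ifelse(b == 0, 0, a / b)
  precision <- safe_div(tp, tp + fp)
  sensitivity <- safe_div(tp, tp + fn)
  f1 <- ifelse(precision + sensitivity == 0, 0,
               2 * precision * sensitivity / (precision + sensitivity))
  tibble(
    class = rownames(cm),
    precision = unname(precision),
    sensitivity = unname(sensitivity),
    f1 = unname(f1),
    specificity = unname(safe_div(tn, tn + fp)),
    support = unname(rowSums(cm))
  )
}

#' F1 score from a precision/sensitivity pair
#'
#' The harmonic mean `2 * precision * sensitivity / (precision +
#' sensitivity)`, rounded to the 4-decimal report precision. When both
#' inputs are 0 the score is defined as 0 with a warning.
#'
#' @param precision,sensitivity Values in `[0, 1]`.
#' @param digits Rounding digits (default 4, the table precision).
#' @return The rounded F1 score.
#' @examples
#' f1_from_pr(0.9810, 0.9830)  # 0.9820
#' @export
f1_from_pr <- function(precision, sensitivity, digits = 4) {
  assert_prob(precision, "precision")
  assert_prob(sensitivity, "sensitivity")
  if (precision + sensitivity == 0) {
    warn("Both precision and sensitivity are 0; F1 defined as 0.")
    return(0)
  }
  round(2 * precision * sensitivity / (precision + sensitivity), digits)
}

#' Cohen's kappa from a confusion matrix
#'
#' Chance-corrected agreement `(p_o - p_e) / (1 - p_e)` where `p_o` is the
#' observed accuracy and `p_e` the expected agreement from the confusion
#' marginals.
#'
#' @param cm A confusion matrix.
#' @return Kappa (1 for perfect diagonal agreement, about 0 at chance).
#' @export
cohens_kappa <- function(cm) {
  n <- sum(cm)
  po <- sum(diag(cm)) / n
  pe <- sum(rowSums(cm) * colSums(cm)) / n^2
  if (pe == 1) return(1)
  (po - pe) / (1 - pe)
}

# Macro one-vs-rest AUC from a class-probability matrix; NA when scores are
# unavailable or a class is absent from the truth.
macro_auc <- function(truth, prob) {
  if (is.null(prob)) return(NA_real_)
  truth <- as.character(truth)
  aucs <- vapply(colnames(prob), function(cls) {
    resp <- truth == cls
    if (!any(resp) || all(resp)) return(NA_real_)
    as.numeric(pROC::auc(pROC::roc(resp, prob[, cls], quiet = TRUE,
                                   direction = "<", levels = c(FALSE, TRUE))))
  }, numeric(1))
  mean(aucs, na.rm = TRUE)
}
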