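# Inner fitness evaluators: functions (X, y, idx) -> misclassification
# proportion in [0, 1], where idx is the set of selected column indices.

# Nearest-centroid classifier (a linear decision rule): class means in
# feature space, prediction by smallest Euclidean distance.
nc_fit <- function(X, y) {
  G <- rowsum(X, y)
  counts <- as.vector(table(y)[rownames(G)])
  list(centroids = G / counts, classes = rownames(G))
}

nc_predict <- function(fit, X) {
  C <- fit$centroids
  d2 <- -2 * X %*% t(C)
  d2 <- sweep(d2, 2L, rowSums(C^2), "+")   # ||x||^2 is constant per row
  fit$classes[max.col(-d2, ties.method = "first")]
}

#' Holdout fitness evaluator for wrapper feature selection
#'
#' Returns an evaluator closure `function(X, y, idx) -> error` that restricts
#' `X` to the selected columns `idx`, makes a stratified train/holdout split
#' at a fixed internal seed (so the error is a deterministic function of the
#' selected subset), fits a fast nearest-centroid linear classifier on the
#' training part, and returns the holdout misclassification proportion.
#'
#' @param fraction Holdout fraction (default 0.2, i.e. an 80/20 split).
#' @param seed Internal split seed; fixed so repeated evaluations of the same
#'   mask agree exactly.
#' @return A function `(X, y, idx) -> error in [0, 1]`.
#' @export
holdout_evaluator <- function(fraction = 0.2, seed = 1L) {
  fraction <- assert_prob(fraction, "fraction", lo_open = TRUE, hi_open = TRUE)
  seed <- as.integer(seed)
  function(X, y, idx) {
    y <- factor(y)
    hold <- withr::with_seed(seed, {
      unlist(lapply(split(seq_along(y), y), function(ii) {
        n_h <- max(1L, min(length(ii) - 1L, round(fraction * length(ii))))
        sample(ii, n_h)
      }), use.names = FALSE)
    })
    Xs <- X[, idx, drop = FALSE]
    fit <- nc_fit(Xs[-hold, , drop = FALSE], y[-hold])
    mean(nc_predict(fit, Xs[hold, , drop = FALSE]) != as.character(y[hold]))
  }
}

#' Deterministic toy evaluator backed by an error table
#'
#' Builds an evaluator that looks up the error of a mask in a named vector
#' keyed by the mask's bit string (e.g. `"101"`), ignoring the data. Useful
#' for exercising the optimizer against a fully known fitness landscape.
#'
#' @param table Named numeric vector; names are bit strings over the full
#'   dimension, values are errors in `[0, 1]`.
#' @param d Feature dimension the bit strings refer to.
#' @return A function `(X, y, idx) -> error`.
#' @export
table_evaluator <- function(table, d) {
  function(X, y, idx) {
    bits <- integer(d)
    bits[idx] <- 1L
    key <- mask_key(bits)
    if (!key %in% names(table)) {
      abort(sprintf("Mask '%s' is missing from the error table.", key))
    }
    unname(table[[key]])
  }
}
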