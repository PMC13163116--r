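#' Specification of a stratified train/validation/test split
#'
#' Defaults to the 65/15/20 split at seed 42. Fractions must be in `(0, 1)`
#' and sum to 1.
#'
#' @param train,validation,test Fractions of each partition.
#' @param seed Integer seed (default 42).
#' @param stratified Draw the split per class (the only supported mode;
#'   `FALSE` splits over the pooled indices).
#' @return A `split_spec` list.
#' @export
split_spec <- function(train = 0.65, validation = 0.15, test = 0.20,
                       seed = 42L, stratified = TRUE) {
  for (nm in c("train", "validation", "test")) {
    assert_prob(get(nm), nm, lo_open = TRUE, hi_open = TRUE)
  }
  if (abs(train + validation + test - 1) > 1e-9) {
    abort("Split fractions must sum to 1.")
  }
  structure(list(train = train, validation = validation, test = test,
                 seed = as.integer(seed), stratified = isTRUE(stratified)),
            class = "split_spec")
}

# Allocate n items to the three parts, hitting the fractions within +/- 1 by
# rounding train and validation and giving the remainder to test.
split_counts <- function(n, spec) {
  n_tr <- round(spec$train * n)
  n_va <- round(spec$validation * n)
  n_te <- n - n_tr - n_va
  if (min(n_tr, n_va, n_te) < 1L) {
    abort(sprintf("A class with %d samples cannot be split three ways.", n))
  }
  c(train = n_tr, validation = n_va, test = n_te)
}

#' Stratified train/validation/test split
#'
#' Partitions the rows of a labelled feature table into train, validation
#' and test parts, per class, at the spec's fractions and seed. The result
#' is an exact partition (disjoint, exhaustive) with per-class proportions
#' within one sample of the requested fractions, and is deterministic per
#' seed.
#'
#' @param data Labelled feature tibble.
#' @param spec A [split_spec()].
#' @return A named list of tibbles `train`, `validation`, `test`; the index
#'   partition is attached as attribute `"indices"`.
#' @export
stratified_split <- function(data, spec = split_spec()) {
  parts <- check_feature_data(data)
  groups <- if (spec$stratified) {
    split(seq_len(parts$n), parts$y)
  } else {
    list(all = seq_len(parts$n))
  }
  if (any(lengths(groups) < 3L)) {
    abort("Every class needs at least 3 samples to be split three ways.")
  }
  idx <- withr::with_seed(spec$seed, {
    pieces <- lapply(groups, function(ii) {
      ii <- sample(ii)
      nn <- split_counts(length(ii), spec)
      list(train = ii[seq_len(nn["train"])],
           validation = ii[nn["train"] + seq_len(nn["validation"])],
           test = ii[(nn["train"] + nn["validation"] + 1L):length(ii)])
    })
    list(train = sort(unlist(lapply(pieces, `[[`, "train"), use.names = FALSE)),
         validation = sort(unlist(lapply(pieces, `[[`, "validation"), use.names = FALSE)),
         test = sort(unlist(lapply(pieces, `[[`, "test"), use.names = FALSE)))
  })
  out <- lapply(idx, function(ii) data[ii, , drop = FALSE])
  attr(out, "indices") <- idx
  class(out) <- "bdefs_split"
  out
}

#' @export
print.bdefs_split <- function(x, ...) {
  cat(sprintf("<bdefs_split> train %d / validation %d / test %d rows\n",
              nrow(x$train), nrow(x$validation), nrow(x$test)))
  invisible(x)
}
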