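# Internal helpers shared across modules.

# Run `code` under a fixed RNG seed when `seed` is non-NULL, restoring the
# caller's RNG state afterwards; otherwise run it on the ambient stream.
with_seed_if <- function(seed, code) {
  if (is.null(seed)) force(code) else withr::with_seed(as.integer(seed), code)
}

# A single user-facing seed fans out to per-stage seeds by fixed offsets so
# stages are individually reproducible without sharing a stream.
stage_seed <- function(seed, stage) {
  if (is.null(seed)) return(NULL)
  offsets <- c(simulate = 11L, extract = 23L, select = 37L,
               split = 53L, classify = 71L)
  (as.integer(seed) + offsets[[stage]]) %% .Machine$integer.max
}

assert_count <- function(x, name, min = 1L) {
  if (!is.numeric(x) || length(x) != 1L || is.na(x) || x < min || x != round(x)) {
    abort(sprintf("`%s` must be a single integer >= %d.", name, min))
  }
  as.integer(x)
}

assert_prob <- function(x, name, lo = 0, hi = 1, lo_open = FALSE, hi_open = FALSE) {
  ok <- is.numeric(x) && length(x) == 1L && !is.na(x) &&
    (if (lo_open) x > lo else x >= lo) && (if (hi_open) x < hi else x <= hi)
  if (!ok) abort(sprintf("`%s` must be a number in the range %s%g, %g%s.",
                         name, if (lo_open) "(" else "[", lo, hi,
                         if (hi_open) ")" else "]"))
  as.numeric(x)
}

# Feature-bearing columns follow the on-disk convention f0..f{d-1}; anything
# that is not the label column counts as a feature.
feature_cols <- function(data) setdiff(names(data), "label")

feature_names <- function(d) paste0("f", seq_len(d) - 1L)

# Validate a labelled feature table and return its pieces.
check_feature_data <- function(data, arg = "data") {
  if (!is.data.frame(data)) abort(sprintf("`%s` must be a data frame.", arg))
  if (!"label" %in% names(data)) {
    abort(sprintf("`%s` must contain a `label` column.", arg))
  }
  fc <- feature_cols(data)
  if (length(fc) == 0L) abort(sprintf("`%s` has no feature columns.", arg))
  X <- as.matrix(data[fc])
  if (!is.numeric(X)) abort("Feature columns must all be numeric.")
  if (anyNA(X) || !all(is.finite(X))) {
    abort("Feature columns must be finite with no missing values.")
  }
  y <- data$label
  if (!is.factor(y)) y <- factor(y)
  list(X = X, y = y, features = fc, d = length(fc), n = nrow(data))
}

mask_key <- function(bits) paste(bits, collapse = "")

# Repair an all-zero mask by setting one uniformly random bit; the fitness is
# undefined on an empty feature subset and repair keeps the population size.
repair_mask <- function(bits) {
  if (sum(bits) == 0L) bits[sample.int(length(bits), 1L)] <- 1L
  bits
}
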