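# Shared fixtures, built once per test run.

.fixture_cache <- new.env(parent = emptyenv())

cached <- function(key, builder) {
  if (is.null(.fixture_cache[[key]])) .fixture_cache[[key]] <- builder()
  .fixture_cache[[key]]
}

# d = 8 with two planted informative columns: small enough for the
# exhaustive oracle.
fixture_d8 <- function() cached("d8", function() {
  simulate_features(n_per_class = 50, n_classes = 2, d = 8,
                    informative = c(1, 5), effect_size = 3, seed = 7)
})

# d = 32 with four planted columns over five classes, emulating the
# five-tissue-class deep-feature problem.
fixture_d32 <- function() cached("d32", function() {
  simulate_features(n_per_class = 100, n_classes = 5, d = 32,
                    informative = c(1, 6, 10, 21), effect_size = 3, seed = 7)
})

fixture_d32_planted <- c(1, 6, 10, 21)

# Toy deterministic fitness landscape over d = 3: error falls with subset
# size so sparsity pressure is the only force towards smaller masks.
toy_error_table <- function() {
  c("100" = 0.30, "010" = 0.35, "001" = 0.40,
    "110" = 0.20, "101" = 0.22, "011" = 0.25,
    "111" = 0.10)
}

# A small image tree shared by the extraction tests.
fixture_images <- function() cached("imgs", function() {
  dir <- file.path(tempdir(), "bdefs-test-imgs")
  simulate_images(dir, n_per_class = 6, n_classes = 2, side = 64, seed = 11)
  dir
})

small_extraction_config <- function(...) {
  extraction_config(input_side = 64, hidden_dim = 96, feature_dim = 64,
                    batch_size = 4, seed = 5, ...)
}

# Nearest-centroid holdout error computed independently of the package's
# evaluator plumbing (plain base R), for oracle-style comparisons.
bf_holdout_error <- function(data, cols, frac = 0.25, seed = 99) {
  X <- as.matrix(data[setdiff(names(data), "label")])[, cols, drop = FALSE]
  y <- factor(data$label)
  hold <- withr::with_seed(seed, {
    unlist(lapply(split(seq_along(y), y),
                  function(ii) sample(ii, round(frac * length(ii)))))
  })
  ctr <- vapply(levels(y), function(cl) {
    colMeans(X[-hold, , drop = FALSE][y[-hold] == cl, , drop = FALSE])
  }, numeric(ncol(X)))
  if (is.null(dim(ctr))) ctr <- matrix(ctr, nrow = 1L)
  pred <- levels(y)[apply(X[hold, , drop = FALSE], 1, function(x) {
    which.min(colSums((x - ctr)^2))
  })]
  mean(pred != as.character(y[hold]))
}
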