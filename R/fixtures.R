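#' Simulate a labelled feature matrix with planted informative features
#'
#' Generates a class-conditional Gaussian feature table that emulates the
#' deep-feature matrices consumed by the selection and classification stages,
#' with a known ground truth: a chosen subset of columns carries class signal,
#' every other column is standard Gaussian noise independent of the class.
#'
#' On the informative columns, class `k` (for `k = 0 .. n_classes - 1`) has
#' mean `effect_size * k` and standard deviation `noise_sd`, so consecutive
#' class means are separated by `effect_size` — the simplest linear separation
#' consistent with "discriminative features". Nuisance columns are N(0, 1)
#' for every class.
#'
#' @param n_per_class Samples per class (>= 2).
#' @param n_classes Number of classes (>= 2).
#' @param d Total feature dimension.
#' @param informative Integer vector of 1-based column indices that carry
#'   class signal (may be empty).
#' @param effect_size Separation between consecutive class means on the
#'   informative columns.
#' @param noise_sd Standard deviation of the informative columns (> 0).
#' @param seed Optional integer seed; a fixed seed makes the output
#'   bitwise reproducible.
#'
#' @return A tibble with columns `f0 .. f{d-1}` and a factor `label`, plus
#'   attributes `ground_truth` (length-`d` 0/1 vector marking the informative
#'   columns) and `informative` (the indices themselves). Retrieve the mask
#'   with [ground_truth_mask()].
#' @examples
#' sim <- simulate_features(n_per_class = 20, d = 8, informative = c(1, 5),
#'                          effect_size = 3, seed = 1)
#' ground_truth_mask(sim)
#' @export
simulate_features <- function(n_per_class = 100, n_classes = 2, d = 32,
                              informative = integer(0), effect_size = 3,
                              noise_sd = 1, seed = NULL) {
  n_per_class <- assert_count(n_per_class, "n_per_class", min = 2L)
  n_classes <- assert_count(n_classes, "n_classes", min = 2L)
  d <- assert_count(d, "d", min = 1L)
  if (!is.numeric(noise_sd) || noise_sd <= 0) abort("`noise_sd` must be > 0.")
  informative <- unique(as.integer(informative))
  if (length(informative) && (min(informative) < 1L || max(informative) > d)) {
    abort("`informative` indices must lie in 1..d.")
  }
  n <- n_per_class * n_classes
  labels <- factor(rep(sprintf("class_%d", seq_len(n_classes)), each = n_per_class))
  X <- with_seed_if(seed, {
    M <- matrix(rnorm(n * d), n, d)
    for (j in informative) {
      means <- rep(effect_size * (seq_len(n_classes) - 1L), each = n_per_class)
      M[, j] <- rnorm(n, mean = means, sd = noise_sd)
    }
    M
  })
  colnames(X) <- feature_names(d)
  out <- as_tibble(as.data.frame(X))
  out$label <- labels
  mask <- integer(d)
  mask[informative] <- 1L
  attr(out, "ground_truth") <- mask
  attr(out, "informative") <- informative
  out
}

#' Ground-truth informative-feature mask of a simulated dataset
#'
#' @param data A tibble produced by [simulate_features()].
#' @return Length-`d` integer 0/1 vector, 1 on planted informative columns.
#' @export
ground_truth_mask <- function(data) {
  m <- attr(data, "ground_truth")
  if (is.null(m)) abort("`data` carries no ground-truth mask; was it produced by simulate_features()?")
  m
}

#' Write a tree of procedural texture images, one subdirectory per class
#'
#' Produces a class-per-subdirectory PNG tree suitable as a smoke-test input
#' for the extraction stage. Each class uses a distinct procedural texture
#' (class-specific stripe frequency and orientation plus blob noise) so that
#' pooled convolutional features are class-separable. These are deliberately
#' not histology simulants: the extraction stage only needs separable inputs.
#'
#' @param dir Target directory (created if missing).
#' @param n_per_class Images per class.
#' @param n_classes Number of classes.
#' @param side Image side length in pixels (>= 32); images are square RGB.
#' @param seed Optional integer seed for the blob noise.
#' @return A tibble manifest with columns `path` and `label`, invisibly
#'   row-ordered as written.
#' @export
simulate_images <- function(dir, n_per_class = 2, n_classes = 5, side = 224,
                            seed = NULL) {
  side <- assert_count(side, "side", min = 32L)
  n_per_class <- assert_count(n_per_class, "n_per_class")
  n_classes <- assert_count(n_classes, "n_classes")
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  if (!dir.exists(dir)) abort(sprintf("Cannot create directory '%s'.", dir))
  coords <- outer(seq_len(side) / side, rep(1, side))
  coords_t <- t(coords)
  rows <- with_seed_if(seed, {
    purrr::map_dfr(seq_len(n_classes), function(k) {
      cls <- sprintf("class_%d", k)
      cls_dir <- file.path(dir, cls)
      dir.create(cls_dir, showWarnings = FALSE)
      freq <- 2 + 3 * k                      # stripe frequency grows with class
      angle_mix <- (k %% 2 == 0)             # alternate stripe orientation
      purrr::map_dfr(seq_len(n_per_class), function(i) {
        phase <- runif(1, 0, 2 * pi)
        base <- if (angle_mix) {
          0.5 + 0.5 * sin(2 * pi * freq * coords_t + phase)
        } else {
          0.5 + 0.5 * sin(2 * pi * freq * coords + phase)
        }
        noise <- matrix(runif(side * side, -0.08, 0.08), side, side)
        img <- array(0, c(side, side, 3))
        img[, , 1] <- pmin(pmax(base + noise, 0), 1)
        img[, , 2] <- pmin(pmax(1 - base + noise, 0), 1)
        img[, , 3] <- pmin(pmax(0.3 + 0.4 * base * (k / n_classes) + noise, 0), 1)
        path <- file.path(cls_dir, sprintf("%s_%03d.png", cls, i))
        png::writePNG(img, path)
        tibble(path = path, label = cls)
      })
    })
  })
  invisible(rows)
}
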