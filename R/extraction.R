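#' Configuration of the deep-feature extractor
#'
#' Describes the full extraction stack: square RGB input, a frozen
#' convolutional backbone ending in `backbone_out_channels` feature maps,
#' global average pooling to a vector `z`, and a trainable head
#' `z1 = ReLU(BN(W1 z + b1))` (dropout `dropout_p`),
#' `z2 = ReLU(BN(W2 z1 + b2))` (dropout `dropout_p`),
#' `yhat = Softmax(W3 z2 + b3)`. The penultimate representation `z2`
#' (dimension `feature_dim`) is what [extract_features()] exports.
#'
#' @param input_side Input side length in pixels; images are resized to
#'   `input_side x input_side x 3`. Must be >= 56 so the backbone's spatial
#'   extent stays positive.
#' @param channels Input channels (always promoted to 3).
#' @param backbone_out_channels Channels of the backbone's final feature map.
#' @param hidden_dim Width of the first head block (`z1`).
#' @param feature_dim Width of the exported representation (`z2`); must be
#'   smaller than `hidden_dim`.
#' @param n_classes Number of classes (filled in from the data when `NULL`).
#' @param dropout_p Dropout probability in both head blocks, in `[0, 1)`.
#' @param epochs Head-training epochs.
#' @param batch_size Head-training mini-batch size.
#' @param learning_rate Adam learning rate for head training.
#' @param freeze_backbone Keep every backbone parameter fixed during training.
#' @param pretrained Use downloaded ImageNet backbone weights. Only the
#'   random-weight mode (`FALSE`) is available in this package; see Details.
#' @param normalization_mean,normalization_std Per-channel standardization
#'   statistics (defaults are the ImageNet statistics).
#' @param seed Optional integer seed for backbone/head initialization,
#'   shuffling and dropout.
#'
#' @details `pretrained = TRUE` requires external weight files and errors;
#'   with `pretrained = FALSE` the backbone is a seeded random-projection
#'   convolutional stack (three strided ReLU convolutions ending in
#'   `backbone_out_channels` maps), which preserves enough texture structure
#'   for class-separable pooled features and keeps the full pipeline testable
#'   offline.
#' @return An `extraction_config` list.
#' @export
extraction_config <- function(input_side = 224, channels = 3,
                              backbone_out_channels = 576,
                              hidden_dim = 1536, feature_dim = 1024,
                              n_classes = NULL, dropout_p = 0.3,
                              epochs = 10, batch_size = 32,
                              learning_rate = 0.001,
                              freeze_backbone = TRUE, pretrained = FALSE,
                              normalization_mean = c(0.485, 0.456, 0.406),
                              normalization_std = c(0.229, 0.224, 0.225),
                              seed = NULL) {
  input_side <- assert_count(input_side, "input_side", min = 56L)
  hidden_dim <- assert_count(hidden_dim, "hidden_dim")
  feature_dim <- assert_count(feature_dim, "feature_dim")
  if (feature_dim >= hidden_dim) abort("`feature_dim` must be < `hidden_dim`.")
  dropout_p <- assert_prob(dropout_p, "dropout_p", hi_open = TRUE)
  epochs <- assert_count(epochs, "epochs", min = 0L)
  if (length(normalization_mean) != 3L || length(normalization_std) != 3L) {
    abort("Normalization statistics must be 3-vectors.")
  }
  structure(list(
    input_side = input_side, channels = 3L,
    backbone_out_channels = assert_count(backbone_out_channels, "backbone_out_channels"),
    hidden_dim = hidden_dim, feature_dim = feature_dim,
    n_classes = if (is.null(n_classes)) NULL else assert_count(n_classes, "n_classes", 2L),
    dropout_p = dropout_p, epochs = epochs,
    batch_size = assert_count(batch_size, "batch_size"),
    learning_rate = as.numeric(learning_rate),
    freeze_backbone = isTRUE(freeze_backbone),
    pretrained = isTRUE(pretrained),
    normalization_mean = as.numeric(normalization_mean),
    normalization_std = as.numeric(normalization_std),
    seed = if (is.null(seed)) NULL else as.integer(seed)
  ), class = "extraction_config")
}

#' Load, resize and standardize an image
#'
#' Resizes any RGB (or grayscale, promoted to RGB) image to the configured
#' square input size and standardizes each channel with the configured
#' mean/std (ImageNet statistics by default).
#'
#' @param image A PNG file path or an `H x W x 3` (or `H x W`) array with
#'   values in `[0, 1]`.
#' @param config An [extraction_config()].
#' @return A `3 x side x side` numeric array (channels first).
#' @export
preprocess_image <- function(image, config = extraction_config()) {
  if (is.character(image)) {
    path <- image
    image <- tryCatch(png::readPNG(path),
                      error = function(e) abort(sprintf("Cannot decode image '%s': %s", path, conditionMessage(e))))
  }
  if (length(dim(image)) == 2L) image <- array(rep(image, 3L), c(dim(image), 3L))
  if (dim(image)[3] > 3L) image <- image[, , 1:3, drop = FALSE]  # drop alpha
  if (dim(image)[3] != 3L) abort("Images must have 1, 3 or 4 channels.")
  side <- config$input_side
  if (!all(dim(image)[1:2] == side)) {
    image <- EBImage::resize(image, w = side, h = side)
  }
  out <- array(0, c(3L, side, side))
  for (c in 1:3) {
    out[c, , ] <- (image[, , c] - config$normalization_mean[c]) /
      config$normalization_std[c]
  }
  out
}

#' Global average pooling
#'
#' Collapses a `C x H x W` feature map to a length-`C` vector of spatial
#' means, yielding a fixed-length representation regardless of spatial size.
#'
#' @param h A `C x H x W` numeric array with `H, W >= 1`.
#' @return A length-`C` numeric vector.
#' @export
global_average_pool <- function(h) {
  if (length(dim(h)) != 3L || any(dim(h)[2:3] < 1L)) {
    abort("`h` must be a C x H x W array with positive spatial extent.")
  }
  apply(h, 1L, mean)
}

# ---- backbone -------------------------------------------------------------

# Three strided ReLU convolutions: 3 -> 64 (8x8, stride 8) -> 192 (3x3,
# stride 2) -> backbone_out_channels (3x3, stride 2). He-initialized from the
# config seed; never trained.
init_backbone <- function(config) {
  mk <- function(k, cin, cout) list(
    k = k, cin = cin, cout = cout,
    W = matrix(rnorm(k * k * cin * cout, sd = sqrt(2 / (k * k * cin))),
               k * k * cin, cout),
    b = numeric(cout)
  )
  with_seed_if(config$seed, list(
    mk(8L, 3L, 64L),
    mk(3L, 64L, 192L),
    mk(3L, 192L, config$backbone_out_channels)
  ))
}

# im2col convolution on an H x W x Cin array; valid padding.
conv_forward <- function(x, layer, stride) {
  H <- dim(x)[1]; W <- dim(x)[2]; k <- layer$k
  Ho <- (H - k) %/% stride + 1L
  Wo <- (W - k) %/% stride + 1L
  if (Ho < 1L || Wo < 1L) {
    abort("Backbone spatial extent collapsed; increase `input_side`.")
  }
  P <- matrix(0, Ho * Wo, k * k * layer$cin)
  col <- 0L
  for (c in seq_len(layer$cin)) for (dj in seq_len(k)) for (di in seq_len(k)) {
    col <- col + 1L
    P[, col] <- as.vector(x[seq(di, by = stride, length.out = Ho),
                            seq(dj, by = stride, length.out = Wo), c])
  }
  Y <- P %*% layer$W
  Y <- sweep(Y, 2L, layer$b, "+")
  Y[Y < 0] <- 0
  array(Y, c(Ho, Wo, layer$cout))
}

# 3 x S x S standardized image -> C x H' x W' feature maps.
backbone_forward <- function(backbone, x3ss) {
  x <- aperm(x3ss, c(2, 3, 1))
  x <- conv_forward(x, backbone[[1]], 8L)
  x <- conv_forward(x, backbone[[2]], 2L)
  x <- conv_forward(x, backbone[[3]], 2L)
  aperm(x, c(3, 1, 2))
}

#' Checksum of all backbone parameters
#'
#' Used to verify the freezing contract: the checksum before and after head
#' training must be identical.
#'
#' @param extractor A fitted extractor from [train_extractor()].
#' @return A numeric summary (sum, sum of squares) of every backbone weight.
#' @export
backbone_checksum <- function(extractor) {
  ws <- unlist(lapply(extractor$backbone, function(l) c(l$W, l$b)))
  c(sum = sum(ws), sumsq = sum(ws^2))
}

# Pool backbone features for every image in a manifest.
pooled_features <- function(manifest, backbone, config) {
  Z <- t(vapply(manifest$path, function(p) {
    global_average_pool(backbone_forward(backbone, preprocess_image(p, config)))
  }, numeric(config$backbone_out_channels)))
  rownames(Z) <- NULL
  Z
}

# ---- head -----------------------------------------------------------------

init_head <- function(config) {
  nn_init(c(config$backbone_out_channels, config$hidden_dim,
            config$feature_dim, config$n_classes),
          bn = TRUE, dropout = config$dropout_p)
}

#' Run the trainable head on pooled backbone vectors
#'
#' Applies the two Linear-BatchNorm-ReLU-Dropout blocks and the softmax
#' output layer to a batch of pooled vectors `z`.
#'
#' @param z A batch matrix (`n x backbone_out_channels`) or a single vector.
#' @param extractor A fitted extractor from [train_extractor()].
#' @param mode `"eval"` (dropout inactive, running BatchNorm statistics) or
#'   `"train"` (dropout sampled from the ambient RNG, batch statistics).
#' @return A list with `z2` (`n x feature_dim`, nonnegative) and `probs`
#'   (`n x n_classes`, rows summing to 1).
#' @export
forward_head <- function(z, extractor, mode = c("eval", "train")) {
  mode <- match.arg(mode)
  if (is.null(dim(z))) z <- matrix(z, nrow = 1L)
  if (ncol(z) != extractor$config$backbone_out_channels) {
    abort(sprintf("`z` has %d columns; the head expects %d.",
                  ncol(z), extractor$config$backbone_out_channels))
  }
  fwd <- nn_forward(extractor$head, z, train = identical(mode, "train"))
  list(z2 = fwd$caches[[2]]$out, probs = fwd$probs)
}

#' Train the extractor head on a labelled image tree
#'
#' Builds the frozen backbone, pools a fixed-length vector per image, and
#' trains only the head (Adam, softmax cross-entropy) for the configured
#' number of epochs. Because the backbone is frozen, pooled vectors are
#' computed once and reused across epochs. With `epochs = 0` the head is
#' returned at its random initialization.
#'
#' @param images A class-per-subdirectory image tree (directory path) or a
#'   manifest tibble with `path` and `label` columns.
#' @param config An [extraction_config()].
#' @return A `bdefs_extractor` with the backbone, trained head, class levels,
#'   image manifest and per-epoch training-loss history.
#' @export
train_extractor <- function(images, config = extraction_config()) {
  if (config$pretrained) {
    abort(paste("Pretrained backbone weights are not bundled; use",
                "`pretrained = FALSE` for the random-projection backbone."))
  }
  manifest <- image_manifest(images)
  classes <- levels(manifest$label)
  if (length(classes) < 2L) abort("Head training needs at least 2 classes.")
  config$n_classes <- length(classes)
  backbone <- init_backbone(config)
  Z <- pooled_features(manifest, backbone, config)
  # head init/training uses an offset seed so its stream is independent of
  # the backbone initialization stream
  head_seed <- if (is.null(config$seed)) NULL else config$seed + 1L
  res <- with_seed_if(head_seed, {
    head <- init_head(config)
    if (config$epochs > 0L) {
      nn_train(head, Z, as.integer(manifest$label), config$n_classes,
               config$epochs, config$batch_size, config$learning_rate)
    } else {
      list(net = head, loss_history = numeric(0))
    }
  })
  structure(list(
    config = config, backbone = backbone, head = res$net,
    classes = classes, manifest = manifest,
    loss_history = res$loss_history
  ), class = "bdefs_extractor")
}

#' @export
print.bdefs_extractor <- function(x, ...) {
  cat(sprintf("<bdefs_extractor> %d classes, %d -> %d -> %d head, %d epoch(s)\n",
              length(x$classes), x$config$backbone_out_channels,
              x$config$hidden_dim, x$config$feature_dim,
              length(x$loss_history)))
  invisible(x)
}

#' Export the penultimate deep representation for a set of images
#'
#' Runs every image through preprocessing, the frozen backbone, global
#' average pooling and the head in eval mode, and exports the penultimate
#' activation `z2` as the feature vector.
#'
#' @param images Directory or manifest tibble (as in [train_extractor()]).
#' @param extractor A fitted [train_extractor()] result.
#' @return A tibble with `feature_dim` columns `f0..f{d-1}` and a factor
#'   `label`; the row-aligned image manifest is attached as attribute
#'   `"manifest"`.
#' @export
extract_features <- function(images, extractor) {
  manifest <- image_manifest(images)
  Z <- pooled_features(manifest, extractor$backbone, extractor$config)
  z2 <- forward_head(Z, extractor, mode = "eval")$z2
  colnames(z2) <- feature_names(ncol(z2))
  out <- as_tibble(as.data.frame(z2))
  out$label <- factor(as.character(manifest$label))
  attr(out, "manifest") <- manifest
  out
}
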