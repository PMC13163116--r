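#' Classifier specification with standard hyperparameter defaults
#'
#' Builds a `classifier_spec` for one of the eight supported families with
#' its canonical defaults; any named override is recorded and echoed in the
#' evaluation report.
#'
#' Families and defaults:
#' * `medium_nn`: hidden layers 64/32, ReLU, softmax, Adam (lr 0.001),
#'   cross-entropy, 10 epochs, batch 32.
#' * `wide_nn`: as `medium_nn` with hidden layers 256/128.
#' * `linear_svm`: linear kernel, `C = 1`, gamma "scale", probabilities on.
#' * `quadratic_svm`: polynomial kernel degree 2, `coef0 = 0`, `C = 1`.
#' * `cubic_svm`: polynomial kernel degree 3, `coef0 = 0`, `C = 1`.
#' * `bagged_trees`: 50 bootstrap-aggregated unpruned trees (all features
#'   eligible at every split).
#' * `boosted_trees`: gradient boosting, 100 learners of depth 3,
#'   learning rate 0.1, subsample 1.
#' * `adaboost_trees`: SAMME.R over depth-1 stumps, 100 iterations,
#'   learning rate 0.5.
#'
#' @param family One of the eight family names above.
#' @param ... Named hyperparameter overrides.
#' @return A `classifier_spec`.
#' @export
classifier_spec <- function(family = c("medium_nn", "wide_nn", "linear_svm",
                                       "quadratic_svm", "cubic_svm",
                                       "bagged_trees", "boosted_trees",
                                       "adaboost_trees"), ...) {
  family <- tryCatch(match.arg(family),
                     error = function(e) abort(sprintf("Unknown classifier family '%s'.", family[1])))
  defaults <- switch(family,
    medium_nn = list(hidden = c(64L, 32L), epochs = 10L, batch_size = 32L,
                     learning_rate = 0.001),
    wide_nn = list(hidden = c(256L, 128L), epochs = 10L, batch_size = 32L,
                   learning_rate = 0.001),
    linear_svm = list(kernel = "linear", cost = 1, gamma = "scale"),
    quadratic_svm = list(kernel = "polynomial", degree = 2L, coef0 = 0,
                         cost = 1, gamma = "scale"),
    cubic_svm = list(kernel = "polynomial", degree = 3L, coef0 = 0,
                     cost = 1, gamma = "scale"),
    bagged_trees = list(n_estimators = 50L),
    boosted_trees = list(n_estimators = 100L, max_depth = 3L,
                         learning_rate = 0.1, subsample = 1),
    adaboost_trees = list(n_estimators = 100L, learning_rate = 0.5,
                          max_depth = 1L)
  )
  overrides <- list(...)
  unknown <- setdiff(names(overrides), names(defaults))
  if (length(unknown)) {
    abort(sprintf("Unknown hyperparameter(s) for %s: %s.",
                  family, paste(unknown, collapse = ", ")))
  }
  structure(list(family = family,
                 hyperparameters = modifyList(defaults, overrides),
                 overrides = overrides),
            class = "classifier_spec")
}

#' All eight default classifier specifications
#'
#' @return A named list of [classifier_spec()]s, one per family.
#' @export
default_classifiers <- function() {
  fams <- c("medium_nn", "wide_nn", "linear_svm", "quadratic_svm",
            "cubic_svm", "bagged_trees", "boosted_trees", "adaboost_trees")
  setNames(lapply(fams, classifier_spec), fams)
}

# sklearn-style "scale" gamma: 1 / (n_features * total variance of X).
resolve_gamma <- function(gamma, X) {
  if (identical(gamma, "scale")) {
    v <- stats::var(as.vector(X))
    1 / (ncol(X) * max(v, .Machine$double.eps))
  } else as.numeric(gamma)
}

#' Fit a classifier on a labelled feature table
#'
#' Trains the specified family on the feature columns of `data`. Neural-net
#' families train the in-package MLP (Adam, cross-entropy); SVMs use
#' [e1071::svm()] with probability outputs; bagged trees use
#' [randomForest::randomForest()] with every feature eligible at each split
#' (pure bagging); boosted trees use [xgboost::xgboost()]; AdaBoost is the
#' in-package SAMME.R over depth-1 [rpart::rpart()] stumps.
#'
#' @param data Labelled feature tibble.
#' @param spec A [classifier_spec()] (or a family name).
#' @param seed Optional integer seed for stochastic trainers.
#' @return A `bdefs_model`; predict with [predict.bdefs_model()].
#' @export
fit_classifier <- function(data, spec = classifier_spec("medium_nn"),
                           seed = NULL) {
  if (is.character(spec)) spec <- classifier_spec(spec)
  parts <- check_feature_data(data)
  if (nlevels(parts$y) < 2L) abort("Training data must contain at least 2 classes.")
  X <- parts$X; y <- parts$y
  hp <- spec$hyperparameters
  fit <- with_seed_if(seed, switch(spec$family,
    medium_nn = ,
    wide_nn = {
      net <- nn_init(c(ncol(X), hp$hidden, nlevels(y)), bn = FALSE, dropout = 0)
      nn_train(net, X, as.integer(y), nlevels(y),
               hp$epochs, hp$batch_size, hp$learning_rate)$net
    },
    linear_svm = ,
    quadratic_svm = ,
    cubic_svm = {
      args <- list(x = X, y = y, kernel = hp$kernel, cost = hp$cost,
                   gamma = resolve_gamma(hp$gamma, X), scale = FALSE,
                   probability = TRUE)
      if (!is.null(hp$degree)) {
        args$degree <- hp$degree
        args$coef0 <- hp$coef0
      }
      do.call(e1071::svm, args)
    },
    bagged_trees = randomForest::randomForest(
      x = X, y = y, ntree = hp$n_estimators, mtry = ncol(X), replace = TRUE),
    boosted_trees = xgboost::xgboost(
      x = X, y = y,
      nrounds = hp$n_estimators, max_depth = hp$max_depth,
      learning_rate = hp$learning_rate, subsample = hp$subsample,
      nthreads = 1L, verbosity = 0, seed = seed %||% 0L),
    adaboost_trees = samme_r_fit(X, y, n_estimators = hp$n_estimators,
                                 learning_rate = hp$learning_rate,
                                 max_depth = hp$max_depth)
  ))
  structure(list(spec = spec, fit = fit, classes = levels(y),
                 features = parts$features),
            class = "bdefs_model")
}

#' Predict classes or class probabilities
#'
#' @param object A `bdefs_model` from [fit_classifier()].
#' @param newdata Labelled or unlabelled feature tibble with the training
#'   feature columns.
#' @param type `"class"` for predicted labels, `"prob"` for the class
#'   probability matrix.
#' @param ... Unused.
#' @return A character vector of labels, or an `n x K` probability matrix
#'   with class-named columns.
#' @export
predict.bdefs_model <- function(object, newdata, type = c("class", "prob"), ...) {
  type <- match.arg(type)
  missing_cols <- setdiff(object$features, names(newdata))
  if (length(missing_cols)) {
    abort(sprintf("`newdata` lacks feature column(s): %s.",
                  paste(head(missing_cols, 5), collapse = ", ")))
  }
  X <- as.matrix(newdata[object$features])
  K <- length(object$classes)
  P <- switch(object$spec$family,
    medium_nn = ,
    wide_nn = nn_activations(object$fit, X)$probs,
    linear_svm = ,
    quadratic_svm = ,
    cubic_svm = {
      pr <- predict(object$fit, X, probability = TRUE)
      attr(pr, "probabilities")[, object$classes, drop = FALSE]
    },
    bagged_trees = predict(object$fit, X, type = "prob")[, object$classes, drop = FALSE],
    boosted_trees = {
      pr <- predict(object$fit, X, type = "response")
      if (is.null(dim(pr))) {
        # binary objective returns P(second level)
        pr <- cbind(1 - pr, pr)
        colnames(pr) <- object$classes
      }
      pr[, object$classes, drop = FALSE]
    },
    adaboost_trees = samme_r_prob(object$fit, X)
  )
  dimnames(P) <- list(NULL, object$classes)
  if (type == "prob") return(P)
  object$classes[max.col(P, ties.method = "first")]
}

# ---- AdaBoost (SAMME.R) over rpart stumps ---------------------------------

# Multiclass real-valued AdaBoost: each stage fits a weighted stump, reads
# its class-probability estimates p, contributes
# h(x) = (K-1) * (log p - mean log p), and reweights samples by
# exp(-lr * (K-1)/K * y~ . log p) with y~ the +/- coded true class.
samme_r_fit <- function(X, y, n_estimators, learning_rate, max_depth = 1L) {
  n <- nrow(X); K <- nlevels(y)
  df <- as.data.frame(X)
  df$.y <- y
  w <- rep(1 / n, n)
  ycode <- matrix(-1 / (K - 1), n, K)
  ycode[cbind(seq_len(n), as.integer(y))] <- 1
  stumps <- vector("list", n_estimators)
  ctrl <- rpart::rpart.control(maxdepth = max_depth, cp = 0, minsplit = 2L,
                               xval = 0L, maxcompete = 0L, maxsurrogate = 0L)
  for (m in seq_len(n_estimators)) {
    stump <- rpart::rpart(.y ~ ., data = df, weights = w, method = "class",
                          control = ctrl)
    p <- predict(stump, df, type = "prob")
    p <- pmax(p, 1e-12)
    logp <- log(p / rowSums(p))
    w <- w * exp(-learning_rate * (K - 1) / K * rowSums(ycode * logp))
    s <- sum(w)
    if (!is.finite(s) || s <= 0) break
    w <- w / s
    stumps[[m]] <- stump
  }
  list(stumps = Filter(Negate(is.null), stumps), classes = levels(y), K = K,
       learning_rate = learning_rate)
}

samme_r_decision <- function(fit, X) {
  df <- as.data.frame(X)
  K <- fit$K
  Reduce(`+`, lapply(fit$stumps, function(st) {
    p <- pmax(predict(st, df, type = "prob"), 1e-12)
    logp <- log(p / rowSums(p))
    (K - 1) * (logp - rowMeans(logp))
  }))
}

samme_r_prob <- function(fit, X) {
  D <- samme_r_decision(fit, X)
  softmax_rows(D / (fit$K - 1))
}
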