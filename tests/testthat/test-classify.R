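test_that("the stratified split is an exact partition at the requested fractions", {
  sim <- simulate_features(n_per_class = 50, n_classes = 2, d = 4, seed = 9)
  parts <- stratified_split(sim, split_spec())
  idx <- attr(parts, "indices")
  # per-part sizes within one sample per class of the requested fractions
  expect_true(all(abs(lengths(idx) - c(65, 15, 20)) <= 2))
  for (nm in names(parts)) {
    tab <- table(parts[[nm]]$label)
    expect_true(all(abs(tab - split_spec()[[nm]] * 50) <= 1))
  }
  # exact partition
  all_idx <- sort(unname(unlist(idx)))
  expect_equal(all_idx, 1:100)
  # class balance within each part (+/- 1)
  for (part in parts) {
    tab <- table(part$label)
    expect_lte(diff(range(tab)), 1L)
  }
  # determinism per seed
  parts2 <- stratified_split(sim, split_spec())
  expect_identical(attr(parts2, "indices"), idx)
  parts3 <- stratified_split(sim, split_spec(seed = 43))
  expect_false(identical(attr(parts3, "indices"), idx))

  expect_error(split_spec(0.5, 0.2, 0.2), "sum to 1")
  tiny <- simulate_features(n_per_class = 2, n_classes = 2, d = 2, seed = 1)
  expect_error(stratified_split(tiny, split_spec()), "at least 3")
})

test_that("split proportions hold per class within one sample on unbalanced fractions", {
  sim <- simulate_features(n_per_class = 37, n_classes = 3, d = 3, seed = 4)
  spec <- split_spec(0.8, 0.1, 0.1)
  parts <- stratified_split(sim, spec)
  for (nm in names(parts)) {
    tab <- table(parts[[nm]]$label)
    expect_true(all(abs(tab - spec[[nm]] * 37) <= 1))
  }
})

test_that("classifier specs carry the standard defaults and record overrides", {
  expect_equal(classifier_spec("medium_nn")$hyperparameters$hidden, c(64L, 32L))
  expect_equal(classifier_spec("wide_nn")$hyperparameters$hidden, c(256L, 128L))
  qs <- classifier_spec("quadratic_svm")
  expect_equal(qs$hyperparameters[c("kernel", "degree", "cost", "coef0")],
               list(kernel = "polynomial", degree = 2L, cost = 1, coef0 = 0))
  expect_equal(classifier_spec("cubic_svm")$hyperparameters$degree, 3L)
  expect_equal(classifier_spec("bagged_trees")$hyperparameters$n_estimators, 50L)
  bt <- classifier_spec("boosted_trees")$hyperparameters
  expect_equal(bt[c("n_estimators", "max_depth", "learning_rate")],
               list(n_estimators = 100L, max_depth = 3L, learning_rate = 0.1))
  ab <- classifier_spec("adaboost_trees")$hyperparameters
  expect_equal(ab[c("n_estimators", "learning_rate", "max_depth")],
               list(n_estimators = 100L, learning_rate = 0.5, max_depth = 1L))
  ov <- classifier_spec("medium_nn", epochs = 3L)
  expect_equal(ov$overrides, list(epochs = 3L))
  expect_error(classifier_spec("lstm"), "Unknown classifier family")
  expect_error(classifier_spec("medium_nn", warp = 2), "Unknown hyperparameter")
})

test_that("every family fits, predicts labels, and emits probability rows", {
  sim <- cached("clf_sim", function() {
    simulate_features(n_per_class = 40, n_classes = 3, d = 10,
                      informative = c(1, 4, 7), effect_size = 3, seed = 6)
  })
  parts <- stratified_split(sim, split_spec())
  for (fam in names(default_classifiers())) {
    spec <- if (fam %in% c("medium_nn", "wide_nn")) {
      classifier_spec(fam)
    } else if (fam == "adaboost_trees") {
      classifier_spec(fam, n_estimators = 20L)
    } else if (fam == "boosted_trees") {
      classifier_spec(fam, n_estimators = 20L)
    } else classifier_spec(fam)
    m <- fit_classifier(parts$train, spec, seed = 1)
    cls <- predict(m, parts$test, type = "class")
    expect_true(all(cls %in% levels(sim$label)))
    P <- predict(m, parts$test, type = "prob")
    expect_equal(dim(P), c(nrow(parts$test), 3L))
    expect_equal(rowSums(P), rep(1, nrow(P)), tolerance = 1e-6)
  }
})

test_that("confusion matrices count truth rows against prediction columns", {
  truth <- c("a", "a", "b", "b", "c")
  cm <- confusion_matrix(truth, truth)
  expect_true(all(cm[upper.tri(cm) | lower.tri(cm)] == 0))
  expect_equal(sum(cm), 5L)

  pred <- c("a", "b", "b", "b", "c")
  cm2 <- confusion_matrix(truth, pred)
  expect_equal(sum(cm2), 5L)
  expect_equal(cm2["a", "b"], 1L)
  expect_equal(rowSums(cm2), c(a = 2L, b = 2L, c = 1L))
  # swapping two prediction entries relocates exactly 2 units of mass
  # (each moved unit leaves one cell and enters another: L1 distance 4,
  # net change 0)
  pred2 <- pred; pred2[c(1, 3)] <- pred[c(3, 1)]
  delta <- cm2 - confusion_matrix(truth, pred2)
  expect_equal(sum(abs(delta)), 4L)
  expect_equal(sum(delta), 0L)
  expect_error(confusion_matrix(truth, c("a", "a", "b", "b", "z"),
                                levels = c("a", "b", "c")), "class set")
})

test_that("F1 reproduces the harmonic mean at report precision", {
  expect_equal(f1_from_pr(0.9810, 0.9830), 0.9820)
  expect_equal(f1_from_pr(1, 1), 1)
  expect_equal(f1_from_pr(0.9690, 0.9632), 0.9661)
  expect_warning(z <- f1_from_pr(0, 0), "defined as 0")
  expect_equal(z, 0)
})

test_that("report metrics agree with brute-force counting on random instances", {
  withr::with_seed(10, {
    classes <- letters[1:4]
    for (rep in 1:1000) {
      n <- sample(5:40, 1)
      truth <- sample(classes, n, replace = TRUE)
      pred <- sample(classes, n, replace = TRUE)
      cm <- confusion_matrix(truth, pred, levels = classes)
      pc <- per_class_metrics(cm)
      expect_equal(sum(diag(cm)) / n, mean(truth == pred))
      # brute-force one-vs-rest counts for a randomly chosen class
      cl <- sample(classes, 1)
      tp <- sum(truth == cl & pred == cl)
      fp <- sum(truth != cl & pred == cl)
      fn <- sum(truth == cl & pred != cl)
      tn <- sum(truth != cl & pred != cl)
      row <- pc[pc$class == cl, ]
      expect_equal(row$precision, if (tp + fp == 0) 0 else tp / (tp + fp))
      expect_equal(row$sensitivity, if (tp + fn == 0) 0 else tp / (tp + fn))
      expect_equal(row$specificity, if (tn + fp == 0) 0 else tn / (tn + fp))
      p <- row$precision; s <- row$sensitivity
      expect_equal(row$f1, if (p + s == 0) 0 else 2 * p * s / (p + s))
    }
  })
})

test_that("macro metrics are invariant under class relabeling", {
  withr::with_seed(3, {
    truth <- sample(letters[1:3], 60, replace = TRUE)
    pred <- sample(letters[1:3], 60, replace = TRUE)
    pc <- per_class_metrics(confusion_matrix(truth, pred))
    relabel <- c(a = "z", b = "x", c = "y")
    pc2 <- per_class_metrics(confusion_matrix(relabel[truth], relabel[pred]))
    expect_equal(mean(pc$precision), mean(pc2$precision))
    expect_equal(mean(pc$sensitivity), mean(pc2$sensitivity))
    expect_equal(mean(pc$f1), mean(pc2$f1))
  })
})

test_that("kappa follows its defining formula and is 1 only on diagonal confusion", {
  cm <- matrix(c(10L, 0L, 0L, 12L), 2, 2, dimnames = list(c("a", "b"), c("a", "b")))
  expect_equal(cohens_kappa(cm), 1)
  cm2 <- matrix(c(8L, 2L, 3L, 7L), 2, 2, byrow = TRUE,
                dimnames = list(c("a", "b"), c("a", "b")))
  po <- 15 / 20
  pe <- (10 * 11 + 10 * 9) / 400
  expect_equal(cohens_kappa(cm2), (po - pe) / (1 - pe))
  # uniformly random predictions on balanced classes: kappa near 0
  withr::with_seed(8, {
    truth <- rep(letters[1:5], each = 2000)
    pred <- sample(letters[1:5], 10000, replace = TRUE)
    expect_lt(abs(cohens_kappa(confusion_matrix(truth, pred))), 0.02)
  })
})

test_that("evaluation reports satisfy their internal identities", {
  sim <- cached("clf_sim", function() {
    simulate_features(n_per_class = 40, n_classes = 3, d = 10,
                      informative = c(1, 4, 7), effect_size = 3, seed = 6)
  })
  parts <- stratified_split(sim, split_spec())
  m <- fit_classifier(parts$train, classifier_spec("linear_svm"))
  rep <- evaluate_classifier(m, parts$test)
  ov <- rep$overall
  expect_equal(ov$misclassification_rate, 1 - ov$accuracy, tolerance = 1e-12)
  expect_equal(sum(rep$confusion), rep$n_test)
  expect_equal(ov$balanced_accuracy, mean(rep$per_class$sensitivity))
  expect_equal(ov$f1, mean(rep$per_class$f1))
  expect_equal(ov$ci_halfwidth,
               1.96 * sqrt(ov$accuracy * (1 - ov$accuracy) / rep$n_test))
  expect_true(ov$auc >= 0 && ov$auc <= 1)
  # perfect predictor degenerate case
  perfect <- rep
  perfect$confusion <- diag(c(5L, 5L, 5L))
  dimnames(perfect$confusion) <- list(truth = letters[1:3], predicted = letters[1:3])
  expect_equal(cohens_kappa(perfect$confusion), 1)
  expect_true(all(per_class_metrics(perfect$confusion)$specificity == 1))
})

test_that("report comparison tabulates accuracy differences and speed-ups", {
  mk_report <- function(fam, acc, t) {
    structure(list(
      overall = tibble::tibble(accuracy = acc, prediction_time_s = t),
      classifier = fam), class = "evaluation_report")
  }
  before <- list(quadratic_svm = mk_report("quadratic_svm", 0.9898, 20))
  after <- list(quadratic_svm = mk_report("quadratic_svm", 0.9814, 2))
  cmp <- compare_reports(before, after)
  expect_equal(cmp$accuracy_difference, -0.0084, tolerance = 1e-12)
  expect_equal(cmp$speed_up, 10)
  expect_equal(cmp$speed_up_label, "10.00x")
  # identical reports: zero difference, unit speed-up
  cmp2 <- compare_reports(before, before)
  expect_equal(cmp2$accuracy_difference, 0)
  expect_equal(cmp2$speed_up_label, "1.00x")
  expect_error(compare_reports(before, list(foo = after[[1]])), "families")
})

test_that("tidy and glance methods expose reports and DE runs as tibbles", {
  sim <- fixture_d8()
  res <- run_de(sim, de_config(max_iter = 10, seed = 1))
  td <- tidy(res)
  expect_named(td, c("feature", "index", "selected", "frequency"))
  expect_equal(sum(td$selected), res$best_k)
  gl <- glance(res)
  expect_equal(gl$k, res$best_k)
  parts <- stratified_split(sim, split_spec())
  m <- fit_classifier(parts$train, classifier_spec("linear_svm"))
  repo <- evaluate_classifier(m, parts$test)
  expect_named(glance(repo)[1:2], c("classifier", "accuracy"))
  expect_s3_class(tidy(repo), "tbl_df")
  # plots build without error
  expect_s3_class(autoplot(res), "ggplot")
  expect_s3_class(plot_selection_frequency(res, highlight = c(1, 5)), "ggplot")
  expect_s3_class(autoplot(repo), "ggplot")
})

test_that("the pipeline reduces features and reports every classifier above chance", {
  sim <- fixture_d32()
  pipe <- cached("pipe32", function() {
    run_pipeline(sim, de = de_config(seed = 42),
                 classifiers = default_classifiers(), seed = 1)
  })
  expect_lt(pipe$de$best_k, 32L)
  expect_equal(nrow(pipe$comparison), 8L)
  # every family on DE-selected features beats chance + 0.2 (5 classes)
  accs <- vapply(pipe$reports_reduced, function(r) r$overall$accuracy, numeric(1))
  expect_true(all(accs > 1 / 5 + 0.2))
})
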