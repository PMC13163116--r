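#' Configuration for binary differential-evolution feature selection
#'
#' Bundles the optimizer parameters: population size `Pop`, generation count
#' `Gmax`, mutation factor `F`, crossover rate `Cr` and the sparsity weight
#' `alpha` that penalizes larger subsets. Defaults are the settings used for
#' 1024-dimensional deep-feature selection: a small fixed population of 10,
#' 200 generations, `F = 0.5`, `Cr = 0.7`, `alpha = 0.005`.
#'
#' @param pop_size Population size (>= 4; mutation draws three donors
#'   distinct from the target).
#' @param max_iter Number of generations.
#' @param mutation_factor Differential weight `F` (> 0).
#' @param crossover_rate Crossover probability `Cr` in `(0, 1]`.
#' @param alpha Sparsity penalty weight (>= 0).
#' @param seed Optional integer seed; fixes the whole run.
#' @param evaluator Inner fitness evaluator, a function
#'   `(X, y, idx) -> error in [0, 1]`; see [holdout_evaluator()].
#' @param fitness_form `"penalty"` (default): `error + alpha * k/d`.
#'   `"convex"`: the alternative convex blend `alpha * error +
#'   (1 - alpha) * k/d`, kept for comparison; with small `alpha` it weights
#'   the error term by `alpha` and drives masks towards emptiness, so the
#'   penalty form — under which `alpha` is literally a subset-size penalty —
#'   is the default.
#' @param cache Cache fitness values by mask bits (the evaluator is the
#'   dominant cost and the optimizer revisits masks).
#' @return A `de_config` list.
#' @export
de_config <- function(pop_size = 10, max_iter = 200, mutation_factor = 0.5,
                      crossover_rate = 0.7, alpha = 0.005, seed = NULL,
                      evaluator = holdout_evaluator(),
                      fitness_form = c("penalty", "convex"), cache = TRUE) {
  pop_size <- assert_count(pop_size, "pop_size", min = 4L)
  max_iter <- assert_count(max_iter, "max_iter", min = 1L)
  if (!is.numeric(mutation_factor) || mutation_factor <= 0) {
    abort("`mutation_factor` must be > 0.")
  }
  crossover_rate <- assert_prob(crossover_rate, "crossover_rate", lo_open = TRUE)
  if (!is.numeric(alpha) || alpha < 0) abort("`alpha` must be >= 0.")
  if (!is.function(evaluator)) abort("`evaluator` must be a function (X, y, idx) -> error.")
  structure(list(
    pop_size = pop_size, max_iter = max_iter,
    mutation_factor = as.numeric(mutation_factor),
    crossover_rate = crossover_rate, alpha = as.numeric(alpha),
    seed = if (is.null(seed)) NULL else as.integer(seed),
    evaluator = evaluator, fitness_form = match.arg(fitness_form),
    cache = isTRUE(cache)
  ), class = "de_config")
}

# Evaluator + penalty, with optional caching keyed on the mask bits.
make_fitness <- function(X, y, config) {
  d <- ncol(X)
  cache_env <- new.env(parent = emptyenv())
  n_evals <- 0L
  fit_fun <- function(bits) {
    key <- mask_key(bits)
    if (config$cache && !is.null(cache_env[[key]])) return(cache_env[[key]])
    k <- sum(bits)
    if (k == 0L) abort("Fitness is undefined on an empty mask; repair first.")
    err <- config$evaluator(X, y, which(bits == 1L))
    if (!is.finite(err) || err < 0 || err > 1) {
      abort(sprintf("Evaluator returned %s; errors must lie in [0, 1].", format(err)))
    }
    f <- switch(config$fitness_form,
      penalty = err + config$alpha * k / d,
      convex = config$alpha * err + (1 - config$alpha) * k / d
    )
    n_evals <<- n_evals + 1L
    if (config$cache) cache_env[[key]] <- f
    f
  }
  list(f = fit_fun, evals = function() n_evals)
}

#' Sparsity-penalized fitness of a feature mask
#'
#' Evaluates `error(X restricted to the mask) + alpha * k / d` (or the
#' convex alternative, per the config), where `error` is the inner
#' evaluator's misclassification proportion and `k` the number of selected
#' features.
#'
#' @param data Labelled feature tibble (feature columns plus `label`).
#' @param mask Length-`d` 0/1 vector with at least one 1.
#' @param config A [de_config()].
#' @return A single fitness value.
#' @examples
#' toy <- table_evaluator(c("10" = 0.2, "01" = 0.3, "11" = 0.1), d = 2)
#' cfg <- de_config(alpha = 0, evaluator = toy)
#' dat <- simulate_features(n_per_class = 5, d = 2, seed = 1)
#' mask_fitness(dat, c(1, 1), cfg)  # 0.1
#' @export
mask_fitness <- function(data, mask, config = de_config()) {
  parts <- check_feature_data(data)
  mask <- as.integer(mask)
  if (length(mask) != parts$d) abort("`mask` length must equal the feature dimension.")
  if (!all(mask %in% c(0L, 1L))) abort("`mask` must be a 0/1 vector.")
  if (sum(mask) == 0L) abort("`mask` must select at least one feature.")
  make_fitness(parts$X, parts$y, config)$f(mask)
}

#' Initialize a random binary population
#'
#' Draws a `pop_size x d` matrix of uniform random bits, repairs any all-zero
#' row (one random bit set), evaluates every row, and starts the best-so-far
#' bookkeeping.
#'
#' @param data Labelled feature tibble.
#' @param config A [de_config()]; its seed fixes the draw.
#' @return A `de_state` list with the population, fitness vector and best
#'   mask/fitness.
#' @export
init_population <- function(data, config = de_config()) {
  parts <- check_feature_data(data)
  fit <- make_fitness(parts$X, parts$y, config)
  with_seed_if(config$seed, {
    state <- new_de_state(parts$d, config, fit)
    class(state) <- "de_state"
    state
  })
}

new_de_state <- function(d, config, fit) {
  pop <- matrix(sample(0:1, config$pop_size * d, replace = TRUE),
                config$pop_size, d)
  pop <- t(apply(pop, 1L, repair_mask))
  fitness <- apply(pop, 1L, fit$f)
  best <- which.min(fitness)
  list(population = pop, fitness = fitness,
       best_mask = pop[best, ], best_fitness = fitness[best],
       generation = 0L, d = d, config = config, fit = fit)
}

#' Differential mutation of a population member
#'
#' Draws three donors `r1, r2, r3`, mutually distinct and distinct from the
#' target index, and forms `v = x_r1 + F * (x_r2 - x_r3)` clipped into
#' `[0, 1]` componentwise.
#'
#' @param state A `de_state` (from [init_population()] or [run_de()]).
#' @param target_index Index of the target member.
#' @param config A [de_config()].
#' @return A real-valued length-`d` mutant vector in `[0, 1]`.
#' @export
de_mutate <- function(state, target_index, config = state$config) {
  donors <- sample(setdiff(seq_len(config$pop_size), target_index), 3L)
  v <- state$population[donors[1], ] +
    config$mutation_factor *
    (state$population[donors[2], ] - state$population[donors[3], ])
  pmin(pmax(v, 0), 1)
}

#' Binomial crossover with strict binarization
#'
#' Forms the trial vector: coordinate `j` inherits the mutant value when
#' `runif() <= Cr` or `j == jrand` (a uniformly drawn forced index
#' guaranteeing at least one mutant coordinate), otherwise it keeps the
#' target bit. Mutant-inherited coordinates are binarized by the strict
#' threshold `value > 0.5 -> 1` (exactly 0.5 maps to 0). An all-zero trial is
#' repaired with one random bit.
#'
#' @param target Length-`d` 0/1 target mask.
#' @param mutant Length-`d` real mutant vector.
#' @param config A [de_config()].
#' @return A length-`d` 0/1 trial mask with at least one 1.
#' @export
de_crossover <- function(target, mutant, config = de_config()) {
  d <- length(target)
  if (length(mutant) != d) abort("`target` and `mutant` lengths differ.")
  jrand <- sample.int(d, 1L)
  take <- runif(d) <= config$crossover_rate
  take[jrand] <- TRUE
  trial <- as.integer(target)
  trial[take] <- as.integer(mutant[take] > 0.5)
  repair_mask(trial)
}

#' Greedy one-to-one selection
#'
#' The trial replaces the target iff its fitness is strictly smaller; ties
#' keep the incumbent.
#'
#' @param target_fitness,trial_fitness Finite fitness values.
#' @return `TRUE` to replace, `FALSE` to keep the target.
#' @export
de_select_step <- function(target_fitness, trial_fitness) {
  if (!is.finite(target_fitness) || !is.finite(trial_fitness)) {
    abort("Fitness values must be finite.")
  }
  trial_fitness < target_fitness
}

#' Run binary differential-evolution feature selection
#'
#' Maintains a population of binary masks and iterates mutation (weighted
#' donor difference, clipped to `[0, 1]`), binomial crossover with strict
#' binarization, and greedy selection for `max_iter` generations, minimizing
#' the sparsity-penalized classification error. Fully reproducible for a
#' fixed `config$seed`.
#'
#' @param data Labelled feature tibble (feature columns plus `label`).
#' @param config A [de_config()].
#' @return A `de_result` with the best-ever mask (`best_mask`, 0/1 vector),
#'   its fitness, the per-generation `history` tibble (best fitness, best
#'   `k`, mean fitness), the final population, pooled selection counts for
#'   [selection_frequency()], and a config echo. Methods: [tidy()],
#'   [glance()], [autoplot()].
#' @examples
#' sim <- simulate_features(n_per_class = 30, d = 8, informative = c(1, 2),
#'                          effect_size = 3, seed = 1)
#' res <- run_de(sim, de_config(max_iter = 20, seed = 1))
#' glance(res)
#' @export
run_de <- function(data, config = de_config()) {
  parts <- check_feature_data(data)
  fit <- make_fitness(parts$X, parts$y, config)
  d <- parts$d
  with_seed_if(config$seed, {
    state <- new_de_state(d, config, fit)
    pop <- state$population
    fitness <- state$fitness
    best_mask <- state$best_mask
    best_fitness <- state$best_fitness
    freq_counts <- numeric(d)
    history <- vector("list", config$max_iter)
    for (g in seq_len(config$max_iter)) {
      for (i in seq_len(config$pop_size)) {
        state$population <- pop
        v <- de_mutate(state, i, config)
        u <- de_crossover(pop[i, ], v, config)
        fu <- fit$f(u)
        if (de_select_step(fitness[i], fu)) {
          pop[i, ] <- u
          fitness[i] <- fu
          if (fu < best_fitness) {
            best_fitness <- fu
            best_mask <- u
          }
        }
      }
      freq_counts <- freq_counts + colSums(pop)
      history[[g]] <- tibble(
        generation = g, best_fitness = best_fitness,
        best_k = sum(best_mask), mean_fitness = mean(fitness)
      )
    }
    structure(list(
      best_mask = as.integer(best_mask), best_fitness = best_fitness,
      best_k = sum(best_mask), d = d,
      history = dplyr::bind_rows(history),
      population = pop, fitness = fitness,
      freq_counts = freq_counts,
      freq_slots = config$pop_size * config$max_iter,
      n_evals = fit$evals(),
      feature_names = parts$features,
      config = config
    ), class = "de_result")
  })
}

#' @export
print.de_result <- function(x, ...) {
  cat(sprintf(paste0("<de_result> d = %d, selected k = %d (%.2f%% reduction), ",
                     "best fitness = %.6f after %d generation(s)\n"),
              x$d, x$best_k, reduction_percentage(x$d, x$best_k),
              x$best_fitness, max(x$history$generation)))
  invisible(x)
}

#' Exhaustive-search oracle over all non-empty masks
#'
#' Enumerates every non-empty mask (requires `d <= 15`), evaluates each with
#' the identical fitness as [run_de()], and returns the global minimizer,
#' breaking fitness ties by the lexicographically smallest bit vector.
#'
#' @param data Labelled feature tibble with at most 15 feature columns.
#' @param config A [de_config()].
#' @return A list with `optimal_mask` (0/1 vector) and `optimal_fitness`.
#' @export
exhaustive_search <- function(data, config = de_config()) {
  parts <- check_feature_data(data)
  d <- parts$d
  if (d > 15L) {
    abort(sprintf(paste("Exhaustive search over 2^%d - 1 masks is refused;",
                        "it is intended as a small-dimension oracle (d <= 15).",
                        "Use run_de() instead."), d))
  }
  fit <- make_fitness(parts$X, parts$y, config)
  best_mask <- NULL
  best_fitness <- Inf
  best_key <- ""
  for (m in seq_len(2^d - 1L)) {
    bits <- as.integer(intToBits(m)[seq_len(d)])
    f <- fit$f(bits)
    key <- mask_key(bits)
    if (f < best_fitness || (f == best_fitness && key < best_key)) {
      best_fitness <- f
      best_mask <- bits
      best_key <- key
    }
  }
  list(optimal_mask = best_mask, optimal_fitness = best_fitness)
}

#' Per-feature selection frequency across a run's population history
#'
#' For one or more completed runs, returns the fraction of
#' (population member x generation) slots in which each feature's bit was 1,
#' pooled over the supplied runs — an estimate of the probability of each
#' feature being selected across the search.
#'
#' @param states A `de_result` or a list of `de_result`s sharing `d`.
#' @return A tibble with `feature`, `index` and `frequency` (in `[0, 1]`).
#' @export
selection_frequency <- function(states) {
  if (inherits(states, "de_result")) states <- list(states)
  ds <- vapply(states, `[[`, integer(1), "d")
  if (length(unique(ds)) != 1L) abort("All runs must share the same feature dimension.")
  counts <- Reduce(`+`, lapply(states, `[[`, "freq_counts"))
  slots <- sum(vapply(states, `[[`, numeric(1), "freq_slots"))
  tibble(
    feature = states[[1]]$feature_names,
    index = seq_len(ds[1]),
    frequency = as.numeric(counts / slots)
  )
}

#' Percentage reduction of the feature space
#'
#' `100 * (d - k) / d`, rounded to 2 decimals: e.g. reducing 1024 features
#' to 60 is a 94.14% reduction.
#'
#' @param d Original dimension.
#' @param k Selected subset size, `1 <= k <= d`.
#' @return The reduction percentage.
#' @export
reduction_percentage <- function(d, k) {
  d <- assert_count(d, "d")
  k <- assert_count(k, "k")
  if (k > d) abort("`k` must not exceed `d`.")
  round(100 * (d - k) / d, 2)
}

#' Restrict a feature table to a mask's selected columns
#'
#' @param data Labelled feature tibble.
#' @param mask Length-`d` 0/1 vector or a `de_result`.
#' @return The tibble with only the selected feature columns (original names
#'   preserved) and the `label` column.
#' @export
apply_mask <- function(data, mask) {
  if (inherits(mask, "de_result")) mask <- mask$best_mask
  parts <- check_feature_data(data)
  if (length(mask) != parts$d) abort("`mask` length must equal the feature dimension.")
  keep <- parts$features[mask == 1L]
  data[c(keep, "label")]
}
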