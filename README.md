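# bdefs

Binary differential-evolution feature selection for high-dimensional deep
image features, with a transfer-learning feature extractor and a
multi-classifier evaluation harness.

## The problem

Histopathological image classifiers (for example, distinguishing lung
adenocarcinoma, lung squamous cell carcinoma, benign lung, colon
adenocarcinoma and benign colon tissue) typically work from deep features: a
lightweight convolutional backbone is frozen, each image is pooled into a
fixed-length vector, and a small trainable head maps it to a compact
representation — here a 1024-dimensional vector `z2`. Those 1024 dimensions
are redundant: most classifiers run an order of magnitude faster, with
little accuracy cost, on a well-chosen small subset. Choosing that subset is
a combinatorial search over 2^1024 masks, which this package attacks with a
binary variant of differential evolution (DE).

`bdefs` is for researchers who want the complete pipeline — extraction,
wrapper selection, benchmark — as composable, tibble-in/tibble-out R
functions, plus the analytics (selection frequency, exhaustive oracle,
before/after comparison tables) to validate each stage.

## The method

A feature subset is a binary mask `x ∈ {0,1}^d` (bit `j` keeps feature `j`).
Each candidate is scored by a sparsity-penalized wrapper fitness

    F(x) = Error(X restricted to x, y) + α · |x| / d

where `Error` is the misclassification proportion of a fast inner classifier
(by default nearest-centroid on a stratified 80/20 holdout at a fixed
internal seed) and `α = 0.005` penalizes subset size. DE maintains a
population of `Pop = 10` masks for `Gmax = 200` generations; each target
`x_i` undergoes

* **mutation** — three distinct donors `r1, r2, r3 ≠ i`:
  `v_j = x_{r1,j} + F·(x_{r2,j} − x_{r3,j})`, clipped into `[0, 1]`,
  with `F = 0.5`;
* **crossover** — coordinate `j` takes the mutant value when
  `rand ≤ Cr = 0.7` or `j = jrand` (a forced index), binarized strictly
  (`> 0.5 → 1`); all-zero trials are repaired with one random bit;
* **selection** — the trial replaces the target iff its fitness is strictly
  smaller.

The surrounding harness provides a stratified 65/15/20 split (seed 42),
eight classifier families (medium/wide MLPs, linear/quadratic/cubic SVMs,
bagged trees, gradient-boosted trees, AdaBoost stumps) and full multiclass
reports: accuracy, macro precision/recall/F1, per-class one-vs-rest metrics,
macro AUC, balanced accuracy, Cohen's kappa, Wald 95% half-widths, and
prediction-time speed-ups.

## Worked example

```r
library(bdefs)

# synthetic stand-in for a deep-feature matrix: 5 classes, 32 features,
# 4 of them carrying class signal
sim <- simulate_features(n_per_class = 100, n_classes = 5, d = 32,
                         informative = c(1, 6, 10, 21), effect_size = 3,
                         seed = 7)

res <- run_de(sim, de_config(seed = 42))
res
#> <de_result> d = 32, selected k = 8 (75.00% reduction), best fitness = 0.001250 after 200 generation(s)
glance(res)
#> # A tibble: 1 × 6
#>   best_fitness     k     d reduction_percentage generations n_evals
#>          <dbl> <int> <int>                <dbl>       <int>   <int>
#> 1      0.00125     8    32                   75         200      57
```

The selector kept 8 of 32 features (a 75% reduction); the best fitness
0.00125 is a zero holdout error plus the sparsity penalty `0.005 · 8/32`.
`tidy(res)` lists per-feature selection frequencies and
`plot_selection_frequency(res, highlight = c(1, 6, 10, 21))` shows the
planted columns dominating the search.

The full pipeline — split, select (leakage-safe: DE never sees the test
partition), classify on both feature spaces, compare:

```r
pipe <- run_pipeline(sim, de = de_config(seed = 42),
                     classifiers = default_classifiers()[c("medium_nn",
                                                           "quadratic_svm",
                                                           "bagged_trees")],
                     seed = 1)
pipe
#> <bdefs_pipeline> 32 -> 3 features (90.62% reduction)
#>     classifier accuracy_before accuracy_after accuracy_difference speed_up_label
#>      medium_nn            0.63           0.56               -0.07          1.20x
#>  quadratic_svm            1.00           0.96               -0.04          4.25x
#>   bagged_trees            0.97           0.91               -0.06          4.57x
```

Accuracy dips slightly on the reduced space while prediction speeds up —
the trade the selector is designed to expose. Image-based workflows start
from `simulate_images()` / `train_extractor()` / `extract_features()`
instead of `simulate_features()`; a shell entry point for every stage ships
in `inst/cli/bdefs`.

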