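---
title: "Methods: wrapper feature selection for deep image features"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: wrapper feature selection for deep image features}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(bdefs)
```

# The model

`bdefs` implements a three-stage hybrid pipeline for image classification
problems whose inputs are high-dimensional deep features, motivated by
five-class lung/colon histopathology but agnostic to the tissue domain.

**Extraction.** A frozen convolutional backbone maps a `224 × 224 × 3`
standardized image to `h ∈ R^{576 × H' × W'}`; global average pooling
collapses it to `z ∈ R^576`; a trainable head expands and compresses it:

* `z1 = ReLU(BN(W1 z + b1))`, `W1 ∈ R^{1536 × 576}`, dropout `p = 0.3`,
* `z2 = ReLU(BN(W2 z1 + b2))`, `W2 ∈ R^{1024 × 1536}`, dropout `p = 0.3`,
* `ŷ = Softmax(W3 z2 + b3)`, `W3 ∈ R^{C × 1024}`.

Only the head is trained (10 epochs, Adam at learning rate 0.001, batch 32,
cross-entropy); the backbone never changes, which
`backbone_checksum()` lets callers verify. The penultimate activation `z2`
is exported as the feature vector. Block order is Linear → BatchNorm → ReLU
→ Dropout, i.e. the composition `σ(BN(W·+b))` with dropout applied after
the activation.

**Selection.** A feature subset is a mask `x ∈ {0,1}^d`. Binary
differential evolution minimizes

$$F(x) = \mathrm{Error}(X_x, y) + \alpha \frac{|x|}{d},$$

with mutation `v = x_{r1} + F (x_{r2} − x_{r3})` clipped to `[0,1]`,
binomial crossover at rate `Cr` with a forced coordinate `jrand`, strict
binarization (`> 0.5 → 1`), and greedy one-to-one selection. Defaults:
population 10, 200 generations, `F = 0.5`, `Cr = 0.7`, `α = 0.005`.

**Evaluation.** Stratified 65/15/20 splitting at seed 42, eight classifier
families at standard hyperparameters, and reports built entirely from the
confusion matrix plus class-probability scores.

# Tunable parameters

| Parameter | Default | Meaning |
|---|---|---|
| `alpha` | 0.005 | penalty per selected feature, in units of error per (k/d); at `d = 1024` one extra feature must buy ~5e-6 less error |
| `pop_size` | 10 | small fixed population; keeps a 200-generation run near 2000 evaluations |
| `max_iter` | 200 | generations; the fitness trajectory typically flattens well before this on low-dimensional fixtures |
| `mutation_factor` | 0.5 | differential weight `F` |
| `crossover_rate` | 0.7 | probability a coordinate is inherited from the mutant |
| `dropout_p` | 0.3 | head dropout, both blocks |
| `effect_size` | 3 | class-mean separation (in noise SDs) on planted fixture columns |
| split | 65/15/20, seed 42 | stratified; an 80/10/10 protocol is the same code path with different fractions |

# Design choices where the design was open

**Fitness form.** Two formulations of the objective circulate: the additive
penalty `Error + α·k/d` and the convex blend `α·Error + (1−α)·k/d`. With
`α = 0.005` the convex form weights the error term by 0.005 and the
sparsity term by 0.995, which drives every search towards single-feature
masks regardless of accuracy; under the additive form `α` is literally a
small per-feature penalty, which matches its description as a subset-size
regularizer. The additive form is therefore the default and the convex form
is kept behind `fitness_form = "convex"` for comparison.

**Inner evaluator.** The classifier and validation protocol inside the
wrapper fitness are deliberately pluggable (`evaluator` is any function
`(X, y, idx) → error`). The default is a nearest-centroid linear classifier
on a stratified 80/20 holdout with a fixed internal seed: linear, O(n·k)
per evaluation, and — critically — a *deterministic* function of the mask,
so DE's greedy selection compares like with like and caching by mask bits
is sound. Fitness caching matters because DE revisits masks often; the
`n_evals` field of a result counts distinct evaluator calls.

**Empty-mask repair.** The error term is undefined on zero selected
columns, so any all-zero vector (at initialization or after crossover) has
one uniformly random bit set. This keeps the population size fixed rather
than discarding candidates.

**Donor and tie rules.** Donors `r1, r2, r3` are mutually distinct and
distinct from the target (the classic rand/1 scheme). Binarization is
strict (`exactly 0.5 → 0`). Selection ties keep the incumbent. Exhaustive
ties return the lexicographically smallest bit vector, making the oracle
deterministic.

**Leakage policy.** `run_pipeline()` runs DE on the training + validation
portion only, so the test partition never influences which features are
kept. The alternative ordering — select on all data, then split — is
available as `paper_faithful = TRUE` because published pipelines sometimes
apply a post-hoc split to an already-selected matrix; it leaks test
information into selection and is kept only for protocol reproduction.

**Selection frequency.** The per-feature frequency is pooled over
(population member × generation) slots of the supplied runs. Pooling over
generations of a single run is the finest granularity available without
rerunning; multiple runs can be pooled by passing a list.

**Aggregate F1.** The report's F1 is the unweighted (macro) mean of
per-class F1 values, not the harmonic mean of macro precision and macro
recall; the macro mean is the definition consistent with class-wise tables.

**Confidence interval.** The report's `ci_halfwidth` is the Wald 95%
interval on test accuracy, `1.96·sqrt(acc(1−acc)/n)` — documented rather
than matched to any external table, since published CI recipes for this
kind of report are often unstated.

**AUC.** Macro one-vs-rest over predicted class probabilities (SVM scores
are converted to probabilities by the standard calibration in `e1071`).
Models without scores report `NA` rather than a fabricated value.

# The synthetic generator

`simulate_features()` emulates the *statistical shape* of a deep-feature
matrix with a known answer: informative columns are class-conditional
Gaussians with class `k` centred at `effect_size · k` (SD `noise_sd`),
nuisance columns are standard Gaussians independent of the class. The
canonical test fixtures are:

* `d = 8`, two planted columns, two classes, 50 samples per class — small
  enough for the exhaustive oracle over all 255 non-empty masks;
* `d = 32`, four planted columns (indices 1, 6, 10, 21), **five classes**
  (the number of tissue classes in the motivating problem), 100 samples per
  class, `effect_size = 3`. With five classes a single planted column
  misclassifies a few percent of holdout samples, so complementary planted
  columns genuinely reduce the error and the selector is rewarded for
  recovering several of them — with two classes a lone column is already
  perfect and sparsity pressure correctly prunes the rest.

Because planted columns share the same mean pattern, they are redundant
replicates: recovering *all* four is not optimal under the penalty, and
recovery counts of 2–4 across seeds are the expected behaviour, not a
failure of the search.

`simulate_images()` writes procedural stripe/blob textures, one texture
family per class. These are class-separable inputs for smoke-testing the
extraction plumbing — they are **not** histology simulants. Passing tests
on these fixtures demonstrates the mechanics (shapes, freezing, learning
dynamics, separability) and nothing about stain variation, scanner
artifacts, tissue morphology, or real-data accuracy.

# Numerical choices

* BatchNorm uses biased batch variance, `eps = 1e-5`, running statistics
  with momentum 0.1 (used in eval mode).
* Dense layers are He-initialized; Adam uses `β1 = 0.9`, `β2 = 0.999`,
  `eps = 1e-8`.
* The random-projection backbone is three strided ReLU convolutions
  (8×8/stride 8, then two 3×3/stride 2), He-initialized from the config
  seed and never trained. `input_side` must be at least 56 so the final map
  retains positive spatial extent. With `pretrained = FALSE` this makes the
  whole pipeline runnable offline; `pretrained = TRUE` (ImageNet weights)
  requires external files this package does not bundle and errors with a
  clear message.
* The exhaustive oracle refuses `d > 15` (2^d blow-up); it exists to
  certify small-dimension optima, not as an alternative selector.
* A single user seed fans out to stage seeds by fixed offsets; every
  stochastic function also accepts its own seed and restores the caller's
  RNG state.

# Problem sizes used by the test suite

The suite exercises the d = 8 oracle fixture (10 DE runs of 60
generations), the d = 32 recovery fixture (one 200-generation run at
defaults, reused across tests), a 12-image 64-pixel extraction smoke test
with a 96/64 head, 1000 random confusion instances for metric equivalence,
and a 10,000-prediction chance-level kappa check. These sizes make every
statistical assertion stable at fixed seeds while keeping a full run in
well under a minute.

# Known limitations

* Published headline numbers for the motivating 25,000-image problem
  (≈0.98 test accuracy, order-of-magnitude prediction speed-ups at
  1024 → 60 features) depend on that dataset, pretrained backbone weights
  and the authors' hardware; nothing at fixture scale estimates them, and
  the package makes no claim of matching them numerically.
* Prediction times (and therefore speed-ups) are wall-clock measurements:
  reported for context, hardware-dependent, and excluded from assertions.
* The selected subset size `k` varies across seeds; the package reports
  `k` and the reduction percentage per run rather than claiming a canonical
  value.
* Balanced-accuracy and kappa values published alongside class-wise tables
  elsewhere are not always reproducible from those tables under the
  standard definitions used here; this package asserts only its own
  definitions (balanced accuracy = macro sensitivity,
  `κ = (p_o − p_e)/(1 − p_e)`).
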