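---
title: "Methods: mixture QSAR for nanoparticle–heavy-metal cytotoxicity"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: mixture QSAR for nanoparticle–heavy-metal cytotoxicity}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(mixqsar)
```

This vignette documents the statistical methodology implemented in
**mixqsar**, the assumptions behind each stage, every tunable parameter with
its default and rationale, what the synthetic-data generator does and does
not emulate, and the numerical choices made in the implementation —
including where the package deliberately departs from common practice in the
mixture-QSAR literature and why.

## 1. Scientific setting and modeling assumptions

The package models the *in vitro* cytotoxicity (cell viability) of binary
mixtures of a co-exposed nanomaterial (e.g. nano-TiO~2~ at a fixed
concentration) with a panel of heavy-metal compounds tested over a
concentration series. The workflow rests on three assumptions:

1. **Electronic structure determines reactivity.** Each pure component is
   characterized by eight conceptual-DFT descriptors: the frontier orbital
   energies $E_{HOMO}$ and $E_{LUMO}$, and quantities derived from them via
   the Koopmans approximations — ionization potential $IP = -E_{HOMO}$,
   electron affinity $EA = -E_{LUMO}$, electronegativity
   $\chi = (IP + EA)/2$, chemical hardness $\eta = (IP - EA)/2$ — plus the
   total molecular energy and the adsorption energy of the component on the
   nanomaterial surface. `derive_electronic_descriptors()` computes the four
   derived quantities; supplying them by hand is not allowed, so the
   identities always hold exactly. A consequence worth noting: the eight
   descriptors span only a **rank-4** linear space (four of them are linear
   combinations of $E_{HOMO}$ and $E_{LUMO}$), which matters for linear
   methods (Section 4.1).

2. **Concentration addition at the descriptor level.** A mixture's
   descriptor vector is the concentration-weighted sum of its components'
   vectors,
   $$D_{mix} = \sum_i D_i\, x_i ,$$
   computed by `mix_descriptors()`. The `weighting` argument selects what
   $x_i$ is: `"fraction"` (the default) uses mole fractions
   $x_i = c_i / \sum_j c_j$, so $D_{mix}$ is a convex combination on the
   scale of the pure-component descriptors; `"concentration"` uses the raw
   molar concentrations, so $D_{mix}$ scales with total dose. The fraction
   mode is the default because it keeps the mixture descriptor on a
   physically interpretable (eV / kcal-like) scale and makes descriptors of
   different dose levels comparable; the raw mode is retained because it
   encodes total dose directly into the descriptors, which some designs
   rely on. This choice is exposed, not hidden, because published
   descriptions of concentration-addition descriptor weighting are
   frequently ambiguous between the two readings.

3. **Viability from plate absorbance.** Cell viability is the
   blank-corrected absorbance ratio
   $$S = \frac{A_{exp} - A_{blank}}{A_{control} - A_{blank}},$$
   implemented in `compute_viability()` with an explicit error when the
   control does not exceed the blank. Values slightly above 1 (hormesis or
   plate noise) are allowed and not clipped.

## 2. Study design and data flow

The canonical design is a panel of 8 variable components, each mixed with
the fixed co-component and tested at 9 concentrations (multiples of a
per-component step), giving $8 \times 9 = 72$ mixture samples. The design
matrix has one row per sample (the 8 mixed descriptors) and viability as
the response. `build_design_table()` assembles it.

All modeling uses a random 3:1 train:test split (`split_train_test()`,
`ratio = 3`): 54/18 on the pooled data, 27/9 within a category. The test
count is `round(n / (ratio + 1))`, sampled without stratification — the
split is random by design, matching standard practice, and stratified
variants can be built by splitting per category.

## 3. Component categorization

`kmeans_components()` clusters the **components** (8 rows), not the 72
mixture samples, on their standardized descriptors. Mixtures then inherit
the category of their variable component (`assign_mixtures()`). Clustering
at the component level is the only coherent option under concentration
addition: all 9 samples of a component differ only in dose weighting, so
sample-level clustering would largely rediscover the dose axis.

**Numerical choice — exact k-means for tiny panels.** Lloyd's algorithm
with random restarts is a local optimizer; on a panel of 8 points even the
best of all data-point pair initializations misses the global 2-partition
optimum on some inputs (we observed roughly 1 failure in 300 random
panels). Since the number of bipartitions of $n \le 16$ points is at most
$2^{15}$, the package **enumerates all bipartitions** when $k = 2$ and
$n \le 16$ and returns the certified global optimum. For larger problems it
falls back to `stats::kmeans` (Lloyd, `nstart` restarts). This makes the
categorization deterministic and restart-independent exactly where the
canonical design lives.

Parameters: `k = 2` (two reactivity classes, e.g. soft/electron-accepting
vs hard/surface-binding), `scale = TRUE` (descriptors have incommensurate
units; zero-variance columns are mapped to 0 rather than NaN),
`n_restarts = 10` (only used on the Lloyd fallback path).

## 4. Regression backends

Three backends are available through `fit_backend()`; all return a
`qsar_model` with a common `predict()` interface and a normalized
importance vector.

### 4.1 Partial least squares

PLS regression (via **mixOmics**) handles the collinear descriptor block
directly. The number of latent components is chosen by leave-one-out
$Q^2$ over `1:rank(X)` in `fit_pls()`. Because the eight descriptors are
rank-4 (Section 1), the component count is **capped at the design rank**,
with a warning; requesting more would make the inner regressions singular.
A one-column design degenerates to simple least squares, which the package
computes directly (`pls_univariate`) since a 1-component PLS model on one
predictor *is* ordinary least squares.

### 4.2 Random forest

`randomForest` with default `mtry`/node-size; the tuned hyperparameters
are the ensemble size `n_estimators` and the RNG seed `random_state`
(Section 5). Importance is `IncNodePurity`, normalized to sum to 1.

### 4.3 AdaBoost.R2

AdaBoost.R2 (squared loss) is implemented in the package
(`adaboost_r2()`) on top of **rpart** base learners, because no maintained
CRAN implementation of the R2 variant for regression exists. The base
learner mirrors the common depth-3 regression-tree weak learner
(`maxdepth = 3`, `cp = 0`, `minsplit = 5`). Each round draws a weighted
bootstrap sample, computes per-sample losses $(|e_i|/\max_j |e_j|)^2$,
stops if the weighted loss $\bar L \ge 0.5$ or the fit is perfect, and
updates weights by $w_i \leftarrow w_i \beta^{1 - L_i}$ with
$\beta = \bar L / (1 - \bar L)$. Prediction is the **weighted median** of
the tree predictions with weights $\log(1/\beta_t)$. The implementation
was cross-checked against scikit-learn's
`AdaBoostRegressor(loss = "square")` on matched simulations (mean test
$R^2$ 0.742 vs 0.729 over 10 replicates) — agreement to within seed-level
noise, since the two code bases cannot share RNG streams.

## 5. Hyperparameter grid search and its objective

`grid_search_fit()` searches the Cartesian grid
`estimator_range × seed_range` (defaults in `run_config()`: `1:30 × 1:10`;
the literature-scale grid is `1:100 × 1:100`) and refits the best cell.
Ties go to the smallest `(n_estimators, random_state)` in that order.

Two objectives are provided, and the difference is the single most
important methodological caveat in the package:

- `objective = "test_r2"` (default) selects the cell maximizing $R^2$ on
  the **test partition**. This reproduces the selection procedure common
  in the applied mixture-QSAR literature, including treating the RNG seed
  as a tunable hyperparameter. It is **optimistically biased**: the test
  set participates in model selection, so "test" $R^2$ is no longer an
  unbiased estimate of generalization error, and tuning the seed amounts
  to selecting a lucky bootstrap. The package implements it faithfully so
  that published-style results can be reproduced and *audited*.
- `objective = "cv"` selects by $k$-fold cross-validated $R^2$ on the
  training partition only (`cv_folds = 5`), leaving the test set untouched
  until final evaluation. This is the honest mode and the recommended one
  for new work.

The default is the literature-style mode because the package's first job
is to reproduce that workflow; the documentation flags the bias rather
than silently "fixing" the procedure.

**Reduced default grid sizes.** `run_config()` defaults to a
`30 × 10` grid and 10 Y-randomization iterations rather than the
literature-scale `100 × 100` and 50. This is purely a runtime choice for a
package default (a full-scale run multiplies grid cost ~33×); the
full-scale settings are one argument away
(`estimator_range = 1:100, seed_range = 1:100, yrand_n_iter = 50`).

## 6. Descriptor selection

After the pooled grid search, `select_features()` retains descriptors with
normalized importance **strictly greater than** `threshold = 0.1` and
re-runs the grid search on the reduced design. If nothing passes the
threshold (e.g. a flat importance profile), the single most important
descriptor is kept, with a warning — a model must retain at least one
predictor. Cross-category models (Section 7) skip selection: their fit is
too poor for importance ranks to be meaningful.

## 7. Model tracks A–D and the pipeline

`run_pipeline()` fits, on one dataset:

- three **pooled** models (PLS, random forest, AdaBoost.R2) on the 54/18
  split, with grid search and descriptor selection;
- per-category models **A** and **B**: random forests on each category's
  27/9 split (split seed offset by category index so the two splits are
  independent);
- cross-category models **C** and **D**: the model trained on one
  category's training partition evaluated on the *other* category's test
  partition — a deliberate extrapolation probe that is expected to fail,
  quantifying how category-specific the structure–toxicity relationship
  is.

`compare_models()` ranks all tracks by (number of validation criteria
passed, then test $R^2$).

## 8. Validation battery

`validate_model()` computes, for each track:

- $R^2 = 1 - SSE/SST$ on train and test (the coefficient of
  determination, **not** squared Pearson correlation — they differ for
  biased predictions) and RMSE;
- **$Q^2_{LOO}$**: leave-one-out on the **training partition**, refitting
  with the hyperparameters **fixed** at the selected values. Re-running
  the full grid search inside each LOO fold would be nested selection —
  correct but ~50× slower and not what the reported statistic means in the
  source literature; the fixed-hyperparameter convention is stated here so
  the number is interpreted correctly.
- **Y-randomization**: the response is permuted jointly across train+test,
  the **full** selection procedure (grid search, and PLS component
  selection on the PLS track) is re-run on the permuted data, and the
  resulting train $R^2$ / $Q^2_{LOO}$ are averaged over `n_iter`
  permutations. Re-running the whole procedure is essential: permutation
  tests must subject the null data to the same optimization pressure as
  the real data, otherwise the leak of Section 5 goes undetected. The
  reported `r2_yrand`/`q2_yrand` are **means** over permutations (the
  conservative criterion would be the maximum; per-iteration vectors are
  returned so users can apply either).
- external predictivity $Q^2_{F1}, Q^2_{F2}, Q^2_{F3}$ (differing in the
  reference mean — training mean, test mean, and training mean with
  training-size normalization, respectively) and **Lin's concordance
  correlation coefficient** (CCC).

`evaluate_criteria()` applies the standard acceptance thresholds, all
strict inequalities: $Q^2_{LOO} > 0.5$, $R^2_{yrand} < 0.5$,
$Q^2_{yrand} < 0.5$, $RMSE_{test} < 0.2$, $R^2_{test} > 0.6$,
$Q^2_{F1/F2/F3} > 0.5$, $CCC > 0.85$.

## 9. Applicability domain (Williams plot)

`williams_report()` computes leverages
$h_i = x_i (X^\top X)^{-1} x_i^\top$ against the **training** design and
standardized residuals (residual / training RMSE). A sample is in-domain
iff $h_i \le h^* = 3(p + 1)/n$ **and** $|r_i| \le 2.5$.

Three conventions are made explicit because they change the numbers:

- $p$ is the number of **retained** descriptors after selection, not the
  original eight — the domain is defined in the space the model actually
  uses. With the canonical sizes this gives the four critical leverages
  $h^* = 3\cdot5/54 \approx 0.2778$, $3\cdot6/54 \approx 0.3333$,
  $3\cdot6/27 \approx 0.6667$, $3\cdot5/27 \approx 0.5556$.
- The design is used **as-is** (no intercept column, no centering) by
  default, matching the descriptor-space convention; `center = TRUE` is
  available for the mean-centered variant.
- When $X^\top X$ is singular (collinear retained descriptors), the
  Moore–Penrose pseudo-inverse (`MASS::ginv`) is used, with a warning;
  leverages then sum to the design rank rather than the column count.

Note that for very small training sets $h^*$ can exceed 1 while
$h_i \le 1$ always holds for rows of the training design — in that regime
no training sample can be flagged on leverage, which is a property of the
$3(p+1)/n$ rule itself, not a defect of the implementation.

## 10. The synthetic-data generator

`simulate_mixture_study()` (configured by `synthetic_config()`) generates
a complete study with known ground truth. What it **emulates**:

- a panel of 8 components drawn from **2 latent descriptor clusters**
  (Gaussian around cluster centroids in $(E_{HOMO}, E_{LUMO},
  E_{molecular}, E_{ads})$, with derived descriptors computed — never
  sampled — so the Koopmans identities hold; draws with
  $E_{LUMO} < E_{HOMO}$ are rejected and resampled);
- a fixed co-component (nano-TiO~2~-like, 25 µmol/L) in every mixture;
- 9-point concentration series with per-component step sizes drawn from
  {5, 10, 30, 100} µmol/L, emulating potency-matched dose ranges;
- viability following a four-parameter logistic **decline in log total
  dose**, whose log-potency is a linear function of the mixed descriptors:
  $m = a_g + w_g^\top D_{mix}$ with cluster-specific weights $w_g$ loading
  on hardness and adsorption energy with **opposite orientation** in the
  two clusters — so a single pooled linear model is misspecified while
  per-category models are well-specified, which is the qualitative
  phenomenon the category workflow is designed to detect;
- Gaussian plate noise (`noise_sd = 0.05`) and truncation to $[0, 1.2]$
  (non-negative viability, mild hormesis allowed);
- absorbances consistent with the viability equation
  (`generate_absorbances()` inverts the blank-corrected ratio exactly with
  control 0.9, blank 0.1), so the plate → viability path can be tested
  end-to-end.

What it does **not** emulate: real quantum-chemical correlation structure
beyond the Koopmans identities, chemical interaction (synergy/antagonism —
concentration addition is assumed in both generator and model, so the
generator cannot falsify that assumption), plate-position effects,
replicate structure, or measurement error in the descriptors themselves.

Default parameter values are design-time calibration choices (centroids
at chemically plausible frontier-orbital energies; logistic midpoints
placed inside the simulated dose ranges) and are **study conditions**, not
tuning knobs: they were fixed before the validation thresholds were ever
evaluated against generator output.

## 11. Reproducibility

Every stochastic step takes an explicit seed (`synthetic_config(seed=)`,
`split_seed`, `cluster_seed`, `random_state`, `yrand_seed`), and
`run_pipeline()` is a pure function of its `run_config()`. The
command-line interface (`inst/cli/mixqsar.R`) exposes `simulate` and `run`
subcommands over the same functions, and `write_run_report()` serializes
all tables and a JSON summary for archival.
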