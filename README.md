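# mixqsar

Mixture QSAR modeling of nanoparticle–heavy-metal cytotoxicity in R.

## The problem

Engineered nanomaterials such as nano-TiO₂ rarely occur alone in the
environment; they co-occur with heavy-metal pollutants, and the toxicity of
the *mixture* is what cells actually experience. Testing every
metal × nanoparticle × dose combination is infeasible, so mixture QSAR
(quantitative structure–activity relationship) models predict mixture
cytotoxicity from the electronic structure of the pure components.

**mixqsar** implements that workflow end to end:

- **Descriptors** — eight conceptual-DFT descriptors per component:
  E_HOMO, E_LUMO, and their Koopmans derivatives (ionization potential
  IP = −E_HOMO, electron affinity EA = −E_LUMO, electronegativity
  χ = (IP+EA)/2, hardness η = (IP−EA)/2), plus molecular energy and the
  adsorption energy on the nanomaterial.
- **Mixing** — concentration addition at the descriptor level,
  D_mix = Σᵢ Dᵢ·xᵢ, with mole-fraction (default) or raw-concentration
  weighting; viability from plate absorbance,
  S = (A_exp − A_blank)/(A_control − A_blank).
- **Categorization** — k-means clustering of the *components* (exact,
  certified-global solution for k = 2 on small panels), with mixture
  samples inheriting their component's category.
- **Models** — partial least squares, random forest, and a built-in
  AdaBoost.R2, each with a two-axis grid search
  (`n_estimators × random_state`) and importance-threshold (> 0.1)
  descriptor selection; pooled models plus per-category models A/B and
  cross-category extrapolation probes C/D.
- **Validation** — R² = 1 − SSE/SST, RMSE, leave-one-out Q², full-procedure
  Y-randomization, external Q²_F1/F2/F3, Lin's concordance correlation, and
  the standard pass/fail criteria battery.
- **Applicability domain** — Williams-plot analysis with leverage
  h = x(XᵀX)⁻¹xᵀ, critical leverage h* = 3(p+1)/n (p = retained
  descriptors), and ±2.5 standardized-residual limits.
- **Synthetic data** — a generator with known ground truth (two latent
  reactivity clusters with opposite descriptor–potency orientation) for
  structure-recovery studies.

The grid-search default reproduces the selection procedure common in the
applied literature (maximize *test* R², seed treated as a hyperparameter),
which is optimistically biased; an honest cross-validated objective is
available via `objective = "cv"`. See the methods vignette
(`vignettes/mixture-qsar-methods.Rmd`) for all conventions and caveats.

## Worked example

Descriptors for a pure component — only E_HOMO/E_LUMO and the two energies
are supplied; the Koopmans quantities are derived:

```r
library(mixqsar)
cu <- derive_electronic_descriptors("CuCl2", homo = -7.28, lumo = -4.43,
                                    molecular_energy = -2260.1,
                                    adsorption_energy = -1.27)
round(cu[, c("ionization_potential", "electron_affinity",
             "electronegativity", "hardness")], 3)
#>   ionization_potential electron_affinity electronegativity hardness
#> 1                 7.28              4.43             5.855    1.425
```

A complete run on a simulated study (8 metals × 9 concentrations = 72
mixture samples, nano-TiO₂ fixed at 25 µmol/L), fitting all seven model
tracks:

```r
cfg <- run_config(synthetic = synthetic_config(seed = 42),
                  estimator_range = 1:30, seed_range = 1:10,
                  yrand_n_iter = 10)
report <- run_pipeline(cfg)
report
#> Mixture-QSAR run: 7 model track(s)
#>   component categories: category 1: 4; category 2: 4
#>     model n_train n_test r2_test rmse_test q2_loo   ccc criteria_passed
#>   model_A      27      9   0.964    0.0373  0.860 0.981               9
#>  adaboost      54     18   0.946    0.0422  0.856 0.973               9
#>        rf      54     18   0.932    0.0474  0.891 0.966               9
#>   model_B      27      9   0.914    0.0585  0.874 0.951               9
#>       pls      54     18   0.875    0.0642  0.875 0.945               9
#>   model_C      27      9   0.693    0.1104  0.898 0.796               8
#>   model_D      27      9  -0.203    0.2151  0.840 0.210               3
```

The pattern is the one the category workflow is built to expose: the
per-category random forests (model_A, model_B) and the pooled ensembles
pass all nine validation criteria, while the cross-category probes
(model_C, model_D — trained on one reactivity category, evaluated on the
other) degrade sharply, because the descriptor–toxicity relationship is
category-specific.

Descriptor selection and the applicability domain for the pooled random
forest:

```r
rf <- report$models$rf
rf$retained
#> [1] "electron_affinity" "electronegativity" "hardness" "molecular_energy"
round(rf$ad$h_star, 4)
#> [1] 0.2778          # h* = 3(p+1)/n = 3*5/54
rf$ad$n_outside
#> train  test
#>     0     2
```

A command-line interface wrapping the same functions ships in
`inst/cli/mixqsar.R` (`simulate` and `run --config run.yaml` subcommands).

## Package layout

- `R/descriptors.R` — descriptor derivation, mixing, viability
- `R/synthetic-data.R` — ground-truth study generator
- `R/clustering.R` — component k-means (exact for k = 2, n ≤ 16) and
  category assignment
- `R/backends.R`, `R/modeling.R` — PLS / random forest / AdaBoost.R2,
  splits, grid search, descriptor selection
- `R/validation.R` — metric battery, Y-randomization, criteria
- `R/appdomain.R` — leverages, Williams report
- `R/pipeline.R` — `run_config()`, `run_pipeline()`, report writing
- `vignettes/mixture-qsar-methods.Rmd` — full methods documentation
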