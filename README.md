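# grud

Classification of irregularly sampled multivariate time series with
missing values — the regime of ICU vitals-and-labs data, where *when and
how often* a variable is measured ("informative missingness") can carry as
much signal as the measured values.

The package implements the GRU-D recurrent cell and everything needed to
study it at desk scale:

* the masking / time-interval data model: per sample, measurements
  `x (T x D)`, observation mask `m`, shared stamps `s` (first stamp 0), and
  per-variable elapsed times `δ` from the causal recursion
  `δ[t,d] = s[t] − s[t−1] + (1 − m[t−1,d]) δ[t−1,d]`;
* the GRU-D cell: trainable decay rates
  `γ = exp{−max(0, W_γ δ_t + b_γ)} ∈ (0,1]`, a *diagonal* input decay that
  relaxes a stale measurement toward the training mean
  (`x̂ = m x + (1−m)(γ_x x_last + (1−γ_x) x̃)`), a dense hidden-state decay
  `ĥ = γ_h ⊙ h`, and masks fed to all gates through `V` matrices;
* the three standard baselines on the same GRU backbone: mean imputation,
  forward (carry-last) imputation, and concatenation of `[x; m; δ]`
  (with the published mask-less and interval-less ablations);
* hand-written backpropagation through time (no deep-learning runtime is
  used), Adam, batch-norm + dropout head, per-sequence recurrent dropout,
  early stopping on validation AUC, and parameter-budget matching across
  variants;
* a synthetic-data generator with a knob `ρ` that controls the Pearson
  correlation between per-sample missing rates and the binary label while
  holding the overall missing rate fixed;
* evaluation: rank-based AUC, stratified k-fold cross-validation, online
  (truncated-prefix) prediction curves, and decay-interpretation reports;
* long-format CSV I/O, JSON configs/checkpoints, and a CLI.

See `vignettes/grud-methods.Rmd` for the model, the design decisions and
the generator's stated world.

## Worked example

Generate strongly informative missingness (`ρ = 0.9`), train GRU-D, and
score held-out samples:

```r
library(grud)
gen <- generate_synthetic(synthetic_config(n_samples = 600, rho = 0.9,
                                           seed = 1))
gen$report
#> <generation_report> overall missing rate 0.398
#>   per-variable |corr(missing rate, label)|:  0.54 0.56 0.62 0.67 0.71
#>   0.75 0.78 0.79 0.74 0.73

parts <- train_valid_test_split(gen$dataset, seed = 2)
model <- fit_model(parts$train, parts$valid,
                   model_config(mode = "grud", seed = 3))
model
#> <grud_model> mode = grud, H = 16, best validation AUC = 0.9994
auc(predict(model, parts$test), parts$test$labels)
#> [1] 1
```

The generator placed moderate per-variable missing-rate/label correlations
(0.54–0.79) while the measured values carry only a weak signal
(value-only AUC ≈ 0.6): the near-perfect test AUC is the model reading the
missingness itself. Rerun with `rho = 0` and the same pipeline lands near
the value-only AUC instead.

Inspect what the model learned about each variable's staleness:

```r
decay_report(model)
#> <decay_report>
#>   mean |W_gh| per variable:
#>     v1     v2     v3     v4     v5     v6     v7     v8     v9    v10
#> 0.0163 0.0227 0.0269 0.0258 0.0289 0.0292 0.0332 0.0314 0.0311 0.0285
```

The same experiment across all four variants and a ρ grid (the package's
core synthetic study) is one call —
`informative_missingness_sweep(rho_grid = c(0, 0.9), seeds = 1:5)` — or via
the CLI:

```sh
Rscript -e 'grud::run_cli()' sweep --rho-grid 0,0.9 --seeds 1,2,3 \
    --out sweep.csv
```

CLI subcommands: `generate`, `train`, `evaluate`, `online-curve`,
`decay-report`, `sweep` (see `inst/cli/grud`).

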