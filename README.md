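# missboost

Imputation of missing values in mixed-type tabular biomedical data by an
iterative, column-wise gradient-boosted-tree algorithm — plus everything
needed to decide whether to trust it: baseline imputers, an MCAR
masking/RMSE benchmark harness, missingness-exploration backends, feature
ranking, and response-excluded cross-validated prediction.

Wide clinical tables (laboratory panels extracted from electronic health
records are the motivating case) combine strong cross-feature correlation
with heavy missingness. missboost exploits that correlation: after an
initial mean fill, columns are visited in order of increasing missingness
and each incomplete column is re-imputed by a gradient-boosted tree model
(xgboost, 100 trees per fit) trained on the other columns' current values,

    X_miss(s)  <-  predict( boost( y_obs(s) ~ X_obs(s) ) ),

sweeping until a convergence delta

    Δ_cont = Σ(X_new − X_old)² / Σ X_new²   (continuous cells)
    Δ_cat  = #changed / #missing            (categorical cells)

first *increases* (the previous iterate is returned) or a sweep cap is
reached. Mean/median, k-nearest-neighbour, soft-thresholded-SVD matrix
completion and deterministic chained-equations imputers provide the
comparison set, all behind one `imputer_spec()` interface and one
contract: observed cells are never modified and every completion is a
pure function of `(data, spec, seed)`.

Tables are plain tibbles — numeric columns continuous, factor columns
categorical, `NA` missing — so everything composes with the tidyverse;
results carry `tidy()`, `glance()` and `autoplot()` methods.

## Worked example

```r
library(missboost)

# a synthetic 500 x 10 low-rank table with known ground truth
fx <- standard_suite(seed = 1)$rank2

# hide 20% of the cells completely at random, then impute
mk <- mask_mcar(fx$truth, rate = 0.2, seed = 7)
completed <- impute_boosted(mk$masked, seed = 1)
glance(completed)
#> # A tibble: 1 × 6
#>   method  n_imputed n_sweeps converged_reason delta_continuous delta_categorical
#>   <chr>       <int>    <int> <chr>                       <dbl>             <dbl>
#> 1 boosted      1000        7 delta_increased          0.000888                 0

# error on the deliberately hidden cells, against the stored truth
rmse_on_masked(mk$plan, completed)
#> [1] 0.2423257
rmse_on_masked(mk$plan, impute_simple(mk$masked, "mean"))
#> [1] 1.143437
```

The boosted imputer recovered the hidden cells with roughly a fifth of the
error of mean imputation: the table's columns share a rank-2 latent
structure, and the per-column models learn it. The `glance()` line shows
the run took 7 sweeps and stopped because the convergence delta rose —
the returned matrix is the sweep-6 iterate.

Method comparison over a missing-rate grid, with paired masks:

```r
report <- benchmark_grid(
  fx$truth,
  methods = list(mean = imputer_spec("mean"),
                 knn = imputer_spec("knn"),
                 boosted = imputer_spec("boosted")),
  rates = c(0.1, 0.3, 0.5), n_replicates = 5, base_seed = 1
)
tidy(report)      # mean / sd RMSE per (method, rate)
autoplot(report)  # RMSE curves against missing rate
```

Downstream prediction after response-excluded imputation:

```r
sig <- standard_suite(seed = 1)$signal
split <- exclude_response(
  dplyr::mutate(sig$truth, outcome = sig$labels$response), "outcome")
completed <- impute_missing(split$predictors, imputer_spec("boosted"), seed = 1)
ranking <- rank_features(as_plain_tibble(completed), split$response,
                         method = "lasso", top_n = 5, seed = 1)
report <- cv_predict(as_plain_tibble(completed)[ranking$feature[ranking$selected]],
                     split$response, method = "penalized_linear", seed = 1)
glance(report)$auc
#> [1] 0.8421424
```

A command-line wrapper (`inst/scripts/missboost`) exposes the same
pipelines as subcommands (`explore`, `impute`, `evaluate`, `cluster`,
`rank`, `predict`) driven by a YAML run configuration; every output
directory includes a provenance JSON sufficient to re-run the command
bit-identically.

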