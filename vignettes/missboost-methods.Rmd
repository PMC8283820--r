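---
title: "Iterative boosted-tree imputation: models, defaults and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Iterative boosted-tree imputation: models, defaults and design notes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(missboost)
```

## The problem

Wide biomedical tables — electronic-health-record laboratory panels above
all — routinely miss a large share of their cells, and most downstream
machinery (regression, clustering, feature selection) wants a complete
matrix. missboost fills missing cells of a mixed continuous/categorical
table and, just as importantly, ships the harness needed to decide whether
a given imputer can be trusted on data like yours: a
missing-completely-at-random (MCAR) masking benchmark, exploration
backends for missingness structure, and a response-excluded prediction
stage that measures what imputation quality buys downstream.

Tables are ordinary tibbles: numeric columns are continuous features,
factor columns categorical, and `NA` is the missingness marker. Every
user-facing function takes the data frame first and returns a tibble (or a
tibble-backed result object with `tidy()`/`glance()`/`autoplot()`
methods), so pipelines compose with the pipe.

## The core imputer

`impute_boosted()` adapts the iterative-forest imputation scheme, replacing
the per-column random forest with gradient-boosted trees (xgboost, 100
trees per fit by default — the setting also used for runtime comparisons in
the boosting literature; remaining learner parameters are the library
defaults). Writing $X$ for the $n \times m$ data matrix:

1. Fill every missing cell by mean (or median/mode) imputation.
2. Sort column indices by ascending missing count (stable; ties keep the
   original order).
3. Sweep over the incomplete columns in that order. For column $s$, fit a
   boosted model of the observed entries $y_{obs}(s)$ on the other
   columns' current values $X_{obs}(s)$, predict the missing entries from
   $X_{miss}(s)$, and write the predictions into the working matrix
   immediately (later columns in the same sweep see them).
4. After each sweep compute two convergence deltas:
   $$\Delta_{cont} = \frac{\sum_{cont}(X_{new} - X_{old})^2}{\sum_{cont} X_{new}^2},
     \qquad
     \Delta_{cat} = \frac{\#\{\text{changed categorical imputations}\}}{\#\{\text{missing categorical cells}\}}$$
   and repeat until a stopping rule fires.

**Stopping rule.** The literature this algorithm family descends from
stops when a delta first *increases* — the new sweep started fitting noise
— and returns the previous iterate. We adopt exactly that rule (either
delta strictly increasing stops the loop and returns the sweep-before
matrix), plus a hard cap of `max_iter = 10` sweeps that returns the
current iterate. Both the per-sweep deltas and the final iterate pair are
retained in the result's `iter_state`, so the decision is auditable after
the fact.

**Mixed types.** Continuous targets use squared-error boosting; categorical
targets a softmax classifier whose argmax (ties to the lowest level code)
becomes the imputed level. Categorical *predictors* are one-hot encoded for
every learner; the encoding is recorded in the result's provenance. The
learner itself sits behind a small fit/predict contract, so a different
boosting backend is a configuration rather than a code change.

**Determinism.** Column order is deterministic; the learner runs
single-threaded with an explicit seed and no row/column subsampling by
default, so identical `(data, spec, seed)` give bit-identical completions.
A practical corollary used heavily in the tests: with a single missing
cell and one sweep, the imputed value must *equal* the prediction of an
independently trained model with the same settings.

## Baseline imputers

* `impute_simple()` — column mean/median, modal level for factors (ties to
  the lowest level code).
* `impute_knn()` — per missing cell, the mean/mode of the `k = 5` nearest
  rows among those observing that column. Distances are partial Euclidean
  over the columns observed in both rows (continuous columns standardized,
  categorical contributing 0/1 mismatch), rescaled by
  `n_columns / n_shared` so sparsely-shared rows are not spuriously close.
  Rows sharing no column with any donor fall back to the column mean/mode
  with a warning.
* `impute_soft_svd()` — soft-impute matrix completion: standardize by
  observed statistics, fill with column means, then iterate SVD →
  soft-threshold singular values by $\lambda$ → refill the missing
  entries. The default $\lambda$ is 1/50 of the initial top singular
  value, following the convention of the established soft-impute
  implementations. Two numerical facts shaped the interface. First, at
  exactly $\lambda = 0$ with a full-rank SVD the refill step is the
  identity, so the initial fill would be returned unchanged; exact
  completion of a known-low-rank matrix therefore uses $\lambda = 0$
  together with the `max_rank` cap (hard truncation), mirroring the
  `rank.max`/`max_rank` parameter of the reference implementations.
  Second, standardizing a rank-1 matrix with positive factors makes all
  its columns collinear — the mean-filled standardized matrix is already
  a fixed point — so the rank-1 recovery check runs with
  `standardize = FALSE`. Both behaviours are documented on the function.
* `impute_chained()` — chained equations on the same sweep skeleton, with
  ridge-regularized linear (continuous) or multinomial logistic
  (categorical) conditional models, run for exactly `n_cycles = 10`
  sweeps. Conditional *means* are imputed rather than posterior draws:
  the package's contract that a completion is a pure function of
  `(data, spec, seed)` favours the deterministic variant, as in
  scikit-learn's iterative imputer. Singular fits fall back to the column
  mean/mode for that sweep with a warning.

## The evaluation harness

`mask_mcar()` hides `floor(rate × n_eligible)` uniformly sampled observed
cells — already-missing cells are never eligible, so the harness works on
incomplete tables too — and errors if any column would lose its last
observed cell. The mask plan stores the true values and the original
per-column observed statistics, so `rmse_on_masked()` (raw by default,
z-scored on request for cross-dataset aggregation; raw is the default
because per-dataset error curves need no normalization) and
`pfc_on_masked()` are pure functions of plan and completion.

`benchmark_grid()` scans rates 0.1–0.9 with 10 masking replicates by
default. Each `(rate, replicate)` derives its mask seed from
`(base_seed, rate index, replicate)` and **all methods impute the same
masked table**, so comparisons are paired and adding a method never
changes existing numbers. Failures are recorded per cell rather than
aborting the sweep; wall-clock seconds are logged per run but never
asserted on, since they are hardware facts, not algorithm facts.

`holdout_correlation_diagnostic()` implements the per-variable sanity
check: hide ~5% of each column's observed cells (at least one), impute
once, and report imputed-vs-true Pearson correlation per continuous column
(accuracy per categorical column). Columns with fewer than three holdout
cells or constant truth report a flagged absolute-error statistic instead,
because a correlation on two points is noise.

## Exploration backends

The missingness image (`missingness_pattern()`) clusters features by
average-linkage hierarchical clustering on Euclidean distances between the
binary missingness indicators. Average linkage on indicator columns is a
deliberate default: it merges features with *similar missingness
profiles* — exactly the structure one inspects before deciding on a
filtering threshold — and is deterministic. `embed_samples()` offers PCA
(on z-standardized features, with the sign of each component fixed so its
largest-magnitude loading is positive, making runs reproducible) and an
exact all-pairs t-SNE (perplexity 30, learning rate 200, 1000 iterations
by default) written in-package because no t-SNE implementation is
otherwise available to depend on; exact t-SNE is adequate at the table
sizes this package embeds. `elbow_suggest_k()` formalizes the elbow as the
interior k maximizing the second difference of the within-cluster
sum-of-squares curve over k = 1..9, ties to the smallest k — a
deterministic rule for a method usually applied by eye. The WCSS curve is
checked to be non-increasing and a violation (possible with too few
k-means restarts) raises a warning rather than being silently accepted.

## Prediction stage

`exclude_response()` removes the response before imputation — imputing the
response's own predictors *with* the response present would leak outcome
information into features that later cross-validation treats as clean.
`rank_features()` scores standardized features by |coefficient| of
lasso/ridge/elastic-net fits at a penalty chosen by internal 5-fold
cross-validation (the conservative one-standard-error penalty, so pure
noise shrinks all the way to zero), or by boosted split-gain importance.
`cv_predict()` runs stratified seeded 5-fold cross-validation — the
stratification stabilizes AUC at modest n, where an unlucky unstratified
split can starve a fold of one class — and pools out-of-fold class-1
probability scores. `roc_pr_metrics()` sweeps thresholds over unique
scores (one ROC vertex per tie group, curve anchored at (0,0) and (1,1))
and integrates by the trapezoid rule, which equals the Mann–Whitney
probability that a random positive outscores a random negative with ties
counted half; the tests verify that identity exactly against a brute-force
pair count. For a binary response "lasso" means L1-penalized *logistic*
regression; for a continuous response, penalized linear regression.

## Synthetic fixtures: what they emulate, and what they do not

`generate_fixture()` draws a low-rank latent Gaussian block
($L R^\top$ plus independent noise), emulating the strong cross-feature
correlation that makes EHR laboratory panels imputable at all. On top of
the base draw it can plant linear column dependencies, well-separated
sample clusters, a binary response driven by designated columns, and
per-column MCAR missingness. Each ingredient draws from its own seeded
substream, so adding planted structure never perturbs the base draw. The
planted response rescales its composite linear predictor to a fixed
standard deviation (the Euclidean norm of the effect vector): the
informative columns share latent factors, so without the rescaling the
realized signal strength would swing with the random correlations among
them from one seed to the next.

`standard_suite()` freezes five fixtures used across the tests: `rank2`
(500×10, rank 2, noise 0.1), `linear` (500×6 with column 3 = 2·column 1 +
N(0, 0.05)), `clusters3` (300×5, three equal clusters, centers 10
within-cluster sd apart), and `signal`/`null` (500×20, rank 4, noise 0.7,
with effects 1.5/1.2/1.0 on columns 2/5/9 or an independent Bernoulli(1/2)
response). The signal effect sizes and noise level were chosen by direct
simulation before the suite was frozen, so that the cross-validated AUC on
complete data clears 0.8 with margin, the planted features are separable
from their latent proxies by both lasso and boosted importance, and the
boosted-vs-mean imputation advantage survives 40% masking.

What the fixtures do **not** emulate: informative (non-random)
missingness, the long-tailed and bounded marginals of real laboratory
values, block-structured missingness from panel ordering, or
relational/ICD-code structure. Green tests on these fixtures demonstrate
algorithmic correctness and the expected ordering of methods under MCAR on
correlated Gaussian data — not clinical-grade imputation accuracy on any
particular real table; the masking harness exists precisely so users can
measure that on their own data.

## Numerical and interface decisions

* **Coordinates are 1-based** everywhere (mask plans, tidy cell reports):
  R's native indexing convention is the single-convention choice that
  avoids off-by-one errors in an R package.
* **Type inference** in `read_table()`: a column whose non-missing cells
  all parse as numbers is continuous regardless of its distinct-value
  count — a lab analyte with three observed readings must stay continuous
  for error metrics to make sense — and anything else is categorical;
  per-column hints override. Missing tokens default to
  `"", "NA", "NaN", "nan", "NULL"`, matched after trimming whitespace.
* **Seed plumbing**: all derived seeds come from one integer mixing
  function kept below 2^31; replicate seeds depend only on
  (base seed, rate index, replicate index), never on the method list.
* **Degenerate inputs**: fully missing columns error early naming the
  column; constant columns get unit scale during standardization instead
  of dividing by zero; correlation on constant holdouts is flagged rather
  than `NaN`.
* **Problem sizes**: tests and the acceptance script run on the fixture
  sizes above (hundreds of rows, tens of columns) with 100-tree fits —
  the package's reference scale for demonstrating the method's behaviour;
  the implementation itself has no size-dependent switches.

## Known limitations

Single imputation only — no multiple-imputation variance pooling, so
downstream standard errors will be optimistic when missingness is heavy.
MCAR is the only masking mechanism offered; evaluation numbers under MCAR
are optimistic for data missing not at random. Generative-adversarial
imputation is documented in the literature this package draws on but is
out of scope here. The chained-equations imputer is the deterministic
conditional-mean variant, not a proper posterior-draw MICE; use it as a
fast baseline, not for uncertainty statements.
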