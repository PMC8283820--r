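test_that("mask counts follow floor(rate x eligible) and draws are deterministic", {
  d <- tibble::as_tibble(as.data.frame(matrix(rnorm(50), 10, 5)))
  mk <- mask_mcar(d, 0.2, seed = 3)
  expect_equal(nrow(mk$plan), 10)          # floor(0.2 * 50)
  expect_equal(sum(is.na(mk$masked)) , 10)
  mk2 <- mask_mcar(d, 0.2, seed = 3)
  expect_identical(mk$plan$row, mk2$plan$row)
  expect_identical(mk$plan$col, mk2$plan$col)
  mk3 <- mask_mcar(d, 0.2, seed = 4)
  expect_false(identical(mk$plan$row, mk3$plan$row) &&
                 identical(mk$plan$col, mk3$plan$col))
})

test_that("the full rate grid hides the exact floor counts on a 100x20 table", {
  fx <- generate_fixture(fixture_spec(n_samples = 100, n_continuous = 20,
                                      seed = 14))
  for (i in 1:9) {
    rate <- i / 10
    mk <- mask_mcar(fx$truth, rate, seed = 50 + i)
    expect_equal(nrow(mk$plan), 200 * i)
    # no column fully masked
    expect_true(all(colSums(is.na(mk$masked)) < 100))
  }
})

test_that("unmasking a plan restores the original table exactly", {
  fx <- generate_fixture(fixture_spec(
    n_samples = 25, n_continuous = 3, n_categorical = 1, seed = 16
  ))
  mk <- mask_mcar(fx$truth, 0.3, seed = 8)
  expect_identical(unmask(mk$masked, mk$plan), fx$truth)
})

test_that("eligibility excludes already-missing cells", {
  d <- tibble::tibble(a = c(1, NA, 3, 4, 5, 6), b = c(1, 2, 3, 4, 5, 6) * 1.0)
  mk <- mask_mcar(d, 0.5, seed = 1)
  expect_equal(nrow(mk$plan), floor(0.5 * 11))
  expect_true(all(!(mk$plan$row == 2 & mk$plan$col == 1)))
})

test_that("rmse matches hand cases and a naive loop oracle", {
  d <- tibble::as_tibble(as.data.frame(matrix(rnorm(80), 20, 4)))
  mk <- mask_mcar(d, 0.25, seed = 5)
  # imputing with the truth gives zero error
  oracle <- unmask(mk$masked, mk$plan)
  expect_equal(rmse_on_masked(mk$plan, oracle), 0)
  # constant offset d gives RMSE d
  off <- oracle
  for (i in seq_len(nrow(mk$plan))) {
    off[[mk$plan$col[i]]][mk$plan$row[i]] <-
      off[[mk$plan$col[i]]][mk$plan$row[i]] + 0.7
  }
  expect_equal(rmse_on_masked(mk$plan, off), 0.7, tolerance = 1e-12)
  # random completion equals the naive loop computation
  comp <- impute_simple(mk$masked, "mean")
  acc <- 0
  for (i in seq_len(nrow(mk$plan))) {
    imp <- comp[[mk$plan$col[i]]][mk$plan$row[i]]
    acc <- acc + (imp - mk$plan$true_num[i])^2
  }
  expect_equal(rmse_on_masked(mk$plan, comp), sqrt(acc / nrow(mk$plan)),
               tolerance = 1e-12)
  # zscore scale divides by the original observed sd
  expect_gt(rmse_on_masked(mk$plan, comp, scale = "zscore"), 0)
})

test_that("rmse ignores the imputation of non-hidden cells", {
  d <- tibble::as_tibble(as.data.frame(matrix(rnorm(60), 15, 4)))
  mk <- mask_mcar(d, 0.2, seed = 6)
  comp <- impute_simple(mk$masked, "mean")
  r1 <- rmse_on_masked(mk$plan, comp)
  tweaked <- as_plain_tibble(comp)
  hidden <- cbind(mk$plan$row, mk$plan$col)
  for (j in seq_along(tweaked)) {
    hit <- hidden[hidden[, 2] == j, 1]
    free <- setdiff(seq_len(nrow(tweaked)), hit)
    tweaked[[j]][free] <- tweaked[[j]][free] + 100
  }
  expect_equal(rmse_on_masked(mk$plan, tweaked), r1)
})

test_that("pfc counts wrong levels exactly", {
  d <- tibble::tibble(g = factor(rep(c("a", "b"), 20), levels = c("a", "b")))
  mk <- mask_mcar(d, 0.5, seed = 2)
  right <- unmask(mk$masked, mk$plan)
  expect_equal(pfc_on_masked(mk$plan, right), 0)
  wrong <- right
  wrong$g <- factor(ifelse(right$g == "a", "b", "a"), levels = c("a", "b"))
  expect_equal(pfc_on_masked(mk$plan, wrong), 1)
  n_h <- nrow(mk$plan)
  part <- right
  flip <- mk$plan[seq_len(7), ]
  for (i in seq_len(7)) {
    part$g[flip$row[i]] <- if (flip$true_level[i] == "a") "b" else "a"
  }
  expect_equal(pfc_on_masked(mk$plan, part), 7 / n_h)
  expect_error(rmse_on_masked(mk$plan, right), "pfc")
})

test_that("benchmark grid aggregates exactly and an oracle method scores zero", {
  fx <- generate_fixture(fixture_spec(n_samples = 40, n_continuous = 4,
                                      seed = 18))
  truth <- fx$truth
  oracle_method <- function(masked, seed) truth
  rep <- benchmark_grid(
    truth,
    methods = list(mean = imputer_spec("mean"), oracle = oracle_method),
    rates = 0.2, n_replicates = 3, base_seed = 5
  )
  mean_rows <- rep[rep$method == "mean" & rep$metric == "rmse", ]
  expect_equal(nrow(mean_rows), 3)
  agg <- tidy(rep)
  expect_equal(agg$mean[agg$method == "mean"], mean(mean_rows$value))
  expect_equal(agg$mean[agg$method == "oracle"], 0)
  expect_equal(glance(rep)$n_failed, 0)
})

test_that("a single-replicate grid equals the manual mask-impute-metric chain", {
  fx <- generate_fixture(fixture_spec(n_samples = 30, n_continuous = 4,
                                      seed = 19))
  rep <- benchmark_grid(fx$truth, methods = list(mean = imputer_spec("mean")),
                        rates = 0.3, n_replicates = 1, base_seed = 11)
  seed <- missboost:::derive_seed(11, 1, 1)
  mk <- mask_mcar(fx$truth, 0.3, seed = seed)
  manual <- rmse_on_masked(mk$plan, impute_simple(mk$masked, "mean"))
  expect_equal(rep$value[rep$metric == "rmse"], manual)
})

test_that("masks are shared between methods within a replicate", {
  fx <- generate_fixture(fixture_spec(n_samples = 30, n_continuous = 4,
                                      seed = 20))
  # an imputer that records the mask it saw
  seen <- list()
  recorder <- function(masked, seed) {
    seen[[length(seen) + 1]] <<- missing_mask(masked)
    impute_simple(masked, "mean")
  }
  rep <- benchmark_grid(
    fx$truth,
    methods = list(r1 = recorder, r2 = recorder),
    rates = 0.2, n_replicates = 2, base_seed = 3
  )
  expect_identical(seen[[1]], seen[[2]])
  expect_identical(seen[[3]], seen[[4]])
  expect_false(identical(seen[[1]], seen[[3]]))
})

test_that("holdout diagnostic: oracle imputer gives perfect correlation; small columns are flagged", {
  fx <- generate_fixture(fixture_spec(n_samples = 100, n_continuous = 3,
                                      seed = 23))
  truth <- fx$truth
  # a column with exactly 40 observed cells -> 2 holdouts -> flagged
  res <- holdout_correlation_diagnostic(truth, imputer_spec("mean"),
                                        fraction = 0.05, seed = 2)
  expect_equal(res$n_holdout, rep(5L, 3))

  small <- truth[seq_len(40), ]
  res_small <- holdout_correlation_diagnostic(small, imputer_spec("mean"),
                                              fraction = 0.05, seed = 2)
  expect_equal(res_small$n_holdout, rep(2L, 3))
  expect_true(all(res_small$flagged))
  expect_true(all(res_small$statistic == "mae"))
})

test_that("holdout diagnostic recovers a strongly predictable column", {
  fx <- standard_suite(1)$linear
  res <- holdout_correlation_diagnostic(
    fx$truth, imputer_spec("boosted", nrounds = 50), fraction = 0.05, seed = 3
  )
  dep <- res[res$name == "x3", ]
  expect_identical(dep$statistic, "correlation")
  expect_gt(dep$value, 0.9)
})
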