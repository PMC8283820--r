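test_that("exclude_response splits and re-attaches losslessly", {
  d <- tibble::tibble(x1 = rnorm(10), x2 = rnorm(10), x3 = rnorm(10),
                      x4 = rnorm(10), y = rbinom(10, 1, 0.5) * 1.0)
  sp <- exclude_response(d, "y")
  expect_identical(names(sp$predictors), c("x1", "x2", "x3", "x4"))
  expect_equal(length(sp$response), 10)
  rejoined <- dplyr::bind_cols(sp$predictors, tibble::tibble(y = sp$response))
  expect_equal(rejoined, d)
  expect_error(exclude_response(d, "nope"), "unknown")
  d$y[c(3, 7)] <- NA
  expect_error(exclude_response(d, "y"), "3, 7")
})

test_that("lasso ranks a single planted regressor first", {
  set.seed(41)
  n <- 200
  d <- tibble::as_tibble(as.data.frame(matrix(rnorm(n * 6), n, 6)))
  names(d) <- paste0("x", 1:6)
  y <- 3 * d$x4 + rnorm(n, sd = 0.1)
  rk <- rank_features(d, y, method = "lasso", top_n = 1, seed = 2)
  expect_identical(rk$feature[rk$rank == 1], "x4")
  expect_true(rk$selected[rk$feature == "x4"])
})

test_that("boosted importance ranks a step-function regressor first", {
  set.seed(43)
  n <- 300
  d <- tibble::as_tibble(as.data.frame(matrix(rnorm(n * 5), n, 5)))
  names(d) <- paste0("x", 1:5)
  y <- as.double(d$x2 > 0)
  rk <- rank_features(d, y, method = "boosted_importance", top_n = 1, seed = 2)
  expect_identical(rk$feature[rk$rank == 1], "x2")
})

test_that("lasso fully shrinks a response independent of all features", {
  hits <- 0
  for (s in 1:10) {
    fx <- generate_fixture(fixture_spec(n_samples = 500, n_continuous = 20,
                                        latent_rank = 4, noise_sd = 0.7,
                                        seed = 1000 + s))
    rk <- rank_features(fx$truth, fx$labels$response, method = "lasso",
                        top_n = 5, seed = s)
    hits <- hits + all(rk$score == 0)
  }
  expect_gte(hits, 9)
})

test_that("penalized ranking is invariant to feature rescaling", {
  set.seed(44)
  n <- 150
  d <- tibble::as_tibble(as.data.frame(matrix(rnorm(n * 4), n, 4)))
  names(d) <- paste0("x", 1:4)
  y <- 2 * d$x1 - d$x3 + rnorm(n, sd = 0.2)
  r1 <- rank_features(d, y, method = "ridge", top_n = 4, seed = 3)
  d_scaled <- d
  d_scaled$x1 <- d$x1 * 1000
  d_scaled$x3 <- d$x3 / 50
  r2 <- rank_features(d_scaled, y, method = "ridge", top_n = 4, seed = 3)
  expect_identical(r1$rank, r2$rank)
})

test_that("roc/auc hand cases and tie handling", {
  expect_equal(roc_pr_metrics(c(1, 1, 0, 0), c(1, 1, 0, 0))$auc, 1.0)
  expect_equal(roc_pr_metrics(c(0, 0, 1, 1), c(1, 1, 0, 0))$auc, 0.0)
  m <- roc_pr_metrics(c(.9, .8, .7, .6, .5, .4, .3, .2),
                      c(1, 1, 1, 0, 1, 0, 0, 0))
  expect_equal(m$auc, mann_whitney_auc(c(.9, .8, .7, .6, .5, .4, .3, .2),
                                       c(1, 1, 1, 0, 1, 0, 0, 0)))
  # curve endpoints
  expect_equal(unlist(m$roc_points[1, c("fpr", "tpr")]), c(fpr = 0, tpr = 0))
  expect_equal(unlist(m$roc_points[nrow(m$roc_points), c("fpr", "tpr")]),
               c(fpr = 1, tpr = 1))
  expect_error(roc_pr_metrics(c(1, 2), c(1, 1)), "both classes")
})

test_that("trapezoidal auc equals brute-force pair counting on random fixtures", {
  set.seed(45)
  for (i in 1:100) {
    n <- sample(6:30, 1)
    scores <- sample(seq(0, 1, by = 0.1), n, replace = TRUE)  # many ties
    truth <- rbinom(n, 1, 0.5)
    if (sum(truth) == 0 || sum(truth) == n) next
    expect_equal(roc_pr_metrics(scores, truth)$auc,
                 mann_whitney_auc(scores, truth))
  }
})

test_that("auc agrees with an established ROC implementation", {
  skip_if_not_installed("pROC")
  set.seed(46)
  scores <- rnorm(80)
  truth <- rbinom(80, 1, 0.4)
  expect_equal(roc_pr_metrics(scores, truth)$auc,
               as.double(suppressMessages(pROC::auc(truth, scores))),
               tolerance = 1e-12)
})

test_that("cross-validation covers every sample exactly once and is deterministic", {
  fx <- generate_fixture(fixture_spec(n_samples = 120, n_continuous = 5,
                                      seed = 47))
  y <- fx$labels$response
  rep1 <- cv_predict(fx$truth, y, method = "penalized_linear", seed = 5)
  expect_identical(sort(rep1$scores$sample), 1:120)
  expect_identical(sort(unique(rep1$scores$fold)), 1:5)
  expect_false(any(is.na(rep1$scores$score)))
  # stratification: every fold contains both classes
  tab <- table(rep1$scores$fold, rep1$scores$label)
  expect_true(all(tab > 0))
  rep2 <- cv_predict(fx$truth, y, method = "penalized_linear", seed = 5)
  expect_identical(rep1$scores, rep2$scores)
  expect_error(cv_predict(fx$truth, c(rep(0, 3), rep(1, 117)), n_folds = 5),
               "fewer folds")
})

test_that("a separable two-class problem scores a perfect AUC", {
  set.seed(48)
  n <- 100
  y <- rep(c(0, 1), each = n / 2)
  d <- tibble::tibble(f1 = rnorm(n) + 10 * y, f2 = rnorm(n) - 10 * y)
  rep <- cv_predict(d, y, method = "penalized_linear", seed = 3)
  expect_equal(rep$auc, 1.0, tolerance = 1e-8)
  # tree/knn scores are pooled across folds, where slight calibration
  # differences can swap a handful of near-certain scores
  for (meth in c("boosted_trees", "random_forest", "knn")) {
    expect_gte(cv_predict(d, y, method = meth, seed = 3)$auc, 0.98)
  }
})

test_that("label-shuffled data scores near chance in most seeds", {
  fx <- standard_suite(1)$null
  hits <- 0
  for (s in 1:10) {
    y <- missboost:::with_seed(2000 + s, sample(fx$labels$response))
    rep <- cv_predict(fx$truth, y, method = "penalized_linear", seed = s)
    hits <- hits + (rep$auc > 0.35 && rep$auc < 0.65)
  }
  expect_gte(hits, 9)
})
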