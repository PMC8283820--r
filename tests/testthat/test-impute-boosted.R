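test_that("column order sorts by ascending missing count with index tie-break", {
  mk <- function(counts, n = 10) {
    m <- matrix(FALSE, n, length(counts))
    for (j in seq_along(counts)) if (counts[j] > 0) m[seq_len(counts[j]), j] <- TRUE
    m
  }
  expect_identical(sort_columns_by_missingness(mk(c(3, 0, 1))), c(2L, 3L, 1L))
  expect_identical(sort_columns_by_missingness(mk(c(2, 2, 2))), c(1L, 2L, 3L))
  # independent argsort oracle on a random 50-column mask
  set.seed(8)
  mask <- matrix(runif(30 * 50) < 0.3, 30, 50)
  counts <- colSums(mask)
  oracle <- order(counts + seq_along(counts) * 1e-9)
  expect_identical(sort_columns_by_missingness(mask), oracle)
})

test_that("stopping rule: continue, return-previous on delta rise, cap at max_iter", {
  dh <- function(...) {
    v <- list(...)
    tibble::tibble(delta_continuous = vapply(v, `[`, double(1), 1),
                   delta_categorical = vapply(v, `[`, double(1), 2))
  }
  expect_identical(stopping_criterion(dh(c(0.5, 0)), 1, 10), "continue")
  expect_identical(stopping_criterion(dh(c(0.5, 0), c(0.2, 0), c(0.3, 0)), 3, 10),
                   "stop_return_previous")
  expect_identical(stopping_criterion(dh(c(0.5, 0), c(0.4, 0), c(0.3, 0)), 3, 3),
                   "stop_return_current")
  # categorical delta rise alone also stops
  expect_identical(stopping_criterion(dh(c(0.5, 0.1), c(0.4, 0.3)), 2, 10),
                   "stop_return_previous")
})

test_that("a complete table is returned unchanged with zero sweeps", {
  d <- tibble::tibble(x = c(1, 2, 3, 4, 5), y = c(5, 4, 3, 2, 1))
  comp <- impute_boosted(d, seed = 1)
  expect_equal(as_plain_tibble(comp), d)
  expect_equal(glance(comp)$n_sweeps, 0L)
})

test_that("a single masked cell with one sweep equals an independently trained model", {
  set.seed(99)
  n <- 60
  d <- tibble::tibble(
    a = rnorm(n), b = rnorm(n),
    g = factor(sample(c("u", "v", "w"), n, TRUE))
  )
  d$y <- 2 * d$a - d$b + rnorm(n, sd = 0.1)
  i <- 17
  dm <- d
  dm$y[i] <- NA
  comp <- impute_boosted(dm, imputer_spec("boosted", max_iter = 1), seed = 5)

  # oracle: plain xgboost with the same learner settings and seed,
  # trained on the complete rows only
  x <- cbind(a = dm$a, b = dm$b,
             `g=u` = as.double(dm$g == "u"),
             `g=v` = as.double(dm$g == "v"),
             `g=w` = as.double(dm$g == "w"))
  fit <- xgboost::xgb.train(
    params = list(objective = "reg:squarederror", nthread = 1, seed = 5L),
    data = xgboost::xgb.DMatrix(x[-i, , drop = FALSE], label = d$y[-i],
                                nthread = 1),
    nrounds = 100, verbose = 0
  )
  oracle <- as.double(predict(fit, x[i, , drop = FALSE]))
  expect_identical(comp$y[i], oracle)
})

test_that("one sweep equals independent per-column fits on a 3-column fixture", {
  set.seed(31)
  n <- 50
  d <- tibble::tibble(p = rnorm(n), q = rnorm(n), r = rnorm(n))
  d$q <- d$p + rnorm(n, sd = 0.2)
  dm <- d
  dm$q[1:4] <- NA      # 4 missing
  dm$r[1:2] <- NA      # 2 missing -> visited first
  nr <- 25
  comp <- impute_boosted(dm, imputer_spec("boosted", max_iter = 1, nrounds = nr),
                         seed = 3)

  # oracle sweep: mean init, columns in missingness order, immediate updates
  work <- as.data.frame(dm)
  for (j in names(work)) work[[j]][is.na(work[[j]])] <- mean(work[[j]], na.rm = TRUE)
  for (s in c("r", "q")) {
    miss <- is.na(dm[[s]])
    x <- as.matrix(work[setdiff(names(work), s)])
    fit <- xgboost::xgb.train(
      params = list(objective = "reg:squarederror", nthread = 1, seed = 3L),
      data = xgboost::xgb.DMatrix(x[!miss, , drop = FALSE],
                                  label = work[[s]][!miss], nthread = 1),
      nrounds = nr, verbose = 0
    )
    work[[s]][miss] <- predict(fit, x[miss, , drop = FALSE])
  }
  expect_equal(comp$q, work$q, tolerance = 1e-12)
  expect_equal(comp$r, work$r, tolerance = 1e-12)
})

test_that("boosted imputation halves the mean-imputation error on a planted linear pair", {
  fx <- standard_suite(1)$linear
  mk <- mask_mcar(fx$truth[3], 0.1, seed = 2)   # mask only the dependent column
  dm <- fx$truth
  dm[[3]] <- mk$masked[[1]]
  comp <- impute_boosted(dm, seed = 1)
  cmean <- impute_simple(dm, "mean")
  plan <- mk$plan
  rmse <- function(comp_tbl) {
    sqrt(mean((comp_tbl[[3]][plan$row] - plan$true_num)^2))
  }
  expect_lt(rmse(comp), 0.5 * rmse(cmean))
})

test_that("identical data, spec and seed give identical output", {
  fx <- generate_fixture(fixture_spec(
    n_samples = 50, n_continuous = 4, missing = 0.15, seed = 12
  ))
  spec <- imputer_spec("boosted", nrounds = 20, max_iter = 2)
  c1 <- impute_boosted(fx$data, spec, seed = 7)
  c2 <- impute_boosted(fx$data, spec, seed = 7)
  expect_identical(as_plain_tibble(c1), as_plain_tibble(c2))
})

test_that("recorded convergence deltas are reproducible from the stored iterates", {
  fx <- generate_fixture(fixture_spec(
    n_samples = 60, n_continuous = 4, n_categorical = 1,
    missing = 0.2, seed = 13
  ))
  comp <- impute_boosted(fx$data, imputer_spec("boosted", nrounds = 15),
                         seed = 2)
  st <- attr(comp, "iter_state")
  dh <- st$delta_history
  expect_gte(nrow(dh), 1)
  types <- st$types
  num <- den <- 0
  for (j in which(types == "continuous")) {
    num <- num + sum((st$X_new_imp[[j]] - st$X_old_imp[[j]])^2)
    den <- den + sum(st$X_new_imp[[j]]^2)
  }
  expect_equal(dh$delta_continuous[nrow(dh)], num / den, tolerance = 1e-12)
  # the reported reason is one of the two stopping modes
  expect_true(st$converged_reason %in% c("delta_increased", "max_iter"))
})

test_that("preconditions name the offending column", {
  d <- tibble::tibble(x = c(1, NA, NA, NA, NA, NA), y = 1:6 * 1.0)
  expect_error(impute_boosted(d, seed = 1), "x")
  expect_error(impute_boosted(tibble::tibble(z = c(1, NA, 3)), seed = 1),
               "2 columns")
})
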