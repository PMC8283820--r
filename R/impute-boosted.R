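#' Column visit order for iterative imputation
#'
#' Stable sort of column indices by ascending per-column missing-cell count,
#' ties broken by original column index, so the easiest (least missing)
#' columns are (re)fitted first in every sweep.
#'
#' @param mask Logical matrix, `TRUE` = missing (see [missing_mask()]).
#' @return Integer vector: a permutation of `1:ncol(mask)`.
#' @export
#' @examples
#' sort_columns_by_missingness(cbind(c(TRUE, TRUE), c(FALSE, FALSE), c(TRUE, FALSE)))
sort_columns_by_missingness <- function(mask) {
  counts <- colSums(mask)
  order(counts, seq_along(counts))
}

#' Decide whether the iterative imputer keeps sweeping
#'
#' After each sweep the imputer records a continuous convergence delta
#' (sum of squared cell changes over the sum of squared current values,
#' continuous cells) and a categorical delta (fraction of imputed
#' categorical cells that changed level). Sweeping continues while both
#' deltas keep decreasing; the first strict increase of either delta stops
#' the loop and the previous iterate is returned (the new sweep made the
#' imputation worse, by the usual iterative-forest convention); hitting
#' `max_iter` stops with the current iterate.
#'
#' @param delta_history Data frame with columns `delta_continuous` and
#'   `delta_categorical`, one row per completed sweep.
#' @param iteration Number of completed sweeps.
#' @param max_iter Sweep cap.
#' @return `"continue"`, `"stop_return_previous"` or `"stop_return_current"`.
#' @export
stopping_criterion <- function(delta_history, iteration, max_iter) {
  stopifnot(nrow(delta_history) >= 1, iteration >= 1)
  t <- nrow(delta_history)
  if (t >= 2) {
    inc_cont <- delta_history$delta_continuous[t] > delta_history$delta_continuous[t - 1]
    inc_cat <- delta_history$delta_categorical[t] > delta_history$delta_categorical[t - 1]
    if (inc_cont || inc_cat) return("stop_return_previous")
  }
  if (iteration >= max_iter) return("stop_return_current")
  "continue"
}

# --- internal sweep machinery shared by boosted and chained imputers ------

# Working state: list of columns; continuous as doubles, categorical as
# integer level codes. All cells filled (post initial guess).
as_work <- function(completed) {
  lapply(as_plain_tibble(completed), function(col) {
    if (is.factor(col)) as.integer(col) else as.double(col)
  })
}

work_onehot <- function(work, types, levels_list, exclude_j) {
  cols <- list()
  nms <- names(work)
  for (j in seq_along(work)) {
    if (j == exclude_j) next
    if (types[j] == "categorical") {
      lev <- levels_list[[j]]
      for (l in seq_along(lev)) {
        cols[[paste0(nms[j], "=", lev[l])]] <- as.double(work[[j]] == l)
      }
    } else {
      cols[[nms[j]]] <- work[[j]]
    }
  }
  do.call(cbind, cols)
}

work_to_tibble <- function(work, template) {
  out <- template
  for (j in seq_along(out)) {
    if (is.factor(template[[j]])) {
      out[[j]] <- factor(levels(template[[j]])[work[[j]]],
                         levels = levels(template[[j]]))
    } else {
      out[[j]] <- work[[j]]
    }
  }
  out
}

# Convergence deltas between two working states (Frobenius-type ratio over
# continuous cells; changed fraction over missing categorical cells).
sweep_deltas <- function(work_old, work_new, types, mask) {
  cont <- which(types == "continuous")
  num <- 0
  den <- 0
  for (j in cont) {
    num <- num + sum((work_new[[j]] - work_old[[j]])^2)
    den <- den + sum(work_new[[j]]^2)
  }
  delta_cont <- if (den > 0) num / den else 0
  catj <- which(types == "categorical")
  n_miss_cat <- sum(mask[, catj, drop = FALSE])
  if (n_miss_cat == 0) {
    delta_cat <- 0
  } else {
    changed <- 0
    for (j in catj) {
      mj <- mask[, j]
      changed <- changed + sum(work_new[[j]][mj] != work_old[[j]][mj])
    }
    delta_cat <- changed / n_miss_cat
  }
  list(delta_continuous = delta_cont, delta_categorical = delta_cat)
}

check_iterative_preconditions <- function(data, mask, min_obs = 5) {
  if (ncol(data) < 2) abort("iterative imputation needs at least 2 columns.")
  check_observed_columns(data)
  n_obs <- nrow(data) - colSums(mask)
  bad <- which(colSums(mask) > 0 & n_obs < min_obs)
  if (length(bad)) {
    abort(sprintf(
      "column(s) with missing cells but fewer than %d observed rows: %s",
      min_obs, paste(names(data)[bad], collapse = ", ")
    ))
  }
  invisible(data)
}

# xgboost fit/predict for one imputation target. Constant learner settings
# across fits; `seed` is passed to xgboost (no subsampling by default, so
# results are reproducible and an independently trained model with the same
# settings predicts identically).
fit_predict_boosted <- function(x_obs, y_obs, x_miss, type, n_levels,
                                nrounds, seed, extra_params) {
  base <- list(nthread = 1, seed = as.integer(seed))
  if (type == "continuous") {
    params <- utils::modifyList(c(base, list(objective = "reg:squarederror")),
                                extra_params)
    fit <- xgboost::xgb.train(
      params = params,
      data = xgboost::xgb.DMatrix(x_obs, label = y_obs, nthread = 1),
      nrounds = nrounds, verbose = 0
    )
    stats::predict(fit, x_miss)
  } else {
    present <- sort(unique(y_obs))
    if (length(present) == 1) {
      return(rep(present, nrow(x_miss)))
    }
    y0 <- match(y_obs, present) - 1
    params <- utils::modifyList(
      c(base, list(objective = "multi:softprob", num_class = length(present))),
      extra_params
    )
    fit <- xgboost::xgb.train(
      params = params,
      data = xgboost::xgb.DMatrix(x_obs, label = y0, nthread = 1),
      nrounds = nrounds, verbose = 0
    )
    prob <- matrix(stats::predict(fit, x_miss), nrow = nrow(x_miss),
                   byrow = TRUE)
    present[max.col(prob, ties.method = "first")]
  }
}

# Ridge-regularized linear/multinomial fit for the chained imputer.
fit_predict_ridge <- function(x_obs, y_obs, x_miss, type, n_levels,
                              ridge_lambda) {
  if (ncol(x_obs) < 2) {
    pad <- function(m) cbind(m, `..pad..` = 0)
    x_obs <- pad(x_obs)
    x_miss <- pad(x_miss)
  }
  if (type == "continuous") {
    fit <- glmnet::glmnet(x_obs, y_obs, alpha = 0, lambda = ridge_lambda,
                          family = "gaussian")
    as.double(stats::predict(fit, x_miss, s = ridge_lambda))
  } else {
    present <- sort(unique(y_obs))
    if (length(present) == 1) return(rep(present, nrow(x_miss)))
    yf <- factor(y_obs, levels = present)
    fit <- glmnet::glmnet(x_obs, yf, alpha = 0, lambda = ridge_lambda,
                          family = "multinomial")
    prob <- stats::predict(fit, x_miss, s = ridge_lambda, type = "response")[, , 1]
    if (is.null(dim(prob))) prob <- matrix(prob, nrow = 1)
    present[max.col(prob, ties.method = "first")]
  }
}

# Shared column-sweep engine. `fit_col(x_obs, y_obs, x_miss, type, n_levels)`
# returns predictions for the missing rows of the target column.
run_sweeps <- function(data, mask, init, fit_col, max_iter,
                       stop_rule = c("delta", "fixed")) {
  stop_rule <- match.arg(stop_rule)
  types <- column_types(data)
  levels_list <- lapply(data, function(col) if (is.factor(col)) levels(col) else NULL)
  ord <- sort_columns_by_missingness(mask)
  target_cols <- ord[colSums(mask)[ord] > 0]

  init_completed <- impute_simple(data, init)
  work <- as_work(init_completed)

  delta_history <- tibble(sweep = integer(), delta_continuous = double(),
                          delta_categorical = double())
  iteration <- 0L
  work_prev <- work
  converged_reason <- NA_character_
  last_pair <- NULL

  repeat {
    iteration <- iteration + 1L
    work_old <- work
    for (s in target_cols) {
      miss <- mask[, s]
      x_all <- work_onehot(work, types, levels_list, exclude_j = s)
      y <- work[[s]]
      pred <- fit_col(
        x_obs = x_all[!miss, , drop = FALSE],
        y_obs = y[!miss],
        x_miss = x_all[miss, , drop = FALSE],
        type = types[s],
        n_levels = length(levels_list[[s]] %||% character(0))
      )
      work[[s]][miss] <- pred
    }
    d <- sweep_deltas(work_old, work, types, mask)
    delta_history <- bind_rows(delta_history,
                               tibble(sweep = iteration,
                                      delta_continuous = d$delta_continuous,
                                      delta_categorical = d$delta_categorical))
    last_pair <- list(old = work_old, new = work)

    if (stop_rule == "fixed") {
      if (iteration >= max_iter) {
        converged_reason <- "max_iter"
        result <- work
        break
      }
    } else {
      decision <- stopping_criterion(delta_history, iteration, max_iter)
      if (decision == "stop_return_previous") {
        converged_reason <- "delta_increased"
        result <- work_old
        break
      }
      if (decision == "stop_return_current") {
        converged_reason <- "max_iter"
        result <- work
        break
      }
    }
    work_prev <- work_old
  }

  list(
    result = work_to_tibble(result, data),
    iter_state = list(
      iteration = iteration,
      order = ord,
      delta_history = delta_history,
      converged_reason = converged_reason,
      X_old_imp = last_pair$old,
      X_new_imp = last_pair$new,
      types = types
    )
  )
}

#' Iterative gradient-boosted-tree imputation
#'
#' The package's core imputer. After an initial mean (or median) fill,
#' columns are visited in order of increasing missingness; for each column
#' with missing cells a gradient-boosted tree model (xgboost, 100 trees by
#' default) is fitted with the column's observed entries as the target and
#' the current imputed values of all other columns as predictors, and its
#' predictions overwrite that column's missing cells. Sweeps over all
#' incomplete columns repeat until the convergence deltas first increase
#' (the previous iterate is then returned) or `max_iter` sweeps have run;
#' see [stopping_criterion()]. Complete columns are never refitted but serve
#' as predictors. Categorical targets use a boosted softmax classifier;
#' categorical predictors are one-hot encoded.
#'
#' @inheritParams impute_missing
#' @param spec An [imputer_spec()] with `method = "boosted"`; its parameters
#'   (`nrounds`, `max_iter`, `init`, extra xgboost settings) control the run.
#' @param seed Integer passed to the learner; identical `(data, spec, seed)`
#'   give identical output.
#' @return A `completed_tbl` whose `iter_state` attribute holds the visit
#'   order, per-sweep convergence deltas, stop reason and final iterate pair.
#' @export
#' @examples
#' d <- data.frame(x = c(1, 2, 3, 4, 5, 6), y = c(2.1, 3.9, NA, 8.2, 9.8, 12))
#' glance(impute_boosted(d, seed = 1))
impute_boosted <- function(data, spec = imputer_spec("boosted"), seed = 1L) {
  stopifnot(inherits(spec, "imputer_spec"), spec$method == "boosted")
  data <- mb_normalise(data)
  mask <- missing_mask(data)
  if (!any(mask)) {
    st <- list(iteration = 0L, order = sort_columns_by_missingness(mask),
               delta_history = tibble(sweep = integer(),
                                      delta_continuous = double(),
                                      delta_categorical = double()),
               converged_reason = "no_missing")
    return(new_completed(data, spec, mask, iter_state = st,
                         provenance = list(seed = seed, encoding = "one_hot")))
  }
  check_iterative_preconditions(data, mask)
  p <- spec$params
  extra <- p[setdiff(names(p), c("nrounds", "max_iter", "init"))]
  fit_col <- function(x_obs, y_obs, x_miss, type, n_levels) {
    fit_predict_boosted(x_obs, y_obs, x_miss, type, n_levels,
                        nrounds = p$nrounds, seed = seed,
                        extra_params = extra)
  }
  run <- run_sweeps(data, mask, init = p$init, fit_col = fit_col,
                    max_iter = p$max_iter, stop_rule = "delta")
  new_completed(run$result, spec, mask, iter_state = run$iter_state,
                provenance = list(seed = seed, encoding = "one_hot",
                                  learner = "xgboost"))
}

#' Chained-equations imputation with ridge-regularized conditional models
#'
#' The same column-sweep skeleton as [impute_boosted()], with a
#' ridge-regularized linear model for continuous targets and a
#' ridge-regularized multinomial logistic model for categorical targets,
#' run for exactly `n_cycles` sweeps (no convergence test) and returning the
#' final sweep. Conditional means are imputed (no posterior noise draws), so
#' the result is deterministic.
#'
#' @inheritParams impute_missing
#' @param n_cycles Number of sweeps over the incomplete columns.
#' @param ridge_lambda Ridge penalty of the per-column models.
#' @param init Initial fill, `"mean"` or `"median"`.
#' @return A `completed_tbl`. A column whose model fit fails falls back to
#'   its mean/mode fill for that sweep, with a warning.
#' @export
impute_chained <- function(data, n_cycles = 10, seed = 1L,
                           ridge_lambda = 0.01, init = "mean") {
  data <- mb_normalise(data)
  mask <- missing_mask(data)
  spec <- imputer_spec("chained", n_cycles = n_cycles,
                       ridge_lambda = ridge_lambda, init = init)
  if (!any(mask)) {
    return(new_completed(data, spec, mask,
                         provenance = list(seed = seed, encoding = "one_hot")))
  }
  check_iterative_preconditions(data, mask)
  fills <- column_fill_values(data, init)
  fit_col <- function(x_obs, y_obs, x_miss, type, n_levels) {
    tryCatch(
      fit_predict_ridge(x_obs, y_obs, x_miss, type, n_levels, ridge_lambda),
      error = function(e) {
        warn(sprintf("chained fit failed (%s); using column fill.",
                     conditionMessage(e)))
        fv <- y_obs[0]
        rep(if (type == "continuous") mean(y_obs) else {
          tab <- tabulate(y_obs, nbins = max(n_levels, 1))
          which.max(tab)
        }, nrow(x_miss))
      }
    )
  }
  run <- run_sweeps(data, mask, init = init, fit_col = fit_col,
                    max_iter = n_cycles, stop_rule = "fixed")
  new_completed(run$result, spec, mask, iter_state = run$iter_state,
                provenance = list(seed = seed, encoding = "one_hot",
                                  learner = "glmnet_ridge"))
}
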