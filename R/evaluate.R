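#' Hide observed cells completely at random
#'
#' Draws a uniform random sample, without replacement, of
#' `floor(rate * n_eligible)` cells from the currently observed (eligible)
#' cells and sets them to missing. Already-missing cells are never selected,
#' so the harness also works on incomplete inputs. Deterministic in
#' `(data, rate, seed)`.
#'
#' @param data A data frame in canonical form.
#' @param rate Fraction of eligible cells to hide, in (0, 1).
#' @param seed Integer RNG seed.
#' @return A list with `masked` (the tibble with extra `NA`s) and `plan`
#'   (a `mask_plan`): one row per hidden cell with 1-based `row`, `col`,
#'   `name`, `type` and the true value (`true_num` for continuous cells,
#'   `true_level` for categorical), plus the rate, seed and per-column
#'   observed statistics of the input as attributes.
#' @export
mask_mcar <- function(data, rate, seed = 1L) {
  data <- mb_normalise(data)
  if (rate <= 0 || rate >= 1) abort("`rate` must be in (0, 1).")
  mask0 <- missing_mask(data)
  eligible <- which(!mask0)
  if (length(eligible) < 1) abort("no eligible (observed) cells to mask.")
  n_hide <- floor(rate * length(eligible))
  if (n_hide < 1) abort("rate too small: zero cells would be hidden.")
  hide <- with_seed(seed, sort(sample(eligible, n_hide)))

  n <- nrow(data)
  rows <- ((hide - 1) %% n) + 1L
  cols <- ((hide - 1) %/% n) + 1L

  new_obs <- (n - colSums(mask0)) - tabulate(cols, nbins = ncol(data))
  if (any(new_obs == 0)) {
    abort(sprintf(
      "masking at rate %.3g would leave column(s) %s with no observed cells; lower the rate.",
      rate, paste(names(data)[new_obs == 0], collapse = ", ")
    ))
  }

  types <- column_types(data)
  plan <- tibble(
    row = as.integer(rows),
    col = as.integer(cols),
    name = names(data)[cols],
    type = unname(types[cols]),
    true_num = vapply(seq_along(hide), function(i) {
      col <- data[[cols[i]]]
      if (is.factor(col)) NA_real_ else col[rows[i]]
    }, double(1)),
    true_level = vapply(seq_along(hide), function(i) {
      col <- data[[cols[i]]]
      if (is.factor(col)) as.character(col[rows[i]]) else NA_character_
    }, character(1))
  )
  attr(plan, "rate") <- rate
  attr(plan, "seed") <- seed
  attr(plan, "col_stats") <- tibble(
    name = names(data),
    mean = vapply(data, function(c) if (is.factor(c)) NA_real_ else mean(c, na.rm = TRUE), double(1)),
    sd = vapply(data, function(c) if (is.factor(c)) NA_real_ else stats::sd(c, na.rm = TRUE), double(1))
  )
  class(plan) <- c("mask_plan", class(plan))

  masked <- data
  for (j in unique(cols)) {
    masked[[j]][rows[cols == j]] <- NA
  }
  list(masked = masked, plan = plan)
}

#' Restore hidden cells from a mask plan
#'
#' @param masked The masked tibble from [mask_mcar()].
#' @param plan The corresponding `mask_plan`.
#' @return The original tibble (hidden cells restored to their true values).
#' @export
unmask <- function(masked, plan) {
  out <- masked
  for (i in seq_len(nrow(plan))) {
    j <- plan$col[i]
    out[[j]][plan$row[i]] <- if (is.factor(out[[j]])) {
      factor(plan$true_level[i], levels = levels(out[[j]]))
    } else {
      plan$true_num[i]
    }
  }
  out
}

#' Root-mean-squared imputation error over hidden continuous cells
#'
#' @param plan A `mask_plan` from [mask_mcar()].
#' @param completed The completed table (a `completed_tbl` or plain data
#'   frame) obtained by imputing the masked table.
#' @param scale `"raw"` compares on the original scale; `"zscore"`
#'   standardizes imputed and true values by the true data's per-column
#'   observed mean/sd before differencing (for cross-dataset aggregation).
#' @return sqrt(mean((imputed - true)^2)) over hidden continuous cells.
#' @export
rmse_on_masked <- function(plan, completed, scale = c("raw", "zscore")) {
  scale <- match.arg(scale)
  cont <- plan[plan$type == "continuous", ]
  if (nrow(cont) == 0) {
    abort("no hidden continuous cells; use pfc_on_masked() for categorical error.")
  }
  imp <- vapply(seq_len(nrow(cont)), function(i) {
    as.double(completed[[cont$col[i]]][cont$row[i]])
  }, double(1))
  tru <- cont$true_num
  if (scale == "zscore") {
    st <- attr(plan, "col_stats")
    mu <- st$mean[cont$col]
    sdv <- st$sd[cont$col]
    sdv[!is.finite(sdv) | sdv == 0] <- 1
    imp <- (imp - mu) / sdv
    tru <- (tru - mu) / sdv
  }
  sqrt(mean((imp - tru)^2))
}

#' Proportion of falsely classified hidden categorical cells
#'
#' @inheritParams rmse_on_masked
#' @return Fraction in \[0, 1\] of hidden categorical cells whose imputed
#'   level differs from the true level.
#' @export
pfc_on_masked <- function(plan, completed) {
  cat <- plan[plan$type == "categorical", ]
  if (nrow(cat) == 0) abort("no hidden categorical cells.")
  wrong <- vapply(seq_len(nrow(cat)), function(i) {
    as.character(completed[[cat$col[i]]][cat$row[i]]) != cat$true_level[i]
  }, logical(1))
  mean(wrong)
}

#' Benchmark imputation methods over an MCAR rate grid
#'
#' The standard harness for comparing imputers on a complete reference
#' table: for every `(rate, replicate)` one MCAR mask is drawn with a seed
#' derived from `(base_seed, rate index, replicate)` and shared by all
#' methods (paired design — adding a method never changes the masks), every
#' method imputes the same masked table, and RMSE (continuous cells) and PFC
#' (categorical cells, when present) are recorded per run together with
#' wall-clock seconds (informational only).
#'
#' @param data A complete data frame (no missing cells).
#' @param methods Named list of [imputer_spec()]s; an entry may also be a
#'   function `(masked_data, seed) -> completed table` (e.g. an oracle
#'   test-double).
#' @param rates Missing rates to scan (default 0.1 to 0.9 by 0.1).
#' @param n_replicates Mask draws per rate (default 10).
#' @param base_seed Integer seed of the whole grid.
#' @return An `evaluation_report` tibble, one row per
#'   (method, rate, replicate, metric): columns `method`, `rate`,
#'   `replicate`, `metric` (`"rmse"`/`"pfc"`), `value`, `seconds`, `error`.
#'   Aggregate with [tidy.evaluation_report()], plot with `autoplot()`.
#' @export
benchmark_grid <- function(data,
                           methods = list(mean = imputer_spec("mean"),
                                          boosted = imputer_spec("boosted")),
                           rates = seq(0.1, 0.9, by = 0.1),
                           n_replicates = 10,
                           base_seed = 1L) {
  data <- mb_normalise(data)
  mb_stopifnot_complete(data, "benchmark input")
  if (is.null(names(methods)) || any(!nzchar(names(methods)))) {
    abort("`methods` must be a named list.")
  }
  has_cat <- any(column_types(data) == "categorical")

  rows <- list()
  for (ri in seq_along(rates)) {
    for (rep_i in seq_len(n_replicates)) {
      seed <- derive_seed(base_seed, ri, rep_i)
      mk <- mask_mcar(data, rates[ri], seed = seed)
      for (mname in names(methods)) {
        t0 <- proc.time()[["elapsed"]]
        res <- tryCatch({
          method <- methods[[mname]]
          completed <- if (is.function(method)) {
            method(mk$masked, seed)
          } else {
            impute_missing(mk$masked, method, seed = seed)
          }
          vals <- list()
          if (any(mk$plan$type == "continuous")) {
            vals$rmse <- rmse_on_masked(mk$plan, completed)
          }
          if (has_cat && any(mk$plan$type == "categorical")) {
            vals$pfc <- pfc_on_masked(mk$plan, completed)
          }
          list(vals = vals, error = NA_character_)
        }, error = function(e) {
          list(vals = list(), error = conditionMessage(e))
        })
        secs <- proc.time()[["elapsed"]] - t0
        if (length(res$vals) == 0) {
          rows[[length(rows) + 1L]] <- tibble(
            method = mname, rate = rates[ri], replicate = rep_i,
            metric = NA_character_, value = NA_real_, seconds = secs,
            error = res$error
          )
        } else {
          for (metric in names(res$vals)) {
            rows[[length(rows) + 1L]] <- tibble(
              method = mname, rate = rates[ri], replicate = rep_i,
              metric = metric, value = res$vals[[metric]], seconds = secs,
              error = res$error
            )
          }
        }
      }
    }
  }
  out <- bind_rows(rows)
  attr(out, "base_seed") <- base_seed
  attr(out, "n_replicates") <- n_replicates
  attr(out, "rates") <- rates
  attr(out, "methods") <- names(methods)
  class(out) <- c("evaluation_report", class(out))
  out
}

#' Aggregate a benchmark grid to mean and sd per (method, rate, metric)
#'
#' @param x An `evaluation_report` from [benchmark_grid()].
#' @param ... Unused.
#' @return A tibble with `method`, `rate`, `metric`, `mean`, `sd`, `n`.
#' @method tidy evaluation_report
#' @export
tidy.evaluation_report <- function(x, ...) {
  as_tibble(x) |>
    filter(!is.na(.data$metric)) |>
    group_by(.data$method, .data$rate, .data$metric) |>
    summarise(mean = mean(.data$value), sd = stats::sd(.data$value),
              n = dplyr::n(), .groups = "drop")
}

#' @method glance evaluation_report
#' @export
glance.evaluation_report <- function(x, ...) {
  tibble(
    n_methods = length(attr(x, "methods")),
    n_rates = length(attr(x, "rates")),
    n_replicates = attr(x, "n_replicates"),
    n_failed = sum(!is.na(x$error)),
    base_seed = attr(x, "base_seed")
  )
}

#' Per-variable holdout diagnostic of imputation quality
#'
#' Hides a small fraction of each column's observed cells (all columns'
#' holdouts hidden simultaneously), imputes once with `spec`, and reports a
#' per-column agreement statistic between imputed and true holdout values:
#' Pearson correlation for continuous columns with at least 3 holdout cells
#' and non-constant truth, level accuracy for categorical columns, and mean
#' absolute error (flagged) for continuous columns with too few holdout
#' cells or constant truth.
#'
#' @param data A data frame, possibly with missing cells.
#' @param spec An [imputer_spec()].
#' @param fraction Fraction of each column's observed cells to hold out
#'   (minimum one cell per column).
#' @param seed Integer RNG seed.
#' @return A tibble with `name`, `type`, `n_holdout`, `statistic`
#'   (`"correlation"`, `"accuracy"` or `"mae"`), `value`, `flagged`.
#' @export
holdout_correlation_diagnostic <- function(data, spec = imputer_spec("boosted"),
                                           fraction = 0.05, seed = 1L) {
  data <- mb_normalise(data)
  check_observed_columns(data)
  mask0 <- missing_mask(data)
  n <- nrow(data)

  holdout <- with_seed(seed, {
    lapply(seq_along(data), function(j) {
      obs <- which(!mask0[, j])
      k <- max(1L, floor(fraction * length(obs)))
      if (k >= length(obs)) {
        abort(sprintf("column '%s' has too few observed cells to hold out from.",
                      names(data)[j]))
      }
      sort(sample(obs, k))
    })
  })

  masked <- data
  for (j in seq_along(data)) masked[[j]][holdout[[j]]] <- NA
  completed <- impute_missing(masked, spec, seed = seed)

  purrr::map_dfr(seq_along(data), function(j) {
    idx <- holdout[[j]]
    truth <- data[[j]][idx]
    imp <- completed[[j]][idx]
    if (is.factor(data[[j]])) {
      tibble(name = names(data)[j], type = "categorical",
             n_holdout = length(idx), statistic = "accuracy",
             value = mean(as.character(imp) == as.character(truth)),
             flagged = FALSE)
    } else if (length(idx) < 3 || stats::sd(truth) == 0) {
      tibble(name = names(data)[j], type = "continuous",
             n_holdout = length(idx), statistic = "mae",
             value = mean(abs(imp - truth)), flagged = TRUE)
    } else {
      tibble(name = names(data)[j], type = "continuous",
             n_holdout = length(idx), statistic = "correlation",
             value = suppressWarnings(stats::cor(imp, truth)), flagged = FALSE)
    }
  })
}
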