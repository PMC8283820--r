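#' Specify an imputation method and its parameters
#'
#' A validated container naming one of the six imputers and its settings,
#' used by [impute_missing()], [benchmark_grid()] and the command-line
#' entry points.
#'
#' @param method One of `"mean"`, `"median"`, `"knn"`, `"soft_svd"`,
#'   `"chained"`, `"boosted"`.
#' @param ... Method parameters. Recognised, with defaults:
#'   * `knn`: `k = 5` nearest neighbours.
#'   * `soft_svd`: `lambda = NULL` (singular-value shrinkage; when `NULL`,
#'     set to 1/50 of the top singular value of the initially filled,
#'     standardized matrix), `max_iter = 100`, `tol = 1e-5`.
#'   * `chained`: `n_cycles = 10` sweeps, `ridge_lambda = 0.01`,
#'     `init = "mean"`.
#'   * `boosted`: `nrounds = 100` trees per fit, `max_iter = 10` sweeps,
#'     `init = "mean"` or `"median"`, plus any xgboost parameter
#'     (`eta`, `max_depth`, ...) passed through to the learner.
#' @return An object of class `imputer_spec`.
#' @export
#' @examples
#' imputer_spec("boosted", nrounds = 50)
#' imputer_spec("knn", k = 3)
imputer_spec <- function(method = c("boosted", "mean", "median", "knn",
                                    "soft_svd", "chained"),
                         ...) {
  method <- match.arg(method)
  params <- list(...)
  defaults <- switch(method,
    mean = list(),
    median = list(),
    knn = list(k = 5),
    soft_svd = list(lambda = NULL, max_iter = 100, tol = 1e-5),
    chained = list(n_cycles = 10, ridge_lambda = 0.01, init = "mean"),
    boosted = list(nrounds = 100, max_iter = 10, init = "mean")
  )
  known <- names(defaults)
  extra <- setdiff(names(params), known)
  if (method != "boosted" && length(extra)) {
    abort(sprintf("unknown parameter(s) for method '%s': %s",
                  method, paste(extra, collapse = ", ")))
  }
  spec <- utils::modifyList(defaults, params)
  if (method == "knn") {
    if (!is.numeric(spec$k) || spec$k < 1) abort("knn `k` must be >= 1.")
    spec$k <- as.integer(spec$k)
  }
  if (method == "soft_svd" && !is.null(spec$lambda) && spec$lambda < 0) {
    abort("soft_svd `lambda` must be >= 0.")
  }
  if (method == "chained" && spec$n_cycles < 1) abort("`n_cycles` must be >= 1.")
  if (method == "boosted") {
    spec$init <- match.arg(spec$init, c("mean", "median"))
    if (spec$max_iter < 1) abort("`max_iter` must be >= 1.")
  }
  structure(list(method = method, params = spec), class = "imputer_spec")
}

#' @export
print.imputer_spec <- function(x, ...) {
  ps <- x$params[!vapply(x$params, is.null, logical(1))]
  cat("<imputer_spec> ", x$method,
      if (length(ps)) paste0(" (", paste(names(ps), unlist(lapply(ps, format)),
                                         sep = "=", collapse = ", "), ")"),
      "\n", sep = "")
  invisible(x)
}

#' Impute a table with any configured method
#'
#' Single dispatch point over the six imputers. All imputers share the same
#' contract: observed cells are returned bit-identical, only missing cells
#' are filled, and the result is a pure function of `(data, spec, seed)`.
#'
#' @param data A data frame with `NA` for missing cells; numeric columns are
#'   treated as continuous, factor/character columns as categorical.
#' @param spec An [imputer_spec()].
#' @param seed Integer seed governing any learner randomness.
#' @return A `completed_tbl`: the completed tibble with the spec, original
#'   missingness mask and (for the boosted method) iteration trace attached
#'   as attributes; see [tidy.completed_tbl()] and [glance.completed_tbl()].
#' @export
impute_missing <- function(data, spec = imputer_spec("boosted"), seed = 1L) {
  stopifnot(inherits(spec, "imputer_spec"))
  p <- spec$params
  switch(spec$method,
    mean = impute_simple(data, "mean"),
    median = impute_simple(data, "median"),
    knn = impute_knn(data, k = p$k),
    soft_svd = impute_soft_svd(data, lambda = p$lambda, max_iter = p$max_iter,
                               tol = p$tol),
    chained = impute_chained(data, n_cycles = p$n_cycles, seed = seed,
                             ridge_lambda = p$ridge_lambda, init = p$init),
    boosted = impute_boosted(data, spec = spec, seed = seed)
  )
}

# Constructor for completed results: a tibble carrying provenance.
new_completed <- function(data, spec, mask, iter_state = NULL,
                          provenance = list()) {
  structure(
    data,
    imputer = spec,
    original_mask = mask,
    iter_state = iter_state,
    provenance = provenance,
    class = c("completed_tbl", class(tibble()))
  )
}

#' Strip provenance from a completed table
#' @param x A `completed_tbl`.
#' @return A plain tibble.
#' @export
as_plain_tibble <- function(x) {
  attr(x, "imputer") <- NULL
  attr(x, "original_mask") <- NULL
  attr(x, "iter_state") <- NULL
  attr(x, "provenance") <- NULL
  class(x) <- setdiff(class(x), "completed_tbl")
  as_tibble(x)
}

#' @export
print.completed_tbl <- function(x, ...) {
  sp <- attr(x, "imputer")
  n_imp <- sum(attr(x, "original_mask"))
  cat(sprintf("<completed_tbl> %d x %d, %d cell(s) imputed by '%s'\n",
              nrow(x), ncol(x), n_imp, sp$method))
  print(as_plain_tibble(x), ...)
  invisible(x)
}

#' Long tibble of imputed cells from a completed table
#'
#' @param x A `completed_tbl` returned by an imputer.
#' @param ... Unused.
#' @return A tibble with one row per originally missing cell: `row`, `col`
#'   (1-based), `name`, `type`, and the imputed `value` (level label for
#'   categorical cells, formatted number otherwise) plus `value_num` for
#'   continuous cells.
#' @method tidy completed_tbl
#' @export
tidy.completed_tbl <- function(x, ...) {
  mask <- attr(x, "original_mask")
  idx <- which(mask, arr.ind = TRUE)
  if (nrow(idx) == 0) {
    return(tibble(row = integer(), col = integer(), name = character(),
                  type = character(), value = character(),
                  value_num = double()))
  }
  types <- column_types(as_plain_tibble(x))
  tibble(
    row = as.integer(idx[, 1]),
    col = as.integer(idx[, 2]),
    name = names(x)[idx[, 2]],
    type = unname(types[idx[, 2]]),
    value = vapply(seq_len(nrow(idx)), function(i) {
      v <- x[[idx[i, 2]]][idx[i, 1]]
      if (is.factor(x[[idx[i, 2]]])) as.character(v) else format(v, digits = 15)
    }, character(1)),
    value_num = vapply(seq_len(nrow(idx)), function(i) {
      col <- x[[idx[i, 2]]]
      if (is.factor(col)) NA_real_ else col[idx[i, 1]]
    }, double(1))
  ) |>
    arrange(.data$col, .data$row)
}

#' One-row summary of an imputation run
#'
#' @param x A `completed_tbl`.
#' @param ... Unused.
#' @return A one-row tibble: `method`, `n_imputed`, `n_sweeps`,
#'   `converged_reason`, `delta_continuous`, `delta_categorical` (last sweep;
#'   `NA` for non-iterative methods).
#' @method glance completed_tbl
#' @export
glance.completed_tbl <- function(x, ...) {
  st <- attr(x, "iter_state")
  dh <- st$delta_history
  tibble(
    method = attr(x, "imputer")$method,
    n_imputed = sum(attr(x, "original_mask")),
    n_sweeps = if (is.null(st)) NA_integer_ else st$iteration,
    converged_reason = if (is.null(st)) NA_character_ else st$converged_reason,
    delta_continuous = if (is.null(dh) || !nrow(dh)) NA_real_ else dh$delta_continuous[nrow(dh)],
    delta_categorical = if (is.null(dh) || !nrow(dh)) NA_real_ else dh$delta_categorical[nrow(dh)]
  )
}
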