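# Column-wise fill values: mean/median for continuous, modal level for
# categorical (ties broken by the lowest level code).
column_fill_values <- function(data, strategy = c("mean", "median")) {
  strategy <- match.arg(strategy)
  lapply(data, function(col) {
    obs <- col[!is.na(col)]
    if (is.factor(col)) {
      tab <- tabulate(as.integer(obs), nbins = nlevels(col))
      factor(levels(col)[which.max(tab)], levels = levels(col))
    } else if (strategy == "mean") {
      mean(obs)
    } else {
      stats::median(obs)
    }
  })
}

check_observed_columns <- function(data) {
  all_missing <- vapply(data, function(col) all(is.na(col)), logical(1))
  if (any(all_missing)) {
    abort(sprintf("column(s) with no observed cells: %s",
                  paste(names(data)[all_missing], collapse = ", ")))
  }
  invisible(data)
}

#' Mean/median/mode imputation
#'
#' Fills each missing continuous cell with its column's observed mean (or
#' median) and each missing categorical cell with the modal observed level
#' (ties broken by the lowest level code). Also used as the initial guess of
#' the iterative imputers.
#'
#' @inheritParams impute_missing
#' @param strategy `"mean"` or `"median"`.
#' @return A `completed_tbl`.
#' @export
#' @examples
#' impute_simple(data.frame(x = c(1, NA, 3)), "mean")$x
impute_simple <- function(data, strategy = c("mean", "median")) {
  strategy <- match.arg(strategy)
  data <- mb_normalise(data)
  check_observed_columns(data)
  mask <- missing_mask(data)
  fills <- column_fill_values(data, strategy)
  out <- data
  for (j in seq_along(out)) {
    miss <- is.na(out[[j]])
    if (any(miss)) out[[j]][miss] <- fills[[j]]
  }
  new_completed(out, imputer_spec(strategy), mask)
}

#' k-nearest-neighbour imputation with partial distances
#'
#' Each missing cell `(i, j)` is filled from the `k` rows nearest to row `i`
#' among rows where column `j` is observed, using the mean (continuous) or
#' modal level (categorical) of their column-`j` values. Distance between two
#' rows is a partial Euclidean distance over the columns observed in both:
#' continuous columns are standardized by observed statistics, categorical
#' columns contribute 0/1 mismatch, and the squared distance is rescaled by
#' `n_columns / n_usable` so rows with few shared columns are not
#' artificially close.
#'
#' @inheritParams impute_missing
#' @param k Number of neighbours (default 5).
#' @return A `completed_tbl`. Rows sharing no observed column with any donor
#'   fall back to the column mean/mode with a warning.
#' @export
impute_knn <- function(data, k = 5) {
  data <- mb_normalise(data)
  check_observed_columns(data)
  k <- as.integer(k)
  if (k < 1) abort("`k` must be >= 1.")
  n <- nrow(data)
  if (n < k + 1) abort(sprintf("need at least k + 1 = %d rows.", k + 1))
  mask <- missing_mask(data)
  m <- ncol(data)

  # standardized numeric representation; categorical as codes
  z <- matrix(NA_real_, n, m)
  is_cat <- vapply(data, is.factor, logical(1))
  for (j in seq_len(m)) {
    col <- data[[j]]
    if (is_cat[j]) {
      z[, j] <- as.integer(col)
    } else {
      mu <- mean(col, na.rm = TRUE)
      sdv <- stats::sd(col, na.rm = TRUE)
      if (!is.finite(sdv) || sdv == 0) sdv <- 1
      z[, j] <- (col - mu) / sdv
    }
  }
  obs <- !mask

  fills <- column_fill_values(data, "mean")
  out <- data
  fallback <- FALSE
  need_rows <- which(rowSums(mask) > 0)
  for (i in need_rows) {
    # squared partial distances from row i to all rows, vectorized over rows
    diff <- sweep(z, 2, z[i, ], "-")
    if (any(is_cat)) diff[, is_cat] <- as.double(diff[, is_cat, drop = FALSE] != 0)
    shared <- obs & rep(obs[i, ], each = n)
    diff[!shared] <- 0
    usable <- rowSums(shared)
    d2 <- rowSums(diff^2) * m / pmax(usable, 1)
    d2[usable == 0] <- Inf
    d2[i] <- Inf
    for (j in which(mask[i, ])) {
      donors <- which(obs[, j] & is.finite(d2))
      if (length(donors) == 0) {
        out[[j]][i] <- fills[[j]]
        fallback <- TRUE
        next
      }
      ord <- donors[order(d2[donors], donors)]
      nb <- ord[seq_len(min(k, length(ord)))]
      if (is_cat[j]) {
        tab <- tabulate(as.integer(data[[j]][nb]), nbins = nlevels(data[[j]]))
        out[[j]][i] <- factor(levels(data[[j]])[which.max(tab)],
                              levels = levels(data[[j]]))
      } else {
        out[[j]][i] <- mean(data[[j]][nb])
      }
    }
  }
  if (fallback) {
    warn("some cells had no usable neighbour; filled with column mean/mode.")
  }
  new_completed(out, imputer_spec("knn", k = k), mask)
}
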