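#' Matrix completion by iterative soft-thresholded SVD
#'
#' Low-rank matrix completion: missing entries are filled with the current
#' estimate (initially the column mean), and the filled matrix is repeatedly
#' replaced by its SVD reconstruction with every singular value shrunk by
#' `lambda` (values below `lambda` vanish). Iteration stops when the relative
#' change of the filled entries drops below `tol` or after `max_iter` sweeps.
#' Categorical columns are one-hot expanded internally and re-assigned by the
#' largest reconstructed indicator.
#'
#' With `standardize = TRUE` (default) columns are centered and scaled by
#' their observed statistics before completion and back-transformed after, so
#' `lambda` acts on the correlation-like scale; a `lambda` exceeding the top
#' singular value shrinks everything to zero and missing cells revert to
#' column means. Note that at exactly `lambda = 0` with no rank cap the
#' reconstruction is the identity and the initial fill is returned unchanged;
#' exact completion of a known-low-rank matrix uses `lambda = 0` with
#' `max_rank` set to that rank (hard truncation), typically with
#' `standardize = FALSE` since standardizing a rank-1 matrix makes its
#' columns collinear.
#'
#' @inheritParams impute_missing
#' @param lambda Singular-value shrinkage, `>= 0`. `NULL` (default) uses
#'   1/50 of the top singular value of the initially filled matrix.
#' @param max_iter Maximum number of SVD sweeps.
#' @param tol Relative-change convergence threshold on the filled entries.
#' @param max_rank Optional hard cap on the reconstruction rank; singular
#'   values beyond it are zeroed after shrinkage.
#' @param standardize Center/scale columns by observed statistics first.
#' @return A `completed_tbl`; a `converged` flag in its provenance records
#'   whether `tol` was reached.
#' @export
impute_soft_svd <- function(data, lambda = NULL, max_iter = 100, tol = 1e-5,
                            max_rank = NULL, standardize = TRUE) {
  data <- mb_normalise(data)
  check_observed_columns(data)
  if (!is.null(lambda) && lambda < 0) abort("`lambda` must be >= 0.")
  mask <- missing_mask(data)
  if (!any(mask)) {
    return(new_completed(data, imputer_spec("soft_svd", lambda = lambda %||% 0,
                                            max_iter = max_iter, tol = tol),
                         mask, provenance = list(converged = TRUE, n_iter = 0L)))
  }
  is_cat <- vapply(data, is.factor, logical(1))

  # numeric working matrix: continuous columns as-is, categorical one-hot
  blocks <- list()      # working-matrix column indices per feature
  work_cols <- list()
  for (j in seq_along(data)) {
    col <- data[[j]]
    if (is_cat[j]) {
      code <- as.integer(col)
      idx <- integer(nlevels(col))
      for (l in seq_len(nlevels(col))) {
        v <- as.double(code == l)
        v[is.na(code)] <- NA
        work_cols[[length(work_cols) + 1L]] <- v
        idx[l] <- length(work_cols)
      }
      blocks[[j]] <- idx
    } else {
      work_cols[[length(work_cols) + 1L]] <- as.double(col)
      blocks[[j]] <- length(work_cols)
    }
  }
  W <- do.call(cbind, work_cols)
  wmiss <- is.na(W)

  if (standardize) {
    mu <- colMeans(W, na.rm = TRUE)
    sdv <- apply(W, 2, stats::sd, na.rm = TRUE)
    sdv[!is.finite(sdv) | sdv == 0] <- 1
  } else {
    mu <- rep(0, ncol(W))
    sdv <- rep(1, ncol(W))
  }
  Z <- sweep(sweep(W, 2, mu, "-"), 2, sdv, "/")
  # initial fill: column mean (zero in the standardized space)
  cm <- colMeans(Z, na.rm = TRUE)
  for (j in seq_len(ncol(Z))) Z[wmiss[, j], j] <- cm[j]

  if (is.null(lambda)) lambda <- svd(Z, nu = 0, nv = 0)$d[1] / 50

  converged <- FALSE
  it <- 0L
  repeat {
    it <- it + 1L
    sv <- svd(Z)
    d <- pmax(sv$d - lambda, 0)
    if (!is.null(max_rank) && length(d) > max_rank) {
      d[seq(max_rank + 1L, length(d))] <- 0
    }
    recon <- sv$u %*% (d * t(sv$v))
    old_fill <- Z[wmiss]
    Z[wmiss] <- recon[wmiss]
    denom <- sqrt(sum(old_fill^2))
    change <- sqrt(sum((Z[wmiss] - old_fill)^2)) / max(denom, .Machine$double.eps)
    if (change < tol) {
      converged <- TRUE
      break
    }
    if (it >= max_iter) break
  }
  if (!converged) {
    warn(sprintf("soft-SVD completion did not reach tol = %.1e in %d sweeps.",
                 tol, max_iter))
  }

  filled <- sweep(sweep(Z, 2, sdv, "*"), 2, mu, "+")
  out <- data
  for (j in seq_along(out)) {
    miss <- mask[, j]
    if (!any(miss)) next
    if (is_cat[j]) {
      sub <- filled[miss, blocks[[j]], drop = FALSE]
      out[[j]][miss] <- factor(levels(data[[j]])[apply(sub, 1, which.max)],
                               levels = levels(data[[j]]))
    } else {
      out[[j]][miss] <- filled[miss, blocks[[j]]]
    }
  }
  new_completed(out,
                imputer_spec("soft_svd", lambda = lambda, max_iter = max_iter,
                             tol = tol),
                mask,
                provenance = list(converged = converged, n_iter = it,
                                  lambda = lambda, max_rank = max_rank,
                                  standardize = standardize))
}
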