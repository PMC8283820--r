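#' @importFrom rlang abort warn .data %||% :=
#' @importFrom tibble tibble as_tibble
#' @importFrom dplyr mutate select filter arrange group_by summarise ungroup bind_rows
#' @importFrom generics tidy glance
NULL

#' @export
generics::tidy

#' @export
generics::glance

# Normalize a user data frame into the package's canonical form:
# a tibble whose numeric columns are continuous features and whose
# factor columns are categorical features; NA marks a missing cell.
# Character columns are coerced to factors (levels in order of first
# appearance is NOT used: sorted unique levels, matching read_table).
mb_normalise <- function(data) {
  if (!is.data.frame(data)) {
    abort("`data` must be a data frame or tibble.")
  }
  nm <- names(data)
  if (anyDuplicated(nm) || any(!nzchar(nm))) {
    abort("column names must be unique and non-empty.")
  }
  out <- as_tibble(data)
  for (j in seq_along(out)) {
    col <- out[[j]]
    if (is.character(col)) {
      out[[j]] <- factor(col, levels = sort(unique(col[!is.na(col)])))
    } else if (is.logical(col)) {
      out[[j]] <- factor(col, levels = c("FALSE", "TRUE"))
    } else if (is.integer(col)) {
      out[[j]] <- as.double(col)
    } else if (!is.numeric(col) && !is.factor(col)) {
      abort(sprintf("column '%s' has unsupported type '%s'.", nm[j], class(col)[1]))
    }
  }
  out
}

#' Per-column feature types of a table
#'
#' @param data A data frame; numeric columns are `"continuous"`, factor
#'   (or character) columns `"categorical"`.
#' @return Named character vector of `"continuous"`/`"categorical"`.
#' @export
column_types <- function(data) {
  data <- mb_normalise(data)
  vapply(data, function(col) {
    if (is.factor(col)) "categorical" else "continuous"
  }, character(1))
}

#' Missingness mask of a table
#'
#' @param data A data frame.
#' @return A logical matrix, `TRUE` where a cell is missing.
#' @export
missing_mask <- function(data) {
  m <- matrix(FALSE, nrow(data), ncol(data), dimnames = list(NULL, names(data)))
  for (j in seq_along(data)) m[, j] <- is.na(data[[j]])
  m
}

# Deterministic seed mixing kept below 2^31 so derived seeds are valid
# R integers. Adding methods or replicates never perturbs earlier draws.
derive_seed <- function(base_seed, ...) {
  idx <- c(...)
  s <- as.double(base_seed) %% 2147483647
  for (k in seq_along(idx)) {
    s <- (s * 48271 + as.double(idx[k]) * 9973 + 1) %% 2147483647
  }
  as.integer(s)
}

# Evaluate `expr` under a temporary RNG state seeded with `seed`.
with_seed <- function(seed, expr) {
  old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    get(".Random.seed", envir = globalenv())
  } else {
    NULL
  }
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
        rm(".Random.seed", envir = globalenv())
      }
    } else {
      assign(".Random.seed", old, envir = globalenv())
    }
  })
  set.seed(seed)
  expr
}

# One-hot design matrix for mixed-type predictors. Continuous columns pass
# through; each categorical column expands to one indicator per level.
# Deterministic column order: input order, levels in level order.
onehot_matrix <- function(data, exclude = character(0)) {
  keep <- setdiff(names(data), exclude)
  cols <- list()
  for (nm in keep) {
    col <- data[[nm]]
    if (is.factor(col)) {
      lev <- levels(col)
      code <- as.integer(col)
      for (l in seq_along(lev)) {
        cols[[paste0(nm, "=", lev[l])]] <- as.double(code == l)
      }
    } else {
      cols[[nm]] <- as.double(col)
    }
  }
  mat <- do.call(cbind, cols)
  colnames(mat) <- names(cols)
  mat
}

mb_stopifnot_complete <- function(data, what = "input") {
  if (any(vapply(data, function(x) anyNA(x), logical(1)))) {
    abort(sprintf("%s must not contain missing cells.", what))
  }
  invisible(data)
}
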