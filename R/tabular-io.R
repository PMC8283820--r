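#' Read a delimited table with explicit missing-value tokens and type inference
#'
#' Reads a CSV/TSV file with a header row into a tibble in the package's
#' canonical form: numeric columns are continuous features, factor columns
#' categorical, `NA` marks a missing cell. A cell whose whitespace-trimmed
#' text matches one of `missing_tokens` is treated as missing. A column whose
#' non-missing cells all parse as numbers is continuous; any other column is
#' categorical with levels sorted alphabetically. `type_hints` override the
#' inference per column.
#'
#' @param path Path to a delimited text file with a header row.
#' @param missing_tokens Character vector of cell values denoting missingness
#'   (compared after trimming surrounding whitespace).
#' @param type_hints Optional named character vector mapping column names to
#'   `"continuous"` or `"categorical"`.
#' @param max_categories A categorical column with more distinct levels than
#'   this triggers a warning (it is likely an identifier column).
#' @param delim Field delimiter; by default inferred from the file extension
#'   (`.tsv`/`.txt` are tab-separated, anything else comma-separated).
#' @return A tibble of continuous (double) and categorical (factor) columns.
#' @export
#' @examples
#' path <- tempfile(fileext = ".csv")
#' writeLines(c("a,b", "1.5,x", "NA,y", "2.0,x"), path)
#' read_table(path)
read_table <- function(path,
                       missing_tokens = c("", "NA", "NaN", "nan", "NULL"),
                       type_hints = NULL,
                       max_categories = 20,
                       delim = NULL) {
  if (!file.exists(path)) abort(sprintf("file '%s' does not exist.", path))
  if (is.null(delim)) {
    delim <- if (grepl("\\.(tsv|txt)$", path, ignore.case = TRUE)) "\t" else ","
  }
  raw <- suppressWarnings(suppressMessages(readr::read_delim(
    path,
    delim = delim,
    col_types = readr::cols(.default = readr::col_character()),
    na = character(0),
    trim_ws = FALSE,
    progress = FALSE,
    show_col_types = FALSE
  )))
  prob <- readr::problems(raw)
  if (nrow(prob) > 0) {
    abort(sprintf(
      "ragged row(s) while parsing '%s': first problem at row %d (%s).",
      path, prob$row[1], prob$expected[1]
    ))
  }
  nm <- names(raw)
  if (anyDuplicated(sub("\\.\\.\\.[0-9]+$", "", nm))) {
    abort("duplicate header names.")
  }
  if (nrow(raw) == 0) abort("no data rows.")

  out <- vector("list", ncol(raw))
  names(out) <- nm
  for (j in seq_along(raw)) {
    cell <- trimws(raw[[j]])
    cell[cell %in% missing_tokens | is.na(cell)] <- NA_character_
    obs <- cell[!is.na(cell)]
    hint <- if (!is.null(type_hints)) unname(type_hints[nm[j]]) else NA_character_
    num <- suppressWarnings(as.double(obs))
    numeric_ok <- length(obs) > 0 && !anyNA(num)
    type <- if (!is.na(hint)) {
      match.arg(hint, c("continuous", "categorical"))
    } else if (numeric_ok) {
      "continuous"
    } else {
      "categorical"
    }
    if (type == "continuous") {
      val <- suppressWarnings(as.double(cell))
      if (any(is.na(val) & !is.na(cell))) {
        abort(sprintf("column '%s' hinted continuous but has non-numeric cells.", nm[j]))
      }
      out[[j]] <- val
    } else {
      lev <- sort(unique(obs))
      if (length(lev) > max_categories) {
        warn(sprintf(
          "categorical column '%s' has %d levels (max_categories = %d); is it an identifier?",
          nm[j], length(lev), max_categories
        ))
      }
      out[[j]] <- factor(cell, levels = lev)
    }
  }
  as_tibble(out)
}

#' Write a table with a configurable missing-value token
#'
#' Inverse of [read_table()]: categorical cells are written as their level
#' labels, missing cells as `missing_token`. Reading the result back with the
#' same token reproduces the table (values, missingness, column types).
#'
#' @param data A data frame in canonical form.
#' @param path Output file path; extension selects the delimiter as in
#'   [read_table()].
#' @param missing_token String written for missing cells.
#' @param delim Optional delimiter override.
#' @return `path`, invisibly.
#' @export
write_table <- function(data, path, missing_token = "NA", delim = NULL) {
  data <- mb_normalise(data)
  if (is.null(delim)) {
    delim <- if (grepl("\\.(tsv|txt)$", path, ignore.case = TRUE)) "\t" else ","
  }
  chr <- lapply(data, function(col) {
    s <- if (is.factor(col)) as.character(col) else format(col, digits = 17, trim = TRUE, scientific = FALSE)
    s[is.na(col)] <- missing_token
    s
  })
  readr::write_delim(as_tibble(chr), path, delim = delim, na = missing_token, progress = FALSE)
  invisible(path)
}

#' Per-column missingness and distribution summaries
#'
#' @param data A data frame in canonical form.
#' @return A tibble with one row per column, in column order: `name`, `type`,
#'   `n_observed`, `missing_fraction` (exact count ratio), `mean` and `median`
#'   of observed values (continuous columns), `n_levels` and `top_level`
#'   (categorical columns).
#' @export
missing_rate_summary <- function(data) {
  data <- mb_normalise(data)
  n <- nrow(data)
  purrr::map_dfr(names(data), function(nm) {
    col <- data[[nm]]
    obs <- col[!is.na(col)]
    cont <- !is.factor(col)
    tibble(
      name = nm,
      type = if (cont) "continuous" else "categorical",
      n_observed = length(obs),
      missing_fraction = sum(is.na(col)) / n,
      mean = if (cont && length(obs)) mean(obs) else NA_real_,
      median = if (cont && length(obs)) stats::median(obs) else NA_real_,
      n_levels = if (cont) NA_integer_ else nlevels(col),
      top_level = if (cont || !length(obs)) NA_character_ else {
        tab <- table(obs)
        names(tab)[which.max(tab)]
      }
    )
  })
}

#' Drop columns that exceed a missingness threshold
#'
#' Retains exactly the columns whose missing fraction is at most
#' `max_fraction`, preserving column order and all rows; the standard
#' pre-filter before imputing tables with very sparse features (e.g.
#' laboratory panels where some tests are rarely ordered).
#'
#' @param data A data frame in canonical form.
#' @param max_fraction Highest tolerated per-column missing fraction.
#' @return The filtered tibble.
#' @export
filter_by_missingness <- function(data, max_fraction) {
  data <- mb_normalise(data)
  frac <- colMeans(missing_mask(data))
  keep <- frac <= max_fraction
  if (!any(keep)) {
    abort(sprintf(
      "all %d columns exceed missing fraction %.3g; raise `max_fraction`.",
      ncol(data), max_fraction
    ))
  }
  data[, keep, drop = FALSE]
}
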