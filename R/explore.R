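#' Pearson correlation between two continuous features, with scatter points
#'
#' @param data A data frame (typically a completed table).
#' @param feature_a,feature_b Names of two continuous columns.
#' @return A list with `estimate` (Pearson r; `NA` with `flagged = TRUE`
#'   when either feature is constant) and `points`, a tibble of the paired
#'   values for scatter rendering.
#' @export
pairwise_correlation <- function(data, feature_a, feature_b) {
  data <- mb_normalise(data)
  for (nm in c(feature_a, feature_b)) {
    if (!nm %in% names(data)) abort(sprintf("unknown feature '%s'.", nm))
    if (is.factor(data[[nm]])) abort(sprintf("feature '%s' is categorical.", nm))
  }
  a <- data[[feature_a]]
  b <- data[[feature_b]]
  keep <- !is.na(a) & !is.na(b)
  if (sum(keep) < 3) abort("need at least 3 complete pairs.")
  flagged <- stats::sd(a[keep]) == 0 || stats::sd(b[keep]) == 0
  list(
    estimate = if (flagged) NA_real_ else stats::cor(a[keep], b[keep]),
    flagged = flagged,
    points = tibble(!!feature_a := a[keep], !!feature_b := b[keep])
  )
}

#' Missingness pattern matrix with optional feature dendrogram
#'
#' Builds the binary missingness image (1 = missing) of a table. With
#' `cluster_features = TRUE`, features are hierarchically clustered
#' (average linkage on Euclidean distances between the binary indicator
#' columns) and reordered by the dendrogram's leaf order, so features that
#' go missing together sit next to each other.
#'
#' @param data A data frame in canonical form.
#' @param cluster_features Reorder columns by the missingness dendrogram.
#' @return A `pattern_view` list: `matrix` (0/1, display order), `row_order`,
#'   `col_order` (permutations of the original indices), `merges` (tibble of
#'   `node_a`, `node_b`, `height` in hclust convention: negative = leaf,
#'   positive = earlier merge) and the `hclust` object (or `NULL`).
#' @export
missingness_pattern <- function(data, cluster_features = TRUE) {
  data <- mb_normalise(data)
  mask <- missing_mask(data)
  bin <- matrix(as.integer(mask), nrow(mask), ncol(mask),
                dimnames = list(NULL, colnames(mask)))
  col_order <- seq_len(ncol(bin))
  merges <- NULL
  hc <- NULL
  if (cluster_features && ncol(bin) >= 2) {
    d <- stats::dist(t(bin), method = "euclidean")
    hc <- stats::hclust(d, method = "average")
    col_order <- hc$order
    merges <- tibble(
      node_a = hc$merge[, 1],
      node_b = hc$merge[, 2],
      height = hc$height
    )
  }
  structure(
    list(
      matrix = bin[, col_order, drop = FALSE],
      row_order = seq_len(nrow(bin)),
      col_order = col_order,
      merges = merges,
      hclust = hc
    ),
    class = "pattern_view"
  )
}

#' @export
print.pattern_view <- function(x, ...) {
  cat(sprintf("<pattern_view> %d x %d, %.1f%% missing%s\n",
              nrow(x$matrix), ncol(x$matrix), 100 * mean(x$matrix),
              if (is.null(x$hclust)) "" else ", features clustered"))
  invisible(x)
}

# Standardize columns (observed stats); constant columns become zero.
standardize_columns <- function(mat) {
  mu <- colMeans(mat)
  sdv <- apply(mat, 2, stats::sd)
  sdv[!is.finite(sdv) | sdv == 0] <- 1
  sweep(sweep(mat, 2, mu, "-"), 2, sdv, "/")
}

#' Two-dimensional embedding of samples by PCA or t-SNE
#'
#' Operates on the z-standardized numeric representation of a completed
#' table (categorical columns one-hot expanded). PCA returns the first two
#' principal-component scores with a deterministic sign convention (each
#' component's largest-magnitude loading is positive); t-SNE runs the
#' exact (all-pairs) algorithm with perplexity calibration.
#'
#' @param data A completed data frame (no missing cells).
#' @param method `"pca"` or `"tsne"`.
#' @param seed Integer seed (t-SNE initialization; PCA is deterministic).
#' @param perplexity,learning_rate,n_iter t-SNE parameters.
#' @return An `embedding` tibble with columns `.sample`, `dim1`, `dim2`;
#'   for PCA the component standard deviations are attached as attribute
#'   `sdev`.
#' @export
embed_samples <- function(data, method = c("pca", "tsne"), seed = 1L,
                          perplexity = 30, learning_rate = 200,
                          n_iter = 1000) {
  method <- match.arg(method)
  data <- mb_normalise(data)
  mb_stopifnot_complete(data, "embedding input")
  if (nrow(data) < 3) abort("need at least 3 samples.")
  x <- standardize_columns(onehot_matrix(data))

  if (method == "pca") {
    pc <- stats::prcomp(x, center = FALSE, scale. = FALSE)
    k <- min(2L, ncol(pc$rotation))
    coords <- matrix(0, nrow(x), 2)
    for (c_i in seq_len(k)) {
      load <- pc$rotation[, c_i]
      flip <- if (load[which.max(abs(load))] < 0) -1 else 1
      coords[, c_i] <- flip * pc$x[, c_i]
    }
    out <- tibble(.sample = seq_len(nrow(x)), dim1 = coords[, 1],
                  dim2 = coords[, 2])
    attr(out, "sdev") <- pc$sdev
    attr(out, "method") <- "pca"
    class(out) <- c("embedding", class(out))
    return(out)
  }

  if (perplexity >= nrow(x)) abort("perplexity must be < n_samples.")
  coords <- tsne_exact(x, perplexity = perplexity, eta = learning_rate,
                       n_iter = n_iter, seed = seed)
  out <- tibble(.sample = seq_len(nrow(x)), dim1 = coords[, 1],
                dim2 = coords[, 2])
  attr(out, "method") <- "tsne"
  class(out) <- c("embedding", class(out))
  out
}

#' Seeded best-of-n k-means on 2-D (or any) coordinates
#'
#' @param points A data frame of numeric coordinates (e.g. an embedding;
#'   a `.sample` column is ignored) or a numeric matrix.
#' @param k Number of clusters, `1 <= k <= n`.
#' @param seed Integer seed for the random restarts.
#' @param n_init Number of random restarts; the lowest within-cluster sum
#'   of squares wins.
#' @return A list with `labels` (integer per sample), `wcss` (total
#'   within-cluster sum of squares), `centers`.
#' @export
kmeans_cluster <- function(points, k, seed = 1L, n_init = 10) {
  x <- points_matrix(points)
  if (k < 1 || k > nrow(x)) abort("`k` must be in [1, n_samples].")
  if (k == 1) {
    ctr <- colMeans(x)
    return(list(labels = rep(1L, nrow(x)),
                wcss = sum(sweep(x, 2, ctr, "-")^2),
                centers = matrix(ctr, nrow = 1)))
  }
  if (k == nrow(x)) {
    return(list(labels = seq_len(nrow(x)), wcss = 0, centers = x))
  }
  km <- with_seed(seed, suppressWarnings(
    stats::kmeans(x, centers = k, nstart = n_init, iter.max = 50)
  ))
  list(labels = as.integer(km$cluster), wcss = km$tot.withinss,
       centers = km$centers)
}

points_matrix <- function(points) {
  if (is.matrix(points)) return(points)
  df <- as.data.frame(points)
  df <- df[, setdiff(names(df), ".sample"), drop = FALSE]
  as.matrix(df)
}

#' Suggest the number of clusters by the elbow (second-difference) rule
#'
#' Runs [kmeans_cluster()] for `k` in `[k_min, k_max]` and suggests the
#' interior `k` maximizing the second difference of the within-cluster
#' sum-of-squares curve, `(wcss[k-1] - wcss[k]) - (wcss[k] - wcss[k+1])` —
#' the sharpest knee; ties go to the smallest `k`. The curve is checked to
#' be non-increasing; a violation (possible with too few restarts) raises a
#' warning diagnostic.
#'
#' @inheritParams kmeans_cluster
#' @param k_min,k_max Range of cluster counts (defaults 1 and 9).
#' @return A list with `suggested_k` and `wcss_by_k` (tibble `k`, `wcss`).
#' @export
elbow_suggest_k <- function(points, k_min = 1, k_max = 9, seed = 1L,
                            n_init = 10) {
  x <- points_matrix(points)
  if (k_max > nrow(x)) abort("`k_max` must be <= n_samples.")
  ks <- seq.int(k_min, k_max)
  if (length(ks) < 3) abort("need at least 3 k values for an interior elbow.")
  wcss <- vapply(ks, function(k) {
    kmeans_cluster(x, k, seed = derive_seed(seed, k), n_init = n_init)$wcss
  }, double(1))
  if (any(diff(wcss) > 1e-8 * max(wcss, 1))) {
    warn("wcss curve is not non-increasing; consider more restarts (n_init).")
  }
  list(
    suggested_k = ks[knee_index(wcss)],
    wcss_by_k = tibble(k = ks, wcss = wcss)
  )
}

# Index (into the wcss vector) of the interior point with the largest
# second difference; ties resolve to the smallest k (which.max takes the
# first maximum).
knee_index <- function(wcss) {
  interior <- seq(2, length(wcss) - 1)
  second_diff <- (wcss[interior - 1] - wcss[interior]) -
    (wcss[interior] - wcss[interior + 1])
  interior[which.max(second_diff)]
}
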