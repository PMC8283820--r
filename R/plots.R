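#' @importFrom ggplot2 ggplot aes geom_line geom_point geom_tile geom_col
#'   geom_abline labs theme_minimal scale_fill_manual autoplot
NULL

#' @export
ggplot2::autoplot

#' Benchmark curves: mean imputation error against missing rate
#'
#' @param object An `evaluation_report` from [benchmark_grid()].
#' @param metric Which metric to draw (default `"rmse"`).
#' @param ... Unused.
#' @return A ggplot.
#' @method autoplot evaluation_report
#' @export
autoplot.evaluation_report <- function(object, metric = "rmse", ...) {
  agg <- tidy(object) |> filter(.data$metric == !!metric)
  ggplot(agg, aes(x = .data$rate, y = .data$mean, colour = .data$method)) +
    geom_line() +
    geom_point() +
    labs(x = "missing rate", y = paste("mean", toupper(metric)),
         colour = "method") +
    theme_minimal()
}

#' Missingness-pattern image (black = missing)
#'
#' @param object A `pattern_view` from [missingness_pattern()].
#' @param ... Unused.
#' @return A ggplot.
#' @method autoplot pattern_view
#' @export
autoplot.pattern_view <- function(object, ...) {
  df <- as_tibble(as.data.frame.table(object$matrix, stringsAsFactors = FALSE))
  names(df) <- c("row", "feature", "missing")
  df$row <- as.integer(factor(df$row, levels = unique(df$row)))
  df$feature <- factor(df$feature, levels = colnames(object$matrix))
  ggplot(df, aes(x = .data$feature, y = .data$row,
                 fill = factor(.data$missing))) +
    geom_tile() +
    scale_fill_manual(values = c(`0` = "white", `1` = "black"),
                      labels = c(`0` = "observed", `1` = "missing")) +
    labs(x = NULL, y = "sample", fill = NULL) +
    theme_minimal()
}

#' ROC curve of a cross-validated prediction report
#'
#' @param object A `prediction_report` from [cv_predict()].
#' @param ... Unused.
#' @return A ggplot.
#' @method autoplot prediction_report
#' @export
autoplot.prediction_report <- function(object, ...) {
  ggplot(object$roc_points, aes(x = .data$fpr, y = .data$tpr)) +
    geom_abline(slope = 1, intercept = 0, linetype = "dashed",
                colour = "grey60") +
    geom_line() +
    labs(x = "false positive rate", y = "true positive rate",
         title = sprintf("%s, AUC = %.3f", object$method, object$auc)) +
    theme_minimal()
}

#' Feature-ranking bar chart
#'
#' @param object A `feature_ranking` from [rank_features()].
#' @param ... Unused.
#' @return A ggplot.
#' @method autoplot feature_ranking
#' @export
autoplot.feature_ranking <- function(object, ...) {
  df <- as_tibble(object) |> arrange(.data$rank)
  df$feature <- factor(df$feature, levels = rev(df$feature))
  ggplot(df, aes(x = .data$score, y = .data$feature,
                 fill = .data$selected)) +
    geom_col() +
    labs(x = paste0("score (", attr(object, "method"), ")"), y = NULL,
         fill = "selected") +
    theme_minimal()
}

#' Scatter plot of a 2-D embedding, optionally coloured by cluster labels
#'
#' @param embedding An `embedding` tibble from [embed_samples()].
#' @param labels Optional per-sample labels (e.g. from [kmeans_cluster()]).
#' @return A ggplot.
#' @export
plot_embedding <- function(embedding, labels = NULL) {
  df <- as_tibble(embedding)
  if (!is.null(labels)) df$cluster <- factor(labels)
  p <- ggplot(df, aes(x = .data$dim1, y = .data$dim2))
  p <- if (is.null(labels)) {
    p + geom_point(alpha = 0.7)
  } else {
    p + geom_point(aes(colour = .data$cluster), alpha = 0.7)
  }
  p + labs(x = "dimension 1", y = "dimension 2") + theme_minimal()
}

#' Elbow curve of within-cluster sum of squares by k
#'
#' @param elbow Result of [elbow_suggest_k()].
#' @return A ggplot with the suggested k marked.
#' @export
plot_elbow <- function(elbow) {
  df <- elbow$wcss_by_k
  ggplot(df, aes(x = .data$k, y = .data$wcss)) +
    geom_line() +
    geom_point() +
    geom_point(data = df[df$k == elbow$suggested_k, ],
               colour = "forestgreen", size = 3) +
    labs(x = "k", y = "within-cluster sum of squares") +
    theme_minimal()
}
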