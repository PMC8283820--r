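#' Split off a response column before imputation
#'
#' When downstream prediction is planned, the response must not leak into
#' the imputation of its predictors; this removes it up front. The response
#' must be fully observed.
#'
#' @param data A data frame containing the response column.
#' @param response_name Name of the response column.
#' @return A list with `predictors` (tibble without the response) and
#'   `response` (the response vector).
#' @export
exclude_response <- function(data, response_name) {
  data <- mb_normalise(data)
  if (!response_name %in% names(data)) {
    abort(sprintf("unknown response column '%s'.", response_name))
  }
  y <- data[[response_name]]
  if (anyNA(y)) {
    abort(sprintf("response '%s' has missing values at row(s): %s",
                  response_name,
                  paste(which(is.na(y)), collapse = ", ")))
  }
  list(
    predictors = data[, setdiff(names(data), response_name), drop = FALSE],
    response = y
  )
}

# Binary responses are accepted as 0/1 numerics, logicals or 2-level
# factors; returns integer 0/1.
as_binary_response <- function(y) {
  if (is.factor(y)) {
    if (nlevels(y) != 2) abort("factor response must have exactly 2 levels.")
    return(as.integer(y) - 1L)
  }
  u <- sort(unique(y))
  if (!all(u %in% c(0, 1))) abort("binary response must take values 0/1.")
  as.integer(y)
}

#' Rank features by penalized-regression coefficients or boosted importance
#'
#' Features are standardized (categorical columns one-hot expanded); the
#' score of a feature is the absolute coefficient of an L1/L2/elastic-net
#' penalized (logistic for binary responses, linear otherwise) regression
#' at a penalty chosen by internal cross-validation, or the total split-gain
#' importance of a 100-round boosted-tree model. One-hot columns of the same
#' categorical feature are summed back to a single per-feature score.
#'
#' @param data A completed data frame (no missing cells).
#' @param response Response vector (binary 0/1 for classification, numeric
#'   otherwise).
#' @param method `"lasso"`, `"ridge"`, `"elastic_net"` or
#'   `"boosted_importance"`.
#' @param top_n How many features to flag as selected (clipped to the
#'   feature count with a warning).
#' @param seed Integer seed (cross-validation folds / learner).
#' @return A `feature_ranking` tibble: `feature`, `score` (>= 0), `rank`
#'   (ties keep original feature order), `selected`.
#' @export
rank_features <- function(data, response,
                          method = c("lasso", "ridge", "elastic_net",
                                     "boosted_importance"),
                          top_n = 10, seed = 1L) {
  method <- match.arg(method)
  data <- mb_normalise(data)
  mb_stopifnot_complete(data, "feature-ranking input")
  if (length(response) != nrow(data)) abort("response length mismatch.")
  if (top_n > ncol(data)) {
    warn(sprintf("top_n = %d exceeds the %d features; clipping.",
                 top_n, ncol(data)))
    top_n <- ncol(data)
  }
  x <- onehot_matrix(data)
  feat_of_col <- sub("=.*$", "", colnames(x))
  binary <- is.factor(response) || all(response %in% c(0, 1))

  if (method == "boosted_importance") {
    y <- if (binary) as_binary_response(response) else as.double(response)
    params <- list(
      objective = if (binary) "binary:logistic" else "reg:squarederror",
      nthread = 1, seed = as.integer(seed)
    )
    fit <- xgboost::xgb.train(
      params = params,
      data = xgboost::xgb.DMatrix(x, label = y, nthread = 1),
      nrounds = 100, verbose = 0
    )
    imp <- xgboost::xgb.importance(model = fit)
    col_score <- stats::setNames(rep(0, ncol(x)), colnames(x))
    col_score[imp$Feature] <- imp$Gain
  } else {
    alpha <- switch(method, lasso = 1, ridge = 0, elastic_net = 0.5)
    family <- if (binary) "binomial" else "gaussian"
    y <- if (binary) as_binary_response(response) else as.double(response)
    xs <- standardize_columns(x)
    cvfit <- with_seed(seed, glmnet::cv.glmnet(xs, y, alpha = alpha,
                                               family = family, nfolds = 5,
                                               standardize = FALSE))
    beta <- as.matrix(stats::coef(cvfit, s = "lambda.1se"))[-1, 1]
    col_score <- abs(beta)
  }

  score <- vapply(names(data), function(nm) {
    sum(col_score[feat_of_col == nm])
  }, double(1))
  ord <- order(-score, seq_along(score))
  rank <- integer(length(score))
  rank[ord] <- seq_along(score)
  out <- tibble(
    feature = names(data),
    score = unname(score),
    rank = rank,
    selected = rank <= top_n
  )
  attr(out, "method") <- method
  attr(out, "seed") <- seed
  class(out) <- c("feature_ranking", class(out))
  out
}

#' ROC and precision-recall metrics from scores and binary truth
#'
#' Sweeps thresholds over the unique score values (ties grouped: one ROC
#' vertex per unique score), computes the ROC curve from (0, 0) to (1, 1),
#' the trapezoidal area under it (equal to the Mann-Whitney probability
#' that a random positive outscores a random negative, ties counted half),
#' and the precision-recall curve at the same thresholds.
#'
#' @param scores Numeric prediction scores (higher = more positive).
#' @param truth Binary labels (0/1, logical or 2-level factor).
#' @return A list with `auc`, `roc_points` (tibble `fpr`, `tpr`,
#'   `threshold`) and `pr_points` (tibble `recall`, `precision`).
#' @export
#' @examples
#' roc_pr_metrics(c(0.9, 0.4, 0.8, 0.1), c(1, 0, 1, 0))$auc
roc_pr_metrics <- function(scores, truth) {
  truth <- as_binary_response(truth)
  stopifnot(length(scores) == length(truth))
  n_pos <- sum(truth == 1)
  n_neg <- sum(truth == 0)
  if (n_pos == 0 || n_neg == 0) abort("both classes must be present.")

  ord <- order(-scores)
  s <- scores[ord]
  y <- truth[ord]
  # group tied scores: one vertex per unique score
  last_of_group <- c(s[-1] != s[-length(s)], TRUE)
  tp <- cumsum(y)[last_of_group]
  fp <- cumsum(1 - y)[last_of_group]
  thr <- s[last_of_group]

  tpr <- c(0, tp / n_pos)
  fpr <- c(0, fp / n_neg)
  auc <- sum(diff(fpr) * (utils::head(tpr, -1) + utils::tail(tpr, -1)) / 2)

  recall <- tp / n_pos
  precision <- tp / (tp + fp)
  list(
    auc = auc,
    roc_points = tibble(fpr = fpr, tpr = tpr,
                        threshold = c(Inf, thr)),
    pr_points = tibble(recall = recall, precision = precision)
  )
}

# Stratified fold assignment: within each class, samples are shuffled and
# dealt round-robin, so every fold holds both classes whenever counts allow.
stratified_folds <- function(truth, n_folds, seed) {
  fold <- integer(length(truth))
  with_seed(seed, {
    for (cls in unique(truth)) {
      idx <- which(truth == cls)
      idx <- sample(idx)
      fold[idx] <- rep_len(seq_len(n_folds), length(idx))
    }
  })
  fold
}

#' Cross-validated out-of-fold prediction of a binary response
#'
#' Stratified, seeded k-fold cross-validation: for each fold a model is
#' trained on the remaining folds and produces scores for the held-out
#' samples, so every sample receives exactly one out-of-fold score; ROC/PR
#' metrics are computed on the pooled scores. Scores are class-1
#' probabilities for every method.
#'
#' @param features A completed data frame of predictors (no missing cells).
#' @param response Binary response (0/1, logical or 2-level factor).
#' @param method `"penalized_linear"` (L1-penalized logistic regression
#'   with internally cross-validated penalty), `"random_forest"` (ranger
#'   probability forest), `"boosted_trees"` (xgboost, 100 rounds) or
#'   `"knn"` (class-vote fraction, k = 5).
#' @param n_folds Number of folds (default 5).
#' @param seed Integer seed for fold assignment and learners.
#' @return A `prediction_report` list: `scores` tibble (`sample`, `fold`,
#'   `score`, `label`), `auc`, `roc_points`, `pr_points`, `method`,
#'   `n_folds`, `seed`. Use `tidy()` for the per-sample table and
#'   `glance()` for the one-row summary; `autoplot()` draws the ROC curve.
#' @export
cv_predict <- function(features, response,
                       method = c("penalized_linear", "random_forest",
                                  "boosted_trees", "knn"),
                       n_folds = 5, seed = 1L) {
  method <- match.arg(method)
  features <- mb_normalise(features)
  mb_stopifnot_complete(features, "cv_predict features")
  y <- as_binary_response(response)
  if (length(y) != nrow(features)) abort("response length mismatch.")
  counts <- table(y)
  if (any(counts < n_folds)) {
    abort(sprintf(
      "class with %d member(s) cannot populate %d folds; use fewer folds.",
      min(counts), n_folds
    ))
  }
  fold <- stratified_folds(y, n_folds, seed)
  x <- onehot_matrix(features)

  score <- rep(NA_real_, length(y))
  for (f in seq_len(n_folds)) {
    tr <- fold != f
    te <- !tr
    score[te] <- fit_predict_classifier(
      x[tr, , drop = FALSE], y[tr], x[te, , drop = FALSE],
      method = method, seed = derive_seed(seed, f)
    )
  }
  metrics <- roc_pr_metrics(score, y)
  structure(
    list(
      scores = tibble(sample = seq_along(y), fold = fold, score = score,
                      label = y),
      auc = metrics$auc,
      roc_points = metrics$roc_points,
      pr_points = metrics$pr_points,
      method = method,
      n_folds = n_folds,
      seed = seed
    ),
    class = "prediction_report"
  )
}

fit_predict_classifier <- function(x_tr, y_tr, x_te, method, seed) {
  switch(method,
    penalized_linear = {
      fit <- with_seed(seed, glmnet::cv.glmnet(x_tr, y_tr, family = "binomial",
                                               alpha = 1, nfolds = 5))
      as.double(stats::predict(fit, x_te, s = "lambda.min", type = "response"))
    },
    random_forest = {
      df <- as.data.frame(x_tr)
      names(df) <- make.names(names(df), unique = TRUE)
      df$.y <- factor(y_tr, levels = c(0, 1))
      fit <- ranger::ranger(dependent.variable.name = ".y", data = df,
                            probability = TRUE, num.trees = 500,
                            seed = seed, num.threads = 1)
      dfte <- as.data.frame(x_te)
      names(dfte) <- make.names(names(dfte), unique = TRUE)
      stats::predict(fit, data = dfte, num.threads = 1)$predictions[, "1"]
    },
    boosted_trees = {
      params <- list(objective = "binary:logistic", nthread = 1,
                     seed = as.integer(seed))
      fit <- xgboost::xgb.train(
        params = params,
        data = xgboost::xgb.DMatrix(x_tr, label = y_tr, nthread = 1),
        nrounds = 100, verbose = 0
      )
      as.double(stats::predict(fit, x_te))
    },
    knn = {
      xs_tr <- standardize_columns(x_tr)
      mu <- colMeans(x_tr)
      sdv <- apply(x_tr, 2, stats::sd)
      sdv[!is.finite(sdv) | sdv == 0] <- 1
      xs_te <- sweep(sweep(x_te, 2, mu, "-"), 2, sdv, "/")
      pred <- with_seed(seed, class::knn(xs_tr, xs_te,
                                         cl = factor(y_tr, levels = c(0, 1)),
                                         k = 5, prob = TRUE))
      p_win <- attr(pred, "prob")
      ifelse(pred == "1", p_win, 1 - p_win)
    }
  )
}

#' @export
print.prediction_report <- function(x, ...) {
  cat(sprintf("<prediction_report> %s, %d-fold CV, n = %d, AUC = %.3f\n",
              x$method, x$n_folds, nrow(x$scores), x$auc))
  invisible(x)
}

#' @method tidy prediction_report
#' @export
tidy.prediction_report <- function(x, ...) x$scores

#' @method glance prediction_report
#' @export
glance.prediction_report <- function(x, ...) {
  tibble(method = x$method, n = nrow(x$scores), n_folds = x$n_folds,
         auc = x$auc, seed = x$seed)
}
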