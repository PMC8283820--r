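#' Specify a synthetic mixed-type fixture
#'
#' Describes a deterministic generator of correlated mixed-type tables with
#' known ground truth: a low-rank latent Gaussian block plus independent
#' noise, optionally with planted linear column dependencies, planted
#' well-separated sample clusters, a planted (or null) binary response, and
#' per-column MCAR missingness.
#'
#' @param n_samples,n_continuous,n_categorical Table dimensions; categorical
#'   columns are built by quantile-binning designated latent scores.
#' @param latent_rank Rank of the shared latent block (`<= min(n, m)`).
#' @param noise_sd Standard deviation of the independent per-cell noise.
#' @param n_levels Number of quantile bins for categorical columns.
#' @param planted Optional list with any of:
#'   * `linear`: list of `list(from, to, slope, sd)` — column `to` is
#'     rebuilt as `slope * column(from) + N(0, sd)`;
#'   * `clusters`: `list(k, scale)` — samples are split into `k` equal
#'     groups whose latent scores are shifted by centers `scale` apart
#'     (in within-cluster sd units);
#'   * `response`: `list(indices, effects)` — a binary response drawn with
#'     log-odds proportional to `sum(effects * z(column(indices)))`,
#'     rescaled to standard deviation `sqrt(sum(effects^2))` so the signal
#'     strength does not depend on the random correlation among the
#'     informative columns; with no `response` entry, [generate_fixture()]
#'     still draws an independent Bernoulli(1/2) response usable as a null.
#' @param missing Optional per-column MCAR rates in \[0, 1) (recycled).
#' @param seed Integer seed; the base draw, noise, masking and label
#'   substreams are derived from it independently, so adding planted
#'   structure never perturbs the base draw.
#' @return A `fixture_spec` list.
#' @export
fixture_spec <- function(n_samples, n_continuous, n_categorical = 0,
                         latent_rank = 2, noise_sd = 0.1, n_levels = 3,
                         planted = list(), missing = NULL, seed = 1L) {
  stopifnot(n_samples >= 1, n_continuous + n_categorical >= 1,
            latent_rank >= 1, noise_sd >= 0, n_levels >= 2)
  m <- n_continuous + n_categorical
  if (latent_rank > min(n_samples, m)) {
    abort("`latent_rank` must be <= min(n_samples, n_features).")
  }
  if (!is.null(missing) && any(missing < 0 | missing >= 1)) {
    abort("`missing` rates must be in [0, 1).")
  }
  structure(
    list(n_samples = n_samples, n_continuous = n_continuous,
         n_categorical = n_categorical, latent_rank = latent_rank,
         noise_sd = noise_sd, n_levels = n_levels, planted = planted,
         missing = missing, seed = as.integer(seed)),
    class = "fixture_spec"
  )
}

#' Generate a synthetic fixture with known ground truth
#'
#' @param spec A [fixture_spec()].
#' @return A `fixture` list: `data` (tibble, with `NA`s when missingness is
#'   planted), `truth` (the complete pre-masking tibble), `labels` (list
#'   with `cluster` and `response` vectors) and the `spec`. Deterministic:
#'   the same spec always yields a bit-identical fixture.
#' @export
generate_fixture <- function(spec) {
  stopifnot(inherits(spec, "fixture_spec"))
  n <- spec$n_samples
  m <- spec$n_continuous + spec$n_categorical
  r <- spec$latent_rank

  seed_base <- derive_seed(spec$seed, 101)
  seed_noise <- derive_seed(spec$seed, 202)
  seed_mask <- derive_seed(spec$seed, 303)
  seed_labels <- derive_seed(spec$seed, 404)

  L <- with_seed(seed_base, matrix(stats::rnorm(n * r), n, r))
  R <- with_seed(derive_seed(spec$seed, 102),
                 matrix(stats::rnorm(m * r), m, r))

  cluster_labels <- rep(1L, n)
  if (!is.null(spec$planted$clusters)) {
    k <- spec$planted$clusters$k
    scale <- spec$planted$clusters$scale %||% 10
    cluster_labels <- rep_len(seq_len(k), n)
    # centers on unit directions in the first two latent dimensions
    ang <- 2 * pi * (seq_len(k) - 1) / k
    centers <- matrix(0, k, r)
    centers[, 1] <- scale * cos(ang)
    if (r >= 2) centers[, 2] <- scale * sin(ang)
    L <- L + centers[cluster_labels, , drop = FALSE]
  }

  X <- L %*% t(R)
  if (spec$noise_sd > 0) {
    X <- X + with_seed(seed_noise,
                       matrix(stats::rnorm(n * m, sd = spec$noise_sd), n, m))
  }

  if (!is.null(spec$planted$linear)) {
    pl <- spec$planted$linear
    if (!is.null(pl$from)) pl <- list(pl)  # single pair given unnested
    for (i in seq_along(pl)) {
      p <- pl[[i]]
      sdp <- p$sd %||% spec$noise_sd
      eps <- if (sdp > 0) {
        with_seed(derive_seed(spec$seed, 505, i), stats::rnorm(n, sd = sdp))
      } else {
        0
      }
      X[, p$to] <- p$slope * X[, p$from] + eps
    }
  }

  cols <- list()
  for (j in seq_len(spec$n_continuous)) {
    cols[[paste0("x", j)]] <- X[, j]
  }
  if (spec$n_categorical > 0) {
    for (jj in seq_len(spec$n_categorical)) {
      j <- spec$n_continuous + jj
      q <- stats::quantile(X[, j], probs = seq(0, 1, length.out = spec$n_levels + 1))
      q[1] <- -Inf
      q[length(q)] <- Inf
      lev <- paste0("l", seq_len(spec$n_levels))
      cols[[paste0("c", jj)]] <- factor(lev[cut(X[, j], q, labels = FALSE)],
                                        levels = lev)
    }
  }
  truth <- as_tibble(cols)

  resp_spec <- spec$planted$response
  response <- with_seed(seed_labels, {
    if (!is.null(resp_spec)) {
      z <- vapply(resp_spec$indices, function(j) {
        as.double(scale(X[, j]))
      }, double(n))
      lp <- as.double(z %*% resp_spec$effects)
      # informative columns share latent factors, so the raw combination's
      # variance depends on their (random) correlations; rescale to sd
      # = ||effects|| so the planted signal strength is seed-invariant
      lp <- lp * sqrt(sum(resp_spec$effects^2)) / stats::sd(lp)
      stats::rbinom(n, 1, stats::plogis(lp))
    } else {
      stats::rbinom(n, 1, 0.5)
    }
  })

  data <- truth
  if (!is.null(spec$missing)) {
    rates <- rep_len(spec$missing, m)
    with_seed(seed_mask, {
      for (j in seq_len(m)) {
        if (rates[j] <= 0) next
        hide <- sample(n, floor(rates[j] * n))
        data[[j]][hide] <- NA
      }
    })
  }

  structure(
    list(data = data, truth = truth,
         labels = list(cluster = cluster_labels, response = response),
         spec = spec),
    class = "fixture"
  )
}

#' @export
print.fixture <- function(x, ...) {
  cat(sprintf("<fixture> %d x %d (%d continuous, %d categorical), rank %d, %.1f%% missing\n",
              x$spec$n_samples, x$spec$n_continuous + x$spec$n_categorical,
              x$spec$n_continuous, x$spec$n_categorical,
              x$spec$latent_rank, 100 * mean(missing_mask(x$data))))
  invisible(x)
}

#' The canonical named fixtures used across the package's tests and examples
#'
#' Five deterministic fixtures:
#' * `rank2` — 500 x 10 continuous, latent rank 2, noise sd 0.1; the
#'   low-rank benchmark table for imputer comparisons.
#' * `linear` — 500 x 6 continuous with column 3 planted as
#'   `2 * column 1 + N(0, 0.05)`.
#' * `clusters3` — 300 x 5 continuous with three equal planted clusters,
#'   centers 10 within-cluster sd apart.
#' * `signal` — 500 x 20 continuous, latent rank 4, with a binary response
#'   driven by columns 2, 5 and 9 (standardized effects 1.5, 1.2, 1.0).
#' * `null` — as `signal` but the response is an independent Bernoulli(1/2).
#'
#' @param seed Integer master seed for the suite.
#' @return Named list of `fixture` objects.
#' @export
standard_suite <- function(seed = 1L) {
  list(
    rank2 = generate_fixture(fixture_spec(
      n_samples = 500, n_continuous = 10, latent_rank = 2, noise_sd = 0.1,
      seed = derive_seed(seed, 11)
    )),
    linear = generate_fixture(fixture_spec(
      n_samples = 500, n_continuous = 6, latent_rank = 2, noise_sd = 0.1,
      planted = list(linear = list(list(from = 1, to = 3, slope = 2, sd = 0.05))),
      seed = derive_seed(seed, 22)
    )),
    clusters3 = generate_fixture(fixture_spec(
      n_samples = 300, n_continuous = 5, latent_rank = 2, noise_sd = 0.5,
      planted = list(clusters = list(k = 3, scale = 10)),
      seed = derive_seed(seed, 33)
    )),
    signal = generate_fixture(fixture_spec(
      n_samples = 500, n_continuous = 20, latent_rank = 4, noise_sd = 0.7,
      planted = list(response = list(indices = c(2, 5, 9),
                                     effects = c(1.5, 1.2, 1.0))),
      seed = derive_seed(seed, 44)
    )),
    null = generate_fixture(fixture_spec(
      n_samples = 500, n_continuous = 20, latent_rank = 4, noise_sd = 0.7,
      seed = derive_seed(seed, 55)
    ))
  )
}
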