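# Exact (all-pairs) t-SNE, sufficient for the table sizes this package
# embeds (hundreds of samples). Conditional-probability bandwidths are
# calibrated per point by binary search on the target perplexity; the map
# is optimized by gradient descent with momentum, adaptive gains and early
# exaggeration, as in the reference algorithm.
tsne_exact <- function(x, perplexity = 30, eta = 200, n_iter = 1000,
                       seed = 1L) {
  n <- nrow(x)
  if (n < 4) abort("t-SNE needs at least 4 samples.")

  # pairwise squared Euclidean distances
  ss <- rowSums(x^2)
  D <- outer(ss, ss, "+") - 2 * tcrossprod(x)
  D[D < 0] <- 0
  diag(D) <- 0

  logU <- log(perplexity)
  P <- matrix(0, n, n)
  for (i in seq_len(n)) {
    di <- D[i, -i]
    beta <- 1
    beta_lo <- -Inf
    beta_hi <- Inf
    for (iter in 1:50) {
      p <- exp(-di * beta)
      sumP <- sum(p)
      if (sumP <= 0) sumP <- .Machine$double.xmin
      H <- log(sumP) + beta * sum(di * p) / sumP
      if (abs(H - logU) < 1e-5) break
      if (H > logU) {
        beta_lo <- beta
        beta <- if (is.finite(beta_hi)) (beta + beta_hi) / 2 else beta * 2
      } else {
        beta_hi <- beta
        beta <- if (is.finite(beta_lo)) (beta + beta_lo) / 2 else beta / 2
      }
    }
    P[i, -i] <- p / sumP
  }
  P <- (P + t(P)) / (2 * n)
  P <- pmax(P, 1e-12)

  Y <- with_seed(seed, matrix(stats::rnorm(n * 2, sd = 1e-4), n, 2))
  dY <- matrix(0, n, 2)
  gains <- matrix(1, n, 2)
  exagg_until <- min(250L, max(50L, n_iter %/% 4))
  P_run <- P * 4  # early exaggeration (exact-algorithm setting)

  for (it in seq_len(n_iter)) {
    if (it == exagg_until + 1L) P_run <- P
    momentum <- if (it <= exagg_until) 0.5 else 0.8

    ssy <- rowSums(Y^2)
    num <- 1 / (1 + outer(ssy, ssy, "+") - 2 * tcrossprod(Y))
    diag(num) <- 0
    Q <- num / sum(num)
    Q <- pmax(Q, 1e-12)

    W <- (P_run - Q) * num
    grad <- 4 * (diag(rowSums(W)) - W) %*% Y

    gains <- ifelse(sign(grad) != sign(dY), gains + 0.2, gains * 0.8)
    gains[gains < 0.01] <- 0.01
    dY <- momentum * dY - eta * gains * grad
    Y <- Y + dY
    Y <- sweep(Y, 2, colMeans(Y), "-")
  }
  Y
}
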