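# Small table builders shared across the test files.

# Mixed-type tibble with a known missingness layout.
tiny_mixed <- function() {
  tibble::tibble(
    a = c(1.5, NA, 2.0, 4.5),
    b = factor(c("x", "y", NA, "x"), levels = c("x", "y")),
    c = c(10, 20, 30, 40)
  )
}

# Write a tibble as CSV text and return the path.
write_fixture_csv <- function(lines) {
  path <- tempfile(fileext = ".csv")
  writeLines(lines, path)
  path
}

# Agreement between two labelings up to relabeling (max over label
# permutations of the matched fraction).
label_agreement <- function(a, b) {
  ua <- sort(unique(a))
  perms <- function(v) {
    if (length(v) <= 1) return(list(v))
    out <- list()
    for (i in seq_along(v)) {
      for (p in perms(v[-i])) out[[length(out) + 1]] <- c(v[i], p)
    }
    out
  }
  best <- 0
  for (p in perms(ua)) {
    remap <- stats::setNames(p, ua)
    best <- max(best, mean(remap[as.character(a)] == b))
  }
  best
}

# Independent brute-force Mann-Whitney AUC: probability that a random
# positive outscores a random negative, ties counted one half.
mann_whitney_auc <- function(scores, truth) {
  pos <- scores[truth == 1]
  neg <- scores[truth == 0]
  total <- 0
  for (p in pos) {
    total <- total + sum(p > neg) + 0.5 * sum(p == neg)
  }
  total / (length(pos) * length(neg))
}

# Independent average-linkage agglomeration over a distance matrix;
# returns the sorted merge heights.
average_linkage_heights <- function(D) {
  m <- nrow(D)
  active <- as.list(seq_len(m))
  heights <- numeric(0)
  dist_between <- function(g1, g2) {
    mean(D[g1, g2])
  }
  while (length(active) > 1) {
    best <- c(1, 2)
    best_d <- Inf
    for (i in seq_len(length(active) - 1)) {
      for (j in seq(i + 1, length(active))) {
        d <- dist_between(active[[i]], active[[j]])
        if (d < best_d) {
          best_d <- d
          best <- c(i, j)
        }
      }
    }
    heights <- c(heights, best_d)
    merged <- c(active[[best[1]]], active[[best[2]]])
    active <- active[-best]
    active[[length(active) + 1]] <- merged
  }
  sort(heights)
}
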