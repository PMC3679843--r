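# Fixtures and independent brute-force oracles used across the suite.
# The oracles are deliberately naive (explicit loops, no sorting shortcuts
# shared with the implementation) so agreement is a genuine cross-check.

toy_1d <- function(values, ids = NULL) {
  descriptor_table(matrix(values, ncol = 1L), ids = ids)
}

random_table <- function(n, p, seed) {
  set.seed(seed)
  descriptor_table(matrix(rnorm(n * p), n, p), ids = paste0("m", seq_len(n)))
}

# Naive distance between two vectors.
naive_dist <- function(x, z, metric = "euclidean", W = NULL) {
  switch(metric,
    euclidean = sqrt(sum((x - z)^2)),
    manhattan = sum(abs(x - z)),
    mahalanobis = sqrt(drop(t(x - z) %*% W %*% (x - z))))
}

# Naive full AD pipeline: per-sample thresholds and query decisions computed
# from scratch with loops. `X` and `Q` are plain matrices (already scaled or
# raw, the caller decides); returns ref_val, K, t, fallback and per-query
# K_j.
naive_knn_ad <- function(X, Q, k, metric = "euclidean", W = NULL) {
  n <- nrow(X)
  avg <- numeric(n)
  sorted_rows <- vector("list", n)
  for (i in seq_len(n)) {
    d <- numeric(0)
    for (j in seq_len(n)) if (j != i)
      d <- c(d, naive_dist(X[i, ], X[j, ], metric, W))
    d <- sort(d)
    sorted_rows[[i]] <- d
    avg[i] <- sum(d[1:k]) / k
  }
  q1 <- quantile(avg, 0.25, type = 7, names = FALSE)
  q3 <- quantile(avg, 0.75, type = 7, names = FALSE)
  rv <- q3 + 1.5 * (q3 - q1)
  K <- integer(n); t <- rep(NA_real_, n)
  for (i in seq_len(n)) {
    kept <- sorted_rows[[i]][sorted_rows[[i]] <= rv]
    K[i] <- length(kept)
    if (K[i] > 0) t[i] <- mean(kept)
  }
  fallback <- K == 0L
  if (all(fallback)) stop("degenerate: all K_i = 0")
  t[fallback] <- min(t[!fallback])
  K_j <- integer(nrow(Q))
  for (q in seq_len(nrow(Q))) {
    cnt <- 0L
    for (i in seq_len(n))
      if (naive_dist(Q[q, ], X[i, ], metric, W) <= t[i]) cnt <- cnt + 1L
    K_j[q] <- cnt
  }
  list(ref_val = rv, K = K, t = t, fallback = fallback, K_j = K_j)
}

# Naive classical kNN AD (loops, independent of build_neighbour_table).
naive_classical_knn <- function(X, Q, k, percentile) {
  n <- nrow(X)
  avg_train <- numeric(n)
  for (i in seq_len(n)) {
    d <- numeric(0)
    for (j in seq_len(n)) if (j != i) d <- c(d, naive_dist(X[i, ], X[j, ]))
    avg_train[i] <- mean(sort(d)[1:k])
  }
  thr <- quantile(avg_train, percentile / 100, type = 7, names = FALSE)
  in_ad <- logical(nrow(Q))
  for (q in seq_len(nrow(Q))) {
    d <- numeric(0)
    for (i in seq_len(n)) d <- c(d, naive_dist(Q[q, ], X[i, ]))
    in_ad[q] <- mean(sort(d)[1:k]) <= thr
  }
  list(threshold = thr, in_ad = in_ad)
}

# Trapezoid quadrature of a fitted 1-D density over a wide grid.
integrate_kde_1d <- function(est, lo, hi, n_grid = 4001L) {
  g <- seq(lo, hi, length.out = n_grid)
  f <- kde_evaluate(est, matrix(g, ncol = 1L), scaled_input = TRUE)
  sum((f[-1] + f[-n_grid]) / 2 * diff(g))
}
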