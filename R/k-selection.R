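#' Box-plot summary of a numeric vector
#'
#' Five-number box summary with whiskers at `Q1 - w*(Q3 - Q1)` and
#' `Q3 + w*(Q3 - Q1)` clipped to the data range; points outside the fences
#' are returned as outliers. Uses the package-wide quantile rule so box
#' summaries are consistent with the reference-value computation.
#'
#' @param values Non-empty numeric vector.
#' @param w Whisker factor (default 1.5).
#' @param quantile_rule See [ad_quantile()].
#' @return List with `median`, `q1`, `q3`, `whisker_low`, `whisker_high`,
#'   `outliers`, `w`.
#' @export
boxplot_summary <- function(values, w = 1.5, quantile_rule = "linear") {
  if (!length(values)) stop("empty input.")
  q <- ad_quantile(values, c(0.25, 0.5, 0.75), rule = quantile_rule)
  iqr <- q[3L] - q[1L]
  lo_fence <- q[1L] - w * iqr
  hi_fence <- q[3L] + w * iqr
  inside <- values >= lo_fence & values <= hi_fence
  list(median = q[2L], q1 = q[1L], q3 = q[3L],
       whisker_low = max(min(values), lo_fence),
       whisker_high = min(max(values), hi_fence),
       outliers = values[!inside], w = w)
}

#' Empirical default smoothing parameter
#'
#' The rule-of-thumb neighbour count `round(n^(1/3))`, clipped to
#' `[1, n - 1]`; adequate for most data sets when a full Monte Carlo
#' optimization is not warranted.
#'
#' @param n Training-set size, `n >= 3`.
#' @return A positive integer.
#' @export
default_k <- function(n) {
  if (!is.numeric(n) || length(n) != 1L || n < 3L) stop("n must be an integer >= 3.")
  as.integer(min(max(round(n^(1 / 3)), 1L), n - 1L))
}

#' Monte Carlo optimization of the smoothing parameter k
#'
#' Repeatedly splits the training set at random (a fraction `test_fraction`
#' held out), fits the kNN-AD on the inner-training part for every candidate
#' `k`, and records the percentage of held-out samples retained within the
#' AD. The same split is shared by all `k` within an iteration (paired
#' comparison), which makes the per-iteration retained percentage
#' non-decreasing in `k` and reduces between-k variance.
#'
#' @param train A [descriptor_table()].
#' @param k_grid Candidate `k` values (default `1:25`); all must be valid
#'   for the inner-training size.
#' @param test_fraction Held-out fraction per iteration (default 0.2).
#' @param iterations Number of random splits (default 1000).
#' @param seed Integer seed; stored in the result for provenance.
#' @param metric A [metric_spec()] or metric name.
#' @param pretreat Autoscale inner-training data per split (default `TRUE`).
#' @param w Whisker factor for the box summaries.
#' @param quantile_rule See [ad_quantile()].
#' @return An object of class `k_optimization` with fields `k_grid`,
#'   `retained_pct` (iterations x k matrix), `summaries`, `mean_curve`,
#'   `seed`, `iterations`, `test_fraction`.
#' @export
optimize_k <- function(train, k_grid = 1:25, test_fraction = 0.2,
                       iterations = 1000L, seed = 1L, metric = "euclidean",
                       pretreat = TRUE, w = 1.5, quantile_rule = "linear") {
  stopifnot(inherits(train, "descriptor_table"))
  n <- nrow(train$X)
  if (test_fraction <= 0 || test_fraction >= 1) stop("test_fraction must be in (0, 1).")
  n_test <- max(1L, floor(test_fraction * n))
  n_inner <- n - n_test
  k_grid <- sort(unique(as.integer(k_grid)))
  if (any(k_grid < 1L)) stop("k_grid values must be >= 1.")
  if (max(k_grid) > n_inner - 1L)
    stop(sprintf("largest k (%d) exceeds inner-training size minus one (%d).",
                 max(k_grid), n_inner - 1L))
  if (n_inner < 3L) stop("inner-training set too small; lower test_fraction.")
  metric <- as_metric(metric)

  # Reorder to a canonical id-sorted permutation so the drawn splits depend
  # on sample identity, not on input row order.
  canon <- order(train$ids)
  train <- train[canon]

  retained <- matrix(NA_real_, iterations, length(k_grid))
  with_preserved_seed(seed, {
    for (it in seq_len(iterations)) {
      hold <- sample.int(n, n_test)
      inner <- train[-hold]
      outer <- train[hold]
      Xi <- inner$X
      scaling <- NULL
      if (pretreat) {
        scaling <- autoscale_fit(inner)
        Xi <- autoscale_apply(inner$X, scaling)
      }
      met <- metric
      if (met$name == "mahalanobis" && is.null(met$inv_cov))
        met$inv_cov <- mahalanobis_inv_cov(Xi)
      tab <- build_neighbour_table(Xi, met)
      Xo <- if (pretreat) autoscale_apply(outer$X, scaling) else outer$X
      Dq <- pairwise_distances(Xo, Xi, tab$metric)
      csum <- t(apply(tab$D, 1L, cumsum))      # fast average distances per k
      for (ki in seq_along(k_grid)) {
        k <- k_grid[ki]
        avg <- csum[, k] / k
        rv <- reference_value(avg, quantile_rule)
        th <- thresholds_from_refval(tab, rv)
        in_ad <- rowSums(sweep(Dq, 2L, th$t, `<=`)) >= 1L
        retained[it, ki] <- 100 * mean(in_ad)
      }
    }
  })
  summaries <- lapply(seq_along(k_grid), function(ki)
    boxplot_summary(retained[, ki], w = w, quantile_rule = quantile_rule))
  structure(list(k_grid = k_grid, retained_pct = retained,
                 summaries = summaries, mean_curve = colMeans(retained),
                 seed = as.integer(seed), iterations = as.integer(iterations),
                 test_fraction = test_fraction, rng = "Mersenne-Twister"),
            class = "k_optimization")
}

# Run `expr` under a fixed seed without disturbing the caller's RNG stream.
with_preserved_seed <- function(seed, expr) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (had) get(".Random.seed", envir = globalenv())
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  eval.parent(substitute(expr))
}

#' @export
print.k_optimization <- function(x, ...) {
  cat(sprintf("<k_optimization> %d iterations, test fraction %.2f, seed %d\n",
              x$iterations, x$test_fraction, x$seed))
  print(summary_table(x), row.names = FALSE, digits = 4)
  invisible(x)
}

#' Summary table of a k optimization
#'
#' @param result A [optimize_k()] result.
#' @return Data frame with one row per `k`: box summary, outlier count and
#'   mean retained percentage.
#' @export
summary_table <- function(result) {
  stopifnot(inherits(result, "k_optimization"))
  data.frame(
    k = result$k_grid,
    median = vapply(result$summaries, `[[`, numeric(1), "median"),
    q1 = vapply(result$summaries, `[[`, numeric(1), "q1"),
    q3 = vapply(result$summaries, `[[`, numeric(1), "q3"),
    whisker_low = vapply(result$summaries, `[[`, numeric(1), "whisker_low"),
    whisker_high = vapply(result$summaries, `[[`, numeric(1), "whisker_high"),
    n_outliers = vapply(result$summaries, function(s) length(s$outliers), integer(1)),
    mean = result$mean_curve)
}

#' Suggest a smoothing parameter from an optimization result
#'
#' Formalizes the by-eye plateau choice: the smallest `k` whose mean
#' retained percentage is within `tolerance_pct` of the grid maximum and
#' whose box summary flags no outliers; if no `k` satisfies both, the
#' smallest `k` within tolerance of the maximum. Small `k` is preferred so
#' training thresholds are not expanded unnecessarily.
#'
#' @param result A [optimize_k()] result.
#' @param tolerance_pct Plateau tolerance in percentage points (default 2).
#' @return A `k` value from the grid.
#' @export
suggest_k <- function(result, tolerance_pct = 2.0) {
  stopifnot(inherits(result, "k_optimization"))
  top <- max(result$mean_curve)
  near <- result$mean_curve >= top - tolerance_pct
  clean <- vapply(result$summaries, function(s) length(s$outliers) == 0L, logical(1))
  both <- near & clean
  if (any(both)) return(result$k_grid[which(both)[1L]])
  result$k_grid[which(near)[1L]]
}

#' Export a k optimization to delimited tables
#'
#' Writes the per-iteration retained percentages (long format: k, iteration,
#' retained_pct) and the per-k summary table.
#'
#' @param result A [optimize_k()] result.
#' @param iterations_path,summary_path Output file paths (either may be
#'   `NULL` to skip).
#' @param delimiter Field delimiter.
#' @return Invisibly, the summary data frame.
#' @export
write_k_optimization <- function(result, iterations_path = NULL,
                                 summary_path = NULL, delimiter = ",") {
  stopifnot(inherits(result, "k_optimization"))
  if (!is.null(iterations_path)) {
    long <- data.frame(
      k = rep(result$k_grid, each = result$iterations),
      iteration = rep(seq_len(result$iterations), length(result$k_grid)),
      retained_pct = as.vector(result$retained_pct))
    utils::write.table(long, iterations_path, sep = delimiter,
                       row.names = FALSE, quote = FALSE)
  }
  st <- summary_table(result)
  if (!is.null(summary_path))
    utils::write.table(st, summary_path, sep = delimiter,
                       row.names = FALSE, quote = FALSE)
  invisible(st)
}

#' Box-and-whisker plot of a k optimization
#'
#' Draws the per-k distribution of retained-test percentages with the mean
#' curve overlaid, mirroring the diagnostic plot used to pick `k`.
#'
#' @param x A [optimize_k()] result.
#' @param ... Passed to [graphics::boxplot()].
#' @return `x`, invisibly.
#' @export
plot.k_optimization <- function(x, ...) {
  graphics::boxplot(x$retained_pct, names = x$k_grid, range = x$summaries[[1L]]$w,
                    xlab = "k", ylab = "test samples retained in AD (%)", ...)
  graphics::lines(seq_along(x$k_grid), x$mean_curve, col = "blue", lwd = 2)
  graphics::points(seq_along(x$k_grid), x$mean_curve, col = "blue", pch = 16)
  invisible(x)
}
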