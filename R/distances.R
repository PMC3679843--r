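#' Specify a distance metric
#'
#' @param name One of `"euclidean"`, `"manhattan"`, `"mahalanobis"`.
#' @param inv_cov Optional inverse covariance matrix for the Mahalanobis
#'   metric. When omitted it is estimated from the training data at fit time
#'   (sample covariance, `n - 1` denominator) and must be invertible.
#' @return An object of class `metric_spec`.
#' @export
metric_spec <- function(name = c("euclidean", "manhattan", "mahalanobis"),
                        inv_cov = NULL) {
  name <- match.arg(name)
  if (!is.null(inv_cov)) {
    inv_cov <- as.matrix(inv_cov)
    if (nrow(inv_cov) != ncol(inv_cov)) stop("`inv_cov` must be square.")
  }
  structure(list(name = name, inv_cov = inv_cov), class = "metric_spec")
}

# Resolve a metric argument: accept a metric_spec or a bare name.
as_metric <- function(metric) {
  if (inherits(metric, "metric_spec")) metric else metric_spec(metric)
}

# Estimate the inverse covariance for the Mahalanobis metric from training
# rows; singularity (p >= n, collinear descriptors) is a hard error because
# AD membership would be ill-defined under a pseudo-inverse.
mahalanobis_inv_cov <- function(X) {
  if (nrow(X) <= ncol(X))
    stop("Mahalanobis metric needs more training samples than descriptors; ",
         "use euclidean/manhattan or reduce dimensionality.")
  S <- stats::cov(X)
  rc <- rcond(S)
  if (!is.finite(rc) || rc < 1e-12)
    stop("training covariance is (near-)singular (rcond = ", format(rc),
         "); regularize the descriptors or choose another metric.")
  solve(S)
}

#' Pairwise distances between two sets of points
#'
#' @param A Numeric matrix `a x p`.
#' @param B Numeric matrix `b x p`.
#' @param metric A [metric_spec()] or metric name. For `"mahalanobis"` the
#'   inverse covariance must be supplied in the spec (models estimate it from
#'   training data and store it).
#' @return An `a x b` matrix of nonnegative distances.
#' @export
pairwise_distances <- function(A, B, metric = "euclidean") {
  metric <- as_metric(metric)
  A <- as.matrix(A); B <- as.matrix(B)
  if (ncol(A) != ncol(B)) stop("A and B must have the same number of columns.")
  switch(metric$name,
    euclidean = euclid_cross(A, B),
    manhattan = {
      D <- matrix(0, nrow(A), nrow(B))
      for (j in seq_len(ncol(A)))
        D <- D + abs(outer(A[, j], B[, j], `-`))
      D
    },
    mahalanobis = {
      W <- metric$inv_cov
      if (is.null(W)) stop("Mahalanobis metric requires an inverse covariance; ",
                           "fit it from training data first.")
      if (nrow(W) != ncol(A)) stop("inverse covariance dimension mismatch.")
      # factor W = R'R, map x -> R x, then Euclidean
      R <- tryCatch(chol(W), error = function(e)
        stop("inverse covariance is not positive definite."))
      euclid_cross(A %*% t(R), B %*% t(R))
    })
}

# Cross Euclidean distances by direct column accumulation: slightly slower
# than the expanded-square identity but free of its cancellation error for
# distant points, which matters when distances sit exactly on thresholds.
euclid_cross <- function(A, B) {
  D2 <- matrix(0, nrow(A), nrow(B))
  for (j in seq_len(ncol(A)))
    D2 <- D2 + outer(A[, j], B[, j], `-`)^2
  sqrt(D2)
}

#' Build the sorted training neighbour table
#'
#' For `n` training samples, returns the `n x (n-1)` matrix `D` whose row `i`
#' holds the distances from sample `i` to all other training samples in
#' increasing order, together with the index matrix identifying which sample
#' attains each sorted distance. Ties are broken by ascending training index
#' so the table is deterministic.
#'
#' @param X_train Numeric training matrix (already pretreated if desired).
#' @param metric A [metric_spec()] or metric name; for `"mahalanobis"`
#'   without a supplied inverse covariance, it is estimated from `X_train`.
#' @return An object of class `neighbour_table` with fields `D` and `idx`.
#' @export
build_neighbour_table <- function(X_train, metric = "euclidean") {
  X_train <- as.matrix(X_train)
  n <- nrow(X_train)
  if (n < 2L) stop("neighbour table needs at least 2 training samples.")
  metric <- as_metric(metric)
  if (metric$name == "mahalanobis" && is.null(metric$inv_cov))
    metric$inv_cov <- mahalanobis_inv_cov(X_train)
  full <- pairwise_distances(X_train, X_train, metric)
  D <- matrix(0, n, n - 1L)
  idx <- matrix(0L, n, n - 1L)
  for (i in seq_len(n)) {
    others <- setdiff(seq_len(n), i)
    d <- full[i, others]
    ord <- order(d, others)          # ties -> ascending training index
    D[i, ] <- d[ord]
    idx[i, ] <- others[ord]
  }
  structure(list(D = D, idx = idx, metric = metric), class = "neighbour_table")
}

#' @export
print.neighbour_table <- function(x, ...) {
  cat(sprintf("<neighbour_table> %d samples, metric %s\n",
              nrow(x$D), x$metric$name))
  invisible(x)
}

#' Quantiles under the package-wide rule
#'
#' All percentile computations (Tukey fences, box-plot quartiles, percentile
#' thresholds of the baseline AD methods) share one quantile convention so
#' results are mutually consistent. The default is linear interpolation
#' between order statistics (R type 7); `"nearest"` selects the nearest-rank
#' alternative (type 1).
#'
#' @param x Numeric vector.
#' @param probs Probabilities in `[0, 1]`.
#' @param rule `"linear"` (default) or `"nearest"`.
#' @return Numeric vector of quantiles.
#' @export
ad_quantile <- function(x, probs, rule = c("linear", "nearest")) {
  rule <- match.arg(rule)
  if (!length(x)) stop("cannot take quantiles of an empty vector.")
  unname(stats::quantile(x, probs, type = if (rule == "linear") 7L else 1L,
                         names = FALSE))
}
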