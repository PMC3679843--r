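# Classical comparison AD methods: descriptor-range bounding box, PCA
# bounding box, convex hull, centroid-distance percentile thresholds and the
# classical kNN percentile threshold. All range/threshold comparisons are
# inclusive (<=), matching the decision rule of the kNN-AD itself.

baseline_result <- function(method_name, query_ids, in_ad, threshold = NULL,
                            extras = NULL) {
  structure(list(method_name = method_name, sample_ids = query_ids,
                 in_ad = unname(in_ad), threshold = unname(threshold),
                 extras = extras),
            class = "baseline_ad_result")
}

#' @export
print.baseline_ad_result <- function(x, ...) {
  cat(sprintf("<baseline_ad_result> %s: %d of %d queries in AD", x$method_name,
              sum(x$in_ad), length(x$in_ad)))
  if (!is.null(x$threshold)) cat(sprintf(" (threshold %.4g)", x$threshold))
  cat("\n")
  invisible(x)
}

check_query_dims <- function(train, query) {
  stopifnot(inherits(train, "descriptor_table"), inherits(query, "descriptor_table"))
  if (ncol(train$X) != ncol(query$X))
    stop("query descriptor count does not match the training data.")
}

#' Bounding-box applicability domain
#'
#' A query is inside the AD iff every descriptor value lies within the
#' training minimum and maximum (inclusive). Applied to raw descriptor
#' values: range methods are scale-equivariant, so no pretreatment is used.
#'
#' @param train,query [descriptor_table()] objects with matching descriptors.
#' @return A `baseline_ad_result`.
#' @export
bounding_box_ad <- function(train, query) {
  check_query_dims(train, query)
  lo <- apply(train$X, 2L, min)
  hi <- apply(train$X, 2L, max)
  ok_lo <- sweep(query$X, 2L, lo, `>=`)
  ok_hi <- sweep(query$X, 2L, hi, `<=`)
  baseline_result("Bounding box", query$ids, rowSums(ok_lo & ok_hi) == ncol(query$X))
}

#' PCA bounding-box applicability domain
#'
#' Autoscales internally, fits principal axes on the training data, retains
#' the leading components reaching `variance_retained` cumulative explained
#' variance, and checks the query scores (projected with the training
#' loadings) against the training score ranges, inclusive.
#'
#' @param train,query [descriptor_table()] objects.
#' @param variance_retained Cumulative explained-variance cutoff in `(0, 1]`
#'   (default 0.95).
#' @return A `baseline_ad_result`; `extras$n_components` records the
#'   retained component count.
#' @export
pca_bounding_box_ad <- function(train, query, variance_retained = 0.95) {
  check_query_dims(train, query)
  if (variance_retained <= 0 || variance_retained > 1)
    stop("variance_retained must be in (0, 1].")
  sc <- autoscale_fit(train)
  Xt <- autoscale_apply(train$X, sc)
  pc <- stats::prcomp(Xt, center = FALSE, scale. = FALSE)
  if (min(pc$sdev) < 1e-12 && variance_retained == 1)
    warning("near-degenerate covariance: trailing components carry no variance.")
  cum <- cumsum(pc$sdev^2) / sum(pc$sdev^2)
  ncomp <- which(cum >= variance_retained)[1L]
  Ts <- pc$x[, seq_len(ncomp), drop = FALSE]
  Tq <- autoscale_apply(query$X, sc) %*% pc$rotation[, seq_len(ncomp), drop = FALSE]
  lo <- apply(Ts, 2L, min); hi <- apply(Ts, 2L, max)
  in_ad <- rowSums(sweep(Tq, 2L, lo, `>=`) & sweep(Tq, 2L, hi, `<=`)) == ncomp
  baseline_result("PCA bounding box", query$ids, in_ad,
                  extras = list(n_components = ncomp))
}

#' Convex-hull applicability domain
#'
#' A query is inside the AD iff it is a convex combination of the training
#' points (boundary inclusive). Membership is decided per query by
#' linear-programming feasibility of
#' \eqn{\sum_i \lambda_i x_i = q,\ \sum_i \lambda_i = 1,\ \lambda_i \ge 0}
#' with an explicit residual verification, which stays robust in moderate
#' dimension where facet enumeration is fragile. Raw descriptor values are
#' used (no pretreatment), as for the bounding box.
#'
#' @param train,query [descriptor_table()] objects.
#' @param tol Feasibility tolerance on the verified residual (default 1e-9,
#'   relative to the descriptor scale).
#' @return A `baseline_ad_result`; queries where the solver fails outright
#'   are reported `NA` in `extras$solver_failed` and counted out of the AD.
#' @export
convex_hull_ad <- function(train, query, tol = 1e-9) {
  check_query_dims(train, query)
  X <- train$X
  n <- nrow(X)
  scale_ref <- max(1, max(abs(X)))
  Aeq <- rbind(t(X), rep(1, n))
  in_ad <- logical(nrow(query$X))
  failed <- logical(nrow(query$X))
  for (j in seq_len(nrow(query$X))) {
    q <- query$X[j, ]
    r <- tryCatch(
      pracma::linprog(rep(0, n), Aeq = Aeq, beq = c(q, 1),
                      maxiter = max(200L, 20L * n)),
      error = function(e) list(errno = NA_integer_, x = NULL))
    if (!is.null(r$x) && !anyNA(r$x) && isTRUE(r$errno == 1)) {
      resid <- max(abs(as.numeric(t(X) %*% r$x) - q), abs(sum(r$x) - 1),
                   -min(r$x, 0))
      in_ad[j] <- resid <= tol * scale_ref
    } else if (isTRUE(r$errno == -4)) {
      in_ad[j] <- FALSE                       # phase-1 infeasible: outside hull
    } else {
      failed[j] <- TRUE
      in_ad[j] <- FALSE
      warning(sprintf("convex hull feasibility solver failed for query '%s'.",
                      query$ids[j]))
    }
  }
  baseline_result("Convex hull", query$ids, in_ad,
                  extras = list(solver_failed = failed))
}

#' Centroid-distance applicability domain
#'
#' Distance of each query from the training centroid, compared against a
#' percentile (default 95th) of the training samples' own centroid
#' distances. Data are autoscaled with training statistics; for the
#' Mahalanobis metric the covariance is estimated on the autoscaled
#' training data.
#'
#' @param train,query [descriptor_table()] objects.
#' @param metric `"euclidean"` or `"mahalanobis"` (a [metric_spec()] is
#'   accepted).
#' @param percentile Threshold percentile of training distances (default 95).
#' @param quantile_rule See [ad_quantile()].
#' @return A `baseline_ad_result` with per-sample distances in `extras`.
#' @export
centroid_distance_ad <- function(train, query, metric = "euclidean",
                                 percentile = 95, quantile_rule = "linear") {
  check_query_dims(train, query)
  metric <- as_metric(metric)
  if (!metric$name %in% c("euclidean", "mahalanobis"))
    stop("centroid-distance AD supports euclidean or mahalanobis metrics.")
  sc <- autoscale_fit(train)
  Xt <- autoscale_apply(train$X, sc)
  Xq <- autoscale_apply(query$X, sc)
  if (metric$name == "mahalanobis" && is.null(metric$inv_cov))
    metric$inv_cov <- mahalanobis_inv_cov(Xt)
  centroid <- matrix(colMeans(Xt), nrow = 1L)
  d_train <- as.numeric(pairwise_distances(Xt, centroid, metric))
  d_query <- as.numeric(pairwise_distances(Xq, centroid, metric))
  thr <- ad_quantile(d_train, percentile / 100, rule = quantile_rule)
  baseline_result(sprintf("%s dist (%g percentile)",
                          tools::toTitleCase(metric$name), percentile),
                  query$ids, d_query <= thr, threshold = thr,
                  extras = list(distance = d_query))
}

#' Classical kNN applicability domain
#'
#' The classical single-threshold kNN rule: the threshold is a percentile
#' (default 95th) of the training samples' average distances to their own
#' `k` nearest neighbours (default `k = 5`); a query is inside the AD iff
#' its average distance to its `k` nearest training samples is at or below
#' that threshold. Data are autoscaled with training statistics.
#'
#' @param train,query [descriptor_table()] objects.
#' @param k Neighbour count (default 5).
#' @param percentile Threshold percentile (default 95).
#' @param metric A [metric_spec()] or metric name.
#' @param quantile_rule See [ad_quantile()].
#' @return A `baseline_ad_result` with per-query average distances in
#'   `extras`.
#' @export
classical_knn_ad <- function(train, query, k = 5L, percentile = 95,
                             metric = "euclidean", quantile_rule = "linear") {
  check_query_dims(train, query)
  n <- nrow(train$X)
  if (k < 1L || k > n - 1L) stop(sprintf("k must be in [1, %d].", n - 1L))
  metric <- as_metric(metric)
  sc <- autoscale_fit(train)
  Xt <- autoscale_apply(train$X, sc)
  Xq <- autoscale_apply(query$X, sc)
  if (metric$name == "mahalanobis" && is.null(metric$inv_cov))
    metric$inv_cov <- mahalanobis_inv_cov(Xt)
  tab <- build_neighbour_table(Xt, metric)
  avg_train <- average_knn_distances(tab, k)
  thr <- ad_quantile(avg_train, percentile / 100, rule = quantile_rule)
  Dq <- pairwise_distances(Xq, Xt, tab$metric)
  avg_query <- apply(Dq, 1L, function(d) mean(sort(d)[seq_len(k)]))
  baseline_result(sprintf("Classical kNN (k = %d)", k), query$ids,
                  avg_query <= thr, threshold = thr,
                  extras = list(avg_knn_distance = avg_query))
}
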