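#' Run all applicability-domain methods on one train/test pair
#'
#' Produces a comparison table with one row per AD method — the kNN-AD with
#' per-sample thresholds, the classical baselines (bounding box, PCA
#' bounding box, convex hull, centroid distances, classical kNN) and the
#' density-based methods — plus a leading "All samples inside" row with no
#' AD applied. When the test table carries measured and predicted
#' responses, each row also reports Q^2 over the samples that method
#' retains. A method that fails (e.g. a singular covariance) is reported as
#' failed without aborting the others.
#'
#' @param train,test [descriptor_table()] objects with matching descriptors.
#' @param k Smoothing parameter for the kNN-AD; `NULL` uses [default_k()].
#' @param metric Metric for the kNN-AD and classical kNN.
#' @param classical_k Neighbour count for the classical kNN rule (default 5).
#' @param percentile Threshold percentile for the distance baselines
#'   (default 95).
#' @param density_k Neighbour count for variable-kernel and
#'   nearest-neighbour density methods (default 15).
#' @param alpha Adaptive-kernel sensitivity (default 0.5).
#' @param cutoff_percentile Density-cutoff percentile (default 5).
#' @param include_density Run the density-based methods (default `TRUE`).
#' @param quantile_rule See [ad_quantile()].
#' @return A data frame of class `ad_comparison`: `method`, `n_in_ad`, `q2`,
#'   `outside_ad` (space-separated ids), `error` (message for failed rows).
#' @export
compare_ad_methods <- function(train, test, k = NULL, metric = "euclidean",
                               classical_k = 5L, percentile = 95,
                               density_k = 15L, alpha = 0.5,
                               cutoff_percentile = 5, include_density = TRUE,
                               quantile_rule = "linear") {
  stopifnot(inherits(train, "descriptor_table"), inherits(test, "descriptor_table"))
  has_resp <- !is.null(test$y) && !is.null(test$y_hat) && !is.null(train$y)
  score <- function(in_ad) {
    if (!has_resp || !any(in_ad)) return(NA_real_)
    q_squared(test$y[in_ad], test$y_hat[in_ad], train$y)
  }
  rows <- list()
  add <- function(method, in_ad = NULL, error = NA_character_) {
    rows[[length(rows) + 1L]] <<- if (is.null(in_ad))
      data.frame(method = method, n_in_ad = NA_integer_, q2 = NA_real_,
                 outside_ad = NA_character_, error = error,
                 stringsAsFactors = FALSE)
    else
      data.frame(method = method, n_in_ad = sum(in_ad), q2 = score(in_ad),
                 outside_ad = if (all(in_ad)) "None"
                              else paste(test$ids[!in_ad], collapse = " "),
                 error = NA_character_, stringsAsFactors = FALSE)
  }
  try_method <- function(method, fun) {
    r <- tryCatch(fun(), error = function(e) conditionMessage(e))
    if (is.character(r)) add(method, error = r) else add(method, r)
  }

  add("All samples inside (no AD)", rep(TRUE, nrow(test$X)))
  try_method(sprintf("kNN-AD (per-sample thresholds, k = %s)",
                     if (is.null(k)) default_k(nrow(train$X)) else k), function() {
    m <- fit_ad(train, k = k, metric = metric, quantile_rule = quantile_rule)
    apply_ad(m, test)$in_ad
  })
  try_method("Bounding box", function() bounding_box_ad(train, test)$in_ad)
  try_method("PCA bounding box", function() pca_bounding_box_ad(train, test)$in_ad)
  try_method("Convex hull", function() convex_hull_ad(train, test)$in_ad)
  try_method("Euclidean dist (95 percentile)", function()
    centroid_distance_ad(train, test, "euclidean", percentile, quantile_rule)$in_ad)
  try_method("Mahalanobis dist (95 percentile)", function()
    centroid_distance_ad(train, test, "mahalanobis", percentile, quantile_rule)$in_ad)
  try_method(sprintf("Classical kNN (k = %d)", classical_k), function()
    classical_knn_ad(train, test, k = classical_k, percentile = percentile,
                     metric = metric, quantile_rule = quantile_rule)$in_ad)
  if (include_density) {
    try_method("Fixed Gaussian kernel", function()
      density_ad(fit_fixed_kde(train), test, cutoff_percentile, quantile_rule)$in_ad)
    try_method("Optimized Gaussian kernel", function() {
      h <- loo_cv_bandwidth(train)
      density_ad(fit_fixed_kde(train, h = as.numeric(h)), test,
                 cutoff_percentile, quantile_rule)$in_ad
    })
    try_method(sprintf("Variable Gaussian kernel (k = %d)", density_k), function()
      density_ad(fit_variable_kde(train, k = density_k), test,
                 cutoff_percentile, quantile_rule)$in_ad)
    try_method("Adaptive Gaussian kernel", function()
      density_ad(fit_adaptive_kde(train, alpha = alpha), test,
                 cutoff_percentile, quantile_rule)$in_ad)
    try_method("Fixed Epanechnikov kernel", function()
      density_ad(fit_fixed_kde(train, kernel = "epanechnikov"), test,
                 cutoff_percentile, quantile_rule)$in_ad)
    try_method(sprintf("Nearest neighbour density (k = %d)", density_k), function()
      density_ad(fit_nn_density(train, k = density_k), test,
                 cutoff_percentile, quantile_rule)$in_ad)
  }
  out <- do.call(rbind, rows)
  class(out) <- c("ad_comparison", "data.frame")
  out
}

#' @export
print.ad_comparison <- function(x, ...) {
  df <- as.data.frame(x)
  df$q2 <- ifelse(is.na(df$q2), "-", sprintf("%.3f", df$q2))
  df$error[is.na(df$error)] <- ""
  print(df, row.names = FALSE, right = FALSE)
  invisible(x)
}
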