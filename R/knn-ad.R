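#' Average distance to the k nearest training neighbours
#'
#' Element `i` is the mean of the first `k` sorted distances of training
#' sample `i`, i.e. the mean distance to its `k` nearest neighbours. For a
#' fixed table the result is elementwise non-decreasing in `k`.
#'
#' @param table A [build_neighbour_table()] result.
#' @param k Neighbour count, `1 <= k <= n - 1`.
#' @return Numeric vector of length `n`.
#' @export
average_knn_distances <- function(table, k) {
  stopifnot(inherits(table, "neighbour_table"))
  nm1 <- ncol(table$D)
  if (!is.numeric(k) || length(k) != 1L || k != as.integer(k) || k < 1L || k > nm1)
    stop(sprintf("k must be an integer in [1, %d].", nm1))
  rowMeans(table$D[, seq_len(k), drop = FALSE])
}

#' Reference value: Tukey upper fence of the average-distance vector
#'
#' Computes `Q3 + 1.5 (Q3 - Q1)` of the average k-neighbour distances. This
#' single global cutoff decides which pairwise distances count towards each
#' training sample's neighbourhood.
#'
#' @param avg_dists Numeric vector of average k-neighbour distances.
#' @param quantile_rule Quantile convention, see [ad_quantile()].
#' @return The reference value (scalar).
#' @export
reference_value <- function(avg_dists, quantile_rule = "linear") {
  if (!length(avg_dists)) stop("empty average-distance vector.")
  if (!all(is.finite(avg_dists))) stop("average distances must be finite.")
  q <- ad_quantile(avg_dists, c(0.25, 0.75), rule = quantile_rule)
  q[2L] + 1.5 * (q[2L] - q[1L])
}

#' Per-sample neighbourhood counts and thresholds
#'
#' For each training sample, `K_i` counts the sorted distances at or below
#' the reference value and `t_i` is their mean — the width of that sample's
#' neighbourhood. A sample retaining no distance (`K_i = 0`, an isolated
#' point) would have a theoretical threshold of zero; pragmatically it
#' inherits the smallest threshold among samples with `K_i >= 1`, and is
#' flagged in `fallback`.
#'
#' @param table A [build_neighbour_table()] result.
#' @param ref_val The reference value from [reference_value()].
#' @return List with integer vector `K`, numeric vector `t` and logical
#'   vector `fallback`.
#' @export
thresholds_from_refval <- function(table, ref_val) {
  stopifnot(inherits(table, "neighbour_table"))
  if (!is.finite(ref_val) || ref_val < 0) stop("ref_val must be finite and >= 0.")
  D <- table$D
  K <- rowSums(D <= ref_val)
  t <- rep(NA_real_, nrow(D))
  ok <- K >= 1L
  if (!any(ok))
    stop("every training sample has K_i = 0: no threshold to fall back on; ",
         "cannot define an applicability domain at this k.")
  for (i in which(ok)) t[i] <- mean(D[i, seq_len(K[i])])
  t[!ok] <- min(t[ok])
  list(K = as.integer(K), t = t, fallback = !ok)
}

#' Fit a kNN applicability-domain model
#'
#' Three-step fit on the training set: (optionally) autoscale, build the
#' sorted neighbour table, compute each sample's average distance to its `k`
#' nearest neighbours, derive the global reference value (Tukey upper fence
#' of those averages) and assign each training sample its individual
#' neighbourhood threshold `t_i` together with its neighbourhood density
#' `K_i`.
#'
#' @param train A [descriptor_table()] with at least 3 samples.
#' @param k Smoothing parameter (neighbour count), `1 <= k <= n - 1`; when
#'   `NULL`, the empirical default `round(n^(1/3))` of [default_k()] is used.
#' @param metric A [metric_spec()] or metric name.
#' @param pretreat Autoscale the training data (and later any query) with
#'   training statistics. Default `TRUE`, the standard pretreatment for
#'   distance-based AD methods.
#' @param quantile_rule Quantile convention for the reference value,
#'   see [ad_quantile()].
#' @return An object of class `knnad_model`.
#' @examples
#' set.seed(1)
#' tr <- descriptor_table(matrix(rnorm(60), 30, 2))
#' m <- fit_ad(tr, k = 3)
#' m
#' @export
fit_ad <- function(train, k = NULL, metric = "euclidean", pretreat = TRUE,
                   quantile_rule = "linear") {
  stopifnot(inherits(train, "descriptor_table"))
  n <- nrow(train$X)
  if (n < 3L) stop("fitting an AD needs at least 3 training samples.")
  if (is.null(k)) k <- default_k(n)
  if (!is.numeric(k) || length(k) != 1L || k != as.integer(k) || k < 1L || k > n - 1L)
    stop(sprintf("k must be an integer in [1, %d].", n - 1L))
  k <- as.integer(k)
  metric <- as_metric(metric)
  scaling <- NULL
  Xs <- train$X
  if (pretreat) {
    scaling <- autoscale_fit(train)
    Xs <- autoscale_apply(train$X, scaling)
  }
  tab <- build_neighbour_table(Xs, metric)
  avg <- average_knn_distances(tab, k)
  rv <- reference_value(avg, quantile_rule)
  th <- thresholds_from_refval(tab, rv)
  structure(list(
    X_train_scaled = Xs,
    train_ids = train$ids,
    scaling = scaling,
    metric = tab$metric,          # carries the fitted inverse covariance
    k = k,
    quantile_rule = quantile_rule,
    avg_knn_dist = avg,
    ref_val = rv,
    K = th$K,
    t = th$t,
    fallback_mask = th$fallback
  ), class = "knnad_model")
}

#' @export
print.knnad_model <- function(x, ...) {
  n <- nrow(x$X_train_scaled)
  cat(sprintf("<knnad_model> n = %d training samples, p = %d descriptors\n",
              n, ncol(x$X_train_scaled)))
  cat(sprintf("  metric: %s   k = %d   pretreatment: %s\n", x$metric$name, x$k,
              if (is.null(x$scaling)) "none" else "autoscaling"))
  cat(sprintf("  Ref Val: %.4g\n", x$ref_val))
  cat(sprintf("  thresholds t_i: min %.4g, median %.4g, max %.4g\n",
              min(x$t), stats::median(x$t), max(x$t)))
  cat(sprintf("  samples with K_i = 0 (fallback threshold): %d of %d\n",
              sum(x$fallback_mask), n))
  invisible(x)
}

#' Evaluate the applicability domain for query samples
#'
#' A query is inside the AD if its distance to at least one training sample
#' is at or below that sample's individual threshold. `K_j` counts how many
#' training thresholds the query satisfies: a reliability measure (high
#' `K_j` = dense, well-represented training region; `K_j = 0` = outside the
#' AD). All `n` training samples are scanned so
#' `nearest_satisfying_distance` (the smallest satisfying distance, `NA`
#' when out of the AD) is exact.
#'
#' @param model A fitted [fit_ad()] model.
#' @param query A [descriptor_table()] with the same descriptor count as the
#'   training data. It is scaled with the model's stored training parameters
#'   before distances are taken.
#' @return A data frame with one row per query: `sample_id`, `in_ad`, `K_j`,
#'   `nearest_satisfying_distance`.
#' @export
apply_ad <- function(model, query) {
  stopifnot(inherits(model, "knnad_model"), inherits(query, "descriptor_table"))
  Xq <- query$X
  if (!is.null(model$scaling)) {
    Xq <- autoscale_apply(Xq, model$scaling)
  } else if (ncol(Xq) != ncol(model$X_train_scaled)) {
    stop("query descriptor count does not match the training data.")
  }
  if (ncol(Xq) != ncol(model$X_train_scaled))
    stop("query descriptor count does not match the training data.")
  Dq <- pairwise_distances(Xq, model$X_train_scaled, model$metric)
  sat <- sweep(Dq, 2L, model$t, `<=`)          # query x train: D_ij <= t_i
  K_j <- as.integer(rowSums(sat))
  nsd <- vapply(seq_len(nrow(Dq)), function(j) {
    s <- sat[j, ]
    if (any(s)) min(Dq[j, s]) else NA_real_
  }, numeric(1))
  data.frame(sample_id = query$ids, in_ad = K_j >= 1L, K_j = K_j,
             nearest_satisfying_distance = nsd,
             stringsAsFactors = FALSE, row.names = NULL)
}

#' Serialize a fitted AD model to structured text
#'
#' Writes every field of the model as JSON at full double precision so a fit
#' and a later apply can run as separate command-line steps and reproduce
#' results exactly.
#'
#' @param model A `knnad_model`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_knnad_model <- function(model, path) {
  stopifnot(inherits(model, "knnad_model"))
  payload <- list(
    class = "knnad_model",
    train_ids = model$train_ids,
    X_train_scaled = model$X_train_scaled,
    scaling = if (!is.null(model$scaling)) unclass(model$scaling),
    metric = list(name = model$metric$name, inv_cov = model$metric$inv_cov),
    k = model$k,
    quantile_rule = model$quantile_rule,
    avg_knn_dist = model$avg_knn_dist,
    ref_val = model$ref_val,
    K = model$K, t = model$t, fallback_mask = model$fallback_mask)
  jsonlite::write_json(payload, path, digits = I(17), auto_unbox = TRUE,
                       matrix = "rowmajor", pretty = TRUE)
  invisible(path)
}

#' Read a serialized AD model
#'
#' @param path Path written by [write_knnad_model()].
#' @return A `knnad_model`.
#' @export
read_knnad_model <- function(path) {
  p <- jsonlite::read_json(path, simplifyVector = TRUE)
  if (!identical(p$class, "knnad_model")) stop("not a serialized knnad_model: ", path)
  scaling <- if (!is.null(p$scaling))
    structure(list(means = p$scaling$means, sds = p$scaling$sds,
                   keep = as.integer(p$scaling$keep),
                   p_full = as.integer(p$scaling$p_full)),
              class = "scaling_params")
  inv_cov <- if (length(p$metric$inv_cov)) as.matrix(p$metric$inv_cov)
  structure(list(
    X_train_scaled = as.matrix(p$X_train_scaled),
    train_ids = p$train_ids,
    scaling = scaling,
    metric = metric_spec(p$metric$name, inv_cov),
    k = as.integer(p$k),
    quantile_rule = p$quantile_rule,
    avg_knn_dist = p$avg_knn_dist,
    ref_val = p$ref_val,
    K = as.integer(p$K),
    t = p$t,
    fallback_mask = as.logical(p$fallback_mask)
  ), class = "knnad_model")
}
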