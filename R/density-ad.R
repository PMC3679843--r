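# Density-based applicability domains: multivariate product-kernel density
# estimators (fixed / LOO-optimized / variable / adaptive Gaussian,
# Epanechnikov) and the k-th-neighbour density estimator, with a
# leave-one-out percentile cutoff turning densities into an in/out rule.

new_density_estimator <- function(kind, X, scaling, h = NULL,
                                  local_factors = NULL, alpha = NULL, k = NULL) {
  structure(list(kind = kind, X_train_scaled = X, scaling = scaling, h = h,
                 local_factors = local_factors, alpha = alpha, k = k),
            class = "density_estimator")
}

#' @export
print.density_estimator <- function(x, ...) {
  cat(sprintf("<density_estimator> kind: %s, n = %d, p = %d\n", x$kind,
              nrow(x$X_train_scaled), ncol(x$X_train_scaled)))
  if (!is.null(x$h)) cat(sprintf("  bandwidth h = %.6g\n", x$h))
  if (!is.null(x$alpha)) cat(sprintf("  sensitivity alpha = %g\n", x$alpha))
  if (!is.null(x$k)) cat(sprintf("  neighbour count k = %d\n", x$k))
  invisible(x)
}

#' Rule-of-thumb bandwidth for multivariate Gaussian kernels
#'
#' Silverman-type plug-in bandwidth
#' \eqn{h = (4 / (n (p + 2)))^{1/(p+4)} \bar\sigma} where
#' \eqn{\bar\sigma} is the mean per-dimension standard deviation (1 for
#' autoscaled data). Used as the default fixed bandwidth and pilot.
#'
#' @param X Numeric matrix of (scaled) training points.
#' @return A positive bandwidth.
#' @export
silverman_bandwidth <- function(X) {
  X <- as.matrix(X)
  n <- nrow(X); p <- ncol(X)
  sigma <- mean(apply(X, 2L, stats::sd))
  if (sigma == 0) sigma <- 1
  (4 / (n * (p + 2)))^(1 / (p + 4)) * sigma
}

# Scale training data per the pretreat flag; returns list(X, scaling).
prep_train <- function(train, pretreat) {
  stopifnot(inherits(train, "descriptor_table"))
  if (pretreat) {
    sc <- autoscale_fit(train)
    list(X = autoscale_apply(train$X, sc), scaling = sc)
  } else list(X = train$X, scaling = NULL)
}

#' Fit a fixed-bandwidth kernel density estimator
#'
#' Gaussian or Epanechnikov product kernel with a single global bandwidth.
#' Data are autoscaled by default (the standard pretreatment for density ADs
#' on descriptor data), and the scaling is stored so evaluation always uses
#' consistent coordinates.
#'
#' @param train A [descriptor_table()].
#' @param h Bandwidth in scaled-descriptor units; default is the
#'   [silverman_bandwidth()] rule of thumb.
#' @param kernel `"gaussian"` or `"epanechnikov"`.
#' @param pretreat Autoscale (default `TRUE`).
#' @return A `density_estimator`.
#' @export
fit_fixed_kde <- function(train, h = NULL, kernel = c("gaussian", "epanechnikov"),
                          pretreat = TRUE) {
  kernel <- match.arg(kernel)
  pr <- prep_train(train, pretreat)
  # Epanechnikov's compact support needs a wider window than the Gaussian
  # rule of thumb; 2.34 is the canonical equivalent-kernel rescaling.
  if (is.null(h)) h <- silverman_bandwidth(pr$X) *
    if (kernel == "epanechnikov") 2.34 else 1
  if (!is.numeric(h) || h <= 0) stop("bandwidth h must be > 0.")
  new_density_estimator(if (kernel == "gaussian") "gaussian_fixed" else
                          "epanechnikov_fixed", pr$X, pr$scaling, h = h)
}

#' Fit a variable-bandwidth (k-th neighbour) Gaussian kernel
#'
#' Each training point gets its own bandwidth proportional to its Euclidean
#' distance to its `k`-th nearest neighbour (Breiman-style variable kernel:
#' sparse regions get wide kernels), normalized so the geometric mean of
#' the k-th-neighbour distances maps to `h0`.
#'
#' @param train A [descriptor_table()].
#' @param k Neighbour count (default 15).
#' @param h0 Global bandwidth scale; default [silverman_bandwidth()].
#' @param pretreat Autoscale (default `TRUE`).
#' @param inverse If `TRUE`, uses the literal inverse reading
#'   (`h_i` proportional to `1 / d_{i,k}`); the proportional default is the
#'   standard construction.
#' @return A `density_estimator` of kind `"gaussian_variable"`.
#' @export
fit_variable_kde <- function(train, k = 15L, h0 = NULL, pretreat = TRUE,
                             inverse = FALSE) {
  pr <- prep_train(train, pretreat)
  n <- nrow(pr$X)
  if (k < 1L || k > n - 1L) stop(sprintf("k must be in [1, %d].", n - 1L))
  if (is.null(h0)) h0 <- silverman_bandwidth(pr$X)
  if (h0 <= 0) stop("h0 must be > 0.")
  tab <- build_neighbour_table(pr$X, "euclidean")
  dk <- tab$D[, k]
  eps <- sqrt(.Machine$double.eps)
  if (any(dk <= 0)) {
    warning("k-th neighbour distance is 0 for some samples (duplicates); ",
            "flooring their bandwidth at a machine-safe epsilon.")
    dk[dk <= 0] <- eps
  }
  raw <- if (inverse) 1 / dk else dk
  lambda <- raw / exp(mean(log(raw)))      # geometric mean 1
  est <- new_density_estimator("gaussian_variable", pr$X, pr$scaling, h = h0,
                               local_factors = lambda, k = as.integer(k))
  est
}

#' Fit an adaptive Gaussian kernel
#'
#' Two-stage adaptive estimator: a fixed Gaussian kernel with bandwidth
#' `h_pilot` provides pilot densities at the training points; local
#' bandwidth factors \eqn{\lambda_i = (\tilde f(x_i)/g)^{-\alpha}} (with `g`
#' the geometric mean of the pilot densities, so the \eqn{\lambda_i} have
#' geometric mean 1) widen kernels in sparse regions and narrow them in
#' dense ones.
#'
#' @param train A [descriptor_table()].
#' @param alpha Sensitivity parameter in `[0, 1]` (default 0.5); `alpha = 0`
#'   reproduces the fixed kernel.
#' @param h_pilot Pilot (and final global) bandwidth; default
#'   [silverman_bandwidth()].
#' @param pretreat Autoscale (default `TRUE`).
#' @return A `density_estimator` of kind `"gaussian_adaptive"`.
#' @export
fit_adaptive_kde <- function(train, alpha = 0.5, h_pilot = NULL, pretreat = TRUE) {
  if (alpha < 0 || alpha > 1) stop("alpha must be in [0, 1].")
  pr <- prep_train(train, pretreat)
  if (is.null(h_pilot)) h_pilot <- silverman_bandwidth(pr$X)
  if (h_pilot <= 0) stop("h_pilot must be > 0.")
  pilot <- new_density_estimator("gaussian_fixed", pr$X, pr$scaling, h = h_pilot)
  f_pilot <- kde_evaluate(pilot, pr$X, scaled_input = TRUE)
  if (any(f_pilot <= 0))
    stop("pilot density is numerically zero at some training points; ",
         "increase h_pilot.")
  g <- exp(mean(log(f_pilot)))
  lambda <- (f_pilot / g)^(-alpha)
  new_density_estimator("gaussian_adaptive", pr$X, pr$scaling, h = h_pilot,
                        local_factors = lambda, alpha = alpha)
}

#' Fit the k-th-nearest-neighbour density estimator
#'
#' Density at `x` is `k / (n * V_p * d_k(x)^p)` where `d_k(x)` is the
#' Euclidean distance from `x` to its `k`-th nearest training point and
#' `V_p` the unit-ball volume in `p` dimensions.
#'
#' @param train A [descriptor_table()].
#' @param k Neighbour count (default 15).
#' @param pretreat Autoscale (default `TRUE`).
#' @return A `density_estimator` of kind `"nn_density"`.
#' @export
fit_nn_density <- function(train, k = 15L, pretreat = TRUE) {
  pr <- prep_train(train, pretreat)
  n <- nrow(pr$X)
  if (k < 1L || k > n) stop(sprintf("k must be in [1, %d].", n))
  new_density_estimator("nn_density", pr$X, pr$scaling, k = as.integer(k))
}

unit_ball_volume <- function(p) pi^(p / 2) / gamma(p / 2 + 1)

#' Evaluate a fitted density estimator
#'
#' Computes the estimated density at each row of `points`. Gaussian kinds
#' use per-sample bandwidths `h * lambda_i` (`lambda_i = 1` for the fixed
#' kind); the Epanechnikov kind uses the compact-support product kernel;
#' the nearest-neighbour kind uses the `k`-th-neighbour distance formula,
#' returning `+Inf` where a query coincides with at least `k` training
#' points.
#'
#' @param est A fitted `density_estimator`.
#' @param points Numeric matrix of query points in the original descriptor
#'   units (scaled internally with the training parameters), or a
#'   [descriptor_table()].
#' @param scaled_input Set `TRUE` when `points` are already in the
#'   estimator's scaled coordinates.
#' @return Numeric vector of densities.
#' @export
kde_evaluate <- function(est, points, scaled_input = FALSE) {
  stopifnot(inherits(est, "density_estimator"))
  if (inherits(points, "descriptor_table")) points <- points$X
  points <- as.matrix(points)
  if (!scaled_input && !is.null(est$scaling))
    points <- autoscale_apply(points, est$scaling)
  X <- est$X_train_scaled
  n <- nrow(X); p <- ncol(X)
  if (ncol(points) != p) stop("query dimension does not match the estimator.")
  if (est$kind == "nn_density") {
    D <- pairwise_distances(points, X, "euclidean")
    dk <- apply(D, 1L, function(d) sort(d)[est$k])
    out <- ifelse(dk == 0, Inf, est$k / (n * unit_ball_volume(p) * dk^p))
    return(out)
  }
  if (est$kind == "epanechnikov_fixed") {
    h <- est$h
    f <- numeric(nrow(points))
    for (j in seq_len(nrow(points))) {
      U <- sweep(X, 2L, points[j, ], `-`) / h          # n x p
      inside <- abs(U) <= 1
      kern <- ifelse(inside, 0.75 * (1 - U^2) / h, 0)
      f[j] <- mean(apply(kern, 1L, prod))
    }
    return(f)
  }
  # Gaussian kinds: f(x) = (1/n) sum_i (2*pi)^(-p/2) h_i^(-p) exp(-||x - x_i||^2 / (2 h_i^2))
  lambda <- if (is.null(est$local_factors)) rep(1, n) else est$local_factors
  hi <- est$h * lambda
  D2 <- euclid_cross(points, X)^2                      # m x n
  E <- exp(sweep(D2, 2L, -2 * hi^2, `/`))
  coef <- (2 * pi)^(-p / 2) * hi^(-p)
  as.numeric(E %*% coef) / n
}

# Leave-one-out densities of the training points under the estimator: each
# point's own kernel contribution is removed so its own mass cannot mask it.
loo_train_densities <- function(est) {
  X <- est$X_train_scaled
  n <- nrow(X); p <- ncol(X)
  if (est$kind == "nn_density") {
    tab <- build_neighbour_table(X, "euclidean")
    dk <- tab$D[, est$k]                               # self excluded already
    return(ifelse(dk == 0, Inf, est$k / (n * unit_ball_volume(p) * dk^p)))
  }
  if (est$kind == "epanechnikov_fixed") {
    full <- kde_evaluate(est, X, scaled_input = TRUE)
    self <- (0.75 / est$h)^p / n                       # own-kernel peak mass
    return(pmax(0, full * n - self * n) / (n - 1))
  }
  lambda <- if (is.null(est$local_factors)) rep(1, n) else est$local_factors
  hi <- est$h * lambda
  coef <- (2 * pi)^(-p / 2) * hi^(-p)
  D2 <- euclid_cross(X, X)^2
  E <- exp(sweep(D2, 2L, -2 * hi^2, `/`))
  tot <- as.numeric(E %*% coef)
  (tot - coef * diag(E)) / (n - 1)                     # diag(E) = 1
}

#' Leave-one-out cross-validated bandwidth
#'
#' Selects, over a grid, the fixed Gaussian bandwidth maximizing the
#' leave-one-out log-likelihood
#' \eqn{\sum_i \log \hat f_{(-i)}(x_i)}.
#'
#' @param train A [descriptor_table()] with at least 3 samples.
#' @param h_grid Positive candidate bandwidths; default is 30 log-spaced
#'   values spanning 1/10 to 10 times the Silverman rule of thumb.
#' @param pretreat Autoscale (default `TRUE`).
#' @return The selected bandwidth, with the grid and per-grid log-likelihoods
#'   attached as attributes `h_grid` and `loglik`.
#' @export
loo_cv_bandwidth <- function(train, h_grid = NULL, pretreat = TRUE) {
  pr <- prep_train(train, pretreat)
  if (nrow(pr$X) < 3L) stop("LOO bandwidth selection needs at least 3 samples.")
  if (is.null(h_grid)) {
    h0 <- silverman_bandwidth(pr$X)
    h_grid <- exp(seq(log(h0 / 10), log(h0 * 10), length.out = 30L))
  }
  if (any(h_grid <= 0)) stop("h_grid must be positive.")
  ll <- vapply(h_grid, function(h) {
    est <- new_density_estimator("gaussian_fixed", pr$X, pr$scaling, h = h)
    f <- loo_train_densities(est)
    if (any(f <= 0)) -Inf else sum(log(f))
  }, numeric(1))
  if (all(!is.finite(ll)))
    stop("all leave-one-out likelihoods are -Inf; the grid bandwidths are ",
         "too small for this data — supply a larger h_grid.")
  h <- h_grid[which.max(ll)]
  attr(h, "h_grid") <- h_grid
  attr(h, "loglik") <- ll
  h
}

#' Density-cutoff applicability domain
#'
#' Turns a fitted density estimator into an in/out rule: the cutoff is a
#' low percentile (default 5th, mirroring the 95th-percentile convention of
#' the distance-based methods) of the leave-one-out training densities; a
#' query is inside the AD iff its estimated density is at or above the
#' cutoff.
#'
#' @param est A fitted `density_estimator`.
#' @param query A [descriptor_table()] (or numeric matrix) of queries in
#'   original descriptor units.
#' @param cutoff_percentile Percentile of LOO training densities (default 5).
#' @param quantile_rule See [ad_quantile()].
#' @return List of class `density_ad_result` with `in_ad`, `densities`,
#'   `cutoff`, `sample_ids`.
#' @export
density_ad <- function(est, query, cutoff_percentile = 5,
                       quantile_rule = "linear") {
  stopifnot(inherits(est, "density_estimator"))
  ids <- if (inherits(query, "descriptor_table")) query$ids
         else paste0("q", seq_len(nrow(as.matrix(query))))
  dens <- kde_evaluate(est, query)
  loo <- loo_train_densities(est)
  finite <- loo[is.finite(loo)]
  if (!length(finite)) stop("no finite leave-one-out training densities.")
  cutoff <- ad_quantile(finite, cutoff_percentile / 100, rule = quantile_rule)
  structure(list(sample_ids = ids, in_ad = dens >= cutoff, densities = dens,
                 cutoff = cutoff),
            class = "density_ad_result")
}

#' @export
print.density_ad_result <- function(x, ...) {
  cat(sprintf("<density_ad_result> %d of %d queries in AD (cutoff %.4g)\n",
              sum(x$in_ad), length(x$in_ad), x$cutoff))
  invisible(x)
}
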