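# Synthetic data generators: (a) a dense isotropic cluster plus a few
# extreme outliers, the geometry used throughout the methods discussion;
# (b) a generic QSAR-like regression set (linear response + Gaussian noise)
# with optional off-support test points, for exercising Q^2 and
# standardized-error reporting.

#' Simulate a dense cluster with extreme outliers
#'
#' Draws `n_cluster` points isotropically (Gaussian, standard deviation
#' `cluster_spread`) around a fixed centroid, then places `n_outliers`
#' points at `outlier_offset * cluster_spread` from the centroid in distinct
#' random directions, redrawn until the outliers are also detached from one
#' another. Outliers receive the last sample indices. With
#' `outlier_offset >= 10` the outliers are guaranteed to be detached from
#' the cluster (checked after generation): under a moderate smoothing
#' parameter they receive `K_i = 0` and the fallback threshold.
#'
#' @param n_cluster Cluster size (>= 10); default 48.
#' @param n_outliers Number of extreme outliers; default 2.
#' @param p Descriptor count; default 2.
#' @param cluster_spread Within-cluster standard deviation; default 1.
#' @param outlier_offset Offset of the outliers from the centroid, in
#'   multiples of `cluster_spread`; default 15.
#' @param seed Integer seed; the same seed reproduces the table exactly.
#' @return A [descriptor_table()] with ids `"s1" ...`; outliers last.
#' @export
simulate_cluster_with_outliers <- function(n_cluster = 48L, n_outliers = 2L,
                                           p = 2L, cluster_spread = 1,
                                           outlier_offset = 15, seed = 1L) {
  if (n_cluster < 10L) stop("n_cluster must be >= 10.")
  if (n_outliers < 0L || p < 1L || cluster_spread <= 0 || outlier_offset <= 0)
    stop("invalid simulation specification.")
  with_preserved_seed(seed, {
    centroid <- rep(0, p)
    Xc <- matrix(stats::rnorm(n_cluster * p, sd = cluster_spread), n_cluster, p)
    Xo <- NULL
    if (n_outliers > 0L) {
      # redraw the direction set until the outliers are detached from each
      # other as well (same margin as the cluster check below), so each one
      # is genuinely isolated rather than part of a small secondary cluster
      for (attempt in 1:100) {
        dirs <- matrix(stats::rnorm(n_outliers * p), n_outliers, p)
        dirs <- dirs / sqrt(rowSums(dirs^2))
        Xo <- dirs * outlier_offset * cluster_spread
        if (n_outliers == 1L || min(stats::dist(Xo)) >= 5 * cluster_spread)
          break
        if (attempt == 100)
          stop("could not place mutually detached outliers; ",
               "reduce n_outliers or increase outlier_offset.")
      }
    }
    X <- rbind(Xc, Xo)
  })
  if (n_outliers > 0L && outlier_offset >= 10) {
    # detachment check: each outlier must clear the cluster by a wide margin
    gap <- pairwise_distances(X[n_cluster + seq_len(n_outliers), , drop = FALSE],
                              X[seq_len(n_cluster), , drop = FALSE])
    if (min(gap) < 5 * cluster_spread)
      stop("generated outliers are not detached from the cluster; ",
           "increase outlier_offset.")
  }
  descriptor_table(X, ids = paste0("s", seq_len(nrow(X))))
}

#' Simulate a QSAR-like regression data set
#'
#' Training and test descriptors are drawn from a common standard-normal
#' distribution; the measured response is a fixed linear combination of the
#' descriptors plus Gaussian noise of standard deviation `noise_sd`. A
#' fraction `shift_fraction` of the test points is displaced by
#' `test_shift` (in descriptor standard deviations, along a random
#' direction) outside the training support, creating genuine out-of-AD
#' cases.
#'
#' The true signal is linear with a mild curvature term
#' \eqn{\gamma (\lVert x \rVert^2 - p) / (2\sqrt{p})} (`curvature` =
#' \eqn{\gamma}): within the training support the curvature contributes a
#' small fraction of the noise scale, so the response is essentially linear
#' there, but it dominates far outside the support. Predicted responses come
#' from an ordinary least-squares linear fit of the training responses on
#' the descriptors (default) — a model that, like any empirical QSAR model,
#' is accurate where it was trained and degrades when extrapolating — or,
#' with `prediction = "oracle"`, from the full noiseless signal, making
#' prediction error exactly the injected noise everywhere.
#'
#' @param n_train,n_test Sample counts.
#' @param p Descriptor count; default 5.
#' @param noise_sd Response noise standard deviation; default 0.5.
#' @param test_shift Displacement of off-support test points, in descriptor
#'   standard deviations; default 6.
#' @param shift_fraction Fraction of test points displaced; default 0.2.
#' @param curvature Coefficient of the centered-quadratic signal term;
#'   default 0.15 (about 5% of the in-support response variance).
#' @param seed Integer seed.
#' @param prediction `"ols"` (default) or `"oracle"`, see Details.
#' @return List with `train` and `test` [descriptor_table()]s (both carry
#'   `y` and `y_hat`) and `shifted_ids`, the ids of displaced test points.
#' @export
simulate_qsar_dataset <- function(n_train = 150L, n_test = 50L, p = 5L,
                                  noise_sd = 0.5, test_shift = 6,
                                  shift_fraction = 0.2, curvature = 0.15,
                                  seed = 1L,
                                  prediction = c("ols", "oracle")) {
  prediction <- match.arg(prediction)
  if (n_train < max(5L, p + 2L) || n_test < 1L) stop("invalid sample sizes.")
  if (noise_sd < 0 || test_shift < 0 || shift_fraction < 0 || shift_fraction > 1)
    stop("invalid simulation specification.")
  beta <- 1.5 * (-1)^(seq_len(p)) * seq_len(p) / p    # fixed coefficients
  signal <- function(X) as.numeric(X %*% beta) +
    curvature * (rowSums(X^2) - p) / (2 * sqrt(p))
  res <- with_preserved_seed(seed, {
    Xtr <- matrix(stats::rnorm(n_train * p), n_train, p)
    Xte <- matrix(stats::rnorm(n_test * p), n_test, p)
    n_shift <- round(shift_fraction * n_test)
    shifted <- if (n_shift > 0L) sample.int(n_test, n_shift) else integer(0)
    if (n_shift > 0L) {
      dirs <- matrix(stats::rnorm(n_shift * p), n_shift, p)
      dirs <- dirs / sqrt(rowSums(dirs^2))
      Xte[shifted, ] <- Xte[shifted, , drop = FALSE] + dirs * test_shift
    }
    ytr <- signal(Xtr) + stats::rnorm(n_train, sd = noise_sd)
    yte <- signal(Xte) + stats::rnorm(n_test, sd = noise_sd)
    list(Xtr = Xtr, Xte = Xte, ytr = ytr, yte = yte, shifted = shifted)
  })
  if (prediction == "ols") {
    fit <- stats::lm.fit(cbind(1, res$Xtr), res$ytr)
    co <- fit$coefficients
    yhat_tr <- as.numeric(cbind(1, res$Xtr) %*% co)
    yhat_te <- as.numeric(cbind(1, res$Xte) %*% co)
  } else {
    yhat_tr <- signal(res$Xtr)
    yhat_te <- signal(res$Xte)
  }
  train <- descriptor_table(res$Xtr, ids = paste0("tr", seq_len(n_train)),
                            y = res$ytr, y_hat = yhat_tr)
  test <- descriptor_table(res$Xte, ids = paste0("ts", seq_len(n_test)),
                           y = res$yte, y_hat = yhat_te)
  list(train = train, test = test,
       shifted_ids = test$ids[sort(res$shifted)], beta = beta)
}
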