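test_that("average k-neighbour distances match hand arithmetic and grow with k", {
  tab <- build_neighbour_table(matrix(c(0, 1, 3), ncol = 1))
  expect_equal(average_knn_distances(tab, 2), c(2.0, 1.5, 2.5))
  expect_equal(average_knn_distances(tab, 1), tab$D[, 1])
  expect_error(average_knn_distances(tab, 3), "in \\[1, 2\\]")
  set.seed(14)
  rt <- build_neighbour_table(matrix(rnorm(40), 20, 2))
  for (k in 1:18)
    expect_true(all(average_knn_distances(rt, k + 1) >=
                    average_knn_distances(rt, k) - 1e-12))
})

test_that("reference value is the Tukey upper fence under the declared rule", {
  expect_equal(reference_value(c(7, 7, 7)), 7)
  expect_equal(reference_value(c(1, 1, 2)), 2.25)
  expect_equal(reference_value(c(1, 1, 1, 98)), 61.625)
  expect_error(reference_value(numeric(0)), "empty")
  # nearest-rank alternative changes the quartiles accordingly
  q1 <- quantile(c(1, 1, 1, 98), 0.25, type = 1, names = FALSE)
  q3 <- quantile(c(1, 1, 1, 98), 0.75, type = 1, names = FALSE)
  expect_equal(reference_value(c(1, 1, 1, 98), quantile_rule = "nearest"),
               q3 + 1.5 * (q3 - q1))
})

test_that("thresholds, densities and the fallback rule follow the full hand enumeration", {
  tab <- build_neighbour_table(matrix(c(0, 1, 2, 100), ncol = 1))
  avg <- average_knn_distances(tab, 1)
  expect_equal(avg, c(1, 1, 1, 98))
  rv <- reference_value(avg)
  expect_equal(rv, 61.625)
  th <- thresholds_from_refval(tab, rv)
  expect_equal(th$K, c(2L, 2L, 2L, 0L))
  expect_equal(th$t, c(1.5, 1.0, 1.5, 1.0))
  expect_equal(th$fallback, c(FALSE, FALSE, FALSE, TRUE))
  # no truncation: huge ref_val keeps all n-1 distances
  th2 <- thresholds_from_refval(tab, 1e6)
  expect_equal(th2$K, rep(3L, 4))
  expect_equal(th2$t, rowMeans(tab$D))
  # ref_val below every distance: degenerate, no AD
  expect_error(thresholds_from_refval(tab, 0.5), "K_i = 0")
})

test_that("fit_ad composes the chain and is deterministic", {
  tr <- toy_1d(c(0, 1, 2, 100))
  m <- fit_ad(tr, k = 1, pretreat = FALSE)
  expect_s3_class(m, "knnad_model")
  expect_equal(m$ref_val, 61.625)
  expect_equal(m$t, c(1.5, 1.0, 1.5, 1.0))
  expect_true(all(m$t <= m$ref_val))
  m2 <- fit_ad(tr, k = 1, pretreat = FALSE)
  expect_identical(m, m2)
  expect_error(fit_ad(tr, k = 4, pretreat = FALSE), "in \\[1, 3\\]")
  expect_error(fit_ad(toy_1d(c(0, 1)), k = 1), "at least 3")
})

test_that("AD decisions follow the at-least-one-threshold rule", {
  m <- fit_ad(toy_1d(c(0, 1, 3)), k = 1, pretreat = FALSE)
  expect_equal(m$t, c(1, 1.5, 2))
  d <- apply_ad(m, toy_1d(2, ids = "q"))
  expect_true(d$in_ad)
  expect_equal(d$K_j, 2L)
  expect_equal(d$nearest_satisfying_distance, 1)
  # query identical to a training sample: distance 0 satisfies its threshold
  d0 <- apply_ad(m, toy_1d(1, ids = "same"))
  expect_true(d0$in_ad)
  expect_equal(d0$nearest_satisfying_distance, 0)
  # far query is out with K_j = 0 and no satisfying distance
  dfar <- apply_ad(m, toy_1d(1e6, ids = "far"))
  expect_false(dfar$in_ad)
  expect_equal(dfar$K_j, 0L)
  expect_true(is.na(dfar$nearest_satisfying_distance))
  expect_error(apply_ad(m, descriptor_table(matrix(1, 1, 2))), "descriptor count")
})

test_that("decisions and thresholds match the naive oracle on random instances", {
  cases <- expand.grid(n = c(10, 30, 50), metric = c("euclidean", "manhattan"),
                       stringsAsFactors = FALSE)
  for (ci in seq_len(nrow(cases))) {
    n <- cases$n[ci]
    set.seed(100 + ci)
    X <- matrix(rnorm(n * 4), n, 4)
    Q <- matrix(rnorm(8 * 4), 8, 4)
    for (k in c(1, 3, n - 1)) {
      o <- naive_knn_ad(X, Q, k, cases$metric[ci])
      tr <- descriptor_table(X); qu <- descriptor_table(Q, ids = paste0("q", 1:8))
      m <- fit_ad(tr, k = k, metric = cases$metric[ci], pretreat = FALSE)
      # integer and logical outputs must agree exactly; real-valued outputs
      # to floating-point association error only
      expect_identical(m$K, o$K)
      expect_identical(m$fallback_mask, o$fallback)
      expect_identical(apply_ad(m, qu)$K_j, o$K_j)
      expect_equal(m$ref_val, o$ref_val, tolerance = 1e-14)
      expect_equal(m$t, o$t, tolerance = 1e-14)
    }
  }
})

test_that("Ref Val, thresholds, densities and memberships are non-decreasing in k", {
  set.seed(21)
  for (rep in 1:5) {
    n <- sample(10:30, 1)
    tr <- descriptor_table(matrix(rnorm(n * 3), n, 3))
    qu <- descriptor_table(matrix(rnorm(12 * 3, sd = 2), 12, 3),
                           ids = paste0("q", 1:12))
    prev <- NULL
    for (k in seq_len(n - 1)) {
      m <- fit_ad(tr, k = k, pretreat = FALSE)
      Kj <- apply_ad(m, qu)$K_j
      if (!is.null(prev)) {
        expect_true(m$ref_val >= prev$rv - 1e-12)
        expect_true(all(m$K >= prev$K))
        expect_true(all(m$t >= prev$t - 1e-12))
        expect_true(all(Kj >= prev$Kj))
      }
      prev <- list(rv = m$ref_val, K = m$K, t = m$t, Kj = Kj)
    }
  }
})

test_that("training samples queried against their own model stay in the AD", {
  set.seed(33)
  tr <- descriptor_table(matrix(rnorm(60), 30, 2), ids = paste0("t", 1:30))
  m <- fit_ad(tr, k = 5)
  stopifnot(all(m$t > 0))
  d <- apply_ad(m, tr)
  expect_true(all(d$in_ad))
  expect_true(all(d$K_j >= 1L))
})

test_that("scaling all coordinates scales distances but not memberships", {
  set.seed(44)
  tr <- descriptor_table(matrix(rnorm(40), 20, 2))
  qu <- descriptor_table(matrix(rnorm(10, sd = 3), 5, 2), ids = paste0("q", 1:5))
  c_mult <- 7.3
  m1 <- fit_ad(tr, k = 4, pretreat = FALSE)
  tr2 <- descriptor_table(tr$X * c_mult)
  qu2 <- descriptor_table(qu$X * c_mult, ids = qu$ids)
  m2 <- fit_ad(tr2, k = 4, pretreat = FALSE)
  expect_equal(m2$avg_knn_dist, c_mult * m1$avg_knn_dist, tolerance = 1e-12)
  expect_equal(m2$ref_val, c_mult * m1$ref_val, tolerance = 1e-12)
  expect_equal(m2$t, c_mult * m1$t, tolerance = 1e-12)
  expect_identical(m2$K, m1$K)
  d1 <- apply_ad(m1, qu); d2 <- apply_ad(m2, qu2)
  expect_identical(d1$K_j, d2$K_j)
  expect_identical(d1$in_ad, d2$in_ad)
})

test_that("model serialization round-trips at full precision", {
  set.seed(55)
  tr <- descriptor_table(matrix(rnorm(36), 12, 3), ids = paste0("t", 1:12))
  qu <- descriptor_table(matrix(rnorm(9, sd = 2), 3, 3), ids = paste0("q", 1:3))
  m <- fit_ad(tr, k = 3, metric = "mahalanobis")
  path <- withr::local_tempfile(fileext = ".json")
  write_knnad_model(m, path)
  back <- read_knnad_model(path)
  expect_equal(back$t, m$t, tolerance = 0)
  expect_equal(back$ref_val, m$ref_val, tolerance = 0)
  expect_identical(back$K, m$K)
  expect_equal(apply_ad(back, qu), apply_ad(m, qu))
  # euclidean model: the absent inverse covariance must read back as NULL
  me <- fit_ad(tr, k = 3)
  path2 <- withr::local_tempfile(fileext = ".json")
  write_knnad_model(me, path2)
  backe <- read_knnad_model(path2)
  expect_null(backe$metric$inv_cov)
  expect_equal(apply_ad(backe, qu), apply_ad(me, qu))
})
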