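test_that("Mahalanobis distance is zero at the mean and in SD units", {
  # 1D cluster with sample mean 0 and variance 1
  x <- matrix(c(-1, 0, 1, 2.5, 3.5, 4.5), ncol = 1)
  labels <- rep(c("a", "b"), each = 3)
  m <- fit_clusters(x, labels, merge_map = NULL)
  d <- cluster_distances(m, 2)
  expect_equal(unname(d[1, "a"]), 2, tolerance = 1e-3)
  expect_equal(unname(cluster_distances(m, 0)[1, "a"]), 0,
               tolerance = 1e-6)
})

test_that("with diagonal covariance the distance is a z-score norm", {
  # hand-built model with exactly diagonal covariance
  C <- diag(c(4, 9, 1))
  model <- structure(list(
    clusters = list(g = list(label = "g", mean = c(1, 2, 3), cov = C,
                             cov_inv = solve(C), n = 10)),
    dof = 3, features = c("f1", "f2", "f3"), merge_map = NULL,
    ridge = 0, standardize = FALSE, center = rep(0, 3),
    scale = rep(1, 3)), class = "cluster_model")
  set.seed(53)
  for (i in 1:10) {
    x <- rnorm(3, 0, 5)
    oracle <- sqrt(sum(((x - c(1, 2, 3)) / c(2, 3, 1))^2))
    expect_equal(unname(cluster_distances(model, x)[1, 1]), oracle)
  }
})

test_that("fitted means and covariances are consistent estimators", {
  set.seed(59)
  S <- matrix(c(2, 0.7, 0.7, 1), 2)
  L <- chol(S)
  x <- matrix(rnorm(2e4), ncol = 2) %*% L
  x2 <- sweep(matrix(rnorm(2e4), ncol = 2) %*% L, 2, c(10, 10), `+`)
  m <- fit_clusters(rbind(x, x2), rep(c("a", "b"), each = 1e4),
                    merge_map = NULL)
  expect_equal(unname(m$clusters$a$mean), c(0, 0), tolerance = 0.05)
  expect_equal(unname(m$clusters$a$cov), S, ignore_attr = TRUE,
               tolerance = 0.05)
})

test_that("the default merge map folds four labels into three clusters", {
  set.seed(61)
  x <- matrix(rnorm(40), ncol = 2)
  m <- fit_clusters(x, rep(c("POm", "SC", "Pons", "Sp5C"), each = 5))
  expect_length(m$clusters, 3)
  expect_setequal(names(m$clusters), c("POm", "SC/Pons", "Sp5C"))
  expect_error(fit_clusters(x[1:6, ], c(rep("a", 5), "b"),
                            merge_map = NULL), "fewer than 2")
  # degenerate cluster of identical points is rescued by the ridge
  xx <- rbind(matrix(1, 4, 2), matrix(c(5, 5, 5, 6, 6, 6, 6, 5), 4, 2))
  m2 <- fit_clusters(xx, rep(c("a", "b"), each = 4), merge_map = NULL,
                     quiet = TRUE)
  expect_true(all(is.finite(cluster_distances(m2, c(1, 1)))))
})

test_that("equidistant cells split confidence evenly", {
  # three clusters that are translates of one symmetric point pattern
  pat <- rbind(c(1, 0), c(-1, 0), c(0, 1), c(0, -1))
  centers <- rbind(c(0, 0), c(6, 0), c(3, 3 * sqrt(3)))
  x <- do.call(rbind, lapply(1:3, function(i)
    sweep(pat, 2, centers[i, ], `+`)))
  m <- fit_clusters(x, rep(c("a", "b", "c"), each = 4), merge_map = NULL)
  centroid <- colMeans(centers)
  r <- classify_cells(m, centroid)
  expect_equal(unname(r$posterior[1, ]), rep(1 / 3, 3), tolerance = 1e-9)
  expect_true(r$tie[1])
  expect_equal(sum(r$posterior[1, ]), 1)
})

test_that("a cell at a cluster mean is assigned there with p = 1", {
  set.seed(67)
  x <- rbind(matrix(rnorm(20, 0, 1), ncol = 2),
             matrix(rnorm(20, 50, 1), ncol = 2))
  labels <- rep(c("near", "far"), each = 10)
  m <- fit_clusters(x, labels, merge_map = NULL)
  r <- classify_cells(m, m$clusters$near$mean)
  expect_equal(r$assigned, "near")
  expect_equal(unname(r$p[1, "near"]), 1) # ChiSqCDF(0) = 0
  expect_gt(r$confidence, 0.999)
})

test_that("chi-squared tail matches the incomplete-gamma oracle", {
  d2 <- c(0.1, 0.5, 1, 2, 3.7, 5, 8, 12, 20, 30)
  for (df in c(1, 2, 3, 5, 6)) {
    impl <- pchisq(d2, df, lower.tail = FALSE)
    oracle <- chisq_tail_oracle(d2, df)
    expect_lt(max(abs(impl - oracle)), 1e-8)
  }
})

test_that("posteriors sum to one and underflow falls back to argmin", {
  set.seed(71)
  x <- rbind(matrix(rnorm(20, 0, 0.1), ncol = 2),
             matrix(rnorm(20, 3, 0.1), ncol = 2))
  m <- fit_clusters(x, rep(c("a", "b"), each = 10), merge_map = NULL)
  pts <- matrix(rnorm(40, 1.5, 2), ncol = 2)
  r <- classify_cells(m, pts)
  expect_equal(unname(rowSums(r$posterior)), rep(1, 20))
  # a point absurdly far from every cluster: underflow flag, argmin kept
  rfar <- classify_cells(m, c(1e5, 1e5))
  expect_true(rfar$underflow[1])
  expect_equal(rfar$confidence[1], 1)
  expect_equal(sum(rfar$posterior[1, ]), 1)
})

test_that("classification is invariant under affine feature rescaling", {
  set.seed(73)
  x <- cbind(rnorm(30, rep(c(0, 5, 10), each = 10)), rnorm(30))
  labels <- rep(c("a", "b", "c"), each = 10)
  m1 <- fit_clusters(x, labels, merge_map = NULL)
  x2 <- x
  x2[, 1] <- x2[, 1] * 250 - 40 # rescaled feature, model refit
  m2 <- fit_clusters(x2, labels, merge_map = NULL)
  q <- c(2.5, 0.3)
  q2 <- c(2.5 * 250 - 40, 0.3)
  expect_equal(cluster_distances(m1, q), cluster_distances(m2, q2),
               tolerance = 1e-6)
  expect_equal(classify_cells(m1, q)$posterior,
               classify_cells(m2, q2)$posterior, tolerance = 1e-6)
})

test_that("confidence decays monotonically away from the cluster mean", {
  set.seed(79)
  x <- rbind(matrix(rnorm(40, 0, 1), ncol = 2),
             matrix(rnorm(40, 30, 1), ncol = 2))
  m <- fit_clusters(x, rep(c("a", "b"), each = 20), merge_map = NULL)
  mu <- m$clusters$a$mean
  dir <- c(1, 0.5) / sqrt(1.25)
  conf <- sapply(seq(0, 4, by = 0.5), function(s)
    classify_cells(m, mu + s * dir)$posterior[1, "a"])
  expect_true(all(diff(conf) <= 1e-12))
})

test_that("well-separated Gaussian clusters are classified correctly", {
  set.seed(83)
  n <- 150
  x <- rbind(cbind(rnorm(n), rnorm(n)),
             cbind(rnorm(n, 8), rnorm(n)),
             cbind(rnorm(n), rnorm(n, 8)))
  labels <- rep(c("a", "b", "c"), each = n)
  ev <- evaluate_cohort(x, labels, merge_map = NULL, loo = FALSE)
  expect_gt(ev$accuracy, 0.99)
  # the training means themselves classify perfectly
  m <- fit_clusters(x, labels, merge_map = NULL)
  centers <- do.call(rbind, lapply(m$clusters, `[[`, "mean"))
  r <- classify_cells(m, centers)
  expect_equal(r$assigned, names(m$clusters))
})

test_that("single-feature spaces underperform the combined space", {
  confs <- sapply(c("depth", "rate", "combined"), function(sp) {
    vals <- sapply(1:6, function(s) {
      cfg <- default_cohort_config(n_dual = 0, seed = 300 + s)
      co <- generate_cohort(cfg, trains = (sp != "depth"))
      fm <- target_feature_matrix(co, sp)
      evaluate_cohort(fm$x, fm$labels, loo = FALSE)$accuracy
    })
    mean(vals)
  })
  expect_gt(confs["combined"], confs["depth"])
  expect_gt(confs["combined"], confs["rate"])
})

test_that("cluster models survive a JSON round trip", {
  set.seed(89)
  x <- matrix(rnorm(60), ncol = 3)
  m <- fit_clusters(x, rep(c("POm", "SC", "Sp5C"), c(7, 7, 6)),
                    quiet = TRUE)
  f <- withr::local_tempfile(fileext = ".json")
  write_cluster_model(m, f)
  m2 <- read_cluster_model(f)
  q <- rnorm(3)
  expect_equal(cluster_distances(m, q), cluster_distances(m2, q),
               tolerance = 1e-10)
  expect_equal(names(m2$clusters), names(m$clusters))
})
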