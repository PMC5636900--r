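test_that("read_swc parses standard records and rejects malformed files", {
  f <- withr::local_tempfile(fileext = ".swc")
  writeLines(c("# comment", "1 1 0 0 0 5 -1", "2 3 0 30 0 0.5 1",
               "3 3 0 70 0 0.5 2"), f)
  m <- read_swc(f)
  expect_s3_class(m, "neuron_morphology")
  expect_equal(nrow(m$nodes), 3)
  expect_equal(attr(laminar_profile(m), "total_length"), 70)

  writeLines(c("1 1 0 0 0 5 -1", "2 3 0 30 0 0.5 9"), f)
  expect_error(read_swc(f), "undeclared parent")
  writeLines(c("1 1 0 0 0 5 -1", "2 2 0 30 0 0.5 1"), f)
  expect_error(read_swc(f), "structure code 2")
  writeLines(c("1 1 0 0 0 5 -1", "2 1 0 30 0 0.5 -1"), f)
  expect_error(read_swc(f), "exactly one root")
  writeLines(c("1 1 0 0 0 5 -1", "2 3 0 x 0 0.5 1"), f)
  expect_error(read_swc(f), "line 2")
})

test_that("write_swc / read_swc round-trips a generated morphology", {
  cfg <- default_cohort_config()
  m <- generate_morphology(cfg$groups$Pons, 1120, seed = 9)
  f <- withr::local_tempfile(fileext = ".swc")
  write_swc(m, f)
  m2 <- read_swc(f)
  expect_equal(m2$nodes$id, m$nodes$id)
  expect_equal(m2$nodes$type, m$nodes$type)
  expect_equal(m2$nodes[c("x", "y", "z")], m$nodes[c("x", "y", "z")],
               tolerance = 1e-7)
})

test_that("laminar profile splits edges at layer boundaries", {
  # vertical 300 um cable from the pia: 100 um in L1, 200 um in L2/3
  m <- make_morph(list(list(1, "apical", 0, 300, 0)), soma = c(0, 0, 0))
  pr <- laminar_profile(m)
  expect_equal(pr$path_length[pr$layer == "L1"], 100)
  expect_equal(pr$path_length[pr$layer == "L2/3"], 200)
  expect_equal(sum(pr$path_length), 300)

  # Y-tree forking at depth 500: one branch point in L2/3
  m <- make_morph(list(list(1, "apical", 0, 500, 0),
                       list(2, "apical", -50, 450, 0),
                       list(2, "apical", 50, 450, 0)),
                  soma = c(0, 600, 0))
  pr <- laminar_profile(m)
  expect_equal(pr$branch_points[pr$layer == "L2/3"], 1)
  expect_equal(sum(pr$branch_points), 1)
  # complexity is length x branch points, 0 wherever bp = 0
  expect_equal(pr$complexity, pr$path_length * pr$branch_points)
  expect_true(all(pr$complexity[pr$branch_points == 0] == 0))
})

test_that("laminar lengths match the dense-sampling oracle", {
  cfg <- default_cohort_config()
  for (g in c("POm", "SC")) {
    m <- generate_morphology(cfg$groups[[g]], 1080, seed = 13)
    pr <- laminar_profile(m)
    oracle <- dense_laminar_lengths(m)
    rel <- abs(pr$path_length - oracle) /
      pmax(oracle, attr(pr, "total_length") * 1e-3)
    expect_true(all(rel < 1e-3))
    # per-layer lengths sum to the total dendritic length
    expect_equal(sum(pr$path_length), attr(pr, "total_length"),
                 tolerance = 1e-9)
  }
})

test_that("laminar profile is invariant to collinear edge subdivision", {
  whole <- make_morph(list(list(1, "apical", 0, 400, 0)),
                      soma = c(0, 1100, 0))
  split <- make_morph(list(list(1, "apical", 0, 800, 0),
                           list(2, "apical", 0, 400, 0)),
                      soma = c(0, 1100, 0))
  expect_equal(laminar_profile(whole)$path_length,
               laminar_profile(split)$path_length)
})

test_that("nodes above the pia are clipped with a warning", {
  m <- make_morph(list(list(1, "apical", 0, -20, 0)), soma = c(0, 50, 0))
  expect_warning(pr <- laminar_profile(m), "pia")
  expect_equal(sum(pr$path_length), 70)
  expect_equal(pr$path_length[1], 70) # all in L1
})

test_that("feature vector of an unbranched basal cable", {
  m <- make_morph(list(list(1, "basal", 1000, 1100, 0)),
                  soma = c(0, 1100, 0))
  expect_warning(fv <- feature_vector(m), "apical")
  expect_equal(unname(fv["total_length"]), 1000)
  expect_equal(unname(fv["basal_length"]), 1000)
  expect_equal(unname(fv["apical_length"]), 0)
  expect_equal(unname(fv["total_bp"]), 0)
  expect_equal(unname(fv["max_branch_order"]), 1)
  expect_equal(unname(fv["n_basal_stems"]), 1)
  expect_equal(unname(fv["soma_depth"]), 1100)
  expect_length(fv, 21)
  expect_identical(names(fv), dendritic_feature_names())
})

test_that("features are consistent with the generator targets", {
  cfg <- default_cohort_config()
  gp <- cfg$groups$POm
  m <- generate_morphology(gp, 1090, seed = 17)
  tgt <- attr(m, "realized_targets")
  fv <- feature_vector(m)
  expect_equal(unname(fv["total_length"]), sum(tgt$length),
               tolerance = 0.05)
  expect_equal(unname(fv["total_bp"]), sum(tgt$bp))
  pr <- laminar_profile(m)
  expect_equal(pr$path_length[1:5], unname(tgt$length), tolerance = 0.05)
  expect_equal(pr$branch_points[1:5], unname(tgt$bp))
})

test_that("PCA reconstructs the z-scored matrix and fixes signs", {
  set.seed(23)
  x <- matrix(rnorm(15 * 6), 15, 6,
              dimnames = list(NULL, paste0("f", 1:6)))
  pc <- pca_features(x)
  z <- scale(x, center = pc$center, scale = pc$scale)
  expect_equal(pc$scores %*% t(pc$loadings), unclass(z),
               ignore_attr = TRUE, tolerance = 1e-10)
  expect_equal(crossprod(pc$loadings), diag(6), ignore_attr = TRUE,
               tolerance = 1e-10)
  expect_equal(sum(pc$explained_variance), 1)
  # sign convention: largest-magnitude loading positive
  for (j in 1:6)
    expect_gt(pc$loadings[which.max(abs(pc$loadings[, j])), j], 0)
})

test_that("PCA handles constant columns and identical cells", {
  set.seed(2)
  x <- cbind(a = rnorm(10), b = rep(3, 10), c = rnorm(10))
  expect_warning(pc <- pca_features(x), "constant")
  expect_identical(pc$dropped, "b")
  expect_equal(ncol(pc$loadings), 2)
  # two identical cells: all scores 0 after centering
  y <- rbind(c(1, 2, 5), c(1, 2, 5))
  expect_warning(pc2 <- pca_features(y), "constant")
  expect_true(all(pc2$scores == 0))
})

test_that("PCA scores are invariant (up to sign) under feature reorder", {
  set.seed(29)
  x <- matrix(rnorm(12 * 5), 12, 5, dimnames = list(NULL, paste0("f", 1:5)))
  pc1 <- pca_features(x)
  pc2 <- pca_features(x[, c(3, 1, 5, 2, 4)])
  for (j in 1:5) {
    same <- max(abs(pc1$scores[, j] - pc2$scores[, j]))
    flip <- max(abs(pc1$scores[, j] + pc2$scores[, j]))
    expect_lt(min(same, flip), 1e-8)
  }
})

test_that("PC1 separates thick-tufted from slender-tufted cohorts", {
  cfg <- default_cohort_config()
  thick <- cfg$groups$Pons
  slender <- thick
  # slender-tufted cells have roughly half the dendritic length
  slender$laminar_length_targets <- thick$laminar_length_targets * 0.45
  slender$laminar_bp_targets <- round(thick$laminar_bp_targets * 0.4)
  set.seed(37)
  cells <- c(lapply(1:8, function(i)
    generate_morphology(thick, 1100, length_jitter_sd = 0.15)),
    lapply(1:8, function(i)
      generate_morphology(slender, 1100, length_jitter_sd = 0.15)))
  feats <- t(sapply(cells, function(m) as.numeric(feature_vector(m))))
  colnames(feats) <- dendritic_feature_names()
  pc <- suppressWarnings(pca_features(feats))
  pc1 <- pc$scores[, 1]
  grp <- rep(c("thick", "slender"), each = 8)
  # complete separation along the first component
  expect_true(max(pc1[grp == "slender"]) < min(pc1[grp == "thick"]) ||
              min(pc1[grp == "slender"]) > max(pc1[grp == "thick"]))
})
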