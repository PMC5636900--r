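test_that("the default calibration carries the published group values", {
  cfg <- default_cohort_config()
  expect_equal(cfg$groups$POm$ongoing_rate_mean, 7.2)
  expect_equal(cfg$groups$Sp5C$onset_prob, 0.64)
  expect_equal(cfg$groups$POm$depth_mean, 1042)
  expect_equal(cfg$groups$Pons$depth_mean, 1131)
  expect_length(cfg$groups, 4)
  expect_equal(cfg$dual_fraction, 0.25)
  expect_equal(sum(vapply(cfg$groups, `[[`, numeric(1),
                          "cells_per_column")), 1135)
  expect_equal(sum(vapply(cfg$groups, `[[`, numeric(1), "pct_neun")), 33)
})

test_that("group parameter invariants are enforced", {
  cfg <- default_cohort_config()
  gp <- cfg$groups$POm
  make <- function(edit) {
    a <- gp; a[names(edit)] <- edit
    do.call(group_params, a[setdiff(names(a), character(0))])
  }
  expect_error(make(list(n_cells = -1)), "n_cells")
  expect_error(make(list(onset_prob = 1.4)), "onset_prob")
  expect_error(make(list(burst100_frac = 0.01)), "burst200")
  expect_error(cohort_config(list(gp), n_trials = 0), "n_trials")
  expect_error(cohort_config(list(gp), window = c(100, 1100)), "stimulus")
})

test_that("an all-empty configuration yields an empty cohort", {
  cfg <- default_cohort_config(n_cells = c(0, 0, 0, 0), n_dual = 0)
  expect_length(generate_cohort(cfg), 0)
})

test_that("cohorts are reproducible for a fixed seed", {
  cfg <- default_cohort_config(seed = 77)
  co1 <- generate_cohort(cfg)
  co2 <- generate_cohort(cfg)
  expect_identical(co1, co2)
  co3 <- generate_cohort(default_cohort_config(seed = 78))
  expect_false(identical(co1, co3))
})

test_that("the default cohort has 22 cells with 3 valid dual labels", {
  co <- generate_cohort(default_cohort_config(seed = 4),
                        morphology = FALSE, trains = FALSE)
  expect_length(co, 22)
  duals <- Filter(function(cell) cell$dual, co)
  expect_length(duals, 3)
  for (cell in duals) {
    expect_length(cell$true_targets, 2)
    expect_false(setequal(cell$true_targets, c("POm", "Sp5C")))
  }
  expect_true(all(sapply(co, function(cell) cell$soma_depth > 0)))
})

test_that("group depth and rate means converge to the calibration", {
  cfg <- default_cohort_config(n_cells = c(200, 0, 0, 0), n_dual = 0,
                               seed = 19)
  co <- generate_cohort(cfg, morphology = FALSE, trains = FALSE)
  depth <- sapply(co, `[[`, "soma_depth")
  expect_lt(abs(mean(depth) - 1042), 3 * 105 / sqrt(200))
  ong <- sapply(co, function(cell) cell$params$ongoing_rate)
  se <- sd(ong) / sqrt(200)
  # truncation at zero biases the mean upward by well under 3 SE
  expect_lt(abs(mean(ong) - 7.2), 3 * se + 0.25)
})

test_that("zero rates produce empty trials", {
  tr <- generate_spike_trains(list(ongoing_rate = 0, onset_rate = 0,
                                   sustained_rate = 0), 10, seed = 1)
  expect_true(all(lengths(tr$trials) == 0))
})

test_that("spike counts match the Poisson expectation", {
  tr <- generate_spike_trains(list(ongoing_rate = 10, onset_rate = 0,
                                   sustained_rate = 0), 2000, seed = 23)
  counts <- sapply(tr$trials, function(t) sum(t >= -200 & t < 0))
  # 200 ms x 10 Hz = 2 expected spikes
  expect_lt(abs(mean(counts) - 2), 3 * sqrt(2) / sqrt(2000))
  expect_equal(ongoing_rate(tr), mean(counts) * 5)
})

test_that("trains respect the window and are strictly increasing", {
  cfg <- default_cohort_config(n_cells = c(3, 3, 3, 3), n_dual = 0,
                               seed = 27)
  co <- generate_cohort(cfg, morphology = FALSE)
  for (cell in co) {
    for (t in cell$trains$trials) {
      if (length(t)) {
        expect_true(all(t >= -200 & t <= 1100))
        if (length(t) > 1) expect_true(all(diff(t) > 0))
      }
    }
  }
})

test_that("without burst injection ongoing ISIs are exponential", {
  # long pre-stimulus window so gap censoring is negligible
  tr <- generate_spike_trains(list(ongoing_rate = 20, onset_rate = 0,
                                   sustained_rate = 0,
                                   burst100_frac = 0, burst200_frac = 0),
                              n_trials = 30, window = c(-20000, 1100),
                              seed = 29)
  isis <- unlist(lapply(tr$trials, function(t) diff(t[t < 0])))
  expect_gt(length(isis), 1e4)
  ks <- suppressWarnings(stats::ks.test(isis, stats::pexp,
                                        rate = 20 / 1000))
  expect_gt(ks$p.value, 0.01)
})

test_that("burst injection raises short-ISI fractions as configured", {
  base <- list(ongoing_rate = 8, onset_rate = 0, sustained_rate = 0,
               burst100_frac = 0, burst200_frac = 0)
  bursty <- base
  bursty$burst100_frac <- 0.15; bursty$burst200_frac <- 0.06
  tr0 <- generate_spike_trains(base, 3000, seed = 31)
  tr1 <- generate_spike_trains(bursty, 3000, seed = 31)
  expect_gt(burst_fraction(tr1, 100), burst_fraction(tr0, 100) + 5)
  expect_lte(burst_fraction(tr1, 200), burst_fraction(tr1, 100))
  # total ongoing rate is preserved by the base-rate compensation
  expect_equal(ongoing_rate(tr1), 8, tolerance = 0.1)
})

test_that("onset probability calibration works from both sides", {
  # expectation above target: trials are thinned down
  tr <- generate_spike_trains(list(ongoing_rate = 5, onset_rate = 10,
                                   sustained_rate = 0, onset_prob = 0.4),
                              4000, seed = 37)
  prob <- mean(sapply(tr$trials, function(t) any(t >= 0 & t < 100)))
  expect_equal(prob, 0.4, tolerance = 0.06)
  # expectation below target: spikeless trials receive injected spikes
  tr <- generate_spike_trains(list(ongoing_rate = 1, onset_rate = 1,
                                   sustained_rate = 0, onset_prob = 0.5),
                              4000, seed = 38)
  prob <- mean(sapply(tr$trials, function(t) any(t >= 0 & t < 100)))
  expect_equal(prob, 0.5, tolerance = 0.06)
})

test_that("degenerate laminar targets give a single-layer cable", {
  lay5 <- c("L1", "L2/3", "L4", "L5A", "L5B")
  tgt <- list(laminar_length_targets =
                stats::setNames(c(0, 0, 0, 0, 1000), lay5),
              laminar_bp_targets = stats::setNames(rep(0, 5), lay5))
  m <- generate_morphology(tgt, soma_depth = 1100)
  pr <- laminar_profile(m)
  expect_equal(pr$path_length[pr$layer == "L5B"], 1000, tolerance = 1e-6)
  expect_equal(sum(pr$path_length), 1000, tolerance = 1e-6)
  expect_equal(sum(pr$branch_points), 0)
})

test_that("unreachable laminar targets raise a generation error", {
  lay5 <- c("L1", "L2/3", "L4", "L5A", "L5B")
  tgt <- list(laminar_length_targets =
                stats::setNames(c(30, 1000, 1000, 1000, 5000), lay5),
              laminar_bp_targets = stats::setNames(rep(0, 5), lay5))
  expect_error(generate_morphology(tgt, soma_depth = 1100),
               "unreachable")
  tgt$laminar_length_targets[1] <- 0
  tgt$laminar_bp_targets[1] <- 3
  expect_error(generate_morphology(tgt, soma_depth = 1100),
               "branch points")
})

test_that("POm trees are the least complex in L5A", {
  cfg <- default_cohort_config()
  set.seed(43)
  mean_l5a <- sapply(cfg$groups, function(gp) {
    mean(sapply(1:6, function(i) {
      pr <- laminar_profile(generate_morphology(gp, 1100))
      pr$complexity[pr$layer == "L5A"]
    }))
  })
  expect_true(all(mean_l5a["POm"] < mean_l5a[c("SC", "Pons", "Sp5C")]))
  # and SC trees are the least complex in L5B
  mean_l5b <- sapply(cfg$groups, function(gp) {
    mean(sapply(1:6, function(i) {
      pr <- laminar_profile(generate_morphology(gp, 1100))
      pr$complexity[pr$layer == "L5B"]
    }))
  })
  expect_true(all(mean_l5b["SC"] < mean_l5b[c("POm", "Pons", "Sp5C")]))
})

test_that("soma fields are reproducible and support NeuN-only mode", {
  cfg <- default_cohort_config()
  f1 <- generate_soma_field(cfg, seed = 47, n_slices = 3)
  f2 <- generate_soma_field(cfg, seed = 47, n_slices = 3)
  expect_identical(f1$slices, f2$slices)
  f3 <- generate_soma_field(cfg, seed = 47, n_slices = 3,
                            include_labeled = FALSE)
  expect_setequal(unique(f3$slices[[1]]$channel), "NeuN")
  expect_length(f3$truth, 0)
})
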