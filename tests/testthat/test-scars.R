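test_that("the retention schedule keeps everything first, two variables last, decreasing between", {
  r <- edfRatio(1:50, 50, 264)
  expect_true(all(diff(r) < 0))
  expect_gt(min(r), 0)
  expect_error(edfRatio(1, 50, 1), "at least two")
  expect_error(edfRatio(0, 50, 264))
  expect_error(edfRatio(51, 50, 264))
})

test_that("informative variables score higher coefficient stability than noise", {
  set.seed(41)
  n <- 60
  X <- matrix(rnorm(n * 20), n)
  y <- 3 * X[, 5] + rnorm(n, 0, 0.3)
  stab <- scarsStability(X, y, scarsConfig(seed = 41))
  expect_length(stab, 20L)
  expect_true(all(stab >= 0))
  expect_equal(which.max(stab), 5L)
  expect_gt(stab[5], 5 * max(stab[-5]))
  expect_error(scarsStability(X, rep(1, n), scarsConfig()),
               "constant response")
})

test_that("band selection is seed-deterministic and tracks the retention schedule", {
  d <- cachedDataset()
  X <- spectraMatrix(d, "absorbance")[1:60, ]
  y <- moisture(d)[1:60]
  g <- frequencyGrid(d)
  cfg <- scarsConfig(n_runs = 20L, seed = 7)
  r1 <- scarsSelect(X, y, g, cfg)
  r2 <- scarsSelect(X, y, g, cfg)
  expect_identical(r1$selected_vars, r2$selected_vars)
  expect_identical(r1$rmsecv, r2$rmsecv)
  # forced sizes follow ceil(r_i * p) while enough variables survive
  sched <- ceiling(edfRatio(seq_len(r1$n_runs_done), 20L, ncol(X)) * ncol(X))
  expect_true(all(r1$forced_sizes <= sched))
  expect_true(all(diff(r1$forced_sizes) <= 0))
  # the retained set after each cycle is within the forced selection budget
  sizes <- lengths(r1$retained_sets)
  expect_true(all(sizes <= r1$forced_sizes))
  # the stochastic dedup never collapses the trajectory: every scheduled
  # cycle runs and the endpoint is still being shrunk by the schedule
  expect_equal(r1$n_runs_done, 20L)
})

test_that("the winning cycle minimizes cross-validated error over the trajectory", {
  d <- cachedDataset()
  X <- spectraMatrix(d, "absorbance")[1:60, ]
  y <- moisture(d)[1:60]
  res <- scarsSelect(X, y, frequencyGrid(d), scarsConfig(seed = 8))
  expect_equal(res$best_run, which.min(res$rmsecv))
  expect_identical(res$selected_vars, res$retained_sets[[res$best_run]])
  expect_equal(res$selected_frequencies,
               freqPoints(frequencyGrid(d))[res$selected_vars])
  expect_true(all(res$selected_vars >= 1 & res$selected_vars <= ncol(X)))
  # an interior optimum: fewer bands than the full spectrum, more than the
  # two-variable endpoint
  expect_lt(length(res$selected_vars), ncol(X))
  expect_gt(length(res$selected_vars), 2L)
})

test_that("the per-channel selection report carries counts, cycles and frequencies", {
  d <- cachedDataset()
  X <- spectraMatrix(d, "absorbance")[1:60, ]
  y <- moisture(d)[1:60]
  res <- scarsSelect(X, y, frequencyGrid(d),
                     scarsConfig(n_runs = 15L, seed = 9))
  tab <- selectionReport(list(absorbance = res))
  expect_equal(tab$dimension, "absorbance")
  expect_equal(tab$times, res$best_run)
  expect_equal(tab$select, length(res$selected_vars))
  expect_equal(tab$minRMSECV, res$rmsecv[res$best_run])
  expect_false(tab$degenerate)
  shown <- as.numeric(strsplit(tab$frequency_points, ", ")[[1]])
  expect_length(shown, length(res$selected_frequencies))
  expect_true(all(diff(shown) >= 0))
  # printed to 2 decimals: each entry within half a printing unit
  expect_lt(max(abs(shown - sort(res$selected_frequencies))), 0.005 + 1e-9)
})
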