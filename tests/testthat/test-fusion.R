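test_that("fused features concatenate channels in fixed order with labelled columns", {
  d <- cachedDataset()
  bands <- list(transmittance = c(0.51, 1.24),
                power = c(0.53, 0.60, 1.08),
                absorbance = c(0.54, 1.19))
  fused <- fuseFeatures(bands, d)
  expect_equal(ncol(fused), 7L)
  lab <- attr(fused, "labels")
  expect_equal(lab$dimension,
               rep(c("power", "absorbance", "transmittance"), c(3, 2, 2)))
  expect_equal(colnames(fused)[1:3],
               c("power_0.53", "power_0.60", "power_1.08"))
  # the same frequency may legitimately appear under two channels
  f2 <- fuseFeatures(list(power = 0.54, absorbance = 0.54), d)
  expect_equal(ncol(f2), 2L)
  # but not twice under one channel
  expect_error(fuseFeatures(list(power = c(0.54, 0.54)), d), "duplicate")
  expect_warning(f3 <- fuseFeatures(list(power = numeric(0),
                                         absorbance = 0.54), d), "skipped")
  expect_equal(ncol(f3), 1L)
  expect_error(suppressWarnings(
    fuseFeatures(list(power = numeric(0)), d)), "nothing to fuse")
})

test_that("the calibration-fitted normalizer standardizes calibration data and freezes for new data", {
  set.seed(61)
  Xc <- matrix(rnorm(40 * 5, mean = 3, sd = 2), 40)
  nz <- normalizeFit(Xc)
  Z <- normalizeApply(nz, Xc)
  expect_lt(max(abs(colMeans(Z))), 1e-12)
  expect_lt(max(abs(apply(Z, 2, sd) - 1)), 1e-12)
  Xp <- matrix(rnorm(10 * 5, mean = 30), 10)
  Zp <- normalizeApply(nz, Xp)
  expect_equal(Zp, sweep(sweep(Xp, 2, nz$center), 2, nz$scale, "/"))
  # constant feature: centred, scale 1, no NaN
  cst <- normalizeFit(cbind(rnorm(10), rep(5, 10)))
  expect_equal(unname(cst$scale[2]), 1)
  expect_true(all(is.finite(normalizeApply(cst, cbind(rnorm(3), rep(5, 3))))))
  mm <- normalizeFit(Xc, method = "minmax")
  Zm <- normalizeApply(mm, Xc)
  expect_equal(unname(apply(Zm, 2, range)), matrix(c(0, 1), 2, 5))
})

test_that("PCA contributions equal squared singular values over their sum", {
  set.seed(62)
  X <- matrix(rnorm(60 * 22), 60)
  pca <- pcaFit(X)
  sv <- svd(scale(X, scale = FALSE))$d
  expect_equal(pca$contributions, sv^2 / sum(sv^2), tolerance = 1e-10)
  expect_equal(sum(pca$contributions), 1, tolerance = 1e-12)
  expect_true(all(diff(pca$contributions) <= 1e-12))
  expect_equal(pca$cumulative_at_k, pca$cumulative[pca$k])
  # rank-1 data: a single component explains everything
  v <- rnorm(22)
  X1 <- outer(rnorm(30), v)
  p1 <- pcaFit(X1)
  expect_equal(p1$k, 1L)
  expect_equal(p1$contributions[1], 1, tolerance = 1e-10)
  # projection of the calibration data matches the loadings algebra
  Z <- pcaApply(pca, X)
  expect_equal(ncol(Z), pca$k)
  expect_equal(Z, sweep(X, 2, pca$center) %*%
                 pca$loadings[, seq_len(pca$k), drop = FALSE])
})

test_that("component selection takes the smallest count reaching the threshold", {
  expect_equal(selectComponents(c(0.6, 0.3, 0.1), 0.85),
               list(k = 2L, cumulative = 0.9))
  expect_equal(selectComponents(1.0, 0.95), list(k = 1L, cumulative = 1.0))
  u <- rep(1 / 22, 22)
  expect_equal(selectComponents(u, 0.95)$k, 21L)
  expect_error(selectComponents(c(0.3, 0.4), 0.5), "non-increasing")
  expect_error(selectComponents(c(0.9, 0.3), 0.5), "at most 1")
  expect_error(selectComponents(c(0.5, 0.2), 0.95), "never reaches")
  expect_error(selectComponents(c(0.5, 0.2), 0), "threshold")
})

test_that("the SVR grid search is deterministic and its winner comes from the grid", {
  set.seed(63)
  Z <- matrix(rnorm(60 * 4), 60)
  y <- as.vector(sin(Z[, 1]) + Z[, 2]^2 * 0.3) + rnorm(60, 0, 0.05)
  grid <- expand.grid(gamma = c(0.1, 1), cost = c(1, 10), epsilon = 0.01)
  f1 <- svrFit(Z, y, grid = grid, cv_folds = 4)
  f2 <- svrFit(Z, y, grid = grid, cv_folds = 4)
  expect_identical(f1$best[, c("gamma", "cost", "epsilon")],
                   f2$best[, c("gamma", "cost", "epsilon")])
  expect_true(any(grid$gamma == f1$best$gamma & grid$cost == f1$best$cost))
  expect_equal(nrow(f1$search), nrow(grid))
  expect_true(all(is.finite(f1$search$cv_r)))
  expect_equal(f1$best$cv_r, max(f1$search$cv_r))
  expect_gt(cor(predict(f1$model, Z), y), 0.9)
})

test_that("the fusion model fits on calibration rows only — prediction rows cannot leak", {
  d <- cachedDataset()
  y <- moisture(d)
  bands <- list(power = c(0.53, 0.60, 1.08), absorbance = c(0.54, 1.19),
                transmittance = c(0.51, 1.24, 1.46))
  fused <- fuseFeatures(bands, d)
  sp <- spxySplit(fused, y, 60)
  fm <- fitFusionModel(fused, y, sp)
  # corrupt the prediction rows: every fitted parameter must be unchanged
  fused2 <- fused
  fused2[sp$prediction, ] <- fused2[sp$prediction, ] * 100 + 7
  attr(fused2, "labels") <- attr(fused, "labels")
  fm2 <- fitFusionModel(fused2, y, sp)
  expect_identical(fm$normalizer, fm2$normalizer)
  expect_identical(fm$pca$loadings, fm2$pca$loadings)
  expect_identical(fm$svr$best, fm2$svr$best)
  expect_identical(predict(fm, fused[sp$calibration, ]),
                   predict(fm2, fused2[sp$calibration, ]))
  ev <- fusionEvaluate(fm, fused, y)
  expect_s3_class(ev$calibration, "FitMetrics")
  expect_equal(nrow(ev$scatter), 80L)
  expect_setequal(unique(ev$scatter$set), c("calibration", "prediction"))
})
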