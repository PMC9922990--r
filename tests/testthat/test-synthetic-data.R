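test_that("moisture labels invert the gravimetric formula exactly", {
  d <- cachedDataset()
  lab <- moistureLabels(d)
  expect_equal(moistureContent(lab$m1_g, lab$m2_g), lab$moisture_pct,
               tolerance = 1e-12)
  expect_equal(nrow(lab), 80L)
  expect_equal(as.vector(table(lab$stress_level)), rep(20L, 4L))
})

test_that("simulation is bit-reproducible for a seed and leaves the caller's RNG alone", {
  set.seed(999)
  before <- .Random.seed
  d1 <- simulateDataset(simConfig(seed = 5))
  expect_identical(.Random.seed, before)
  d2 <- simulateDataset(simConfig(seed = 5))
  expect_identical(spectraMatrix(d1, "power"), spectraMatrix(d2, "power"))
  expect_identical(moisture(d1), moisture(d2))
  d3 <- simulateDataset(simConfig(seed = 6))
  expect_false(identical(moisture(d1), moisture(d3)))
})

test_that("wetter leaves absorb more, transmit less, and register more power at every frequency", {
  d <- cachedDataset()
  w <- moisture(d)
  corAll <- function(ch) apply(spectraMatrix(d, ch), 2L, cor, y = w)
  expect_true(all(corAll("absorbance") > 0))
  expect_true(all(corAll("transmittance") < 0))
  expect_true(all(corAll("power") > 0))
})

test_that("the noiseless generator reproduces the affine absorbance core exactly", {
  cfg <- noiselessConfig(simConfig(seed = 2, leaves_per_level = 2L))
  d <- simulateDataset(cfg)
  co <- simCoefficients(cfg)
  A <- spectraMatrix(d, "absorbance")
  w <- moisture(d)
  for (i in seq_along(w))
    expect_lt(max(abs(A[i, ] - (co$a0 + co$beta * w[i]))), 1e-12)
  expect_equal(unname(spectraMatrix(d, "transmittance")),
               unname(10^(-A)), tolerance = 1e-12)
  expect_equal(w, setNames(rep(cfg$moisture_means, each = 2L), names(w)))
})

test_that("planted mode confines moisture signal to the designated columns", {
  pb <- plantedBandConfig(seed = 3)
  cfg0 <- noiselessConfig(pb$config)
  d <- simulateDataset(cfg0)
  A <- spectraMatrix(d, "absorbance")
  spread <- apply(A, 2L, function(col) diff(range(col)))
  expect_true(all(spread[pb$bands] > 0.1))
  expect_true(all(spread[-pb$bands] < 1e-12))
  # under benchmark noise, off-support columns are exchangeable: no
  # common-mode structure, so inter-column correlations hover near zero
  dn <- simulateDataset(pb$config)
  An <- spectraMatrix(dn, "absorbance")
  off <- setdiff(seq_len(ncol(An)), pb$bands)[1:40]
  cc <- cor(An[, off])
  expect_lt(max(abs(cc[upper.tri(cc)])), 0.5)
})

test_that("replicate scan averaging shrinks scan-level noise", {
  base <- list(seed = 11, leaves_per_level = 10L, n_levels = 1L,
               irrigation_fractions = 0.5, moisture_means = 200)
  one <- do.call(simConfig, c(base, scans_per_leaf = 1L))
  many <- do.call(simConfig, c(base, scans_per_leaf = 10L))
  # isolate the scan tier: disable leaf-level effects
  for (nm in c("thickness_sd", "baseline_offset_sd", "baseline_tilt_sd",
               "moisture_sd", "power_leaf_sd"))
    one[[nm]] <- many[[nm]] <- 0
  resid <- function(cfg) {
    A <- spectraMatrix(simulateDataset(cfg), "absorbance")
    co <- simCoefficients(cfg)
    sd(sweep(A, 2L, co$a0 + co$beta * 200))
  }
  expect_gt(resid(one), 2 * resid(many))
})
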