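test_that("gravimetric moisture arithmetic and its failure modes", {
  expect_equal(moistureContent(2, 1), 100)
  expect_equal(moistureContent(3.6, 0.9), 300)
  expect_equal(moistureContent(c(1.5, 1), c(1, 1)), c(50, 0))
  expect_error(moistureContent(1, 0), "positive")
  expect_error(moistureContent(0.8, 1), "below dry mass")
  expect_error(moistureContent(NA, 1), "finite")
})

test_that("replicate averaging returns the columnwise mean spectrum", {
  scans <- rbind(c(1, 2, 3), c(3, 4, 5))
  expect_equal(averageReplicates(scans), c(2, 3, 4))
  expect_equal(averageReplicates(c(1, 2, 3)), c(1, 2, 3))
  expect_error(averageReplicates(rbind(c(1, NA))), "finite")
})

test_that("smoothing attenuates high-frequency noise but not the underlying curve", {
  set.seed(10)
  f <- seq(0, 1, length.out = 264)
  clean <- sin(2 * pi * f)
  noisy <- clean + rnorm(264, 0, 0.1)
  sm <- sgSmooth(noisy, window = 9)
  expect_lt(sd(sm - clean), 0.6 * sd(noisy - clean))
  # row-wise matrix smoothing agrees with vector smoothing
  M <- rbind(noisy, clean)
  expect_equal(sgSmooth(M, 9)[1, ], sm)
  expect_error(sgSmooth(noisy, window = 4), "odd")
  expect_error(sgSmooth(noisy, window = 3, polyorder = 3), "exceed polyorder")
  expect_error(sgSmooth(noisy[1:3], window = 5), "shorter")
})

test_that("smoothing a dataset preserves length, channels and the transmittance range", {
  d <- cachedDataset()
  sm <- smoothSpectra(d, window = 11)
  expect_s4_class(sm, "THzSpectra")
  expect_equal(dim(sm), dim(d))
  tr <- spectraMatrix(sm, "transmittance")
  expect_true(all(tr > 0 & tr <= 1))
  expect_true(all(spectraMatrix(sm, "power") >= 0))
  # smoothing changes values but not the moisture labels
  expect_identical(moisture(sm), moisture(d))
  expect_false(identical(spectraMatrix(sm, "power"),
                         spectraMatrix(d, "power")))
})

test_that("the window study tabulates every candidate and picks the best calibration fit", {
  d <- cachedDataset()
  res <- selectSgWindow(spectraMatrix(d, "power"), moisture(d))
  expect_equal(res$table$window, c(5L, 7L, 9L, 11L))
  expect_true(all(is.finite(res$table$Rc)))
  expect_equal(res$window, res$table$window[which.max(res$table$Rc)])
  # an injected downstream with equal scores ties to the smaller window
  flat <- function(X, y) list(Rc = 0.5, RMSEC = 1)
  expect_equal(selectSgWindow(spectraMatrix(d, "power"), moisture(d),
                              downstream = flat)$window, 5L)
})
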