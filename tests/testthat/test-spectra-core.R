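test_that("transmittance from power stays in (0, 1], clipping overshoot with a warning", {
  ref <- c(10, 10, 10)
  expect_warning(tr <- powerToTransmittance(c(5, 12, 10), ref),
                 "clipped to 1")
  expect_equal(tr, c(0.5, 1, 1))
  tr0 <- powerToTransmittance(c(0, 5, 10), ref)
  expect_true(all(tr0 > 0 & tr0 <= 1))
  expect_error(powerToTransmittance(c(1, 2), ref), "different grids")
  expect_error(powerToTransmittance(c(1, -1, 1), ref), "non-negative")
  expect_error(powerToTransmittance(c(1, 1, 1), c(10, 0, 10)),
               "strictly positive")
})

test_that("absorbance and transmittance are exact inverses", {
  Tr <- c(1, 0.5, 0.1, 0.01, 1e-6)
  A <- transmittanceToAbsorbance(Tr)
  expect_equal(A[1], 0)
  expect_equal(A[3], 1)
  expect_lt(max(abs(absorbanceToTransmittance(A) - Tr)), 1e-12)
  A2 <- c(0, 0.3, 2.5)
  expect_lt(max(abs(transmittanceToAbsorbance(absorbanceToTransmittance(A2)) -
                      A2)), 1e-12)
  expect_error(transmittanceToAbsorbance(c(0.5, 0)), "strictly positive")
  expect_error(transmittanceToAbsorbance(1.5), "must not exceed 1")
  expect_error(absorbanceToTransmittance(-0.1), "non-negative")
})

test_that("spectra tables survive a write/read round trip losslessly", {
  g <- frequencyGrid(0.5, 0.6, 0.0038)
  set.seed(3)
  vals <- matrix(rexp(5 * length(g)), 5,
                 dimnames = list(sprintf("L1_%02d", 1:5), NULL))
  path <- withr::local_tempfile(fileext = ".csv")
  writeSpectra(vals, g, path)
  back <- readSpectra(path, "power")
  expect_equal(back$sample_ids, rownames(vals))
  expect_equal(unname(back$values), unname(vals), tolerance = 1e-11)
  expect_equal(freqPoints(back$grid), freqPoints(g), tolerance = 1e-9)
})

test_that("malformed spectra files are rejected with the offending location named", {
  path <- withr::local_tempfile(fileext = ".csv")
  writeLines(c("sample_id,f_0.5000,f_0.5038,f_0.5000",
               "a,1,2,3"), path)
  expect_error(readSpectra(path), "not strictly increasing.*f_0.5000")
  writeLines(c("sample_id,f_0.5000,f_0.5038,f_0.6000",
               "a,1,2,3"), path)
  expect_error(readSpectra(path), "not uniformly spaced.*f_0.6000")
  writeLines(c("sample_id,f_0.5000,f_0.5038,f_0.5076",
               "a,1,,3"), path)
  expect_error(readSpectra(path), "row 1 \\(sample 'a'\\).*f_0.5038")
})

test_that("frequencies resolve to the nearest grid column within half a step", {
  g <- frequencyGrid()
  expect_equal(matchFrequencies(c(0.5, 0.53, 1.45), g),
               c(1L, 9L, 251L))
  expect_equal(freqPoints(g)[9], 0.5304, tolerance = 1e-12)
  expect_error(matchFrequencies(2.0, g), "not on the grid")
})

test_that("a dataset of all three channels round-trips through CSV files", {
  d <- cachedDataset()
  dir <- withr::local_tempdir()
  writeDataset(d, dir)
  expect_true(all(file.exists(file.path(
    dir, c("power.csv", "absorbance.csv", "transmittance.csv",
           "labels.csv")))))
  back <- readDataset(dir)
  expect_s4_class(back, "THzSpectra")
  expect_equal(moisture(back), moisture(d), tolerance = 1e-10)
  expect_equal(spectraMatrix(back, "absorbance"),
               spectraMatrix(d, "absorbance"), tolerance = 1e-10)
})

test_that("the spectra container enforces channel value contracts", {
  g <- frequencyGrid(0.5, 0.52, 0.0038)
  set.seed(4)
  ok <- matrix(runif(3 * length(g), 0.1, 0.9), 3)
  expect_s4_class(THzSpectra(list(transmittance = ok), g), "THzSpectra")
  bad <- ok; bad[1, 1] <- 1.5
  expect_error(THzSpectra(list(transmittance = bad), g), "\\(0, 1\\]")
  bad2 <- ok; bad2[2, 2] <- -0.1
  expect_error(THzSpectra(list(absorbance = bad2), g), "non-negative")
  bad3 <- ok; bad3[3, 3] <- NA
  expect_error(THzSpectra(list(power = bad3), g), "non-finite")
  expect_error(THzSpectra(list(intensity = ok), g), "assay names")
})
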