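test_that("dropout-free inference collapses the predictive distribution", {
  fit <- fxMicroModel()
  x <- fxMicroDataset()@input[, , 1]
  um <- mcDropoutPredict(fit, x, n = 3, seed = 7, dropoutRate = 0)
  expect_true(all(um@std == 0))
  expect_equal(um@mean, predictImage(fit, x), tolerance = 1e-12)
  expect_error(mcDropoutPredict(fit, x, n = 1), "n must be")
})

test_that("forced identical masks give zero spread; fresh masks do not", {
  fit <- fxMicroModel()
  x <- fxMicroDataset()@input[, , 2]
  same <- mcDropoutPredict(fit, x, n = 2, seeds = c(5L, 5L))
  expect_true(all(same@std == 0))
  um <- mcDropoutPredict(fit, x, n = 20, seed = 3)
  expect_gt(max(um@std), 0)
  expect_gt(stats::sd(um@std), 0)  # non-constant uncertainty map
})

test_that("the predictive std is invariant to sample order", {
  fit <- fxMicroModel()
  x <- fxMicroDataset()@input[, , 3]
  seeds <- c(11L, 23L, 35L, 47L, 59L)
  a <- mcDropoutPredict(fit, x, n = 5, seeds = seeds)
  b <- mcDropoutPredict(fit, x, n = 5, seeds = rev(seeds))
  expect_equal(a@std, b@std, tolerance = 1e-12)
  expect_equal(a@mean, b@mean, tolerance = 1e-12)
})

test_that("acquisition-noise variability maps behave as specified", {
  fit <- fxMicroModel()
  cfg <- fxMicroPhantomConfig()
  probe <- fxMicroProbe()
  ph <- generateBranchingPhantom(`slot<-`(cfg, "seed", value = 77L))
  grid <- reconGrid(c(0, cfg@zTopMm + cfg@fieldSizeMm / 2), cfg@patchSizeMm,
                    80)
  clean <- simulateRF(ph, probe)
  # noiseless duplicates -> identically zero std
  nv0 <- noiseVariabilityMap(fit, list(clean, clean, clean), grid, probe)
  expect_true(all(nv0@std == 0))
  # noisy acquisitions: std grows with the noise level
  acq <- function(snr, n) lapply(seq_len(n), function(k)
    addNoise(clean, noiseConfig(snr, seed = k), probe = probe))
  hi <- noiseVariabilityMap(fit, acq(60, 8), grid, probe)
  lo <- noiseVariabilityMap(fit, acq(600, 8), grid, probe)
  expect_gt(mean(hi@std), mean(lo@std))
  # the mean map approaches the noise-free prediction
  det <- predictImage(fit, values(dasMBF(clean, grid, probe)))
  expect_lt(mean(abs(hi@mean - det)), 3 * mean(hi@std) + 1e-8)
})

test_that("absolute-error maps have their arithmetic identities", {
  t <- maxNormalize(fxMicroDataset()@target[, , 1])
  expect_true(all(values(absErrorMap(t, t)) == 0))
  z <- matrix(0, nrow(t), ncol(t))
  expect_equal(values(absErrorMap(z, t)), t)
  p <- maxNormalize(matrix(runif(length(t)), nrow(t)))
  expect_lte(max(values(absErrorMap(p, t))), 1)
  expect_error(absErrorMap(matrix(0, 4, 4), t), "shape")
})

test_that("calibration statistics detect matched and unmatched maps", {
  set.seed(9)
  e <- matrix(runif(100 * 100), 100)
  # error map equal to the std map: perfect rank agreement
  cal <- uncertaintyCalibration(e, e)
  expect_equal(cal$spearman, 1.0)
  # independent maps: negligible rank correlation at 1e4 pixels
  r <- matrix(runif(100 * 100), 100)
  cal2 <- uncertaintyCalibration(e, r)
  expect_lt(abs(cal2$spearman), 0.1)
  # constant maps are reported as undefined, not errored
  cal3 <- uncertaintyCalibration(matrix(1, 10, 10), matrix(runif(100), 10))
  expect_true(is.na(cal3$spearman))
  expect_match(cal3$note, "constant")
})
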