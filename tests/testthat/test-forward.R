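test_that("impulse response is band-limited, zero-mean, centred at fc", {
  probe <- fxProbe()
  g <- impulseResponse(probe)
  expect_lt(abs(sum(g)), 1e-12)
  expect_equal(max(abs(g)), 1)
  n <- 8192
  G <- Mod(stats::fft(c(as.numeric(g), numeric(n - length(g)))))
  f <- (0:(n - 1)) * probe@fsMHz / n
  half <- seq_len(n / 2)
  expect_lt(abs(f[which.max(G[half])] - 15.6), probe@fsMHz / length(g))
  # -6 dB (half-amplitude) fractional width within 10% of the nominal 0.6
  i6 <- which(G[half] >= max(G) / 2)
  bw <- (f[max(i6)] - f[min(i6)]) / 15.6
  expect_lt(abs(bw - 0.6) / 0.6, 0.10)
  bad <- linearProbe()
  bad@fsMHz <- 20
  expect_error(impulseResponse(bad), "sampling criterion")
})

test_that("a point source arrives at t = r/c (5.0 us at 7.5 mm depth)", {
  probe <- fxProbe()
  rf <- pointSourceResponse(probe, c(0, 7.5))
  centre <- which.min(abs(probe@positions[, 1]))
  env <- abs(signals(rf)[centre, ])
  tPeak <- (which.max(env) - 1) / probe@fsMHz
  expect_lt(abs(tPeak - 5.0), 2 / probe@fsMHz)
  expect_error(pointSourceResponse(probe, c(0, -1)), "behind")
  expect_true(all(signals(pointSourceResponse(probe, c(0, 5), amplitude = 0))
                  == 0))
})

test_that("on-axis geometry gives exactly mirror-symmetric RF", {
  s <- signals(pointSourceResponse(fxProbe(), c(0, 5)))
  expect_lt(max(abs(s - s[nrow(s):1, ])), 1e-12)
})

test_that("RF synthesis is linear in the object", {
  probe <- fxSmallProbe()
  v <- matrix(0, 20, 20)
  mk <- function(v) absorptionMap(v, 80, c(-0.8, 4))
  v1 <- v; v1[5, 7] <- 0.8
  v2 <- v; v2[15, 12] <- 0.5
  r1 <- signals(simulateRF(mk(v1), probe))
  r2 <- signals(simulateRF(mk(v2), probe))
  r12 <- signals(simulateRF(mk(v1 + v2), probe))
  expect_equal(r12, r1 + r2, tolerance = 1e-12)
  expect_equal(signals(simulateRF(mk(3 * v1), probe)), 3 * r1,
               tolerance = 1e-12)
  expect_true(all(signals(simulateRF(mk(v), probe)) == 0))
})

test_that("no RF energy arrives before the closest possible echo", {
  probe <- fxProbe()
  g <- impulseResponse(probe)
  halfDur <- (attr(g, "center") - 1) / probe@fsMHz
  src <- c(1.2, 6)
  rf <- signals(pointSourceResponse(probe, src))
  rmin <- min(sqrt((probe@positions[, 1] - src[1])^2 + src[2]^2))
  sFirst <- floor((rmin / 1.5 - halfDur) * probe@fsMHz)  # c = 1.5 mm/us
  expect_true(all(rf[, seq_len(sFirst)] == 0))
})

test_that("the system matrix reproduces the forward simulation", {
  probe <- fxSmallProbe()
  grid <- reconGrid(c(0, 4.56), 16 * 0.08, 80)
  S <- buildSystemMatrix(probe, grid)
  # column = vectorized point response at that pixel
  j <- 5L * 16L + 9L  # 0-based col-major (z, x) pixel index -> 1-based col
  px <- grid@xMm[6]; pz <- grid@zMm[10]
  colResp <- as.numeric(signals(pointSourceResponse(probe, c(px, pz))))
  expect_lt(max(abs(S@entries[, j + 1] - colResp)), 1e-12)
  # A vec(delta_j) = column j
  d <- numeric(16 * 16); d[j + 1] <- 1
  expect_lt(max(abs(as.numeric(S@entries %*% d) - colResp)), 1e-12)
  # random object consistency
  set.seed(3)
  v <- matrix(runif(16 * 16), 16, 16) * (matrix(runif(16 * 16), 16) > 0.7)
  obj <- absorptionMap(v, 80, c(grid@xMm[1], grid@zMm[1]))
  y1 <- as.numeric(S@entries %*% as.numeric(v))
  y2 <- as.numeric(signals(simulateRF(obj, probe)))
  expect_lt(sqrt(sum((y1 - y2)^2)) / sqrt(sum(y2^2)), 1e-10)
  expect_error(buildSystemMatrix(probe, reconGrid(c(0, 5), 10, 40),
                                 maxEntries = 1e6), "too large")
})

test_that("additive noise is calibrated to the horizontal-structure SNR", {
  probe <- fxSmallProbe()
  calib <- calibrationAmplitude(probe)
  expect_gt(calib, 0)
  rf <- rfData(matrix(0, nrow(probe@positions), probe@nSamples), probe@fsMHz)
  ratios <- vapply(1:10, function(s) {
    noisy <- addNoise(rf, noiseConfig(60, seed = s), calibration = calib)
    calib / stats::sd(signals(noisy))
  }, numeric(1))
  expect_lt(abs(mean(ratios) - 60) / 60, 0.05)
  # infinite SNR returns the input unchanged
  same <- addNoise(rf, noiseConfig(Inf), calibration = calib)
  expect_identical(signals(same), signals(rf))
  # different seeds give different realizations
  n1 <- addNoise(rf, noiseConfig(60, seed = 1), calibration = calib)
  n2 <- addNoise(rf, noiseConfig(60, seed = 2), calibration = calib)
  expect_false(identical(signals(n1), signals(n2)))
  expect_error(addNoise(rf, noiseConfig(60)), "calibration")
})
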