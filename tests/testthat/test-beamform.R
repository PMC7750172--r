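test_that("beamformers are linear and map zero RF to zero images", {
  probe <- fxSmallProbe()
  grid <- reconGrid(c(0, 4.56), 2.56, 80)
  z <- rfData(matrix(0, nrow(probe@positions), probe@nSamples), probe@fsMHz)
  expect_true(all(values(dasMBF(z, grid, probe)) == 0))
  expect_true(all(values(dasDMBF(z, grid, probe)) == 0))
  r1 <- pointSourceResponse(probe, c(0.4, 4.2))
  r2 <- pointSourceResponse(probe, c(-0.6, 5.0))
  sum12 <- rfData(signals(r1) + signals(r2), probe@fsMHz)
  m12 <- values(dasMBF(sum12, grid, probe))
  expect_equal(m12, values(dasMBF(r1, grid, probe)) +
                 values(dasMBF(r2, grid, probe)), tolerance = 1e-12)
})

test_that("a point source focuses within one pixel in mBF and dmBF", {
  probe <- fxProbe()
  grid <- reconGrid(c(0, 4.56), 5.12, 40)
  src <- c(grid@xMm[70], grid@zMm[60])
  rf <- pointSourceResponse(probe, src)
  for (img in list(dasMBF(rf, grid, probe), dasDMBF(rf, grid, probe))) {
    ix <- which(abs(values(img)) == max(abs(values(img))), arr.ind = TRUE)
    expect_lte(abs(ix[1] - 60), 1)
    expect_lte(abs(ix[2] - 70), 1)
  }
})

test_that("the envelope dominates the modulated image pixel-wise", {
  probe <- fxProbe()
  grid <- reconGrid(c(0, 15.06), 5.12, 80)
  ph <- generateBranchingPhantom(fxBenchPhantomConfig())
  rf <- simulateRF(ph, probe)
  m <- values(dasMBF(rf, grid, probe))
  d <- values(dasDMBF(rf, grid, probe))
  # dmBF >= |mBF| - eps, eps = interpolation tolerance
  expect_true(all(d >= abs(m) - 1e-9 * max(d)))
})

test_that("dmBF peaks track lateral source shifts (translation equivariance)", {
  probe <- fxProbe()
  grid <- reconGrid(c(0, 4.56), 5.12, 80)
  base <- c(grid@xMm[24], grid@zMm[32])
  for (k in c(4L, 9L)) {
    rf1 <- pointSourceResponse(probe, base)
    rf2 <- pointSourceResponse(probe, c(grid@xMm[24 + k], base[2]))
    i1 <- which(values(dasDMBF(rf1, grid, probe)) ==
                  max(values(dasDMBF(rf1, grid, probe))), arr.ind = TRUE)
    i2 <- which(values(dasDMBF(rf2, grid, probe)) ==
                  max(values(dasDMBF(rf2, grid, probe))), arr.ind = TRUE)
    expect_lte(abs((i2[2] - i1[2]) - k), 1)
    expect_lte(abs(i2[1] - i1[1]), 1)
  }
})

test_that("the limited-view artefact appears with a linear array and vanishes with a ring", {
  grid <- reconGrid(c(0, 4.56), 5.12, 80)
  lin <- visibilityDemo(fxProbe(), grid)
  expect_gt(lin$horizontalEnergy, 0)
  expect_lt(lin$ratio, 0.2)
  ring <- ringProbe(nElements = 256L, radiusMm = 10, centerMm = c(0, 4.56))
  omni <- visibilityDemo(ring, grid)
  expect_lt(abs(omni$ratio - 1), 0.3)
  # horizontal-only phantom leaves energy in the horizontal support
  vd <- visibilityDemo(fxProbe(), grid, barLengthMm = 2.0, barWidthMm = 0.24)
  expect_gt(vd$horizontalEnergy, 0)
})
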