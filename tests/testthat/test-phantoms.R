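test_that("phantom generation is a pure function of config and seed", {
  cfg <- phantomConfig(seed = 11L)
  a <- generateBranchingPhantom(cfg)
  b <- generateBranchingPhantom(cfg)
  expect_identical(values(a), values(b))
  expect_false(identical(values(a),
                         values(generateBranchingPhantom(phantomConfig(seed = 12L)))))
})

test_that("degenerate and empty configurations are handled", {
  expect_error(generateBranchingPhantom(
    phantomConfig(fieldSizeMm = 0.4, patchSizeMm = 0.4)), "degenerate")
  z <- generateBranchingPhantom(phantomConfig(nPrimaryBranches = 0L))
  expect_true(all(values(z) == 0))
})

test_that("default phantoms have plausible foreground coverage and range", {
  fr <- vapply(1:15, function(s)
    mean(values(generateBranchingPhantom(phantomConfig(seed = s))) > 0),
    numeric(1))
  expect_true(all(fr >= 0.02 & fr <= 0.25))
  p <- values(generateBranchingPhantom(phantomConfig(seed = 2)))
  expect_gte(min(p), 0)
  expect_lte(max(p), 1)
})

test_that("phantoms contain near-vertical structure (the limited-view case)", {
  for (s in c(1, 5, 9, 13)) {
    o <- structureTensorOrientations(
      generateBranchingPhantom(phantomConfig(seed = s)))
    vertFrac <- sum(o$weight[o$angleDeg < 10]) / sum(o$weight)
    expect_gt(vertFrac, 0.02)
  }
})

test_that("augmentations preserve grid, range, and known identities", {
  img <- generateBranchingPhantom(phantomConfig(seed = 4))
  r0 <- augmentMap(img, list(type = "rotation", angle = 0))
  expect_identical(values(r0), values(img))
  m2 <- augmentMap(augmentMap(img, list(type = "mirror", axis = "horizontal")),
                   list(type = "mirror", axis = "horizontal"))
  expect_identical(values(m2), values(img))
  sh <- augmentMap(img, list(type = "shear", axis = "horizontal",
                             factor = 0.2))
  expect_identical(dim(values(sh)), dim(values(img)))
  expect_gte(min(values(sh)), 0)
  expect_lte(max(values(sh)), 1)
  expect_error(augmentMap(img, list(type = "swirl")), "unknown transform")
})

test_that("90-degree rotation maps a bright pixel to the rotated index", {
  n <- 64L
  v <- matrix(0, n, n)
  r <- 11L; c <- 40L
  v[r, c] <- 1
  img <- absorptionMap(v, 40, c(0, 0))
  rot <- values(augmentMap(img, list(type = "rotation", angle = 90)))
  # counter-clockwise quarter turn in (row, col) space: (r, c) -> (n+1-c, r)
  expect_equal(rot[n + 1L - c, r], 1)
  expect_equal(sum(rot), 1)
})

test_that("background thresholding zeroes exactly the sub-threshold pixels", {
  ramp <- matrix(seq(0, 1, length.out = 64 * 64), 64, 64)
  img <- absorptionMap(ramp, 40, c(0, 0))
  expect_identical(values(thresholdBackground(img, 0)), ramp)
  expect_true(all(values(thresholdBackground(img, max(ramp) + 1)) == 0))
  th <- values(thresholdBackground(img, 0.5))
  expect_equal(sum(th > 0), sum(ramp >= 0.5))
  expect_identical(th[ramp >= 0.5], ramp[ramp >= 0.5])
})

test_that("patch extraction preserves pitch and matches direct indexing", {
  cfg <- phantomConfig(seed = 6)
  img <- generateBranchingPhantom(cfg)
  whole <- extractPatch(img, c(0, cfg@zTopMm + 5), 10)
  expect_identical(values(whole), values(img))
  patch <- extractPatch(img, c(0, cfg@zTopMm + 5), 5.12)
  expect_identical(dim(values(patch)), c(128L, 128L))
  expect_equal(pixelPitch(patch), 40)
  # two disjoint patches equal directly indexed sub-arrays
  p1 <- extractPatch(img, c(-2, cfg@zTopMm + 3), 2)
  i0 <- round((-2 - 1 - img@originMm[1]) / 0.04) + 1
  j0 <- round((cfg@zTopMm + 3 - 1 - img@originMm[2]) / 0.04) + 1
  expect_identical(values(p1), values(img)[j0:(j0 + 49), i0:(i0 + 49)])
  expect_error(extractPatch(img, c(4.9, cfg@zTopMm + 5), 5.12),
               "out of bounds")
})

test_that("dataset pairs are seeded, shaped and split consistently", {
  cfg <- fxMicroPhantomConfig()
  probe <- fxMicroProbe()
  d1 <- buildDataset(6, cfg, probe, seed = 7, split = c(4L, 1L, 1L),
                     reconPitchUm = 80)
  expect_identical(dim(d1@input), c(32L, 32L, 6L))
  expect_identical(dim(d1@target), dim(d1@input))
  expect_identical(table(factor(d1@split,
                                c("train", "val", "test"))),
                   table(factor(rep(c("train", "val", "test"),
                                    c(4, 1, 1)),
                                c("train", "val", "test"))))
  # rerun with the same master seed: bit-identical targets and inputs
  d2 <- buildDataset(6, cfg, probe, seed = 7, split = c(4L, 1L, 1L),
                     reconPitchUm = 80)
  expect_identical(d1@target, d2@target)
  expect_identical(d1@input, d2@input)
  expect_identical(d1@pairSeeds, d2@pairSeeds)
  # split partition is disjoint and exhaustive by construction
  expect_equal(length(d1@split), 6L)
  expect_error(buildDataset(6, cfg, probe, seed = 7, split = c(4L, 1L, 2L)),
               "sum")
  # single-pair dataset
  d3 <- buildDataset(1, cfg, probe, seed = 3, split = c(1L, 0L, 0L),
                     reconPitchUm = 80)
  expect_identical(dim(d3@input)[3], 1L)
})

test_that("datasets and images round-trip through serialization", {
  ds <- fxMicroDataset()
  f <- tempfile(fileext = ".rds")
  writeDataset(ds, f)
  back <- readDataset(f)
  expect_identical(back@input, ds@input)
  expect_identical(back@split, ds@split)
  unlink(f)
  if (requireNamespace("tiff", quietly = TRUE)) {
    tf <- tempfile(fileext = ".tiff")
    exportTiff(ds@target[, , 1], tf)
    expect_true(file.exists(tf))
    v <- tiff::readTIFF(tf)
    expect_equal(dim(v), dim(ds@target[, , 1]))
    unlink(tf)
  }
})
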