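test_that("NCC is exact on identity and invariant to affine intensity maps", {
  p <- fxRefRaster()
  expect_equal(nccScore(p, p), 1.0)
  expect_equal(nccScore(0.5 * p + 0.2, p), 1.0, tolerance = 1e-12)
  expect_equal(nccScore(p, 2 * p - 0.1), 1.0, tolerance = 1e-12)
  expect_error(nccScore(matrix(1, 8, 8), matrix(runif(64), 8)), "constant")
})

test_that("the NCC search window absorbs small shifts but not large ones", {
  p <- fxRefRaster()
  shift <- function(k) rbind(matrix(0, k, ncol(p)), p[1:(nrow(p) - k), ])
  expect_equal(nccScore(shift(2), p), 1.0, tolerance = 1e-6)
  expect_lt(nccScore(shift(10), p), 1.0 - 1e-3)
  # window 0 reduces to zero-lag Pearson
  expect_equal(nccScore(p, p, maxShift = 0L),
               stats::cor(as.numeric(p), as.numeric(p)))
})

test_that("sSSIM removes global scale and shift, and decreases with noise", {
  p <- fxRefRaster()
  expect_equal(sssimScore(p, p), 1.0, tolerance = 1e-9)
  expect_equal(sssimScore(3 * p - 0.4, p), 1.0, tolerance = 1e-9)
  set.seed(11)
  noisy <- function(s) p + matrix(rnorm(length(p), 0, s), nrow(p))
  s1 <- sssimScore(noisy(0.05), p)
  s2 <- sssimScore(noisy(0.15), p)
  s3 <- sssimScore(noisy(0.4), p)
  expect_true(s1 > s2 && s2 > s3)
  expect_true(s1 < 1 && s3 > 0)
  expect_error(sssimScore(matrix(0.3, 16, 16), matrix(runif(256), 16)),
               "zero-variance")
})

test_that("set evaluation aggregates per-pair scores faithfully", {
  p <- fxRefRaster()
  rpt <- evaluateSet(list(list(p, p)))
  expect_equal(rpt@meanNcc, 1.0)
  expect_equal(rpt@meanSssim, 1.0, tolerance = 1e-9)
  q <- p + matrix(rnorm(length(p), 0, 0.1), nrow(p))
  dup <- evaluateSet(list(list(q, p), list(q, p), list(q, p)))
  expect_equal(dup@sdNcc, 0)
  expect_equal(dup@sdSssim, 0)
  expect_equal(dup@meanNcc, dup@perPair$ncc[1])
  # aggregates match direct recomputation from per-pair values
  mix <- evaluateSet(list(list(q, p), list(p, p)))
  expect_equal(mix@meanSssim, mean(mix@perPair$sssim))
  expect_equal(mix@sdNcc, stats::sd(mix@perPair$ncc))
  # failing pairs are reported, not dropped
  bad <- evaluateSet(list(list(p, p), list(matrix(1, nrow(p), ncol(p)), p)))
  expect_equal(nrow(bad@perPair), 2L)
  expect_true(is.na(bad@perPair$ncc[2]))
  expect_identical(attr(bad, "failed"), 2L)
  expect_error(evaluateSet(list()), "empty")
})

test_that("registration recovers known similarity transforms", {
  ref <- fxRefRaster()
  # identity
  r0 <- registerSimilarity(ref, ref)
  expect_equal(r0$correlation, 1.0, tolerance = 1e-6)
  expect_lt(abs(r0$transform@rotationDeg), 0.5)
  expect_lt(max(abs(r0$transform@translationPx)), 0.5)
  expect_lt(abs(r0$transform@scale - 1), 0.01)
  # pure translation by (drow = 5, dcol = -3): recovered as its inverse
  mv <- pavision:::.warpAffineShift(ref, diag(2), c(5, -3))
  r1 <- registerSimilarity(ref, mv)
  expect_lt(abs(r1$transform@translationPx[2] + 5), 0.5)
  expect_lt(abs(r1$transform@translationPx[1] - 3), 0.5)
  # rotation 7 deg + scale 1.05 (applied as a sampling warp): the recovered
  # transform is the inverse warp within 0.5 deg / 1% scale
  A <- pavision:::.rotationMatrix(7 * pi / 180) / 1.05
  mv2 <- pavision:::.warpAffineShift(ref, A, c(0, 0))
  r2 <- registerSimilarity(ref, mv2)
  expect_lt(abs(r2$transform@rotationDeg + 7), 0.5)
  expect_lt(abs(r2$transform@scale - 1 / 1.05), 0.01)
  expect_gt(r2$correlation, 0.9)
})
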