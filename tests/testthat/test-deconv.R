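test_that("FISTA solves trivial systems exactly", {
  set.seed(1)
  y <- rnorm(32)
  A <- diag(32)
  out <- fistaL2(y, A, deconvConfig(alpha = 0, nIter = 500L, tol = 1e-12))
  expect_lt(max(abs(out$x - y)), 1e-6)
  # overwhelming penalty drives the solution to zero
  big <- fistaL2(y, A, deconvConfig(alpha = 1e9, nIter = 50L))
  expect_lt(sqrt(sum(big$x^2)), 1e-6 * sqrt(sum(y^2)))
  expect_error(fistaL2(c(y, NA), rbind(A, A[1, ]), deconvConfig()),
               "non-finite")
})

test_that("FISTA matches the ridge closed form on a random system", {
  set.seed(7)
  A <- matrix(rnorm(200 * 64), 200, 64)
  y <- A %*% rnorm(64) + rnorm(200, 0, 0.1)
  xr <- ridgeClosedForm(y, A, 0.1)
  xf <- fistaL2(y, A, deconvConfig(alpha = 0.1, nIter = 3000L, tol = 1e-12))
  expect_lt(sqrt(sum((xf$x - xr)^2)) / sqrt(sum(xr^2)), 1e-5)
})

test_that("the ridge oracle has its closed-form properties", {
  set.seed(2)
  # orthonormal columns, alpha = 0 -> A'y
  Q <- qr.Q(qr(matrix(rnorm(80 * 20), 80, 20)))
  y <- rnorm(80)
  expect_equal(ridgeClosedForm(y, Q, 0), as.numeric(crossprod(Q, y)),
               tolerance = 1e-10)
  # consistent noiseless system, alpha = 0, full column rank -> exact x0
  A <- matrix(rnorm(60 * 25), 60, 25)
  x0 <- rnorm(25)
  expect_equal(ridgeClosedForm(A %*% x0, A, 0), x0, tolerance = 1e-8)
  expect_error(ridgeClosedForm(rnorm(10), matrix(1, 10, 4), 0), "singular")
})

test_that("the objective decreases below trivial reference solutions", {
  set.seed(5)
  A <- matrix(rnorm(120 * 40), 120, 40)
  y <- A %*% rnorm(40) + rnorm(120, 0, 0.2)
  cfg <- deconvConfig(alpha = 0.5, nIter = 400L)
  out <- fistaL2(y, A, cfg)
  objOf <- function(x) 0.5 * sum((y - A %*% x)^2) + cfg@alpha / 2 * sum(x^2)
  expect_lt(utils::tail(out$objective, 1), objOf(numeric(40)))
  # solution continuity: O(eps) response to an eps perturbation of Y
  out2 <- fistaL2(y + 1e-8, A, cfg)
  expect_lt(sqrt(sum((out2$x - out$x)^2)), 1e-4)
})

test_that("deconvolution localizes a point source on the PA grid", {
  probe <- fxSmallProbe()
  grid <- reconGrid(c(0, 4.56), 5.12, 80)
  S <- buildSystemMatrix(probe, grid)
  src <- c(grid@xMm[38], grid@zMm[25])
  rf <- pointSourceResponse(probe, src)
  sol <- fistaL2(rf, S, deconvConfig(alpha = 1, nIter = 80L))
  img <- sol$image@values
  ix <- which(img == max(img), arr.ind = TRUE)
  expect_lte(abs(ix[1] - 25), 1)
  expect_lte(abs(ix[2] - 38), 1)
  expect_s4_class(sol$image, "ReconImage")
  expect_identical(sol$image@kind, "deconv")
})
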