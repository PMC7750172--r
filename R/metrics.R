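# Evaluation metrics: normalized 2D cross-correlation with a small
# displacement search window, scaled-and-shifted SSIM, test-set aggregation
# and similarity-transform registration.

#' Normalized 2D cross-correlation score
#'
#' Pearson-normalized cross-correlation between the two images, maximized
#' over integer displacements within \code{+/- maxShift} pixels (the window
#' absorbs small registration residue; \code{maxShift = 0} reduces to the
#' zero-lag Pearson correlation). Invariant to affine intensity maps of
#' either argument.
#'
#' @param pred,truth equal-shaped matrices (or image objects), both
#'   max-normalized.
#' @param maxShift displacement search half-window in pixels.
#' @return scalar in [-1, 1].
#' @export
nccScore <- function(pred, truth, maxShift = 3L) {
  p <- .asValues(pred); t <- .asValues(truth)
  if (!all(dim(p) == dim(t))) stop("shape mismatch")
  if (stats::sd(p) == 0 || stats::sd(t) == 0)
    stop("NCC undefined for a constant image")
  best <- -1
  nr <- nrow(p); nc <- ncol(p)
  for (dr in -maxShift:maxShift) {
    for (dc in -maxShift:maxShift) {
      r1 <- max(1, 1 + dr):min(nr, nr + dr)
      r2 <- r1 - dr
      c1 <- max(1, 1 + dc):min(nc, nc + dc)
      c2 <- c1 - dc
      a <- p[r1, c1]; b <- t[r2, c2]
      if (stats::sd(a) == 0 || stats::sd(b) == 0) next
      best <- max(best, stats::cor(as.numeric(a), as.numeric(b)))
    }
  }
  best
}

#' Scaled-and-shifted structural similarity (sSSIM)
#'
#' Fits the intensity map a*pred + b minimizing the squared error to the
#' ground truth, then computes the mean SSIM between the fitted prediction
#' and the truth (Gaussian 11x11 window, standard stability constants,
#' dynamic range taken from the truth). The scale/shift fit makes the score
#' insensitive to the arbitrary intensity scale of a reconstruction.
#'
#' @param pred,truth equal-shaped matrices (or image objects).
#' @param sigma Gaussian window standard deviation (pixels).
#' @param windowSize window side length (odd).
#' @return scalar <= 1, with 1 iff a*pred + b matches the truth exactly.
#' @export
sssimScore <- function(pred, truth, sigma = 1.5, windowSize = 11L) {
  p <- .asValues(pred); t <- .asValues(truth)
  if (!all(dim(p) == dim(t))) stop("shape mismatch")
  vp <- stats::var(as.numeric(p))
  if (vp == 0) stop("sSSIM undefined for a zero-variance prediction")
  a <- stats::cov(as.numeric(p), as.numeric(t)) / vp
  b <- mean(t) - a * mean(p)
  p <- a * p + b
  L <- diff(range(t))
  if (L == 0) L <- 1
  C1 <- (0.01 * L)^2; C2 <- (0.03 * L)^2
  k <- .gaussKernel(sigma, windowSize)
  f <- function(x) .sepConv(x, k)
  mu1 <- f(p); mu2 <- f(t)
  s11 <- f(p * p) - mu1^2
  s22 <- f(t * t) - mu2^2
  s12 <- f(p * t) - mu1 * mu2
  ssim <- ((2 * mu1 * mu2 + C1) * (2 * s12 + C2)) /
    ((mu1^2 + mu2^2 + C1) * (s11 + s22 + C2))
  mean(ssim)
}

.gaussKernel <- function(sigma, n) {
  h <- (n - 1) / 2
  k <- exp(-((-h:h)^2) / (2 * sigma^2))
  k / sum(k)
}

# separable convolution with replicate padding
.sepConv <- function(x, k) {
  h <- (length(k) - 1) / 2
  padIdx <- function(n) c(rep(1, h), seq_len(n), rep(n, h))
  xp <- x[padIdx(nrow(x)), padIdx(ncol(x)), drop = FALSE]
  # rows
  out <- matrix(0, nrow(x), ncol(xp))
  for (i in seq_along(k))
    out <- out + k[i] * xp[i:(i + nrow(x) - 1), , drop = FALSE]
  res <- matrix(0, nrow(x), ncol(x))
  for (i in seq_along(k))
    res <- res + k[i] * out[, i:(i + ncol(x) - 1), drop = FALSE]
  res
}

#' Evaluate a set of (prediction, truth) pairs
#'
#' @param pairs list of \code{list(pred, truth)} pairs (matrices or image
#'   objects); both members of each pair are max-normalized before scoring.
#' @param maxShift NCC displacement window.
#' @return a \linkS4class{MetricsReport}; pairs failing metric preconditions
#'   are reported with NA scores (and named in \code{attr(report, "failed")}),
#'   not silently dropped.
#' @export
evaluateSet <- function(pairs, maxShift = 3L) {
  if (length(pairs) == 0) stop("empty pair list")
  rows <- lapply(seq_along(pairs), function(i) {
    p <- maxNormalize(.asValues(pairs[[i]][[1]]))
    t <- maxNormalize(.asValues(pairs[[i]][[2]]))
    ncc <- tryCatch(nccScore(p, t, maxShift), error = function(e) NA_real_)
    ss <- tryCatch(sssimScore(p, t), error = function(e) NA_real_)
    data.frame(pair = i, ncc = ncc, sssim = ss)
  })
  perPair <- do.call(rbind, rows)
  rpt <- new("MetricsReport", perPair = perPair,
             meanNcc = mean(perPair$ncc, na.rm = TRUE),
             sdNcc = stats::sd(perPair$ncc, na.rm = TRUE),
             meanSssim = mean(perPair$sssim, na.rm = TRUE),
             sdSssim = stats::sd(perPair$sssim, na.rm = TRUE))
  failed <- perPair$pair[!stats::complete.cases(perPair)]
  attr(rpt, "failed") <- failed
  rpt
}

#' Register a moving image to a reference by a similarity transform
#'
#' Finds the rotation/translation/scale maximizing the Pearson correlation
#' between the reference and the warped moving image: coarse grid search
#' over rotation and scale with FFT-based translation estimation, followed
#' by Nelder-Mead refinement of all four parameters.
#'
#' @param reference,moving equal-shaped matrices (or image objects).
#' @param pitchUm pixel pitch used to report the translation in mm.
#' @param rotRangeDeg,scaleRange coarse-search extents.
#' @param maxShiftPx translation search extent (pixels).
#' @return list with \code{transform} (a
#'   \linkS4class{SimilarityTransform}), \code{registered} (warped moving
#'   image matrix) and \code{correlation}; if the optimizer fails the
#'   best-found transform is returned with a warning.
#' @export
registerSimilarity <- function(reference, moving, pitchUm = 40,
                               rotRangeDeg = c(-12, 12),
                               scaleRange = c(0.9, 1.1), maxShiftPx = 12) {
  ref <- .asValues(reference); mov <- .asValues(moving)
  if (!all(dim(ref) == dim(mov))) stop("shape mismatch")
  refC <- ref - mean(ref)

  applyTf <- function(par) {
    # par = (rotDeg, drow, dcol, scale); warp moving onto reference frame
    A <- .rotationMatrix(par[1] * pi / 180) / par[4]
    .warpAffineShift(mov, A, c(par[2], par[3]))
  }
  score <- function(par) {
    w <- applyTf(par)
    if (stats::sd(w) == 0) return(1)  # minimize negative correlation
    -stats::cor(as.numeric(w), as.numeric(ref))
  }

  rots <- seq(rotRangeDeg[1], rotRangeDeg[2], by = 2)
  scls <- seq(scaleRange[1], scaleRange[2], by = 0.05)
  best <- NULL
  for (r in rots) for (s in scls) {
    A <- .rotationMatrix(r * pi / 180) / s
    w <- .warpAffineShift(mov, A, c(0, 0))
    sh <- .bestShift(refC, w - mean(w), maxShiftPx)
    par <- c(r, sh[1], sh[2], s)
    val <- score(par)
    if (is.null(best) || val < best$val) best <- list(par = par, val = val)
  }
  opt <- tryCatch(
    stats::optim(best$par, score, method = "Nelder-Mead",
                 control = list(maxit = 400, reltol = 1e-10,
                                parscale = c(1, 1, 1, 0.02))),
    error = function(e) NULL)
  if (is.null(opt)) {
    warning("refinement failed; returning best grid-search transform")
    par <- best$par; corr <- -best$val
  } else {
    par <- opt$par; corr <- -opt$value
  }
  tf <- new("SimilarityTransform", rotationDeg = par[1],
            translationPx = c(par[3], par[2]),
            translationMm = c(par[3], par[2]) * pitchUm / 1000,
            scale = par[4], correlation = corr)
  list(transform = tf, registered = applyTf(par), correlation = corr)
}

# warp with A about the centre plus output-frame translation (drow, dcol):
# output pixel u samples input at A %*% (u - shift - ctr) + ctr
.warpAffineShift <- function(v, A, shift) {
  nr <- nrow(v); nc <- ncol(v)
  ctr <- c((nr + 1) / 2, (nc + 1) / 2)
  u <- cbind(rep(seq_len(nr), nc) - ctr[1] - shift[1],
             rep(seq_len(nc), each = nr) - ctr[2] - shift[2])
  s <- u %*% t(A)
  ri <- s[, 1] + ctr[1]; ci <- s[, 2] + ctr[2]
  r0 <- floor(ri); c0 <- floor(ci)
  fr <- ri - r0; fc <- ci - c0
  pick <- function(r, c) {
    ok <- r >= 1 & r <= nr & c >= 1 & c <= nc
    out <- numeric(length(r))
    out[ok] <- v[cbind(r[ok], c[ok])]
    out
  }
  val <- pick(r0, c0) * (1 - fr) * (1 - fc) +
    pick(r0 + 1, c0) * fr * (1 - fc) +
    pick(r0, c0 + 1) * (1 - fr) * fc +
    pick(r0 + 1, c0 + 1) * fr * fc
  matrix(val, nr, nc)
}

# integer (drow, dcol) maximizing cross-correlation, via FFT
.bestShift <- function(a, b, maxShiftPx) {
  X <- stats::fft(a) * Conj(stats::fft(b))
  cc <- Re(stats::fft(X, inverse = TRUE))
  nr <- nrow(a); nc <- ncol(a)
  sr <- c(0:min(maxShiftPx, nr - 1), -(min(maxShiftPx, nr - 1):1))
  bestv <- -Inf; best <- c(0, 0)
  for (dr in unique(sr)) for (dc in unique(sr)) {
    v <- cc[(dr %% nr) + 1, (dc %% nc) + 1]
    if (v > bestv) { bestv <- v; best <- c(dr, dc) }
  }
  best
}
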