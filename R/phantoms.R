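#' Generate a synthetic branching-vessel absorption map
#'
#' Draws a recursive random binary tree of quadratic Bezier segments with
#' tapering widths and anti-aliased rasterization, emulating the branching
#' morphology of a vascular network (or an ink-stained leaf skeleton). The
#' first primary trunk is constrained to start within 10 degrees of vertical:
#' steep structures are the ones affected by the limited-view artefact, so a
#' phantom family without them would leave the visibility problem untested.
#'
#' @param config a \linkS4class{PhantomConfig}.
#' @return an \linkS4class{AbsorptionMap}; identical \code{config} (including
#'   its seed) always returns a bit-identical raster.
#' @examples
#' p <- generateBranchingPhantom(phantomConfig(seed = 7))
#' mean(values(p) > 0)
#' @export
generateBranchingPhantom <- function(config) {
  stopifnot(is(config, "PhantomConfig"))
  npx <- round(config@fieldSizeMm * 1000 / config@pixelPitchUm)
  if (npx < 16) stop("degenerate grid: field smaller than 16 px")
  origin <- c(-config@fieldSizeMm / 2, config@zTopMm)
  if (config@nPrimaryBranches == 0L)
    return(absorptionMap(matrix(0, npx, npx), config@pixelPitchUm, origin))

  set.seed(config@seed)
  wmin <- config@veinWidthPxRange[1]
  wmax <- config@veinWidthPxRange[2]
  ys <- xs <- rs <- vector("list", 256L)
  nseg <- 0L

  emit <- function(py, px, pr) {
    nseg <<- nseg + 1L
    ys[[nseg]] <<- py; xs[[nseg]] <<- px; rs[[nseg]] <<- pr
  }

  # draw one Bezier segment from p0 in direction ang (radians), then recurse;
  # segments either continue (small angle change) or bifurcate
  grow <- function(p0, ang, len, width, level, straight = FALSE) {
    if (level > config@branchDepth || width < wmin * 0.75) return(invisible())
    # ang is measured from vertical (+z, i.e. down rows); (row, col) step
    p2 <- p0 + len * c(cos(ang), sin(ang))
    mid <- (p0 + p2) / 2
    perp <- c(-sin(ang), cos(ang))
    curv <- if (straight) 0.05 else 0.16
    p1 <- mid + perp * len * stats::runif(1, -curv, curv)
    nt <- max(6L, ceiling(2 * len))
    tt <- seq(0, 1, length.out = nt)
    b <- outer((1 - tt)^2, p0) + outer(2 * tt * (1 - tt), p1) +
      outer(tt^2, p2)
    wEnd <- max(width * 0.88, wmin)
    emit(b[, 1], b[, 2], pmax(width + (wEnd - width) * tt, 1) / 2)
    if (stats::runif(1) < 0.6 || straight) {  # bifurcate
      spread <- (30 + abs(stats::rnorm(1, 0, config@angleJitterDeg))) *
        pi / 180
      childLen <- len * stats::runif(2, 0.65, 0.9)
      childW <- wEnd * stats::runif(2, 0.68, 0.85)
      grow(p2, ang - spread, childLen[1], max(childW[1], wmin), level + 1)
      grow(p2, ang + spread * stats::runif(1, 0.7, 1.3), childLen[2],
           max(childW[2], wmin), level + 1)
    } else {  # continue with mild jitter, cheap on the depth budget
      grow(p2, ang + stats::rnorm(1, 0, 6) * pi / 180,
           len * stats::runif(1, 0.8, 1), max(wEnd, wmin), level + 1)
    }
    invisible()
  }

  for (b in seq_len(config@nPrimaryBranches)) {
    trunkLen <- npx * stats::runif(1, 0.35, 0.5)
    if (b == 1L) {
      # near-vertical straight trunk entering from the top edge (vertical =
      # along z, i.e. along rows): the limited-view-affected orientation
      start <- c(stats::runif(1, 0.05, 0.2) * npx,
                 stats::runif(1, 0.25, 0.75) * npx)
      ang <- stats::runif(1, -8, 8) * pi / 180
      grow(start, ang, trunkLen, wmax, 1L, straight = TRUE)
      next
    } else {
      # remaining trunks enter from any edge with an inward direction, so
      # the family covers all orientations
      side <- sample(c("top", "left", "right", "bottom"), 1)
      start <- switch(side,
        top = c(stats::runif(1, 0, 0.15) * npx, stats::runif(1, 0.1, 0.9) * npx),
        bottom = c(stats::runif(1, 0.85, 1) * npx,
                   stats::runif(1, 0.1, 0.9) * npx),
        left = c(stats::runif(1, 0.1, 0.9) * npx, stats::runif(1, 0, 0.15) * npx),
        right = c(stats::runif(1, 0.1, 0.9) * npx,
                  stats::runif(1, 0.85, 1) * npx))
      ang <- switch(side,
        top = stats::runif(1, -60, 60) * pi / 180,
        bottom = (180 + stats::runif(1, -60, 60)) * pi / 180,
        left = stats::runif(1, 30, 150) * pi / 180,
        right = stats::runif(1, -150, -30) * pi / 180)
    }
    grow(start, ang, trunkLen, wmax, 1L)
  }

  vals <- cpp_stamp_points(npx, npx,
                           unlist(ys[seq_len(nseg)]) - 1,
                           unlist(xs[seq_len(nseg)]) - 1,
                           unlist(rs[seq_len(nseg)]))
  absorptionMap(vals, config@pixelPitchUm, origin)
}

#' Apply a dataset augmentation transform
#'
#' Supported transforms are the dataset-construction augmentations: rotation,
#' mirror, axis shear and centre expansion/compression. The output stays on
#' the input grid (bilinear resampling, zero background) and is clipped to
#' [0, 1]. Rotations by multiples of 90 degrees and mirrors are exact index
#' permutations.
#'
#' @param img an \linkS4class{AbsorptionMap}.
#' @param transform a list with element \code{type} in \code{"rotation"}
#'   (\code{angle} in degrees), \code{"mirror"} (\code{axis} "horizontal" or
#'   "vertical"), \code{"shear"} (\code{axis}, \code{factor}) or
#'   \code{"center_scale"} (\code{factor}).
#' @return the transformed \linkS4class{AbsorptionMap}.
#' @export
augmentMap <- function(img, transform) {
  stopifnot(is(img, "AbsorptionMap"), is.list(transform))
  v <- img@values
  type <- transform$type
  out <- switch(type,
    rotation = {
      a <- transform$angle %% 360
      if (isTRUE(all.equal(a %% 90, 0))) .rot90k(v, as.integer(a / 90))
      else .warpAffine(v, .rotationMatrix(a * pi / 180))
    },
    mirror = {
      ax <- transform$axis
      if (ax == "horizontal") v[, ncol(v):1, drop = FALSE]
      else if (ax == "vertical") v[nrow(v):1, , drop = FALSE]
      else stop("mirror axis must be 'horizontal' or 'vertical'")
    },
    shear = {
      f <- transform$factor
      A <- if (transform$axis == "horizontal") matrix(c(1, 0, f, 1), 2)
      else if (transform$axis == "vertical") matrix(c(1, f, 0, 1), 2)
      else stop("shear axis must be 'horizontal' or 'vertical'")
      .warpAffine(v, A)
    },
    center_scale = .warpAffine(v, diag(2) * transform$factor),
    stop("unknown transform type: ", type)
  )
  out <- pmin(pmax(out, 0), 1)
  absorptionMap(out, img@pitchUm, img@originMm)
}

# exact rotation by k * 90 degrees (counter-clockwise in (row, col) space)
.rot90k <- function(v, k) {
  k <- k %% 4L
  if (k == 0L) return(v)
  for (i in seq_len(k)) v <- t(v)[ncol(v):1, , drop = FALSE]
  v
}

.rotationMatrix <- function(theta)
  matrix(c(cos(theta), sin(theta), -sin(theta), cos(theta)), 2)

# Warp about the image centre: output pixel u (row, col) takes the value at
# input position A %*% (u - ctr) + ctr. Bilinear sampling, zero background.
.warpAffine <- function(v, A) {
  nr <- nrow(v); nc <- ncol(v)
  ctr <- c((nr + 1) / 2, (nc + 1) / 2)
  u <- cbind(rep(seq_len(nr), nc) - ctr[1],
             rep(seq_len(nc), each = nr) - ctr[2])
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

#' Zero out background pixels below a threshold
#'
#' @param img an \linkS4class{AbsorptionMap}.
#' @param thr threshold (>= 0); pixels with value < thr are set to 0.
#' @return the thresholded map.
#' @export
thresholdBackground <- function(img, thr) {
  stopifnot(is(img, "AbsorptionMap"), thr >= 0)
  v <- img@values
  v[v < thr] <- 0
  absorptionMap(v, img@pitchUm, img@originMm)
}

#' Extract a square patch on the same grid
#'
#' @param img an \linkS4class{AbsorptionMap}.
#' @param centerMm (x, z) patch centre in mm.
#' @param sizeMm patch side length in mm.
#' @return an \linkS4class{AbsorptionMap} with updated origin; pixel pitch is
#'   preserved. Errors if the patch is not fully inside the field.
#' @export
extractPatch <- function(img, centerMm, sizeMm) {
  stopifnot(is(img, "AbsorptionMap"))
  pitchMm <- img@pitchUm / 1000
  n <- round(sizeMm / pitchMm)
  c0 <- round((centerMm[1] - sizeMm / 2 - img@originMm[1]) / pitchMm) + 1
  r0 <- round((centerMm[2] - sizeMm / 2 - img@originMm[2]) / pitchMm) + 1
  if (r0 < 1 || c0 < 1 || r0 + n - 1 > nrow(img@values) ||
      c0 + n - 1 > ncol(img@values))
    stop("patch out of bounds")
  vals <- img@values[r0:(r0 + n - 1), c0:(c0 + n - 1), drop = FALSE]
  absorptionMap(vals, img@pitchUm,
                img@originMm + c((c0 - 1) * pitchMm, (r0 - 1) * pitchMm))
}

#' Dominant local orientations of a raster (structure tensor)
#'
#' Smoothed-gradient structure-tensor orientations, weighted by gradient
#' energy. Used to verify that generated phantoms contain near-vertical
#' segments (the ones the limited-view artefact suppresses).
#'
#' @param v matrix or \linkS4class{AbsorptionMap}.
#' @return data.frame with columns \code{angleDeg} (structure orientation in
#'   degrees, 0 = vertical structure, i.e. elongated along depth z) and
#'   \code{weight}.
#' @export
structureTensorOrientations <- function(v) {
  v <- .asValues(v)
  gz <- v * 0; gx <- v * 0
  gz[2:(nrow(v) - 1), ] <- (v[3:nrow(v), ] - v[1:(nrow(v) - 2), ]) / 2
  gx[, 2:(ncol(v) - 1)] <- (v[, 3:ncol(v)] - v[, 1:(ncol(v) - 2)]) / 2
  Jzz <- .boxSmooth(gz * gz); Jxx <- .boxSmooth(gx * gx)
  Jzx <- .boxSmooth(gz * gx)
  # dominant gradient orientation from the x axis; the structure itself is
  # perpendicular to its gradient, so theta ~ 0 <=> structure along depth z
  theta <- 0.5 * atan2(2 * Jzx, Jxx - Jzz)
  energy <- Jzz + Jxx
  keep <- energy > 0.05 * max(energy)
  ang <- theta[keep] * 180 / pi
  ang <- (ang + 90) %% 180 - 90  # fold to (-90, 90]
  data.frame(angleDeg = abs(ang), weight = energy[keep])
}

.boxSmooth <- function(v) {
  n <- nrow(v); m <- ncol(v)
  p <- rbind(0, rbind(v, 0)); p <- cbind(0, cbind(p, 0))
  (p[1:n, 1:m] + p[1:n, 2:(m + 1)] + p[1:n, 3:(m + 2)] +
     p[2:(n + 1), 1:m] + p[2:(n + 1), 2:(m + 1)] + p[2:(n + 1), 3:(m + 2)] +
     p[3:(n + 2), 1:m] + p[3:(n + 2), 2:(m + 1)] +
     p[3:(n + 2), 3:(m + 2)]) / 9
}
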