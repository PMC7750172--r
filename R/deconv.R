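# L2-regularized least-squares inversion of the forward model:
#   argmin_X 1/2 ||Y - A X||^2 + alpha/2 ||X||^2
# solved by FISTA (accelerated gradient; the penalty is smooth so the
# proximal step is the identity), with the ridge closed form as an oracle.

#' FISTA solver for the L2-penalized inverse problem
#'
#' @param Y an \linkS4class{RFData} or a numeric vector/matrix of
#'   observations.
#' @param A a \linkS4class{SystemMatrix} or a plain (possibly sparse)
#'   matrix.
#' @param cfg a \linkS4class{DeconvConfig}.
#' @return list with \code{x} (solution vector), \code{objective} (trace of
#'   the penalized objective per iteration), \code{iterations}, \code{L}
#'   (Lipschitz estimate) and, when \code{A} is a \linkS4class{SystemMatrix},
#'   \code{image} (a \linkS4class{ReconImage} of kind "deconv").
#' @export
fistaL2 <- function(Y, A, cfg = deconvConfig()) {
  stopifnot(is(cfg, "DeconvConfig"))
  sysmat <- is(A, "SystemMatrix")
  Am <- if (sysmat) A@entries else A
  y <- if (is(Y, "RFData")) as.numeric(Y@signals) else as.numeric(Y)
  if (length(y) != nrow(Am)) stop("shape mismatch between Y and A")
  if (!all(is.finite(y))) stop("non-finite observations")
  if (nrow(Am) == 0 || ncol(Am) == 0) stop("zero-sized system")

  L <- if (is.na(cfg@step)) .powerIterL(Am, n = 50L) + cfg@alpha
       else 1 / cfg@step
  step <- 1 / L
  Aty <- as.numeric(Matrix::crossprod(Am, y))
  obj <- function(x) {
    r <- as.numeric(Am %*% x) - y
    0.5 * sum(r^2) + cfg@alpha / 2 * sum(x^2)
  }
  x <- numeric(ncol(Am))
  z <- x
  t_k <- 1
  trace <- numeric(cfg@nIter)
  it <- 0L
  repeat {
    it <- it + 1L
    g <- as.numeric(Matrix::crossprod(Am, as.numeric(Am %*% z))) - Aty +
      cfg@alpha * z
    xNew <- z - step * g
    tNew <- (1 + sqrt(1 + 4 * t_k^2)) / 2
    z <- xNew + ((t_k - 1) / tNew) * (xNew - x)
    rel <- sqrt(sum((xNew - x)^2)) / max(sqrt(sum(x^2)), 1e-12)
    x <- xNew
    t_k <- tNew
    trace[it] <- obj(x)
    if (it >= cfg@nIter || rel < cfg@tol) break
  }
  out <- list(x = x, objective = trace[seq_len(it)], iterations = it, L = L)
  if (sysmat) {
    nz <- length(A@grid@zMm); nx <- length(A@grid@xMm)
    out$image <- reconImage(matrix(x, nz, nx), A@grid, "deconv")
  }
  out
}

# largest eigenvalue of A'A by power iteration
.powerIterL <- function(Am, n = 50L) {
  set.seed(1L)
  v <- stats::rnorm(ncol(Am))
  v <- v / sqrt(sum(v^2))
  lam <- 1
  for (i in seq_len(n)) {
    w <- as.numeric(Matrix::crossprod(Am, as.numeric(Am %*% v)))
    lam <- sqrt(sum(w^2))
    if (lam == 0) return(1)
    v <- w / lam
  }
  lam
}

#' Closed-form ridge solution (test oracle)
#'
#' The exact minimizer (A'A + alpha I)^-1 A'Y of the same objective, for
#' systems small enough to factor.
#'
#' @inheritParams fistaL2
#' @param alpha L2 regularization weight.
#' @return solution vector (and \code{image} attribute logic as in
#'   \code{\link{fistaL2}} is not applied; this is a numeric oracle).
#' @export
ridgeClosedForm <- function(Y, A, alpha) {
  sysmat <- is(A, "SystemMatrix")
  Am <- if (sysmat) A@entries else A
  y <- if (is(Y, "RFData")) as.numeric(Y@signals) else as.numeric(Y)
  G <- as.matrix(Matrix::crossprod(Am)) + diag(alpha, ncol(Am))
  if (alpha == 0 && rcond(G) < 1e-14)
    stop("singular system with alpha = 0")
  as.numeric(solve(G, as.numeric(Matrix::crossprod(Am, y))))
}

#' Heuristic regularization-weight selection
#'
#' Mirrors tuning "by visually comparing with the ground truth": picks the
#' alpha maximizing sSSIM between the deconvolved image and a held-out
#' ground-truth patch.
#'
#' @param Y observations (see \code{\link{fistaL2}}).
#' @param A a \linkS4class{SystemMatrix}.
#' @param truth ground-truth \linkS4class{AbsorptionMap} or matrix on the
#'   same grid.
#' @param alphas candidate weights.
#' @param cfg base \linkS4class{DeconvConfig}.
#' @return list with \code{alpha}, \code{scores}.
#' @export
selectAlpha <- function(Y, A, truth, alphas = 10^seq(-3, 2),
                        cfg = deconvConfig()) {
  tv <- maxNormalize(.asValues(truth))
  scores <- vapply(alphas, function(a) {
    cfg@alpha <- a
    img <- fistaL2(Y, A, cfg)$image@values
    img[img < 0] <- 0
    sssimScore(maxNormalize(img), tv)
  }, numeric(1))
  list(alpha = alphas[which.max(scores)], scores = scores)
}
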