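# Prediction-uncertainty estimation: Monte-Carlo dropout (stochastic
# forward passes through the trained network), acquisition-noise
# variability (deterministic network, repeated noisy acquisitions), the
# absolute-error map against ground truth, and a quantitative calibration
# check of how uncertainty co-locates with error.

#' Monte-Carlo dropout prediction
#'
#' Runs n stochastic forward passes with the dropout layers active (same
#' rate as during training unless overridden) and batch normalization in
#' inference mode, and returns the pixel-wise mean and standard deviation.
#' Mask sequences are seeded per inference from the master seed, so the
#' whole procedure is reproducible; passing explicit per-pass seeds allows
#' forcing identical masks.
#'
#' @param model a trained \linkS4class{TrainedModel} (its spec must contain
#'   dropout layers for the std to be nonzero).
#' @param mbf input image (\linkS4class{ReconImage} or matrix).
#' @param n number of inferences (>= 2).
#' @param seed master seed.
#' @param dropoutRate override of the spec's dropout rate.
#' @param seeds optional explicit per-pass seeds (length n).
#' @return an \linkS4class{UncertaintyMaps} with source "mc_dropout".
#' @export
mcDropoutPredict <- function(model, mbf, n = 20L, seed = 1L,
                             dropoutRate = NULL, seeds = NULL) {
  stopifnot(is(model, "TrainedModel"))
  if (n < 2) stop("n must be >= 2")
  x <- .asValues(mbf)
  x <- .normalizeInputArray(x)
  rate <- dropoutRate %||% model@spec@dropoutRate
  seeds <- seeds %||% vapply(seq_len(n), function(k) .subSeed(seed, k),
                             integer(1))
  stopifnot(length(seeds) == n)
  H <- dim(x)[1]; W <- dim(x)[2]
  stack <- array(0, c(H, W, n))
  for (k in seq_len(n)) {
    y <- .predictRaw(model@params, model@spec, x, mcDropout = rate > 0,
                     seed = seeds[k], dropoutRate = rate)
    stack[, , k] <- y[, , 1]
  }
  mu <- apply(stack, c(1, 2), mean)
  sdv <- apply(stack, c(1, 2), stats::sd)
  new("UncertaintyMaps", mean = mu, std = sdv, nSamples = as.integer(n),
      source = "mc_dropout")
}

#' Acquisition-noise variability map
#'
#' Beamforms each of several RF acquisitions of the same object, predicts
#' deterministically (dropout disabled), and returns the pixel-wise mean
#' and standard deviation: the variability now comes from the experimental
#' noise while the network remains deterministic.
#'
#' @param model a trained \linkS4class{TrainedModel}.
#' @param rfAcquisitions list of >= 2 \linkS4class{RFData} of one object
#'   under independent noise.
#' @param grid the \linkS4class{ReconGrid}.
#' @param probe the \linkS4class{ProbeGeometry}.
#' @return an \linkS4class{UncertaintyMaps} with source
#'   "acquisition_noise".
#' @export
noiseVariabilityMap <- function(model, rfAcquisitions, grid, probe) {
  stopifnot(length(rfAcquisitions) >= 2)
  n <- length(rfAcquisitions)
  H <- length(grid@zMm); W <- length(grid@xMm)
  stack <- array(0, c(H, W, n))
  for (k in seq_len(n)) {
    mbf <- dasMBF(rfAcquisitions[[k]], grid, probe)
    stack[, , k] <- predictImage(model, mbf@values)
  }
  mu <- apply(stack, c(1, 2), mean)
  sdv <- apply(stack, c(1, 2), stats::sd)
  new("UncertaintyMaps", mean = mu, std = sdv, nSamples = as.integer(n),
      source = "acquisition_noise")
}

#' Absolute-error map against ground truth
#'
#' @param predMean predicted (mean) image, max-normalized.
#' @param truth ground-truth map, max-normalized.
#' @return a \linkS4class{ReconImage} of kind "prediction" holding
#'   |truth - prediction|.
#' @export
absErrorMap <- function(predMean, truth) {
  p <- .asValues(predMean); t <- .asValues(truth)
  if (!all(dim(p) == dim(t))) stop("shape mismatch")
  grid <- if (is(predMean, "ReconImage")) predMean@grid
          else reconGrid(sizeMm = ncol(p) * 40 / 1000, pitchUm = 40)
  reconImage(abs(t - p), grid, "prediction")
}

#' Foreground mask for calibration statistics
#'
#' Union of the truth support and the prediction support, dilated by a few
#' pixels; background clutter would otherwise dominate rank statistics.
#'
#' @param truth,pred max-normalized images.
#' @param thr support threshold.
#' @param dilatePx dilation radius in pixels.
#' @return logical matrix.
#' @export
foregroundMask <- function(truth, pred, thr = 0.05, dilatePx = 2L) {
  t <- .asValues(truth); p <- .asValues(pred)
  m <- (t > thr) | (p > thr)
  brush <- EBImage::makeBrush(2L * dilatePx + 1L, shape = "box")
  EBImage::dilate(m * 1, brush) > 0
}

#' Uncertainty-calibration report
#'
#' Quantifies the co-location of predicted uncertainty and actual error:
#' (i) Spearman rank correlation between the uncertainty (std) map and the
#' absolute-error map over foreground pixels, and (ii) the ratio of the mean
#' std inside the top decile of |error| to the mean std inside the bottom
#' decile. A well-calibrated uncertainty map concentrates where the
#' prediction is wrong, giving a decile ratio well above 1.
#'
#' @param stdMap uncertainty map (matrix or \linkS4class{UncertaintyMaps},
#'   in which case its std slot is used).
#' @param errorMap absolute-error map.
#' @param mask optional logical foreground mask (defaults to all pixels).
#' @return list with \code{spearman}, \code{decileRatio},
#'   \code{nForeground}; constant maps give \code{spearman = NA} with a
#'   \code{note}.
#' @export
uncertaintyCalibration <- function(stdMap, errorMap, mask = NULL) {
  s <- if (is(stdMap, "UncertaintyMaps")) stdMap@std else .asValues(stdMap)
  e <- .asValues(errorMap)
  if (!all(dim(s) == dim(e))) stop("shape mismatch")
  mask <- mask %||% matrix(TRUE, nrow(s), ncol(s))
  sv <- s[mask]; ev <- e[mask]
  if (stats::sd(sv) == 0 || stats::sd(ev) == 0)
    return(list(spearman = NA_real_, decileRatio = NA_real_,
                nForeground = sum(mask),
                note = "constant map: correlation undefined"))
  rho <- stats::cor(sv, ev, method = "spearman")
  qs <- stats::quantile(ev, c(0.1, 0.9))
  lo <- mean(sv[ev <= qs[1]])
  hi <- mean(sv[ev >= qs[2]])
  list(spearman = rho,
       decileRatio = if (lo > 0) hi / lo else Inf,
       nForeground = sum(mask))
}
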