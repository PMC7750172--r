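#' @import methods
NULL

# ---------------------------------------------------------------------------
# Configuration classes
# ---------------------------------------------------------------------------

#' Phantom generator configuration
#'
#' Parameters of the synthetic branching-vessel phantom generator. The
#' generator emulates ink-stained vascular/venation networks: a recursive
#' binary tree of quadratic Bezier segments with tapering widths, rasterized
#' with anti-aliasing on a metric grid.
#'
#' @slot fieldSizeMm physical side length of the simulated field (mm). The
#'   full field is insonified; the network only ever sees a patch.
#' @slot patchSizeMm side length of extracted patches (mm).
#' @slot pixelPitchUm grid pitch (micrometres).
#' @slot nPrimaryBranches number of primary vessel trunks.
#' @slot branchDepth recursion depth of the branching tree.
#' @slot veinWidthPxRange numeric(2), min and max vessel half-width driving
#'   widths in pixels (trunks start at the max, children taper towards the
#'   min; widths never fall below 1 px).
#' @slot angleJitterDeg standard deviation of the branching-angle jitter.
#' @slot zTopMm depth of the top edge of the field below the probe face (mm).
#' @slot seed RNG seed; identical config + seed gives a bit-identical raster.
#' @exportClass PhantomConfig
setClass("PhantomConfig",
  representation(
    fieldSizeMm = "numeric", patchSizeMm = "numeric", pixelPitchUm = "numeric",
    nPrimaryBranches = "integer", branchDepth = "integer",
    veinWidthPxRange = "numeric", angleJitterDeg = "numeric",
    zTopMm = "numeric", seed = "integer"),
  validity = function(object) {
    msg <- NULL
    if (object@fieldSizeMm < object@patchSizeMm)
      msg <- c(msg, "fieldSizeMm must be >= patchSizeMm")
    if (any(object@veinWidthPxRange < 1))
      msg <- c(msg, "vein widths must be >= 1 px")
    if (length(object@veinWidthPxRange) != 2L ||
        diff(object@veinWidthPxRange) < 0)
      msg <- c(msg, "veinWidthPxRange must be (min, max)")
    if (is.null(msg)) TRUE else msg
  })

#' @param fieldSizeMm,patchSizeMm,pixelPitchUm,nPrimaryBranches,branchDepth
#'   see slots.
#' @param veinWidthPxRange,angleJitterDeg,zTopMm,seed see slots.
#' @return a \code{PhantomConfig}.
#' @rdname PhantomConfig-class
#' @export
phantomConfig <- function(fieldSizeMm = 10.0, patchSizeMm = 5.12,
                          pixelPitchUm = 40, nPrimaryBranches = 3L,
                          branchDepth = 4L, veinWidthPxRange = c(3, 12),
                          angleJitterDeg = 14, zTopMm = 10.0, seed = 1L) {
  new("PhantomConfig", fieldSizeMm = fieldSizeMm, patchSizeMm = patchSizeMm,
      pixelPitchUm = pixelPitchUm,
      nPrimaryBranches = as.integer(nPrimaryBranches),
      branchDepth = as.integer(branchDepth),
      veinWidthPxRange = veinWidthPxRange, angleJitterDeg = angleJitterDeg,
      zTopMm = zTopMm, seed = as.integer(seed))
}

#' Transducer array geometry and acquisition parameters
#'
#' Element positions and normals are explicit so that both a conventional
#' linear array and an omnidirectional virtual ring aperture (used to ablate
#' the limited-view mechanism) share one representation.
#'
#' @slot positions n x 2 matrix of element centres (x, z) in mm.
#' @slot normals n x 2 matrix of unit element normals.
#' @slot pitchMm element spacing (mm); informative for linear arrays.
#' @slot fcMHz central frequency (MHz).
#' @slot fracBandwidth -6 dB fractional bandwidth.
#' @slot fsMHz sampling rate (MHz).
#' @slot cMps speed of sound (m/s) assumed for reconstruction.
#' @slot nSamples time samples per channel.
#' @slot t0Us acquisition start time (us).
#' @slot directivity one of "cos" (soft element sensitivity), "none",
#'   "hard" (cutoff at \code{cutoffDeg}).
#' @slot cutoffDeg acceptance half-angle for \code{directivity = "hard"}.
#' @exportClass ProbeGeometry
setClass("ProbeGeometry",
  representation(
    positions = "matrix", normals = "matrix", pitchMm = "numeric",
    fcMHz = "numeric", fracBandwidth = "numeric", fsMHz = "numeric",
    cMps = "numeric", nSamples = "integer", t0Us = "numeric",
    directivity = "character", cutoffDeg = "numeric"),
  validity = function(object) {
    msg <- NULL
    if (object@fsMHz <= 2 * object@fcMHz * (1 + object@fracBandwidth / 2))
      msg <- c(msg, "sampling criterion violated: need fs > 2 fc (1 + bw/2)")
    if (!object@directivity %in% c("cos", "none", "hard"))
      msg <- c(msg, "directivity must be 'cos', 'none' or 'hard'")
    if (nrow(object@positions) != nrow(object@normals))
      msg <- c(msg, "positions/normals mismatch")
    if (is.null(msg)) TRUE else msg
  })

#' Linear transducer array
#'
#' Default geometry mirrors a high-frequency 128-element linear array
#' (15.6 MHz centre frequency, 0.1 mm pitch) at the probe face z = 0,
#' elements looking down (+z).
#'
#' @param nElements,pitchMm,fcMHz,fracBandwidth,fsMHz,cMps,nSamples,t0Us see
#'   \linkS4class{ProbeGeometry} slots.
#' @param directivity,cutoffDeg see \linkS4class{ProbeGeometry} slots.
#' @return a \code{ProbeGeometry}.
#' @export
linearProbe <- function(nElements = 128L, pitchMm = 0.1, fcMHz = 15.6,
                        fracBandwidth = 0.6, fsMHz = 62.5, cMps = 1500,
                        nSamples = 980L, t0Us = 0, directivity = "cos",
                        cutoffDeg = 45) {
  n <- as.integer(nElements)
  x <- (seq_len(n) - (n + 1) / 2) * pitchMm
  new("ProbeGeometry",
      positions = cbind(x = x, z = rep(0, n)),
      normals = cbind(rep(0, n), rep(1, n)),
      pitchMm = pitchMm, fcMHz = fcMHz, fracBandwidth = fracBandwidth,
      fsMHz = fsMHz, cMps = cMps, nSamples = as.integer(nSamples),
      t0Us = t0Us, directivity = directivity, cutoffDeg = cutoffDeg)
}

#' Omnidirectional virtual ring aperture
#'
#' Elements on a full circle around the field, normals pointing inwards.
#' Used to show that the limited-view artefact is a property of the
#' acquisition geometry: with a full angular view it disappears.
#'
#' @param nElements number of virtual elements.
#' @param radiusMm ring radius (mm).
#' @param centerMm (x, z) ring centre in mm.
#' @param ... forwarded to probe acquisition slots (fcMHz, fsMHz, ...).
#' @return a \code{ProbeGeometry}.
#' @export
ringProbe <- function(nElements = 256L, radiusMm = 10, centerMm = c(0, 15.06),
                      ...) {
  base <- linearProbe(nElements = nElements, ...)
  n <- as.integer(nElements)
  th <- 2 * pi * (seq_len(n) - 1) / n
  pos <- cbind(centerMm[1] + radiusMm * cos(th),
               centerMm[2] + radiusMm * sin(th))
  nrm <- cbind(-cos(th), -sin(th))
  base@positions <- pos
  base@normals <- nrm
  base
}

#' Additive-noise configuration
#'
#' White Gaussian noise on RF channels, calibrated so that the peak amplitude
#' of the RF signal of a reference horizontal bar divided by the noise
#' standard deviation equals \code{targetSnr} (amplitude SNR; horizontal
#' structures are the reference because they are the fully visible ones).
#'
#' @slot targetSnr amplitude SNR of the horizontal-structure reference.
#' @slot seed RNG seed.
#' @exportClass NoiseConfig
setClass("NoiseConfig",
  representation(targetSnr = "numeric", seed = "integer"),
  validity = function(object)
    if (object@targetSnr > 0) TRUE else "targetSnr must be > 0")

#' @param targetSnr,seed see slots.
#' @rdname NoiseConfig-class
#' @export
noiseConfig <- function(targetSnr = 60, seed = 1L)
  new("NoiseConfig", targetSnr = targetSnr, seed = as.integer(seed))

#' FISTA deconvolution configuration
#'
#' @slot alpha L2 regularization weight.
#' @slot nIter iteration cap.
#' @slot tol relative-change stopping tolerance.
#' @slot step gradient step; NA means 1/L with L estimated by power iteration.
#' @exportClass DeconvConfig
setClass("DeconvConfig",
  representation(alpha = "numeric", nIter = "integer", tol = "numeric",
                 step = "numeric"),
  validity = function(object) {
    msg <- NULL
    if (object@alpha < 0) msg <- c(msg, "alpha must be >= 0")
    if (object@nIter < 1L) msg <- c(msg, "nIter must be >= 1")
    if (is.null(msg)) TRUE else msg
  })

#' @param alpha,nIter,tol,step see slots.
#' @rdname DeconvConfig-class
#' @export
deconvConfig <- function(alpha = 0.1, nIter = 300L, tol = 1e-6, step = NA_real_)
  new("DeconvConfig", alpha = alpha, nIter = as.integer(nIter), tol = tol,
      step = step)

#' U-Net architecture specification
#'
#' Encoder-decoder with skip concatenations; every scale block is
#' conv3x3-BN-ReLU twice followed by dropout. The output layer is a single
#' 1x1 filter with no activation (the prediction is a real-valued image, not
#' a segmentation).
#'
#' @slot depth number of down/up-sampling levels.
#' @slot baseFilters filters at the first level, doubling per level.
#' @slot dropoutRate dropout rate in every scale block.
#' @slot useBatchnorm logical.
#' @slot outChannels fixed at 1.
#' @slot finalActivation fixed at "none".
#' @exportClass UNetSpec
setClass("UNetSpec",
  representation(depth = "integer", baseFilters = "integer",
                 dropoutRate = "numeric", useBatchnorm = "logical",
                 outChannels = "integer", finalActivation = "character"),
  validity = function(object) {
    msg <- NULL
    if (object@outChannels != 1L) msg <- c(msg, "outChannels must be 1")
    if (object@finalActivation != "none")
      msg <- c(msg, "final activation must be absent ('none')")
    if (object@dropoutRate < 0 || object@dropoutRate >= 1)
      msg <- c(msg, "dropoutRate must be in [0, 1)")
    if (is.null(msg)) TRUE else msg
  })

#' @param depth,baseFilters,dropoutRate,useBatchnorm see slots.
#' @rdname UNetSpec-class
#' @export
unetSpec <- function(depth = 4L, baseFilters = 64L, dropoutRate = 0.5,
                     useBatchnorm = TRUE)
  new("UNetSpec", depth = as.integer(depth),
      baseFilters = as.integer(baseFilters), dropoutRate = dropoutRate,
      useBatchnorm = useBatchnorm, outChannels = 1L, finalActivation = "none")

#' Training configuration
#'
#' @slot loss only "mse" is supported (the training criterion is the mean
#'   squared error between prediction and ground truth).
#' @slot optimizer only "adam".
#' @slot lr learning rate.
#' @slot beta1 Adam first-moment decay (default 0.8).
#' @slot beta2 Adam second-moment decay.
#' @slot batchSize images per gradient step.
#' @slot maxEpochs epoch cap (0 performs no training).
#' @slot patience early-stopping patience on the validation loss, in epochs.
#' @slot bnMomentum running-statistics momentum of the batch-norm layers.
#' @slot seed RNG seed controlling initialization order, shuffling and
#'   dropout masks.
#' @exportClass TrainConfig
setClass("TrainConfig",
  representation(loss = "character", optimizer = "character", lr = "numeric",
                 beta1 = "numeric", beta2 = "numeric", batchSize = "integer",
                 maxEpochs = "integer", patience = "integer",
                 bnMomentum = "numeric", seed = "integer"),
  validity = function(object) {
    msg <- NULL
    if (object@batchSize < 1L) msg <- c(msg, "batchSize must be >= 1")
    if (object@lr < 0) msg <- c(msg, "lr must be >= 0")
    if (object@loss != "mse") msg <- c(msg, "only the MSE loss is supported")
    if (object@optimizer != "adam") msg <- c(msg, "only Adam is supported")
    if (is.null(msg)) TRUE else msg
  })

#' @param lr,beta1,beta2,batchSize,maxEpochs,patience,bnMomentum,seed see
#'   slots.
#' @rdname TrainConfig-class
#' @export
trainConfig <- function(lr = 5e-4, beta1 = 0.8, beta2 = 0.999,
                        batchSize = 8L, maxEpochs = 60L, patience = 8L,
                        bnMomentum = 0.1, seed = 1L)
  new("TrainConfig", loss = "mse", optimizer = "adam", lr = lr, beta1 = beta1,
      beta2 = beta2, batchSize = as.integer(batchSize),
      maxEpochs = as.integer(maxEpochs), patience = as.integer(patience),
      bnMomentum = bnMomentum, seed = as.integer(seed))

#' Learning-curve experiment configuration
#'
#' @slot setSizes training-set sizes to sweep.
#' @slot nRepeats repeats per size with freshly drawn subsets.
#' @slot pretrain logical; run the pretrained arm.
#' @slot pretrainPairs number of simulated pairs for pretraining.
#' @slot seed master seed.
#' @exportClass LearningCurveConfig
setClass("LearningCurveConfig",
  representation(setSizes = "integer", nRepeats = "integer",
                 pretrain = "logical", pretrainPairs = "integer",
                 seed = "integer"),
  validity = function(object) {
    msg <- NULL
    if (any(object@setSizes <= 0L)) msg <- c(msg, "sizes must be positive")
    if (is.unsorted(object@setSizes)) msg <- c(msg, "sizes must be sorted")
    if (object@nRepeats < 1L) msg <- c(msg, "nRepeats must be >= 1")
    if (is.null(msg)) TRUE else msg
  })

#' @param setSizes,nRepeats,pretrain,pretrainPairs,seed see slots.
#' @rdname LearningCurveConfig-class
#' @export
learningCurveConfig <- function(setSizes = c(10L, 25L, 50L, 100L, 200L),
                                nRepeats = 3L, pretrain = TRUE,
                                pretrainPairs = 300L, seed = 1L)
  new("LearningCurveConfig", setSizes = as.integer(setSizes),
      nRepeats = as.integer(nRepeats), pretrain = pretrain,
      pretrainPairs = as.integer(pretrainPairs), seed = as.integer(seed))

# ---------------------------------------------------------------------------
# Data classes
# ---------------------------------------------------------------------------

#' Ground-truth optical absorption map
#'
#' Non-negative 2D raster of absorbers on a metric grid; rows index depth z,
#' columns index the lateral coordinate x. Background pixels are exactly 0.
#'
#' @slot values matrix in [0, 1].
#' @slot pitchUm pixel pitch (micrometres).
#' @slot originMm (x, z) of the centre of pixel [1, 1] in mm.
#' @exportClass AbsorptionMap
setClass("AbsorptionMap",
  representation(values = "matrix", pitchUm = "numeric", originMm = "numeric"),
  validity = function(object) {
    msg <- NULL
    if (any(!is.finite(object@values))) msg <- c(msg, "non-finite values")
    else if (min(object@values) < 0) msg <- c(msg, "values must be >= 0")
    # (<= 1 is a convention of *normalized* maps, not enforced here: the
    # forward model is linear and may be probed with scaled objects)
    if (length(object@originMm) != 2L) msg <- c(msg, "originMm must be (x, z)")
    if (is.null(msg)) TRUE else msg
  })

#' @param values,pitchUm,originMm see slots.
#' @rdname AbsorptionMap-class
#' @export
absorptionMap <- function(values, pitchUm, originMm)
  new("AbsorptionMap", values = values, pitchUm = pitchUm,
      originMm = as.numeric(originMm))

#' Radiofrequency element-time data
#'
#' @slot signals nElements x nSamples matrix.
#' @slot fsMHz sampling rate (MHz).
#' @slot t0Us time of sample 1 (us).
#' @exportClass RFData
setClass("RFData",
  representation(signals = "matrix", fsMHz = "numeric", t0Us = "numeric"),
  validity = function(object)
    if (all(is.finite(object@signals))) TRUE else "non-finite RF samples")

#' @param signals,fsMHz,t0Us see slots.
#' @rdname RFData-class
#' @export
rfData <- function(signals, fsMHz, t0Us = 0)
  new("RFData", signals = signals, fsMHz = fsMHz, t0Us = t0Us)

#' Reconstruction grid
#'
#' @slot xMm lateral pixel-centre coordinates (mm).
#' @slot zMm depth pixel-centre coordinates (mm).
#' @slot pitchUm pixel pitch (micrometres).
#' @exportClass ReconGrid
setClass("ReconGrid",
  representation(xMm = "numeric", zMm = "numeric", pitchUm = "numeric"),
  validity = function(object) {
    ok <- function(v) length(v) < 2L ||
      all(abs(diff(diff(v))) < 1e-9)
    if (ok(object@xMm) && ok(object@zMm)) TRUE else "non-uniform grid spacing"
  })

#' Square reconstruction grid
#'
#' @param centerMm (x, z) centre of the reconstructed area in mm.
#' @param sizeMm side length in mm.
#' @param pitchUm pixel pitch in micrometres.
#' @return a \code{ReconGrid}.
#' @export
reconGrid <- function(centerMm = c(0, 15.06), sizeMm = 5.12, pitchUm = 40) {
  n <- round(sizeMm * 1000 / pitchUm)
  off <- (seq_len(n) - (n + 1) / 2) * pitchUm / 1000
  new("ReconGrid", xMm = centerMm[1] + off, zMm = centerMm[2] + off,
      pitchUm = pitchUm)
}

#' Reconstructed image
#'
#' @slot values 2D raster; real-valued and oscillatory for kind "mBF",
#'   non-negative for "dmBF" and envelope-like kinds.
#' @slot grid the \linkS4class{ReconGrid}.
#' @slot kind one of "mBF", "dmBF", "deconv", "prediction".
#' @exportClass ReconImage
setClass("ReconImage",
  representation(values = "matrix", grid = "ReconGrid", kind = "character"),
  validity = function(object) {
    msg <- NULL
    if (!object@kind %in% c("mBF", "dmBF", "deconv", "prediction"))
      msg <- c(msg, "unknown image kind")
    if (any(!is.finite(object@values))) msg <- c(msg, "non-finite values")
    else if (object@kind == "dmBF" && min(object@values) < 0)
      msg <- c(msg, "dmBF values must be >= 0")
    if (is.null(msg)) TRUE else msg
  })

#' @param values,grid,kind see slots.
#' @rdname ReconImage-class
#' @export
reconImage <- function(values, grid, kind)
  new("ReconImage", values = values, grid = grid, kind = kind)

#' Sparse propagation (system) matrix
#'
#' Column j holds the vectorized RF response (column-major element x sample)
#' of a unit absorber at grid pixel j.
#'
#' @slot entries a sparse \code{dgCMatrix}.
#' @slot grid the image grid.
#' @slot nElements,nSamples RF dimensions.
#' @exportClass SystemMatrix
setClass("SystemMatrix",
  representation(entries = "ANY", grid = "ReconGrid", nElements = "integer",
                 nSamples = "integer"))

#' Pixel-wise uncertainty maps
#'
#' @slot mean predictive mean image.
#' @slot std pixel-wise standard deviation (>= 0).
#' @slot nSamples number of inference samples.
#' @slot source "mc_dropout" or "acquisition_noise".
#' @exportClass UncertaintyMaps
setClass("UncertaintyMaps",
  representation(mean = "matrix", std = "matrix", nSamples = "integer",
                 source = "character"),
  validity = function(object) {
    msg <- NULL
    if (min(object@std) < 0) msg <- c(msg, "std must be >= 0")
    if (!all(dim(object@mean) == dim(object@std)))
      msg <- c(msg, "mean/std shape mismatch")
    if (!object@source %in% c("mc_dropout", "acquisition_noise"))
      msg <- c(msg, "unknown source")
    if (is.null(msg)) TRUE else msg
  })

#' Trained (or untrained) network
#'
#' @slot params named list of weight matrices/vectors, including batch-norm
#'   running statistics.
#' @slot spec the \linkS4class{UNetSpec}.
#' @slot inputSize side length of the square input.
#' @slot history per-epoch train/validation loss data.frame.
#' @slot provenance list of seeds/hashes sufficient to rerun.
#' @exportClass TrainedModel
setClass("TrainedModel",
  representation(params = "list", spec = "UNetSpec", inputSize = "integer",
                 history = "data.frame", provenance = "list"))

#' Paired image dataset
#'
#' Containers hold the network input (mBF image) and the ground-truth patch
#' per pair, with per-pair seeds and a train/val/test split.
#'
#' @slot input H x W x N array of max-|value|-normalized mBF images.
#' @slot target H x W x N array of max-normalized ground-truth patches.
#' @slot inputDmbf optional H x W x N array of dmBF envelopes (list() if
#'   absent).
#' @slot split character vector of "train"/"val"/"test" per pair.
#' @slot pairSeeds integer per-pair generator seeds.
#' @slot pitchUm pixel pitch.
#' @slot meta provenance list (configs, hashes).
#' @exportClass PADataset
setClass("PADataset",
  representation(input = "array", target = "array", inputDmbf = "ANY",
                 split = "character", pairSeeds = "integer",
                 pitchUm = "numeric", meta = "list"),
  validity = function(object) {
    msg <- NULL
    if (!all(dim(object@input) == dim(object@target)))
      msg <- c(msg, "input/target shape mismatch")
    if (length(object@split) != dim(object@input)[3])
      msg <- c(msg, "split length mismatch")
    if (is.null(msg)) TRUE else msg
  })

#' Test-set metrics report
#'
#' @slot perPair data.frame with one row per pair (ncc, sssim).
#' @slot meanNcc,sdNcc,meanSssim,sdSssim aggregates.
#' @exportClass MetricsReport
setClass("MetricsReport",
  representation(perPair = "data.frame", meanNcc = "numeric",
                 sdNcc = "numeric", meanSssim = "numeric",
                 sdSssim = "numeric"))

#' Similarity transform (rotation, translation, scale)
#'
#' @slot rotationDeg rotation about the image centre, degrees.
#' @slot translationMm (dx, dz) in mm.
#' @slot translationPx (dcol, drow) in pixels.
#' @slot scale isotropic scale factor (> 0).
#' @slot correlation Pearson correlation achieved at this transform.
#' @exportClass SimilarityTransform
setClass("SimilarityTransform",
  representation(rotationDeg = "numeric", translationMm = "numeric",
                 translationPx = "numeric", scale = "numeric",
                 correlation = "numeric"),
  validity = function(object)
    if (object@scale > 0) TRUE else "scale must be > 0")
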