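#' Build a paired (mBF image, ground-truth patch) dataset
#'
#' For each pair: generate a seeded branching phantom on the full field,
#' optionally apply a random augmentation (rotation, mirror, shear or centre
#' scaling), simulate the RF acquisition of the whole field (surrounding
#' structures outside the viewed patch still contribute clutter, as they do
#' in practice), beamform the mBF image on the patch grid, and pair it with
#' the ground-truth patch. Inputs are max-|value|-normalized, targets
#' max-normalized. Per-pair seeds are recorded so any pair can be
#' regenerated bit-identically.
#'
#' @param nPairs number of pairs.
#' @param config a \linkS4class{PhantomConfig} (its \code{seed} slot is
#'   ignored; per-pair seeds derive from \code{seed}).
#' @param probe a \linkS4class{ProbeGeometry}.
#' @param noise optional \linkS4class{NoiseConfig}.
#' @param seed master seed.
#' @param split integer(3) train/val/test sizes summing to \code{nPairs}.
#' @param augment apply a random augmentation to each field.
#' @param patchCenterMm patch centre; defaults to the field centre.
#' @param keepDmbf also store the dmBF envelope per pair (for input-type
#'   comparisons).
#' @param cSim,pulseFcScale,pulseBwScale forward-model perturbations for
#'   domain-shift experiments: true speed of sound during synthesis, and
#'   scale factors on the impulse-response centre frequency and bandwidth
#'   (reconstruction always assumes the nominal probe).
#' @param reconPitchUm pixel pitch of the reconstruction/network grid; when
#'   coarser than the phantom raster the ground-truth patch is mean-pooled
#'   by the integer ratio. The phantom raster itself must stay below half
#'   the acoustic wavelength (about 48 um at 15.6 MHz) for the discrete
#'   source superposition to behave like a continuum: coarser source
#'   spacings radiate through grating lobes and artificially weaken the
#'   limited-view artefact.
#' @return a \linkS4class{PADataset}.
#' @export
buildDataset <- function(nPairs, config = phantomConfig(),
                         probe = linearProbe(), noise = NULL, seed = 1L,
                         split = NULL, augment = TRUE, patchCenterMm = NULL,
                         keepDmbf = FALSE, cSim = NULL, pulseFcScale = 1,
                         pulseBwScale = 1, reconPitchUm = NULL) {
  stopifnot(nPairs >= 1)
  if (is.null(split)) split <- c(nPairs, 0L, 0L)
  if (sum(split) != nPairs) stop("split sizes must sum to nPairs")
  patchCenterMm <- patchCenterMm %||%
    c(0, config@zTopMm + config@fieldSizeMm / 2)
  reconPitchUm <- reconPitchUm %||% config@pixelPitchUm
  pool <- reconPitchUm / config@pixelPitchUm
  if (pool != round(pool))
    stop("reconPitchUm must be an integer multiple of the phantom pitch")
  n <- round(config@patchSizeMm * 1000 / reconPitchUm)
  grid <- reconGrid(patchCenterMm, config@patchSizeMm, reconPitchUm)
  pulse <- .perturbedPulse(probe, pulseFcScale, pulseBwScale)
  input <- array(0, c(n, n, nPairs))
  target <- array(0, c(n, n, nPairs))
  dmbf <- if (keepDmbf) array(0, c(n, n, nPairs)) else NULL
  pairSeeds <- integer(nPairs)
  for (i in seq_len(nPairs)) {
    ps <- .subSeed(seed, i)
    pairSeeds[i] <- ps
    cfg <- config
    cfg@seed <- ps
    ph <- generateBranchingPhantom(cfg)
    if (augment) {
      set.seed(.subSeed(ps, 1L))
      ph <- augmentMap(ph, .randomTransform())
      ph <- thresholdBackground(ph, 0.05)
    }
    rf <- simulateRF(ph, probe, noise = noise, cSim = cSim, pulse = pulse,
                     noiseSeed = if (!is.null(noise)) .subSeed(ps, 2L))
    mbf <- dasMBF(rf, grid, probe)
    input[, , i] <- maxNormalize(mbf@values, signed = TRUE)
    tv <- extractPatch(ph, patchCenterMm, config@patchSizeMm)@values
    if (pool > 1) tv <- .meanPool(tv, as.integer(pool))
    target[, , i] <- maxNormalize(tv)
    if (keepDmbf)
      dmbf[, , i] <- maxNormalize(dasDMBF(rf, grid, probe)@values)
  }
  new("PADataset", input = input, target = target,
      inputDmbf = if (keepDmbf) dmbf else list(),
      split = rep(c("train", "val", "test"), times = split),
      pairSeeds = pairSeeds, pitchUm = reconPitchUm,
      meta = list(seed = seed, nPairs = nPairs,
                  patchCenterMm = patchCenterMm,
                  augment = augment,
                  noiseSnr = if (is.null(noise)) Inf else noise@targetSnr,
                  cSim = cSim %||% probe@cMps,
                  pulseFcScale = pulseFcScale, pulseBwScale = pulseBwScale))
}

# block mean-pooling by an integer factor
.meanPool <- function(v, k) {
  n <- nrow(v) %/% k; m <- ncol(v) %/% k
  out <- matrix(0, n, m)
  for (i in seq_len(k)) for (j in seq_len(k))
    out <- out + v[seq(i, by = k, length.out = n),
                   seq(j, by = k, length.out = m)]
  out / k^2
}

.perturbedPulse <- function(probe, fcScale, bwScale) {
  if (fcScale == 1 && bwScale == 1) return(impulseResponse(probe))
  p2 <- probe
  p2@fcMHz <- probe@fcMHz * fcScale
  p2@fracBandwidth <- probe@fracBandwidth * bwScale
  impulseResponse(p2)
}

.randomTransform <- function() {
  type <- sample(c("rotation", "mirror", "shear", "center_scale"), 1)
  switch(type,
    rotation = list(type = "rotation", angle = stats::runif(1, 0, 360)),
    mirror = list(type = "mirror",
                  axis = sample(c("horizontal", "vertical"), 1)),
    shear = list(type = "shear",
                 axis = sample(c("horizontal", "vertical"), 1),
                 factor = stats::runif(1, -0.25, 0.25)),
    center_scale = list(type = "center_scale",
                        factor = stats::runif(1, 0.85, 1.18)))
}

#' Subset a dataset by pair indices
#'
#' @param dataset a \linkS4class{PADataset}.
#' @param idx pair indices to keep.
#' @param split optional replacement split labels for the subset.
#' @return a \linkS4class{PADataset}.
#' @export
subsetDataset <- function(dataset, idx, split = NULL) {
  new("PADataset",
      input = dataset@input[, , idx, drop = FALSE],
      target = dataset@target[, , idx, drop = FALSE],
      inputDmbf = if (is.array(dataset@inputDmbf))
        dataset@inputDmbf[, , idx, drop = FALSE] else list(),
      split = split %||% dataset@split[idx],
      pairSeeds = dataset@pairSeeds[idx],
      pitchUm = dataset@pitchUm,
      meta = c(dataset@meta, list(subsetOf = dataset@meta$seed)))
}

#' Serialize a dataset (or model) to disk
#'
#' Native R serialization; single images can be exchanged as TIFF via
#' \code{\link{exportTiff}}.
#'
#' @param x object to store.
#' @param path file path.
#' @return \code{path}, invisibly.
#' @export
writeDataset <- function(x, path) {
  saveRDS(x, path)
  invisible(path)
}

#' @rdname writeDataset
#' @export
readDataset <- function(path) readRDS(path)

#' Export an image raster as 16-bit-equivalent TIFF
#'
#' @param img matrix or image object; values are max-normalized to [0, 1].
#' @param path output file.
#' @return \code{path}, invisibly. Requires the \pkg{tiff} package.
#' @export
exportTiff <- function(img, path) {
  if (!requireNamespace("tiff", quietly = TRUE))
    stop("the 'tiff' package is required for TIFF export")
  v <- .asValues(img)
  v <- v - min(v)
  v <- maxNormalize(v)
  tiff::writeTIFF(v, path, bits.per.sample = 16L)
  invisible(path)
}
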