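#' Band-limited system impulse response
#'
#' Synthesizes a Gaussian-envelope sinusoid (Gabor pulse) at the probe's
#' central frequency with the requested -6 dB fractional bandwidth, sampled
#' at the acquisition rate. The pulse is exactly zero-mean (the missing DC is
#' what hollows out large absorbers: the limited-bandwidth artefact) and has
#' unit peak amplitude. The attribute \code{"center"} marks the sample that
#' arrives at t = r/c.
#'
#' @param probe a \linkS4class{ProbeGeometry}.
#' @return numeric waveform with attributes \code{center} (1-based index)
#'   and \code{fsMHz}.
#' @export
impulseResponse <- function(probe) {
  stopifnot(is(probe, "ProbeGeometry"))
  if (probe@fsMHz <= 2 * probe@fcMHz * (1 + probe@fracBandwidth / 2))
    stop("sampling criterion violated")
  # -6 dB full spectral width of a Gaussian envelope:
  # |G(f)| = exp(-2 pi^2 sigma^2 (f - fc)^2), width = sqrt(2 ln 2)/(pi sigma)
  sigma <- sqrt(2 * log(2)) / (pi * probe@fcMHz * probe@fracBandwidth)  # us
  nh <- ceiling(4 * sigma * probe@fsMHz)
  t <- (-nh:nh) / probe@fsMHz
  g <- cos(2 * pi * probe@fcMHz * t) * exp(-t^2 / (2 * sigma^2))
  g <- g - mean(g)
  g <- g / max(abs(g))
  attr(g, "center") <- nh + 1L
  attr(g, "fsMHz") <- probe@fsMHz
  g
}

.dirMode <- function(probe)
  switch(probe@directivity, none = 0L, cos = 1L, hard = 2L)

#' RF response of a single point source
#'
#' Each element receives the impulse response delayed by its travel time
#' r/c, scaled by the source amplitude, 2D geometric decay 1/sqrt(r), and
#' the element directivity.
#'
#' @param probe a \linkS4class{ProbeGeometry}.
#' @param srcMm (x, z) source position in mm; must lie in front of a linear
#'   probe (z > 0).
#' @param amplitude source amplitude.
#' @param pulse optional waveform overriding \code{impulseResponse(probe)}.
#' @return an \linkS4class{RFData}.
#' @export
pointSourceResponse <- function(probe, srcMm, amplitude = 1, pulse = NULL) {
  stopifnot(is(probe, "ProbeGeometry"))
  if (all(probe@positions[, 2] == 0) && srcMm[2] <= 0)
    stop("source behind the probe (z <= 0)")
  pulse <- pulse %||% impulseResponse(probe)
  sig <- cpp_simulate_rf(srcMm[1], srcMm[2], amplitude,
                         probe@positions[, 1], probe@positions[, 2],
                         probe@normals[, 1], probe@normals[, 2],
                         as.numeric(pulse), attr(pulse, "center"),
                         probe@fsMHz, probe@t0Us, probe@cMps,
                         probe@nSamples, .dirMode(probe), probe@cutoffDeg)
  rfData(sig, probe@fsMHz, probe@t0Us)
}

#' Simulate RF acquisition of a whole object
#'
#' Superposition of the point-source responses of every nonzero pixel of the
#' absorption map, optionally with calibrated additive noise.
#'
#' @param obj an \linkS4class{AbsorptionMap}.
#' @param probe a \linkS4class{ProbeGeometry}.
#' @param noise optional \linkS4class{NoiseConfig}.
#' @param cSim optional true propagation speed of sound (m/s) used for the
#'   synthesis only; reconstruction always uses \code{probe@cMps}. A mismatch
#'   emulates an unmodeled medium error.
#' @param pulse optional waveform overriding the probe impulse response.
#' @param noiseSeed optional seed overriding \code{noise@seed}.
#' @return an \linkS4class{RFData}; an empty object yields pure noise (or
#'   zeros).
#' @export
simulateRF <- function(obj, probe, noise = NULL, cSim = NULL, pulse = NULL,
                       noiseSeed = NULL) {
  stopifnot(is(obj, "AbsorptionMap"), is(probe, "ProbeGeometry"))
  pulse <- pulse %||% impulseResponse(probe)
  v <- obj@values
  nz <- which(v != 0)
  pitchMm <- obj@pitchUm / 1000
  if (length(nz) > 0) {
    rows <- (nz - 1) %% nrow(v) + 1
    cols <- (nz - 1) %/% nrow(v) + 1
    px <- obj@originMm[1] + (cols - 1) * pitchMm
    pz <- obj@originMm[2] + (rows - 1) * pitchMm
    sig <- cpp_simulate_rf(px, pz, v[nz],
                           probe@positions[, 1], probe@positions[, 2],
                           probe@normals[, 1], probe@normals[, 2],
                           as.numeric(pulse), attr(pulse, "center"),
                           probe@fsMHz, probe@t0Us, cSim %||% probe@cMps,
                           probe@nSamples, .dirMode(probe), probe@cutoffDeg)
  } else {
    sig <- matrix(0, nrow(probe@positions), probe@nSamples)
  }
  rf <- rfData(sig, probe@fsMHz, probe@t0Us)
  if (!is.null(noise)) rf <- addNoise(rf, noise, probe = probe,
                                      seed = noiseSeed)
  rf
}

#' Peak RF amplitude of the horizontal-structure reference
#'
#' The SNR of the acquisition is defined against signals produced by
#' horizontal structures (the fully visible ones). This computes the peak
#' |RF| of a horizontal bar at mid-depth under the given probe, used to
#' calibrate the additive-noise standard deviation.
#'
#' @param probe a \linkS4class{ProbeGeometry}.
#' @param depthMm bar depth; defaults to the 15 mm reference mid-depth of
#'   the standard imaging geometry, or to the middle of the acquisition
#'   window when the window is too short to cover it.
#' @param lengthMm,thicknessMm bar extent.
#' @param pitchUm rasterization pitch of the calibration bar.
#' @return peak absolute RF amplitude (per unit absorber value).
#' @export
calibrationAmplitude <- function(probe, depthMm = NULL, lengthMm = 2.5,
                                 thicknessMm = 0.16, pitchUm = 80) {
  maxDepthMm <- probe@cMps / 1000 * (probe@t0Us + probe@nSamples / probe@fsMHz)
  depthMm <- depthMm %||% (if (maxDepthMm > 1.3 * 15) 15 else maxDepthMm / 2)
  pitchMm <- pitchUm / 1000
  nc <- max(2, round(lengthMm / pitchMm))
  nr <- max(1, round(thicknessMm / pitchMm))
  bar <- absorptionMap(matrix(1, nr, nc), pitchUm,
                       c(-lengthMm / 2, depthMm - thicknessMm / 2))
  rf <- simulateRF(bar, probe)
  max(abs(rf@signals))
}

#' Add calibrated white Gaussian noise to RF data
#'
#' Noise std = (calibration amplitude) / targetSnr, where the calibration
#' amplitude is the peak RF of the horizontal reference bar (computed from
#' \code{probe} unless supplied).
#'
#' @param rf an \linkS4class{RFData}.
#' @param noise a \linkS4class{NoiseConfig}.
#' @param calibration optional precomputed calibration amplitude.
#' @param probe probe used to compute the calibration when missing.
#' @param seed optional seed overriding \code{noise@seed}.
#' @return noisy \linkS4class{RFData}; an infinite \code{targetSnr} returns
#'   the input unchanged.
#' @export
addNoise <- function(rf, noise, calibration = NULL, probe = NULL,
                     seed = NULL) {
  stopifnot(is(rf, "RFData"), is(noise, "NoiseConfig"))
  if (!is.finite(noise@targetSnr)) return(rf)
  if (is.null(calibration)) {
    if (is.null(probe)) stop("supply either 'calibration' or 'probe'")
    calibration <- .calibCached(probe)
  }
  sd <- calibration / noise@targetSnr
  set.seed(seed %||% noise@seed)
  sig <- rf@signals + matrix(stats::rnorm(length(rf@signals), 0, sd),
                             nrow(rf@signals))
  rfData(sig, rf@fsMHz, rf@t0Us)
}

# calibration amplitude depends only on the probe; memoize on its hash
.calibEnv <- new.env(parent = emptyenv())
.calibCached <- function(probe) {
  key <- paste(format(c(probe@fcMHz, probe@fracBandwidth, probe@fsMHz,
                        probe@cMps, probe@nSamples, probe@t0Us,
                        nrow(probe@positions),
                        probe@positions[1, ], probe@positions[2, 2]),
                      digits = 12), collapse = "|")
  if (is.null(.calibEnv[[key]]))
    .calibEnv[[key]] <- calibrationAmplitude(probe)
  .calibEnv[[key]]
}

#' Materialize the propagation matrix A
#'
#' Column j of A is the vectorized (column-major element x sample) RF
#' response of a unit absorber at grid pixel j; A %*% vec(X) equals the
#' noiseless \code{simulateRF} of X on the grid. Stored sparse; intended for
#' deconvolution-scale grids only.
#'
#' @param probe a \linkS4class{ProbeGeometry}.
#' @param grid a \linkS4class{ReconGrid}.
#' @param maxEntries guard on the number of stored nonzeros.
#' @return a \linkS4class{SystemMatrix}.
#' @export
buildSystemMatrix <- function(probe, grid, maxEntries = 1e8) {
  stopifnot(is(probe, "ProbeGeometry"), is(grid, "ReconGrid"))
  pulse <- impulseResponse(probe)
  npix <- length(grid@zMm) * length(grid@xMm)
  est <- as.double(npix) * nrow(probe@positions) * length(pulse)
  if (est > maxEntries)
    stop("system matrix too large (", format(est, big.mark = ","),
         " potential entries); coarsen the grid")
  # pixel order column-major in (z, x): rows = z, cols = x
  px <- rep(grid@xMm, each = length(grid@zMm))
  pz <- rep(grid@zMm, times = length(grid@xMm))
  tri <- cpp_system_triplets(px, pz,
                             probe@positions[, 1], probe@positions[, 2],
                             probe@normals[, 1], probe@normals[, 2],
                             as.numeric(pulse), attr(pulse, "center"),
                             probe@fsMHz, probe@t0Us, probe@cMps,
                             probe@nSamples, .dirMode(probe), probe@cutoffDeg)
  A <- Matrix::sparseMatrix(i = tri$i, j = tri$j, x = tri$x,
                            dims = c(nrow(probe@positions) * probe@nSamples,
                                     npix))
  new("SystemMatrix", entries = A, grid = grid,
      nElements = nrow(probe@positions), nSamples = probe@nSamples)
}
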