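#' Extract the pixel raster of an image-like object
#'
#' @param x an \linkS4class{AbsorptionMap}, \linkS4class{ReconImage} or
#'   \linkS4class{UncertaintyMaps} (returns the mean map).
#' @return a numeric matrix.
#' @export
setGeneric("values", function(x) standardGeneric("values"))

#' @rdname values
#' @export
setMethod("values", "AbsorptionMap", function(x) x@values)

#' @rdname values
#' @export
setMethod("values", "ReconImage", function(x) x@values)

#' @rdname values
#' @export
setMethod("values", "UncertaintyMaps", function(x) x@mean)

#' Pixel pitch in micrometres
#'
#' @param x an object carrying a metric grid.
#' @return pitch in micrometres.
#' @export
setGeneric("pixelPitch", function(x) standardGeneric("pixelPitch"))

#' @rdname pixelPitch
#' @export
setMethod("pixelPitch", "AbsorptionMap", function(x) x@pitchUm)

#' @rdname pixelPitch
#' @export
setMethod("pixelPitch", "ReconGrid", function(x) x@pitchUm)

#' @rdname pixelPitch
#' @export
setMethod("pixelPitch", "ReconImage", function(x) x@grid@pitchUm)

#' RF signal matrix accessor
#'
#' @param x an \linkS4class{RFData}.
#' @return the nElements x nSamples matrix.
#' @export
setGeneric("signals", function(x) standardGeneric("signals"))

#' @rdname signals
#' @export
setMethod("signals", "RFData", function(x) x@signals)

#' Number of trainable parameters of a network
#'
#' Sums the lengths of all trainable weight arrays (convolution kernels,
#' biases, batch-norm scale and shift); batch-norm running statistics are
#' excluded.
#'
#' @param x a \linkS4class{TrainedModel} or \linkS4class{UNetSpec}.
#' @param ... unused.
#' @return integer-valued numeric count.
#' @export
setGeneric("paramCount", function(x, ...) standardGeneric("paramCount"))

setMethod("show", "AbsorptionMap", function(object) {
  d <- dim(object@values)
  cat(sprintf("AbsorptionMap %d x %d px @ %g um (%.2f x %.2f mm)\n",
              d[1], d[2], object@pitchUm, d[1] * object@pitchUm / 1000,
              d[2] * object@pitchUm / 1000))
  cat(sprintf("  origin (x, z) = (%.2f, %.2f) mm, foreground %.1f%%\n",
              object@originMm[1], object@originMm[2],
              100 * mean(object@values > 0)))
})

setMethod("show", "RFData", function(object) {
  d <- dim(object@signals)
  cat(sprintf("RFData: %d elements x %d samples @ %g MHz (t0 = %g us)\n",
              d[1], d[2], object@fsMHz, object@t0Us))
})

setMethod("show", "ReconImage", function(object) {
  d <- dim(object@values)
  cat(sprintf("ReconImage [%s] %d x %d px @ %g um, range [%.3g, %.3g]\n",
              object@kind, d[1], d[2], object@grid@pitchUm,
              min(object@values), max(object@values)))
})

setMethod("show", "ProbeGeometry", function(object) {
  cat(sprintf(
    "ProbeGeometry: %d elements, fc %g MHz (bw %g), fs %g MHz, c %g m/s\n",
    nrow(object@positions), object@fcMHz, object@fracBandwidth, object@fsMHz,
    object@cMps))
})

setMethod("show", "TrainedModel", function(object) {
  cat(sprintf(
    "TrainedModel: depth %d, base %d filters, %d x %d input, %s params\n",
    object@spec@depth, object@spec@baseFilters, object@inputSize,
    object@inputSize, format(paramCount(object), big.mark = ",")))
  if (nrow(object@history) > 0)
    cat(sprintf("  trained %d epochs, best val loss %.3g (epoch %d)\n",
                max(object@history$epoch),
                min(object@history$valLoss),
                object@history$epoch[which.min(object@history$valLoss)]))
  else cat("  untrained\n")
})

setMethod("show", "PADataset", function(object) {
  d <- dim(object@input)
  cat(sprintf("PADataset: %d pairs of %d x %d images (%s)\n", d[3], d[1],
              d[2], paste(sprintf("%s=%d", names(table(object@split)),
                                  table(object@split)), collapse = ", ")))
})

setMethod("show", "MetricsReport", function(object) {
  cat(sprintf("MetricsReport over %d pairs: NCC %.3f +/- %.3f, sSSIM %.3f +/- %.3f\n",
              nrow(object@perPair), object@meanNcc, object@sdNcc,
              object@meanSssim, object@sdSssim))
})

setMethod("show", "SimilarityTransform", function(object) {
  cat(sprintf(
    "SimilarityTransform: rot %.2f deg, shift (%.2f, %.2f) px, scale %.3f (r = %.3f)\n",
    object@rotationDeg, object@translationPx[1], object@translationPx[2],
    object@scale, object@correlation))
})

setMethod("show", "UncertaintyMaps", function(object) {
  cat(sprintf("UncertaintyMaps [%s] over %d samples, max std %.3g\n",
              object@source, object@nSamples, max(object@std)))
})
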