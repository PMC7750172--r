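#' Normalize an image by its maximum
#'
#' Images are compared after max-normalization (no quantitative scale is
#' expected from the reconstruction). An all-zero image is returned as is.
#'
#' @param x numeric matrix/array.
#' @return x divided by \code{max(x)} (or \code{max(abs(x))} for signed
#'   data when \code{signed = TRUE}).
#' @param signed normalize by the maximum absolute value instead.
#' @export
maxNormalize <- function(x, signed = FALSE) {
  m <- if (signed) max(abs(x)) else max(x)
  if (m > 0) x / m else x
}

`%||%` <- function(a, b) if (is.null(a)) b else a

.asValues <- function(x) {
  if (is(x, "AbsorptionMap") || is(x, "ReconImage")) x@values
  else if (is(x, "UncertaintyMaps")) x@mean
  else if (is.matrix(x)) x
  else stop("expected an image-like object or matrix")
}

# deterministic small sub-seed derived from a master seed, kept < 2^31
.subSeed <- function(seed, k) {
  as.integer((as.double(seed) * 7919 + k * 104729) %% 2147483647)
}
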