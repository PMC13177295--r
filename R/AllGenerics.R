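NULL

#' @rdname SpectralAxis-class
#' @param x a \linkS4class{SpectralAxis} (or object carrying one)
#' @export
setGeneric("wavenumbers", function(x) standardGeneric("wavenumbers"))

#' @rdname SpectralAxis-class
#' @export
setGeneric("axisStep", function(x) standardGeneric("axisStep"))

#' @rdname HyperspectralCube-class
#' @export
setGeneric("cubeData", function(x) standardGeneric("cubeData"))

#' @rdname HyperspectralCube-class
#' @export
setGeneric("cubeMeta", function(x) standardGeneric("cubeMeta"))

#' @rdname HyperspectralCube-class
#' @export
setGeneric("spectralAxis", function(x) standardGeneric("spectralAxis"))

#' @rdname TissueMask-class
#' @export
setGeneric("maskMatrix", function(x) standardGeneric("maskMatrix"))

#' @rdname TissueMask-class
#' @export
setGeneric("maskThreshold", function(x) standardGeneric("maskThreshold"))

#' @rdname BackgroundModel-class
#' @export
setGeneric("backgroundSpectrum", function(x) standardGeneric("backgroundSpectrum"))

#' @rdname BackgroundModel-class
#' @export
setGeneric("backgroundSigma", function(x) standardGeneric("backgroundSigma"))

#' @rdname PixelSpectrumSet-class
#' @export
setGeneric("pixelSpectra", function(x) standardGeneric("pixelSpectra"))

#' @rdname PixelSpectrumSet-class
#' @export
setGeneric("pixelCoords", function(x) standardGeneric("pixelCoords"))

#' @rdname SecondDerivSpectrum-class
#' @export
setGeneric("derivValues", function(x) standardGeneric("derivValues"))

#' Rubberband (convex-hull) baseline correction
#'
#' Subtracts the lower convex hull of the spectrum, removing broad
#' scattering backgrounds while leaving band structure intact.
#'
#' @param x numeric spectrum, or a matrix of spectra (rows = spectra)
#' @param axis a \linkS4class{SpectralAxis}
#' @return for a vector, a list with `values` (corrected spectrum) and
#'   `baseline`; for a matrix, a list of two conformable matrices.
#' @export
setGeneric("rubberbandBaseline", function(x, axis) standardGeneric("rubberbandBaseline"))

#' @rdname savgolSecondDerivative
#' @export
setGeneric("savgolSecondDerivative",
  function(x, axis, window = 13L, polyorder = 2L, trimPerSide = 13L)
    standardGeneric("savgolSecondDerivative"))
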