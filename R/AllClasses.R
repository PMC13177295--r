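#' @include AllGenerics.R
NULL

#' Spectral axis
#'
#' An ordered, uniformly spaced wavenumber grid (cm^-1) shared by all
#' spectra and hyperspectral cubes in a study. The instrument acquires the
#' fingerprint region 950--1800 cm^-1 at 2 cm^-1 resolution, giving the
#' canonical 426-point axis.
#'
#' @slot values numeric, strictly increasing, uniformly spaced wavenumbers
#' @slot step grid spacing in cm^-1
#'
#' @examples
#' ax <- SpectralAxis(950, 1800, 2)
#' length(wavenumbers(ax))  # 426
#' @name SpectralAxis-class
#' @aliases SpectralAxis-class wavenumbers axisStep
#' @export
setClass("SpectralAxis",
  representation(values = "numeric", step = "numeric"))

setValidity("SpectralAxis", function(object) {
  v <- object@values
  if (length(v) < 2L) return("axis needs at least 2 points")
  if (any(!is.finite(v))) return("axis values must be finite")
  d <- diff(v)
  if (any(d <= 0)) return("axis must be strictly increasing")
  if (max(abs(d - object@step)) > 1e-9)
    return("axis spacing must be uniform and equal to 'step' within 1e-9")
  TRUE
})

#' Hyperspectral absorbance cube
#'
#' A rows x cols x K absorbance image stack with its wavenumber axis and
#' provenance labels (tissue, preparation protocol, ROI id). One cube holds
#' one acquired region of interest.
#'
#' @slot data numeric array, rows x cols x K absorbance
#' @slot axis the shared \linkS4class{SpectralAxis} (length K)
#' @slot meta named list: `tissue`, `preparation`, `roi_id`
#' @name HyperspectralCube-class
#' @aliases HyperspectralCube-class cubeData cubeMeta spectralAxis
#' @export
setClass("HyperspectralCube",
  representation(data = "array", axis = "SpectralAxis", meta = "list"))

setValidity("HyperspectralCube", function(object) {
  d <- dim(object@data)
  if (length(d) != 3L) return("cube data must be a 3-d array (rows x cols x K)")
  if (d[3L] != length(object@axis@values))
    return("third dimension must equal the axis length")
  if (any(!is.finite(object@data))) return("cube values must all be finite")
  TRUE
})

#' Tissue mask
#'
#' Boolean tissue/background segmentation of one ROI, produced by Otsu
#' thresholding of a single-wavenumber absorbance image, together with the
#' threshold that was applied.
#'
#' @slot mask logical rows x cols matrix; TRUE = tissue
#' @slot threshold absorbance threshold actually used
#' @slot bandWn wavenumber (cm^-1) of the image the threshold was taken on
#' @name TissueMask-class
#' @aliases TissueMask-class maskMatrix maskThreshold
#' @export
setClass("TissueMask",
  representation(mask = "matrix", threshold = "numeric", bandWn = "numeric"))

setValidity("TissueMask", function(object) {
  if (!is.logical(object@mask)) return("mask must be logical")
  if (all(object@mask) || !any(object@mask))
    return("degenerate mask: all-tissue or all-background")
  TRUE
})

#' Background noise model
#'
#' The mean off-tissue spectrum of an ROI and the noise scale sigma used by
#' the 3-sigma dip-detection rule: sigma is the population standard
#' deviation of the Savitzky-Golay second derivative of that mean spectrum,
#' evaluated on the edge-trimmed wavenumber range.
#'
#' @slot meanSpectrum mean absorbance over off-tissue pixels (full axis)
#' @slot sigma noise scale of the second-derivative spectra
#' @slot nPixels number of background pixels averaged
#' @name BackgroundModel-class
#' @aliases BackgroundModel-class backgroundSpectrum backgroundSigma
#' @export
setClass("BackgroundModel",
  representation(meanSpectrum = "numeric", sigma = "numeric",
                 nPixels = "integer"))

setValidity("BackgroundModel", function(object) {
  if (length(object@sigma) != 1L || !is.finite(object@sigma) || object@sigma <= 0)
    return("sigma must be a single positive finite value")
  TRUE
})

#' Sampled pixel spectra
#'
#' A reproducible random sample of tissue pixels from one or more ROIs,
#' stored as a spectra matrix plus pixel coordinates. Sampling is uniform
#' without replacement within the tissue mask.
#'
#' @slot spectra numeric matrix, one row per sampled pixel, K columns
#' @slot coords data.frame with `roi_id`, `row`, `col`
#' @slot axis the shared \linkS4class{SpectralAxis}
#' @slot seed integer seed the sample was drawn with
#' @name PixelSpectrumSet-class
#' @aliases PixelSpectrumSet-class pixelSpectra pixelCoords
#' @export
setClass("PixelSpectrumSet",
  representation(spectra = "matrix", coords = "data.frame",
                 axis = "SpectralAxis", seed = "integer"))

setValidity("PixelSpectrumSet", function(object) {
  if (nrow(object@spectra) != nrow(object@coords))
    return("one coordinate row per spectrum required")
  if (ncol(object@spectra) != length(object@axis@values))
    return("spectra must have one column per axis point")
  if (anyDuplicated(object@coords[, c("roi_id", "row", "col")]))
    return("duplicate pixel coordinates")
  TRUE
})

#' Second-derivative spectra
#'
#' Savitzky-Golay second derivatives (with respect to wavenumber) on the
#' edge-trimmed axis. Absorbance maxima appear as negative dips.
#'
#' @slot values numeric matrix (rows = spectra) of second-derivative values
#' @slot axis trimmed \linkS4class{SpectralAxis}
#' @slot params list recording window, polyorder and trim actually used
#' @name SecondDerivSpectrum-class
#' @aliases SecondDerivSpectrum-class derivValues
#' @export
setClass("SecondDerivSpectrum",
  representation(values = "matrix", axis = "SpectralAxis", params = "list"))

setValidity("SecondDerivSpectrum", function(object) {
  if (ncol(object@values) != length(object@axis@values))
    return("values must have one column per trimmed axis point")
  TRUE
})

## ----- accessors and show methods -------------------------------------------

#' @rdname SpectralAxis-class
#' @export
setMethod("wavenumbers", "SpectralAxis", function(x) x@values)

#' @rdname SpectralAxis-class
#' @export
setMethod("axisStep", "SpectralAxis", function(x) x@step)

#' @export
setMethod("length", "SpectralAxis", function(x) length(x@values))

setMethod("show", "SpectralAxis", function(object) {
  v <- object@values
  cat(sprintf("SpectralAxis: %g..%g cm^-1, step %g (%d points)\n",
              v[1L], v[length(v)], object@step, length(v)))
})

#' @rdname HyperspectralCube-class
#' @export
setMethod("cubeData", "HyperspectralCube", function(x) x@data)

#' @rdname HyperspectralCube-class
#' @export
setMethod("cubeMeta", "HyperspectralCube", function(x) x@meta)

#' @rdname HyperspectralCube-class
#' @export
setMethod("spectralAxis", "HyperspectralCube", function(x) x@axis)

#' @rdname PixelSpectrumSet-class
#' @export
setMethod("spectralAxis", "PixelSpectrumSet", function(x) x@axis)

#' @rdname SecondDerivSpectrum-class
#' @export
setMethod("spectralAxis", "SecondDerivSpectrum", function(x) x@axis)

setMethod("show", "HyperspectralCube", function(object) {
  d <- dim(object@data)
  m <- object@meta
  cat(sprintf("HyperspectralCube: %d x %d pixels x %d wavenumbers\n",
              d[1L], d[2L], d[3L]))
  cat(sprintf("  tissue=%s preparation=%s roi_id=%s\n",
              m$tissue %||% "?", m$preparation %||% "?", m$roi_id %||% "?"))
})

#' @rdname TissueMask-class
#' @export
setMethod("maskMatrix", "TissueMask", function(x) x@mask)

#' @rdname TissueMask-class
#' @export
setMethod("maskThreshold", "TissueMask", function(x) x@threshold)

setMethod("show", "TissueMask", function(object) {
  cat(sprintf("TissueMask: %d x %d, %d tissue pixels (%.1f%%), Otsu threshold %.4g at %g cm^-1\n",
              nrow(object@mask), ncol(object@mask), sum(object@mask),
              100 * mean(object@mask), object@threshold, object@bandWn))
})

#' @rdname BackgroundModel-class
#' @export
setMethod("backgroundSpectrum", "BackgroundModel", function(x) x@meanSpectrum)

#' @rdname BackgroundModel-class
#' @export
setMethod("backgroundSigma", "BackgroundModel", function(x) x@sigma)

setMethod("show", "BackgroundModel", function(object) {
  cat(sprintf("BackgroundModel: sigma = %.4g (from %d background pixels)\n",
              object@sigma, object@nPixels))
})

#' @rdname PixelSpectrumSet-class
#' @export
setMethod("pixelSpectra", "PixelSpectrumSet", function(x) x@spectra)

#' @rdname PixelSpectrumSet-class
#' @export
setMethod("pixelCoords", "PixelSpectrumSet", function(x) x@coords)

setMethod("show", "PixelSpectrumSet", function(object) {
  cat(sprintf("PixelSpectrumSet: %d spectra x %d wavenumbers from %d ROI(s), seed %d\n",
              nrow(object@spectra), ncol(object@spectra),
              length(unique(object@coords$roi_id)), object@seed))
})

#' @rdname SecondDerivSpectrum-class
#' @export
setMethod("derivValues", "SecondDerivSpectrum", function(x) x@values)

setMethod("show", "SecondDerivSpectrum", function(object) {
  cat(sprintf("SecondDerivSpectrum: %d spectra on trimmed axis %g..%g cm^-1 (%d points)\n",
              nrow(object@values), min(object@axis@values),
              max(object@axis@values), length(object@axis@values)))
})

`%||%` <- function(a, b) if (is.null(a)) b else a
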