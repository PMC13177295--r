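## Tissue segmentation, background noise model, pixel sampling.

#' Otsu threshold of a single-band image
#'
#' Computes the threshold maximizing the between-class variance over a
#' 256-bin histogram of the values (the classic Otsu formulation).
#' Candidate thresholds are the interior bin boundaries. When the variance
#' curve has a plateau of tied maxima (an empty gap between two well
#' separated modes), the plateau midpoint is returned, following the
#' classic implementations.
#'
#' @param values numeric vector or matrix with at least two distinct values
#' @param nbins histogram bins (default 256)
#' @return the threshold on the data scale
#' @export
otsuThreshold <- function(values, nbins = 256L) {
  v <- as.numeric(values)
  v <- v[is.finite(v)]
  if (length(unique(v)) < 2L) stop("constant image: Otsu threshold undefined")
  lo <- min(v); hi <- max(v)
  edges <- seq(lo, hi, length.out = nbins + 1L)
  counts <- tabulate(pmin(pmax(findInterval(v, edges, rightmost.closed = TRUE),
                               1L), nbins), nbins)
  mids <- (edges[-1L] + edges[-(nbins + 1L)]) / 2
  w <- cumsum(counts)
  mu <- cumsum(counts * mids)
  n <- w[nbins]; muT <- mu[nbins]
  # between-class variance at each interior boundary t (classes: bins <= t)
  w0 <- w[-nbins]; w1 <- n - w0
  valid <- w0 > 0 & w1 > 0
  bcv <- rep(-Inf, nbins - 1L)
  bcv[valid] <- (muT * w0[valid] - n * mu[-nbins][valid])^2 /
    (as.numeric(w0[valid]) * w1[valid])
  if (!any(is.finite(bcv))) stop("constant image: Otsu threshold undefined")
  mx <- max(bcv)
  tie <- which(bcv >= mx - 1e-12 * max(1, abs(mx)))
  (edges[min(tie) + 1L] + edges[max(tie) + 1L]) / 2
}

#' Segment tissue from background
#'
#' Thresholds the absorbance image at a single wavenumber (nearest grid
#' point; default 1608 cm^-1, on the amide I flank where tissue contrast is
#' strongest) with [otsuThreshold()]. By convention tissue is the
#' high-absorbance class; set `invert = TRUE` for inverted-contrast data.
#'
#' @param cube a \linkS4class{HyperspectralCube}
#' @param bandWn masking wavenumber in cm^-1
#' @param invert tissue is the low-absorbance class
#' @return a \linkS4class{TissueMask}
#' @export
makeTissueMask <- function(cube, bandWn = 1608, invert = FALSE) {
  k <- nearestIndex(spectralAxis(cube), bandWn)
  img <- cubeData(cube)[, , k]
  thr <- otsuThreshold(img)
  m <- if (invert) img <= thr else img > thr
  new("TissueMask", mask = m, threshold = thr,
      bandWn = wavenumbers(spectralAxis(cube))[k])
}

#' Background noise model of an ROI
#'
#' Averages the off-tissue (discarded) pixels into a background spectrum,
#' takes its Savitzky-Golay second derivative, and sets sigma to the
#' population standard deviation of that derivative over the edge-trimmed
#' range. Significant dips in tissue second-derivative spectra are then
#' those below `-3 * sigma`.
#'
#' @param cube a \linkS4class{HyperspectralCube}
#' @param mask a \linkS4class{TissueMask} (or logical matrix); background =
#'   off-mask pixels, at least 50 required
#' @param window,polyorder,trimPerSide Savitzky-Golay parameters, see
#'   [savgolSecondDerivative()]
#' @return a \linkS4class{BackgroundModel}
#' @export
computeBackground <- function(cube, mask, window = 13L, polyorder = 2L,
                              trimPerSide = 13L) {
  m <- if (is(mask, "TissueMask")) maskMatrix(mask) else mask
  d <- cubeData(cube)
  if (!identical(dim(m), dim(d)[1:2])) stop("mask shape does not match cube")
  bgIdx <- which(!m)
  if (length(bgIdx) == 0L) stop("mask complement is empty")
  if (length(bgIdx) < 50L)
    stop(sprintf("only %d background pixels (need >= 50); use a larger ROI",
                 length(bgIdx)))
  K <- dim(d)[3L]
  flat <- matrix(d, nrow = prod(dim(d)[1:2]), ncol = K)
  meanSpec <- colMeans(flat[bgIdx, , drop = FALSE])
  d2 <- savgolSecondDerivative(meanSpec, spectralAxis(cube), window = window,
                               polyorder = polyorder,
                               trimPerSide = trimPerSide)
  v <- derivValues(d2)[1L, ]
  sigma <- sqrt(mean((v - mean(v))^2))  # population sd, n is large and fixed
  if (!is.finite(sigma) || sigma < 1e-12)
    stop("degenerate noise: background second derivative has (near-)zero spread")
  new("BackgroundModel", meanSpectrum = meanSpec, sigma = sigma,
      nPixels = length(bgIdx))
}

#' Sample tissue pixels reproducibly
#'
#' Uniform sampling without replacement from the tissue mask; the default
#' study design draws 2000 pixels per ROI (16 000 spectra per sample type across
#' 8 ROIs).
#'
#' @param cube a \linkS4class{HyperspectralCube}
#' @param mask a \linkS4class{TissueMask} or logical matrix
#' @param n number of pixels (default 2000); must not exceed the tissue
#'   pixel count. `n` equal to the tissue count returns every tissue pixel.
#' @param seed integer seed; identical seeds give identical coordinate sets
#' @return a \linkS4class{PixelSpectrumSet}
#' @export
samplePixels <- function(cube, mask, n = 2000L, seed = 1L) {
  m <- if (is(mask, "TissueMask")) maskMatrix(mask) else mask
  d <- cubeData(cube)
  if (!identical(dim(m), dim(d)[1:2])) stop("mask shape does not match cube")
  tIdx <- which(m)
  if (n > length(tIdx))
    stop(sprintf("requested %d pixels but mask has only %d tissue pixels",
                 n, length(tIdx)))
  sel <- withSeed(seed, sort(sample(tIdx, n)))
  nr <- dim(d)[1L]
  rows <- ((sel - 1L) %% nr) + 1L
  cols <- ((sel - 1L) %/% nr) + 1L
  flat <- matrix(d, nrow = prod(dim(d)[1:2]), ncol = dim(d)[3L])
  roiId <- cubeMeta(cube)$roi_id %||% "roi"
  new("PixelSpectrumSet",
      spectra = flat[sel, , drop = FALSE],
      coords = data.frame(roi_id = roiId, row = rows, col = cols,
                          stringsAsFactors = FALSE),
      axis = spectralAxis(cube), seed = as.integer(seed))
}
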