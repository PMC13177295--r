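## Per-spectrum preprocessing: rubberband baseline, Savitzky-Golay second
## derivative with edge trimming, Z-score normalization.

# lower convex hull (Andrew's monotone chain) of points with ascending x;
# returns indices of hull vertices, always including both endpoints
lowerHullIndices <- function(x, y) {
  n <- length(x)
  hull <- integer(n)
  h <- 0L
  for (i in seq_len(n)) {
    while (h >= 2L) {
      # pop while the turn p[h-1] -> p[h] -> i is not strictly convex (up):
      # lower-hull slopes must strictly increase (counter-clockwise turns)
      cross <- (x[hull[h]] - x[hull[h - 1L]]) * (y[i] - y[hull[h - 1L]]) -
               (y[hull[h]] - y[hull[h - 1L]]) * (x[i] - x[hull[h - 1L]])
      if (cross > 0) break
      h <- h - 1L
    }
    h <- h + 1L
    hull[h] <- i
  }
  hull[seq_len(h)]
}

rubberbandOne <- function(y, wn) {
  if (any(!is.finite(y))) stop("rubberband: spectrum contains NaN/Inf")
  idx <- lowerHullIndices(wn, y)
  base <- stats::approx(wn[idx], y[idx], xout = wn, method = "linear")$y
  corr <- y - base
  corr[idx] <- 0  # contacts are exactly zero
  corr[corr < 0 & corr > -1e-12] <- 0
  list(values = corr, baseline = base)
}

#' @rdname rubberbandBaseline
#' @export
setMethod("rubberbandBaseline", signature(x = "numeric", axis = "SpectralAxis"),
  function(x, axis) {
    if (length(x) < 3L) stop("rubberband needs at least 3 points")
    rubberbandOne(x, wavenumbers(axis))
  })

#' @rdname rubberbandBaseline
#' @export
setMethod("rubberbandBaseline", signature(x = "matrix", axis = "SpectralAxis"),
  function(x, axis) {
    wn <- wavenumbers(axis)
    if (ncol(x) != length(wn)) stop("spectra/axis length mismatch")
    vals <- x; base <- x
    for (i in seq_len(nrow(x))) {
      r <- rubberbandOne(x[i, ], wn)
      vals[i, ] <- r$values
      base[i, ] <- r$baseline
    }
    list(values = vals, baseline = base)
  })

#' @rdname rubberbandBaseline
#' @export
setMethod("rubberbandBaseline",
  signature(x = "PixelSpectrumSet", axis = "missing"),
  function(x, axis) {
    r <- rubberbandBaseline(pixelSpectra(x), spectralAxis(x))
    initialize(x, spectra = r$values)
  })

# central Savitzky-Golay convolution coefficients for the m-th derivative
savgolCoef <- function(window, polyorder, m, step) {
  half <- (window - 1L) %/% 2L
  j <- (-half):half
  A <- outer(j * step, 0:polyorder, `^`)
  # least-squares polynomial fit; derivative m at the window center
  coefs <- solve(crossprod(A), t(A))
  factorial(m) * coefs[m + 1L, ]
}

#' Savitzky-Golay second derivative with edge trimming
#'
#' Smoothing second derivative with respect to wavenumber (window 13 points,
#' polynomial order 2 by default). One full window length is trimmed from
#' each end to discard edge effects, so the default on the 426-point axis
#' yields 400 points (26 removed).
#'
#' @param x numeric spectrum, matrix of spectra (rows = spectra), or a
#'   \linkS4class{PixelSpectrumSet}
#' @param axis the \linkS4class{SpectralAxis} of `x` (taken from the object
#'   for a `PixelSpectrumSet`)
#' @param window odd filter length (grid points)
#' @param polyorder polynomial order, `< window`
#' @param trimPerSide points dropped from each end
#' @return a \linkS4class{SecondDerivSpectrum}
#' @export
#' @rdname savgolSecondDerivative
setMethod("savgolSecondDerivative",
  signature(x = "matrix", axis = "SpectralAxis"),
  function(x, axis, window = 13L, polyorder = 2L, trimPerSide = 13L) {
    K <- length(axis)
    if (ncol(x) != K) stop("spectra/axis length mismatch")
    if (window %% 2L != 1L) stop("window must be odd")
    if (polyorder >= window) stop("polyorder must be smaller than window")
    if (polyorder < 2L) stop("polyorder must be >= 2 for a second derivative")
    if (K <= window + 2L * trimPerSide)
      stop("spectrum too short for this window and trim")
    half <- (window - 1L) %/% 2L
    if (trimPerSide < half)
      stop("trimPerSide must be at least the half window length")
    cf <- savgolCoef(window, polyorder, 2L, axisStep(axis))
    keep <- (trimPerSide + 1L):(K - trimPerSide)
    # banded operator: d2[, i] = sum_j cf[j] * x[, keep[i] - half - 1 + j]
    D <- matrix(0, K, length(keep))
    for (j in seq_len(window))
      D[cbind(keep - half - 1L + j, seq_along(keep))] <- cf[j]
    new("SecondDerivSpectrum", values = x %*% D, axis = trimAxis(axis, trimPerSide),
        params = list(window = window, polyorder = polyorder,
                      trimPerSide = trimPerSide))
  })

#' @rdname savgolSecondDerivative
#' @export
setMethod("savgolSecondDerivative",
  signature(x = "numeric", axis = "SpectralAxis"),
  function(x, axis, window = 13L, polyorder = 2L, trimPerSide = 13L) {
    savgolSecondDerivative(matrix(x, nrow = 1L), axis, window = window,
                           polyorder = polyorder, trimPerSide = trimPerSide)
  })

#' @rdname savgolSecondDerivative
#' @export
setMethod("savgolSecondDerivative",
  signature(x = "PixelSpectrumSet", axis = "missing"),
  function(x, axis, window = 13L, polyorder = 2L, trimPerSide = 13L) {
    savgolSecondDerivative(pixelSpectra(x), spectralAxis(x), window = window,
                           polyorder = polyorder, trimPerSide = trimPerSide)
  })

#' Z-score normalization
#'
#' Standardizes each spectrum across wavenumbers to mean 0, standard
#' deviation 1 (the convention used before PCA/UMAP; per-wavenumber
#' standardization across spectra is available via `perWavenumber = TRUE`).
#'
#' @param x numeric spectrum or matrix of spectra (rows = spectra)
#' @param perWavenumber standardize columns (wavenumbers) instead of rows
#' @return object of the same shape
#' @export
zscoreNormalize <- function(x, perWavenumber = FALSE) {
  if (is.matrix(x)) {
    if (perWavenumber) {
      s <- apply(x, 2L, stats::sd)
      if (any(s == 0)) stop("constant wavenumber column: Z-score undefined")
      return(scale(x, center = TRUE, scale = s)[, , drop = FALSE])
    }
    m <- rowMeans(x)
    s <- sqrt(rowSums((x - m)^2) / (ncol(x) - 1L))
    if (any(s == 0)) stop("constant spectrum: Z-score undefined")
    return((x - m) / s)
  }
  s <- stats::sd(x)
  if (is.na(s) || s == 0) stop("constant spectrum: Z-score undefined")
  (x - mean(x)) / s
}
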