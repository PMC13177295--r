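## Quantitative sub-band analysis: 3-sigma dip detection on second
## derivatives, band occurrence with +/-2 cm^-1 tolerance, composite-Simpson
## band integrals, percent-reduction statistics, Gaussian sub-band fitting.

#' Detect significant second-derivative dips
#'
#' Absorbance maxima appear as negative minima of the second derivative.
#' All strict local minima are returned; a dip is significant when its
#' value lies below `-nsigma * sigma` (one-sided 3-sigma rule by default),
#' with sigma taken from the off-tissue background model. Plateau minima
#' report their leftmost point. Dips within `edgeExclusion` cm^-1 of either
#' end of the trimmed axis are flagged (`edge = TRUE`) so weak boundary
#' features can be excluded from interpretation.
#'
#' @param d2 numeric second-derivative spectrum on the trimmed axis (or a
#'   one-row \linkS4class{SecondDerivSpectrum})
#' @param axis the trimmed \linkS4class{SpectralAxis} (ignored when `d2` is
#'   a `SecondDerivSpectrum`)
#' @param sigma background noise scale, `> 0`
#' @param nsigma significance multiplier (default 3)
#' @param edgeExclusion width in cm^-1 of the edge flag zone (default 10)
#' @return data.frame with `position` (cm^-1), `depth` (second-derivative
#'   value), `significant`, `edge`
#' @export
detectSignificantDips <- function(d2, axis = NULL, sigma, nsigma = 3,
                                  edgeExclusion = 10) {
  if (is(d2, "SecondDerivSpectrum")) {
    axis <- spectralAxis(d2)
    d2 <- derivValues(d2)[1L, ]
  }
  stopifnot(sigma > 0)
  wn <- wavenumbers(axis)
  n <- length(d2)
  # strict local minima; plateaus contribute their leftmost point
  r <- rle(d2)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1L
  nr <- length(r$values)
  isMin <- logical(nr)
  for (k in seq_len(nr)) {
    leftOk <- k == 1L || r$values[k - 1L] > r$values[k]
    rightOk <- k == nr || r$values[k + 1L] > r$values[k]
    isMin[k] <- leftOk && rightOk && !(k == 1L && k == nr)
  }
  # interior minima only: runs touching the ends are boundary artifacts
  isMin[1L] <- FALSE
  isMin[nr] <- FALSE
  pos <- starts[isMin]
  if (!length(pos))
    return(data.frame(position = numeric(0), depth = numeric(0),
                      significant = logical(0), edge = logical(0)))
  depth <- d2[pos]
  data.frame(position = wn[pos], depth = depth,
             significant = depth < -nsigma * sigma,
             edge = wn[pos] < wn[1L] + edgeExclusion |
                    wn[pos] > wn[n] - edgeExclusion)
}

#' Band occurrence counts
#'
#' For every reference band, counts how many pixels of an ROI contain at
#' least one significant dip within `tolerance` cm^-1 of the band center
#' (closed interval; the study convention is +/-2 cm^-1). Each pixel
#' contributes at most once per band; a dip matching several bands is
#' assigned to the nearest center (ties to the lower wavenumber), with a
#' warning when band windows overlap.
#'
#' @param calls list of per-pixel data.frames from
#'   [detectSignificantDips()]
#' @param bands data.frame with `label` and `center`
#' @param tolerance matching tolerance in cm^-1 (must be at least half the
#'   axis step)
#' @param step axis step, used only to validate `tolerance`
#' @return data.frame: `band_label`, `center`, `count`, `n_pixels`
#' @export
occurrenceCounts <- function(calls, bands, tolerance = 2, step = 2) {
  if (tolerance < step / 2) stop("tolerance must be at least half the axis step")
  centers <- bands$center
  if (any(diff(sort(centers)) < 2 * tolerance))
    warning("overlapping band windows: dips assigned to the nearest center")
  counts <- integer(nrow(bands))
  for (px in calls) {
    sig <- px[px$significant, , drop = FALSE]
    if (!nrow(sig)) next
    hit <- logical(nrow(bands))
    for (p in sig$position) {
      dist <- abs(p - centers)
      ok <- dist <= tolerance
      if (!any(ok)) next
      # nearest center wins; ties toward the lower wavenumber
      cand <- which(ok)
      best <- cand[order(dist[cand], centers[cand])][1L]
      hit[best] <- TRUE
    }
    counts <- counts + hit
  }
  data.frame(band_label = bands$label, center = centers, count = counts,
             n_pixels = length(calls), stringsAsFactors = FALSE)
}

#' Integration windows for reference bands
#'
#' Builds `[center - halfWidth, center + halfWidth]` windows for the
#' reference bands and clips them to the trimmed axis. Bands whose window
#' does not retain at least 3 grid points on the axis are dropped with a
#' warning (this affects bands within one trim width of the axis ends).
#'
#' @param bands data.frame with `label`, `center`
#' @param axis the trimmed \linkS4class{SpectralAxis}
#' @param halfWidth window half width in cm^-1 (default 8)
#' @return data.frame: `label`, `center`, `lo`, `hi`
#' @export
bandWindows <- function(bands, axis, halfWidth = 8) {
  wn <- wavenumbers(axis)
  lo <- pmax(bands$center - halfWidth, wn[1L])
  hi <- pmin(bands$center + halfWidth, wn[length(wn)])
  npts <- floor((hi - lo) / axisStep(axis)) + 1L
  drop <- npts < 3L | bands$center < wn[1L] | bands$center > wn[length(wn)]
  if (any(drop))
    warning("dropping band(s) outside the trimmed axis: ",
            paste(bands$label[drop], collapse = ", "))
  data.frame(label = bands$label[!drop], center = bands$center[!drop],
             lo = lo[!drop], hi = hi[!drop], stringsAsFactors = FALSE)
}

#' Composite Simpson integral on a uniform grid
#'
#' Exact for polynomials up to degree 3 on an odd number of points. Even
#' point counts use Simpson on the first `n - 1` points plus a trapezoid on
#' the final interval.
#'
#' @param y values on the grid (length >= 3)
#' @param step grid spacing
#' @return the integral
#' @export
simpsonIntegral <- function(y, step) {
  n <- length(y)
  if (n < 3L) stop("Simpson integration needs at least 3 points")
  if (n %% 2L == 0L) {
    return(simpsonIntegral(y[-n], step) + step * (y[n - 1L] + y[n]) / 2)
  }
  i <- seq(2L, n - 1L, by = 2L)
  step / 3 * (y[1L] + y[n] + 4 * sum(y[i]) + 2 * sum(y[seq(3L, n - 2L, by = 2L)]))
}

#' Band integral of a second-derivative spectrum
#'
#' Integrates `-d2` (so absorbance peaks give positive integrals) over a
#' band window using the composite Simpson rule on the grid points inside
#' `[lo, hi]`.
#'
#' @param d2 numeric second-derivative values on the trimmed axis, or a
#'   one-row \linkS4class{SecondDerivSpectrum}
#' @param window one-row data.frame (or list) with `lo`, `hi`
#' @param axis trimmed \linkS4class{SpectralAxis} (ignored for a
#'   `SecondDerivSpectrum`)
#' @return the band integral (absorbance x cm^-1 scale)
#' @export
integrateBand <- function(d2, window, axis = NULL) {
  if (is(d2, "SecondDerivSpectrum")) {
    axis <- spectralAxis(d2)
    d2 <- derivValues(d2)[1L, ]
  }
  wn <- wavenumbers(axis)
  if (window$lo < wn[1L] - 1e-9 || window$hi > wn[length(wn)] + 1e-9)
    stop("integration window outside the trimmed axis")
  sel <- which(wn >= window$lo - 1e-9 & wn <= window$hi + 1e-9)
  if (length(sel) < 3L) stop("integration window has fewer than 3 grid points")
  simpsonIntegral(-d2[sel], axisStep(axis))
}

#' Percent reduction between preparations
#'
#' `100 * (integralFF - integralFFPE) / integralFF`: the percentage by which
#' the FFPE band integral falls short of the FF one.
#'
#' @param integralFF FF band integral, must be positive
#' @param integralFFPE FFPE band integral
#' @return percent reduction
#' @export
percentReduction <- function(integralFF, integralFFPE) {
  if (any(integralFF <= 0)) stop("FF integral must be positive")
  100 * (integralFF - integralFFPE) / integralFF
}

#' Gaussian sub-band fit of a mean spectrum
#'
#' Nonlinear least squares of a sum of Gaussians to a baseline-corrected
#' average absorbance spectrum, initialized at second-derivative dip
#' positions. Centers are bounded to their initialization +/- 5 cm^-1,
#' amplitudes to be nonnegative.
#'
#' @param y baseline-corrected mean absorbance spectrum
#' @param axis its \linkS4class{SpectralAxis}
#' @param initCenters dip positions in cm^-1 (at least one)
#' @param initFwhm initial band width(s), recycled
#' @param maxIter Levenberg-Marquardt iteration cap
#' @return data.frame (`center`, `fwhm`, `amplitude`) with attributes
#'   `residualNorm` and `converged`
#' @export
fitGaussianSubbands <- function(y, axis, initCenters, initFwhm = 20,
                                maxIter = 200L) {
  if (length(initCenters) < 1L) stop("at least one initial center required")
  wn <- wavenumbers(axis)
  nb <- length(initCenters)
  initFwhm <- rep_len(initFwhm, nb)
  initAmp <- pmax(y[nearestIndex(axis, initCenters)], 1e-4)
  par0 <- c(initAmp, initCenters, initFwhm)
  lower <- c(rep(0, nb), initCenters - 5, rep(2 * axisStep(axis), nb))
  upper <- c(rep(Inf, nb), initCenters + 5, rep(200, nb))
  model <- function(p) {
    amp <- p[seq_len(nb)]
    cen <- p[nb + seq_len(nb)]
    fw <- p[2L * nb + seq_len(nb)]
    rowSums(vapply(seq_len(nb), function(i)
      amp[i] * exp(-4 * log(2) * ((wn - cen[i]) / fw[i])^2),
      numeric(length(wn))))
  }
  fit <- minpack.lm::nls.lm(par = par0, lower = lower, upper = upper,
                            fn = function(p) y - model(p),
                            control = minpack.lm::nls.lm.control(
                              maxiter = maxIter))
  p <- fit$par
  res <- data.frame(center = p[nb + seq_len(nb)],
                    fwhm = p[2L * nb + seq_len(nb)],
                    amplitude = p[seq_len(nb)])
  res <- res[order(res$center), , drop = FALSE]
  row.names(res) <- NULL
  attr(res, "residualNorm") <- sqrt(sum(fit$fvec^2))
  converged <- fit$info %in% 1:4
  attr(res, "converged") <- converged
  if (!converged) {
    cond <- structure(
      class = c("mirsiprep_fit_error", "error", "condition"),
      list(message = sprintf(
             "Gaussian sub-band fit did not converge (info=%d, |r|=%.4g); best-so-far parameters attached",
             fit$info, sqrt(sum(fit$fvec^2))),
           call = sys.call(-1L), fit = res))
    stop(cond)
  }
  res
}

#' Summarize occurrence and integral tables across ROIs
#'
#' Per (sample type, band): mean and sample standard deviation (n - 1) of
#' the band integrals, and box-plot statistics (median, quartiles, whiskers
#' at 1.5 IQR) of the occurrence counts.
#'
#' @param occurrence data.frame with `sample_type`, `roi_id`, `band_label`,
#'   `count`
#' @param integrals data.frame with `sample_type`, `roi_id`, `band_label`,
#'   `integral`
#' @return list of data.frames `integralSummary` and `occurrenceSummary`
#' @export
summarizeBands <- function(occurrence, integrals) {
  if (length(unique(integrals$roi_id)) < 2L)
    stop("summaries need at least 2 ROIs")
  intSumm <- do.call(rbind, lapply(
    split(integrals, integrals[c("sample_type", "band_label")], drop = TRUE),
    function(g) data.frame(sample_type = g$sample_type[1L],
                           band_label = g$band_label[1L],
                           mean = mean(g$integral),
                           sd = stats::sd(g$integral),
                           n_rois = nrow(g), stringsAsFactors = FALSE)))
  occSumm <- do.call(rbind, lapply(
    split(occurrence, occurrence[c("sample_type", "band_label")], drop = TRUE),
    function(g) {
      q <- stats::quantile(g$count, c(0.25, 0.5, 0.75), names = FALSE, type = 7)
      iqr <- q[3L] - q[1L]
      inWhisk <- g$count[g$count >= q[1L] - 1.5 * iqr &
                         g$count <= q[3L] + 1.5 * iqr]
      data.frame(sample_type = g$sample_type[1L],
                 band_label = g$band_label[1L],
                 mean = mean(g$count), median = q[2L], q1 = q[1L], q3 = q[3L],
                 whisker_lo = min(inWhisk), whisker_hi = max(inWhisk),
                 n_rois = nrow(g), stringsAsFactors = FALSE)
    }))
  row.names(intSumm) <- row.names(occSumm) <- NULL
  list(integralSummary = intSumm, occurrenceSummary = occSumm)
}
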