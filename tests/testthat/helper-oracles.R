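# Independent oracles used across the suite. These deliberately use
# different algorithms/code paths than the package implementation.

# brute-force Otsu: plain loop over every interior boundary of the 256-bin
# histogram, computing class weights/means from the histogram each time
bruteForceOtsu <- function(v, nbins = 256L) {
  v <- as.numeric(v)
  edges <- seq(min(v), max(v), length.out = nbins + 1L)
  bin <- pmin(pmax(findInterval(v, edges, rightmost.closed = TRUE), 1L), nbins)
  mids <- (edges[-1L] + edges[-(nbins + 1L)]) / 2
  counts <- tabulate(bin, nbins)
  bcv <- rep(-Inf, nbins - 1L)
  for (b in 1:(nbins - 1L)) {
    n0 <- sum(counts[1:b]); n1 <- sum(counts[(b + 1L):nbins])
    if (n0 == 0 || n1 == 0) next
    mu0 <- sum(counts[1:b] * mids[1:b]) / n0
    mu1 <- sum(counts[(b + 1L):nbins] * mids[(b + 1L):nbins]) / n1
    bcv[b] <- (n0 / length(v)) * (n1 / length(v)) * (mu0 - mu1)^2
  }
  # tied maxima (plateau across an empty gap): midpoint convention
  tie <- which(bcv >= max(bcv) - 1e-12 * max(1, abs(max(bcv))))
  (edges[min(tie) + 1L] + edges[max(tie) + 1L]) / 2
}

# brute-force lower convex hull baseline: for every x, the baseline is the
# maximum over all lines below every data point (support-function form)
bruteForceLowerHull <- function(x, y) {
  n <- length(x)
  base <- rep(-Inf, n)
  for (i in 1:(n - 1)) for (j in (i + 1):n) {
    slope <- (y[j] - y[i]) / (x[j] - x[i])
    line <- y[i] + slope * (x - x[i])
    if (all(line <= y + 1e-9)) base <- pmax(base, line)
  }
  base
}

# fine-grid trapezoid quadrature of the analytic -d2 of a Gaussian band
fineGridGaussD2Integral <- function(amplitude, center, fwhm, lo, hi,
                                    n = 10001L) {
  x <- seq(lo, hi, length.out = n)
  s2 <- (fwhm / (2 * sqrt(2 * log(2))))^2
  d2 <- amplitude * exp(-(x - center)^2 / (2 * s2)) *
    ((x - center)^2 / s2 - 1) / s2
  h <- x[2] - x[1]
  sum(-d2[-1] - d2[-n]) * h / 2
}

# windowed quadratic least-squares second derivative at interior point i
polyfitD2At <- function(y, wn, i, window = 13L) {
  half <- (window - 1L) %/% 2L
  sel <- (i - half):(i + half)
  fit <- stats::lm(y[sel] ~ poly(wn[sel], 2, raw = TRUE))
  2 * stats::coef(fit)[[3]]
}

# empty band library (band-free phantom)
emptyBandLibrary <- function() {
  data.frame(label = character(0), assignment = character(0),
             center = numeric(0), fwhm = numeric(0), amplitude = numeric(0),
             stringsAsFactors = FALSE)
}

# direct Gaussian mixture evaluation (independent of the package's model fn)
bandSumOracle <- function(wn, bands) {
  y <- numeric(length(wn))
  for (i in seq_len(nrow(bands)))
    y <- y + bands$amplitude[i] *
      exp(-(wn - bands$center[i])^2 /
            (2 * (bands$fwhm[i] / (2 * sqrt(2 * log(2))))^2))
  y
}

oneBandLibrary <- function(center, fwhm, amplitude, label = "X") {
  data.frame(label = label, assignment = label, center = center,
             fwhm = fwhm, amplitude = amplitude, stringsAsFactors = FALSE)
}

# spectrum-level sample-type simulator (per-pixel jitter + noise), cheaper
# than full ROI generation for classification tests
simulateTypeSpectra <- function(lib, n, axis = SpectralAxis(950, 1800, 2),
                                noiseSd = 0.0015, jitterSd = 0.1) {
  t(replicate(n, {
    l <- lib
    l$amplitude <- l$amplitude *
      stats::rlnorm(1, meanlog = -jitterSd^2 / 2, sdlog = jitterSd)
    synthesizePixelSpectrum(axis, l, defaultBaselineParams(), noiseSd)
  }))
}
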