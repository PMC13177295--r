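trimmedAxis <- SpectralAxis(976, 1774, 2)

test_that("dip detection is one-sided and finds planted bands", {
  wn <- wavenumbers(trimmedAxis)
  # all-positive second derivative: nothing significant
  pos <- abs(sin(wn / 10)) + 0.1
  calls <- detectSignificantDips(pos, trimmedAxis, sigma = 0.01)
  expect_false(any(calls$significant))

  # planted Gaussian dip, center depth 10 sigma
  sigma <- 1e-5
  s2 <- (30 / (2 * sqrt(2 * log(2))))^2
  shape <- exp(-(wn - 1400)^2 / (2 * s2)) * (1 - (wn - 1400)^2 / s2)
  d2 <- -10 * sigma * shape
  calls <- detectSignificantDips(d2, trimmedAxis, sigma = sigma)
  sig <- calls[calls$significant, ]
  expect_equal(nrow(sig), 1L)
  expect_lte(abs(sig$position - 1400), 2)
  expect_lt(sig$depth, -3 * sigma)

  # plateau minima report their leftmost point
  flat <- rep(0, 400); flat[100:103] <- -1
  pl <- detectSignificantDips(flat, trimmedAxis, sigma = 0.1)
  expect_equal(pl$position, wn[100])

  # edge flagging near the trimmed-axis boundaries
  edge <- rep(0, 400); edge[3] <- -1; edge[200] <- -1
  fl <- detectSignificantDips(edge, trimmedAxis, sigma = 0.1)
  expect_equal(fl$edge, c(TRUE, FALSE))
})

test_that("pure-noise spectra yield below one significant dip on average", {
  set.seed(31)
  sigma <- 1
  counts <- vapply(1:1000, function(i) {
    d2 <- rnorm(400, sd = sigma)
    sum(detectSignificantDips(d2, trimmedAxis, sigma = sigma)$significant)
  }, numeric(1))
  expect_lt(mean(counts), 1)
})

test_that("occurrence counting honours the closed +/-2 tolerance", {
  bands <- data.frame(label = c("A", "B"), center = c(1400, 1500))
  mkCall <- function(pos) data.frame(position = pos, depth = -1,
                                     significant = TRUE, edge = FALSE)
  # every pixel calls exactly at the center
  calls <- rep(list(mkCall(1400)), 25)
  occ <- occurrenceCounts(calls, bands)
  expect_equal(occ$count[occ$band_label == "A"], 25L)
  expect_equal(occ$n_pixels, c(25L, 25L))

  # boundary: +2.0 counted, +2.1 not
  expect_equal(occurrenceCounts(list(mkCall(1402.0)), bands)$count[1], 1L)
  expect_equal(occurrenceCounts(list(mkCall(1402.1)), bands)$count[1], 0L)

  # a pixel contributes at most once per band
  occ2 <- occurrenceCounts(list(mkCall(c(1399, 1400, 1401))), bands)
  expect_equal(occ2$count[1], 1L)

  # overlapping windows: nearest center wins, tie toward lower wavenumber
  close <- data.frame(label = c("L", "H"), center = c(1400, 1403))
  expect_warning(o3 <- occurrenceCounts(list(mkCall(1401.5)), close),
                 "overlapping")
  expect_equal(o3$count, c(1L, 0L))

  expect_error(occurrenceCounts(list(), bands, tolerance = 0.5, step = 2),
               "half the axis step")
})

test_that("occurrence of a band present in 60% of pixels is binomial", {
  ax <- SpectralAxis(950, 1800, 2)
  set.seed(61)
  sigma <- 2.7e-5
  counts <- vapply(1:8, function(r) {
    calls <- lapply(1:100, function(p) {
      lib <- if (runif(1) < 0.6) oneBandLibrary(1400, 20, 0.03)
             else emptyBandLibrary()
      y <- synthesizePixelSpectrum(ax, lib, defaultBaselineParams(), 0.0015)
      d2 <- savgolSecondDerivative(rubberbandBaseline(y, ax)$values, ax)
      detectSignificantDips(derivValues(d2)[1, ], spectralAxis(d2),
                            sigma = sigma)
    })
    occurrenceCounts(calls, data.frame(label = "X", center = 1400))$count
  }, numeric(1))
  expect_gte(mean(counts), 50)
  expect_lte(mean(counts), 70)
})

test_that("composite Simpson integrates exactly where it should", {
  # constant -1 over a 10 cm^-1 window (even point count path)
  expect_equal(simpsonIntegral(rep(1, 6), 2), 10)
  # Simpson is exact for cubics on odd grids: -(x-c)^2 over [c-2, c+2]
  ax5 <- SpectralAxis(1398, 1402, 1)
  x <- wavenumbers(ax5)
  d2 <- -(x - 1400)^2
  w <- data.frame(label = "q", center = 1400, lo = 1398, hi = 1402)
  expect_equal(integrateBand(d2, w, ax5), 16 / 3, tolerance = 1e-12)
  expect_equal(simpsonIntegral(x^3, 1),
               (1402^4 - 1398^4) / 4, tolerance = 1e-10)
  expect_error(integrateBand(d2, data.frame(lo = 900, hi = 1000), ax5),
               "outside")
  expect_error(simpsonIntegral(c(1, 2), 1), "at least 3")
})

test_that("band integrals match a fine-grid quadrature oracle", {
  ax <- SpectralAxis(950, 1800, 2)
  A <- 0.4; fw <- 30; c0 <- 1546
  g <- A * exp(-4 * log(2) * ((wavenumbers(ax) - c0) / fw)^2)
  d2 <- savgolSecondDerivative(g, ax)
  w <- data.frame(label = "g", center = c0, lo = c0 - 8, hi = c0 + 8)
  got <- integrateBand(derivValues(d2)[1, ], w, spectralAxis(d2))
  oracle <- fineGridGaussD2Integral(A, c0, fw, c0 - 8, c0 + 8)
  expect_equal(got, oracle, tolerance = 0.05)
})

test_that("band integrals are linear in planted amplitude", {
  ax <- SpectralAxis(950, 1800, 2)
  amps <- c(0.2, 0.4, 0.8)
  set.seed(77)
  ints <- vapply(amps, function(A) {
    specs <- t(replicate(50, synthesizePixelSpectrum(
      ax, oneBandLibrary(1546, 30, A), defaultBaselineParams(), 0.0015)))
    d2 <- savgolSecondDerivative(rubberbandBaseline(specs, ax)$values, ax)
    w <- data.frame(label = "g", center = 1546, lo = 1538, hi = 1554)
    integrateBand(colMeans(derivValues(d2)), w, spectralAxis(d2))
  }, numeric(1))
  fit <- lm(ints ~ 0 + amps)
  r2 <- 1 - sum(residuals(fit)^2) / sum(ints^2)
  expect_gt(r2, 0.99)
})

test_that("band windows clip to the trimmed axis and drop edge bands", {
  expect_warning(w <- bandWindows(referenceBands(), trimmedAxis),
                 "DNA_966")
  expect_false("DNA_966" %in% w$label)
  expect_true(all(w$lo >= 976 & w$hi <= 1774))
  expect_true(all(w$lo < w$center & w$center < w$hi))
})

test_that("percent reduction follows its definition and preconditions", {
  expect_equal(percentReduction(10, 10), 0)
  expect_equal(percentReduction(10, 0), 100)
  expect_equal(percentReduction(10, 3.37), 66.3)
  expect_error(percentReduction(0, 1), "positive")
  expect_error(percentReduction(-2, 1), "positive")
})

test_that("Gaussian sub-band fitting recovers known mixtures", {
  ax <- SpectralAxis(950, 1800, 2)
  wn <- wavenumbers(ax)
  # single noiseless Gaussian, init at truth: exact recovery
  y <- 0.5 * exp(-4 * log(2) * ((wn - 1400) / 30)^2)
  fit <- fitGaussianSubbands(y, ax, initCenters = 1400, initFwhm = 30)
  expect_equal(fit$center, 1400, tolerance = 1e-6)
  expect_equal(fit$amplitude, 0.5, tolerance = 1e-6)
  expect_equal(fit$fwhm, 30, tolerance = 1e-5)
  expect_lt(attr(fit, "residualNorm"), 1e-8)

  # two Gaussians separated by 3 fwhm, 1% noise, over seeds
  for (s in 1:20) {
    set.seed(400 + s)
    truth <- data.frame(center = c(1300, 1390), fwhm = c(30, 30),
                        amplitude = c(0.6, 0.4))
    y2 <- bandSumOracle(wn, truth) + rnorm(426, sd = 0.006)
    f2 <- fitGaussianSubbands(y2, ax, initCenters = c(1302, 1388),
                              initFwhm = 25)
    expect_lt(max(abs(f2$center - truth$center)), 1)
    expect_lt(max(abs(f2$amplitude - truth$amplitude) / truth$amplitude), 0.05)
  }
})

test_that("a far-off initialization is flagged by its residual", {
  ax <- SpectralAxis(950, 1800, 2)
  wn <- wavenumbers(ax)
  set.seed(12)
  noise <- 0.002
  y <- 0.5 * exp(-4 * log(2) * ((wn - 1400) / 30)^2) + rnorm(426, sd = noise)
  # init 50 cm^-1 from the true band; center bound is +/-5 cm^-1
  fit <- tryCatch(fitGaussianSubbands(y, ax, initCenters = 1350),
                  mirsiprep_fit_error = function(e) e$fit)
  expect_gt(attr(fit, "residualNorm"), 10 * noise * sqrt(426))
})

test_that("band summaries reproduce closed-form statistics", {
  occ <- data.frame(sample_type = "k_FF", roi_id = paste0("r", 1:8),
                    band_label = "A", count = 1:8)
  ints <- data.frame(sample_type = "k_FF", roi_id = paste0("r", 1:8),
                     band_label = "A", integral = rep(0.5, 8))
  s <- summarizeBands(occ, ints)
  expect_equal(s$integralSummary$sd, 0)
  expect_equal(s$occurrenceSummary$mean, 4.5)
  expect_equal(s$occurrenceSummary$median, 4.5)

  ints2 <- data.frame(sample_type = "k_FF", roi_id = paste0("r", 1:8),
                      band_label = "A", integral = 1:8)
  s2 <- summarizeBands(occ, ints2)
  expect_equal(s2$integralSummary$mean, 4.5)
  expect_equal(s2$integralSummary$sd, sd(1:8))  # sample sd, n - 1

  # independent spreadsheet-style recomputation on a two-type fixture
  set.seed(5)
  fx <- expand.grid(sample_type = c("a", "b"), roi_id = paste0("r", 1:4),
                    band_label = c("X", "Y"), stringsAsFactors = FALSE)
  fx$integral <- runif(nrow(fx))
  fx$count <- sample(0:100, nrow(fx))
  s3 <- summarizeBands(fx, fx)
  for (r in seq_len(nrow(s3$integralSummary))) {
    row <- s3$integralSummary[r, ]
    sub <- fx$integral[fx$sample_type == row$sample_type &
                       fx$band_label == row$band_label]
    expect_equal(row$mean, sum(sub) / length(sub))
    expect_equal(row$sd, sqrt(sum((sub - mean(sub))^2) / (length(sub) - 1)))
  }
  expect_error(summarizeBands(occ[1, ], ints[1, ]), "2 ROIs")
})
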