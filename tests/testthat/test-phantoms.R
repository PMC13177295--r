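axis426 <- SpectralAxis(950, 1800, 2)

test_that("default band libraries carry 13 FF and 8/7 (+1026) FFPE bands", {
  ffk <- defaultBandLibrary("kidney", "FF")
  ffl <- defaultBandLibrary("liver", "FF")
  pek <- defaultBandLibrary("kidney", "FFPE")
  pel <- defaultBandLibrary("liver", "FFPE")

  expect_equal(nrow(ffk), 13L)
  expect_equal(nrow(ffl), 13L)
  expect_true(all(c(1658, 1744) %in% ffk$center))
  # the fixation band never appears in fresh-frozen libraries
  expect_false(1026 %in% ffk$center)
  expect_false(1026 %in% ffl$center)

  # FFPE: 8 (kidney) / 7 (liver) retained bands plus the 1026 cm^-1 band
  expect_equal(sum(pek$center != 1026), 8L)
  expect_equal(sum(pel$center != 1026), 7L)
  expect_true(1026 %in% pek$center)
  expect_true(1026 %in% pel$center)
  # amide I/II retained, DNA and lipid bands dropped
  expect_true(all(c(1546, 1658) %in% pel$center))
  expect_false(any(pel$assignment %in% c("DNA", "Lipids")))
  # all centers come from the reference table (plus the fixation band)
  expect_true(all(ffk$center %in% referenceBands()$center))
})

test_that("planted FFPE amide-I attenuation encodes the exact reduction", {
  for (ti in c("kidney", "liver")) {
    ff <- defaultBandLibrary(ti, "FF")
    pe <- defaultBandLibrary(ti, "FFPE")
    f <- 1 - pe$amplitude[pe$label == "AmideI_1658"] /
      ff$amplitude[ff$label == "AmideI_1658"]
    expect_equal(f, c(kidney = 0.663, liver = 0.462)[[ti]], tolerance = 1e-12)
    expect_equal(pe$fwhm[pe$label == "AmideI_1658"],
                 ff$fwhm[ff$label == "AmideI_1658"])
  }
  custom <- defaultBandLibrary("kidney", "FFPE", amideReduction = 0.5)
  ff <- defaultBandLibrary("kidney", "FF")
  expect_equal(custom$amplitude[custom$label == "AmideI_1658"],
               0.5 * ff$amplitude[ff$label == "AmideI_1658"])
  expect_error(defaultBandLibrary("kidney", "FFPE", amideReduction = 1.2))
})

test_that("pixel spectrum synthesis follows the Gaussian-band model", {
  expect_equal(synthesizePixelSpectrum(axis426), numeric(426))
  y <- synthesizePixelSpectrum(axis426, oneBandLibrary(1658, 30, 1))
  expect_equal(max(y), 1.0, tolerance = 1e-12)
  expect_equal(wavenumbers(axis426)[which.max(y)], 1658)
  expect_error(synthesizePixelSpectrum(axis426, oneBandLibrary(100, 30, 1)),
               "outside")
  expect_error(synthesizePixelSpectrum(axis426, oneBandLibrary(1400, -3, 1)),
               "positive")
})

test_that("synthesized noise has the configured scale", {
  set.seed(17)
  draws <- replicate(24, synthesizePixelSpectrum(axis426, noiseSd = 0.01))
  expect_gt(length(draws), 10000)  # > 10 000 Monte-Carlo draws
  expect_equal(sd(draws), 0.01, tolerance = 0.05)  # within 5% of 0.01
})

test_that("analytic second-derivative truth matches finite differences", {
  A <- 0.7; w <- 36; c0 <- 1400
  h <- 1e-3
  g <- function(x) A * exp(-4 * log(2) * ((x - c0) / w)^2)
  fd <- (g(c0 + h) - 2 * g(c0) + g(c0 - h)) / h^2
  expect_equal(-A * 8 * log(2) / w^2, fd, tolerance = 1e-6)
  roi <- generateRoi(phantomConfig("kidney", "FF", roiShape = c(32, 32),
                                   bandLibrary = oneBandLibrary(c0, w, A),
                                   seed = 3))
  expect_equal(roi$truth$bands$d2Depth, fd, tolerance = 1e-6)
})

test_that("equal seeds give bit-identical ROIs", {
  cfg <- phantomConfig("liver", "FFPE", roiShape = c(40, 40), seed = 7)
  a <- generateRoi(cfg)
  b <- generateRoi(cfg)
  expect_identical(cubeData(a$cube), cubeData(b$cube))
  expect_identical(a$truth$mask, b$truth$mask)
})

test_that("off-mask pixels carry baseline plus noise only", {
  cfg <- phantomConfig("liver", "FFPE", roiShape = c(64, 64), seed = 1)
  roi <- generateRoi(cfg)
  d <- cubeData(roi$cube)
  flat <- matrix(d, ncol = dim(d)[3])
  off <- which(!roi$truth$mask)
  dev <- abs(colMeans(flat[off, ]) - roi$truth$baseline)
  expect_lt(max(dev), 4 * cfg$noiseSd / sqrt(length(off)))
})

test_that("FF holes carve the configured fraction of the mask", {
  fracs <- vapply(1:20, function(s) {
    cfg <- phantomConfig("kidney", "FF", roiShape = c(64, 64), seed = 100 + s)
    cfg$maskParams$holeFraction <- 0.2
    tr <- generateRoi(cfg)$truth
    sum(tr$holes) / (sum(tr$mask) + sum(tr$holes))
  }, numeric(1))
  expect_true(all(fracs >= 0.10 & fracs <= 0.30))
  expect_equal(mean(fracs), 0.2, tolerance = 0.25)
  # FFPE default carves no holes
  trPE <- generateRoi(phantomConfig("kidney", "FFPE", roiShape = c(48, 48),
                                    seed = 2))$truth
  expect_equal(sum(trPE$holes), 0L)
})

test_that("study generation enumerates sample types and plants reductions", {
  st <- generateStudy(nRois = 1L, roiShape = c(32, 32), seed = 5)
  expect_length(st$cubes, 4L)
  expect_equal(nrow(st$manifest), 4L)
  amide <- st$trueReductions[st$trueReductions$band_label == "AmideI_1658", ]
  expect_equal(amide$reduction[amide$tissue == "kidney"], 0.663,
               tolerance = 1e-9)
  expect_equal(amide$reduction[amide$tissue == "liver"], 0.462,
               tolerance = 1e-9)
  # manifest band centers pass through the configured library
  expect_setequal(st$truths$kidney_FF_roi1$bands$center,
                  defaultBandLibrary("kidney", "FF")$center)
})

test_that("degenerate phantom masks are rejected", {
  cfg <- phantomConfig("kidney", "FF", roiShape = c(16, 16), seed = 1)
  cfg$maskParams$axisFrac <- c(4, 5)   # ellipses swallow the whole frame
  cfg$maskParams$holeFraction <- 0
  expect_error(generateRoi(cfg), "degenerate")
})
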