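test_that("Otsu threshold separates bimodal data and rejects constants", {
  v <- c(0, 0, 0, 10, 10, 10)
  t1 <- otsuThreshold(v)
  expect_gt(t1, 0)
  expect_lt(t1, 10)

  set.seed(1)
  v2 <- c(rnorm(10000, 0.1, 0.05), rnorm(10000, 0.9, 0.05))
  t2 <- otsuThreshold(v2)
  expect_gt(t2, 0.3)
  expect_lt(t2, 0.7)

  expect_error(otsuThreshold(rep(3, 100)), "constant")
})

test_that("Otsu equals the brute-force between-class-variance scan", {
  set.seed(42)
  cases <- list(
    c(rnorm(3000, 0, 1), rnorm(2000, 5, 1.5)),
    runif(5000),
    c(rexp(2500, 2), 4 + rexp(2500, 1)),
    c(rnorm(400, 0.2, 0.02), rnorm(100, 0.8, 0.1)))
  for (v in cases)
    expect_equal(otsuThreshold(v), bruteForceOtsu(v), tolerance = 1e-12)
})

test_that("Otsu agrees with an external reference implementation", {
  skip_if_not_installed("EBImage")
  set.seed(7)
  img <- matrix(c(rnorm(600, 0.2, 0.05), rnorm(424, 0.7, 0.08)), 32, 32)
  ours <- otsuThreshold(img)
  ref <- EBImage::otsu(img, range = range(img), levels = 256)
  binWidth <- diff(range(img)) / 256
  expect_lt(abs(ours - ref), 2 * binWidth)
})

test_that("tissue masks recover the phantom ground truth", {
  jac <- vapply(1:10, function(s) {
    roi <- generateRoi(phantomConfig("kidney", "FF", roiShape = c(48, 48),
                                     seed = 200 + s))
    m <- maskMatrix(makeTissueMask(roi$cube))
    sum(m & roi$truth$mask) / sum(m | roi$truth$mask)
  }, numeric(1))
  expect_true(all(jac >= 0.98))
})

test_that("masking uses the nearest grid point and supports inversion", {
  roi <- generateRoi(phantomConfig("liver", "FF", roiShape = c(32, 32),
                                   seed = 3))
  m1 <- makeTissueMask(roi$cube, bandWn = 1607.6)
  expect_equal(m1@bandWn, 1608)
  # inverted-contrast convention: tissue = low absorbance
  inv <- makeTissueMask(roi$cube, invert = TRUE)
  expect_equal(maskMatrix(inv), !maskMatrix(makeTissueMask(roi$cube)))
})

test_that("background sigma matches an independent smoother+difference oracle", {
  cfg <- phantomConfig("kidney", "FF", roiShape = c(64, 64), noiseSd = 0.01,
                       seed = 11)
  roi <- generateRoi(cfg)
  bg <- computeBackground(roi$cube, roi$truth$mask)
  mu <- backgroundSpectrum(bg)
  wn <- wavenumbers(spectralAxis(roi$cube))
  # oracle: SG-smooth (order 2, no derivative) then central differences
  smooth <- signal::sgolayfilt(mu, p = 2, n = 13, m = 0)
  fd <- diff(diff(smooth)) / diff(wn)[1]^2
  fdTrim <- fd[13:(length(fd) - 12)]   # align with the 13-per-side trim
  oracle <- sqrt(mean((fdTrim - mean(fdTrim))^2))
  expect_equal(backgroundSigma(bg), oracle, tolerance = 0.25)
})

test_that("degenerate backgrounds raise explicit errors", {
  ax <- SpectralAxis(950, 1800, 2)
  flat <- new("HyperspectralCube",
              data = array(0, c(16, 16, 426)), axis = ax, meta = list())
  m <- matrix(FALSE, 16, 16); m[1:8, ] <- TRUE
  expect_error(computeBackground(flat, m), "degenerate noise")
  roi <- generateRoi(phantomConfig("kidney", "FF", roiShape = c(32, 32),
                                   seed = 2))
  expect_error(computeBackground(roi$cube, matrix(TRUE, 32, 32)), "empty")
  small <- matrix(TRUE, 32, 32); small[1:6, 1:6] <- FALSE
  expect_error(computeBackground(roi$cube, small), ">= 50")
})

test_that("sigma scales linearly with phantom noise on flat baselines", {
  noise <- c(0.005, 0.01, 0.02)
  sig <- vapply(seq_along(noise), function(i) {
    cfg <- phantomConfig("kidney", "FF", roiShape = c(64, 64),
                         baselineParams = list(poly = 0.2, sigmoid = NULL),
                         noiseSd = noise[i], seed = 40 + i)
    roi <- generateRoi(cfg)
    backgroundSigma(computeBackground(roi$cube, roi$truth$mask))
  }, numeric(1))
  fit <- lm(sig ~ 0 + noise)
  r2 <- 1 - sum(residuals(fit)^2) / sum(sig^2)
  expect_gt(r2, 0.99)
})

test_that("pixel sampling is seeded, exhaustive at n = mask size, and checked", {
  roi <- generateRoi(phantomConfig("liver", "FF", roiShape = c(40, 40),
                                   seed = 8))
  mask <- makeTissueMask(roi$cube)
  a <- samplePixels(roi$cube, mask, n = 100, seed = 99)
  b <- samplePixels(roi$cube, mask, n = 100, seed = 99)
  expect_identical(pixelCoords(a), pixelCoords(b))
  expect_identical(pixelSpectra(a), pixelSpectra(b))
  nT <- sum(maskMatrix(mask))
  all <- samplePixels(roi$cube, mask, n = nT, seed = 1)
  expect_equal(nrow(pixelSpectra(all)), nT)
  expect_false(anyDuplicated(pixelCoords(all)[c("row", "col")]) > 0)
  expect_error(samplePixels(roi$cube, mask, n = nT + 1, seed = 1),
               "only")
  # sampled coordinates all lie inside the mask
  co <- pixelCoords(a)
  expect_true(all(maskMatrix(mask)[cbind(co$row, co$col)]))
})
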