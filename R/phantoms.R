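## Synthetic hyperspectral phantoms with known ground truth.
##
## Phantoms emulate QCL mid-IR ROIs of fresh-frozen (FF) and formalin-fixed
## paraffin-embedded (FFPE) kidney/liver tissue: Gaussian vibrational bands
## from the reference band table, a smooth scattering baseline, additive
## detector noise, elliptical tissue masks with off-tissue background, and
## (for FF) morphological holes. Every generated ROI carries its ground
## truth so downstream stages can be validated without tissue data.

FWHM_TO_SIGMA <- 1 / (2 * sqrt(2 * log(2)))
GAUSS_D2_FACTOR <- 8 * log(2)   # |d2| at center = A * 8 ln2 / fwhm^2

#' Reference band table
#'
#' The reference integration band list used throughout the package:
#' assignments and approximate band centers of the fingerprint-region
#' vibrational bands of tissue (DNA, glycogen, protein amide I/II/III,
#' lipids).
#'
#' @return data.frame with columns `label`, `assignment`, `center` (cm^-1)
#' @export
referenceBands <- function() {
  path <- system.file("extdata", "reference_bands.csv", package = "mirsiprep",
                      mustWork = TRUE)
  utils::read.csv(path, stringsAsFactors = FALSE)
}

# FF band profiles (label, fwhm, amplitude). Thirteen bands per tissue,
# drawn from the reference table; the 1030 and 1516 entries are unresolvable
# shoulders of 1035/1546 at this grid and band width, so the 13-band FF
# libraries omit them. Amplitudes are chosen so that every band's
# second-derivative center depth clears the detection threshold by a wide
# margin under the default noise model (see the methods vignette).
.ffProfiles <- function() {
  list(
    kidney = data.frame(
      label = c("DNA_966", "DNA_1035", "DNA_1082", "Glycogen_1154",
                "Proteins_1168", "AmideIII_1238", "AmideIII_1308",
                "Proteins_1400", "Proteins_1448", "Lipids_1462",
                "AmideII_1546", "AmideI_1658", "Lipids_1744"),
      fwhm = c(16, 16, 18, 18, 14, 22, 20, 20, 14, 12, 42, 50, 22),
      amplitude = c(0.040, 0.050, 0.060, 0.060, 0.045, 0.100, 0.080,
                    0.100, 0.060, 0.050, 0.450, 0.750, 0.120),
      stringsAsFactors = FALSE),
    liver = data.frame(
      label = c("DNA_966", "DNA_1035", "DNA_1082", "Glycogen_1154",
                "Proteins_1168", "AmideIII_1238", "AmideIII_1308",
                "Proteins_1400", "Proteins_1448", "Lipids_1462",
                "AmideII_1546", "AmideI_1658", "Lipids_1744"),
      fwhm = c(16, 16, 18, 18, 14, 22, 20, 20, 14, 12, 42, 50, 22),
      amplitude = c(0.030, 0.040, 0.045, 0.090, 0.055, 0.090, 0.070,
                    0.110, 0.070, 0.080, 0.360, 0.470, 0.200),
      stringsAsFactors = FALSE)
  )
}

# bands retained after formalin fixation / paraffin embedding: amide and
# protein bands survive, DNA and lipid bands are lost; kidney additionally
# keeps the 1154 glycogen band (8 vs 7 retained bands).
.ffpeRetained <- list(
  kidney = c("Glycogen_1154", "Proteins_1168", "AmideIII_1238",
             "AmideIII_1308", "Proteins_1400", "Proteins_1448",
             "AmideII_1546", "AmideI_1658"),
  liver  = c("Proteins_1168", "AmideIII_1238", "AmideIII_1308",
             "Proteins_1400", "Proteins_1448", "AmideII_1546",
             "AmideI_1658")
)

#' Default band library for a sample type
#'
#' Returns the Gaussian band library describing one tissue/preparation
#' combination. FF libraries carry thirteen bands; FFPE retains eight
#' (kidney) or seven (liver) of them -- amide/protein bands survive, DNA and
#' lipid bands are dropped -- and every FFPE library additionally carries
#' the ~1026 cm^-1 fixation-associated band that FF tissue never shows.
#'
#' The FFPE amide-I amplitude is attenuated to `(1 - amideReduction)` times
#' the FF amplitude at equal width, which plants the amide-I band-integral
#' reduction exactly; defaults are the planted effect sizes (kidney 0.663,
#' liver 0.462). Other retained FFPE bands take `sharedAttenuation` times
#' the mean FF profile of the two tissues, which homogenizes FFPE
#' composition across organs.
#'
#' @param tissue `"kidney"` or `"liver"`
#' @param preparation `"FF"` or `"FFPE"`
#' @param amideReduction fractional amide-I integral reduction planted in
#'   the FFPE library (0..1); default 0.663 for kidney, 0.462 for liver
#' @param sharedAttenuation FFPE/FF amplitude ratio for non-amide-I retained
#'   bands (applied to the mean FF profile)
#' @param fixationBand add the ~1026 cm^-1 FFPE-specific band
#' @return data.frame with `label`, `assignment`, `center`, `fwhm`,
#'   `amplitude`
#' @examples
#' nrow(defaultBandLibrary("kidney", "FF"))    # 13
#' nrow(defaultBandLibrary("liver", "FFPE"))   # 7 retained + 1026 band
#' @export
defaultBandLibrary <- function(tissue = c("kidney", "liver"),
                               preparation = c("FF", "FFPE"),
                               amideReduction = NULL,
                               sharedAttenuation = 0.6,
                               fixationBand = TRUE) {
  tissue <- match.arg(tissue)
  preparation <- match.arg(preparation)
  ref <- referenceBands()
  prof <- .ffProfiles()

  if (preparation == "FF") {
    lib <- prof[[tissue]]
  } else {
    if (is.null(amideReduction))
      amideReduction <- c(kidney = 0.663, liver = 0.462)[[tissue]]
    if (amideReduction < 0 || amideReduction >= 1)
      stop("amideReduction must be in [0, 1)")
    retained <- .ffpeRetained[[tissue]]
    ffMean <- prof$kidney
    ffMean$amplitude <- (prof$kidney$amplitude + prof$liver$amplitude) / 2
    lib <- ffMean[ffMean$label %in% retained, , drop = FALSE]
    lib$amplitude <- lib$amplitude * sharedAttenuation
    amide <- lib$label == "AmideI_1658"
    lib$amplitude[amide] <-
      prof[[tissue]]$amplitude[prof[[tissue]]$label == "AmideI_1658"] *
      (1 - amideReduction)
    if (fixationBand) {
      lib <- rbind(lib, data.frame(label = "Fixation_1026", fwhm = 14,
                                   amplitude = 0.060))
    }
  }
  centers <- c(stats::setNames(ref$center, ref$label), Fixation_1026 = 1026)
  assign <- c(stats::setNames(ref$assignment, ref$label),
              Fixation_1026 = "Fixation artifact")
  data.frame(label = lib$label,
             assignment = unname(assign[lib$label]),
             center = unname(centers[lib$label]),
             fwhm = lib$fwhm,
             amplitude = lib$amplitude,
             stringsAsFactors = FALSE, row.names = NULL)
}

#' Default scattering-baseline parameters
#'
#' A gentle low-order polynomial plus a broad sigmoid step. The sigmoid
#' supplies the smooth curvature that dominates the second derivative of
#' the averaged background spectrum, so the background-derived noise scale
#' sigma reflects structured background rather than averaged-out white
#' noise (see the methods vignette).
#'
#' @param poly polynomial coefficients on the scaled coordinate
#'   `u = (wn - mid) / halfrange` in `[-1, 1]` (constant first), length <= 4
#' @param sigmoid `c(amplitude, center, width)` of a logistic step in cm^-1,
#'   or `NULL` for none
#' @export
defaultBaselineParams <- function(poly = c(0.10, 0.03, 0.02, 0),
                                  sigmoid = c(0.25, 1240, 15)) {
  stopifnot(length(poly) <= 4L)
  list(poly = poly, sigmoid = sigmoid)
}

#' Evaluate a baseline on an axis
#' @param axis a \linkS4class{SpectralAxis}
#' @param params list as returned by [defaultBaselineParams()]
#' @return numeric baseline absorbance over the axis
#' @export
evalBaseline <- function(axis, params) {
  wn <- wavenumbers(axis)
  if (is.null(params)) return(numeric(length(wn)))
  mid <- (wn[1L] + wn[length(wn)]) / 2
  half <- (wn[length(wn)] - wn[1L]) / 2
  u <- (wn - mid) / half
  b <- numeric(length(wn))
  p <- params$poly
  if (!is.null(p) && length(p))
    for (k in seq_along(p)) b <- b + p[k] * u^(k - 1L)
  s <- params$sigmoid
  if (!is.null(s)) b <- b + s[1L] / (1 + exp(-(wn - s[2L]) / s[3L]))
  b
}

# sum of Gaussian bands evaluated on an axis
bandSum <- function(axis, bands) {
  wn <- wavenumbers(axis)
  y <- numeric(length(wn))
  if (is.null(bands) || nrow(bands) == 0L) return(y)
  for (i in seq_len(nrow(bands)))
    y <- y + bands$amplitude[i] *
      exp(-4 * log(2) * ((wn - bands$center[i]) / bands$fwhm[i])^2)
  y
}

#' Synthesize one pixel spectrum
#'
#' Spectrum = sum of Gaussian bands + smooth baseline + iid Gaussian noise.
#' Noise is drawn from the caller's RNG stream (seed with [set.seed()]).
#' Nonnegativity is not enforced: noise may dip below zero.
#'
#' @param axis a \linkS4class{SpectralAxis}
#' @param bands band library data.frame (`center`, `fwhm`, `amplitude`);
#'   all centers must lie within the axis range and `fwhm > 0`
#' @param baselineParams see [defaultBaselineParams()]; `NULL` = flat zero
#' @param noiseSd additive noise standard deviation (absorbance), `>= 0`
#' @return numeric absorbance spectrum over the axis
#' @export
synthesizePixelSpectrum <- function(axis, bands = NULL, baselineParams = NULL,
                                    noiseSd = 0) {
  stopifnot(noiseSd >= 0)
  wn <- wavenumbers(axis)
  if (!is.null(bands) && nrow(bands)) {
    if (any(bands$fwhm <= 0)) stop("band fwhm must be positive")
    if (any(bands$center < wn[1L] | bands$center > wn[length(wn)]))
      stop("band center outside axis range")
  }
  y <- bandSum(axis, bands) + evalBaseline(axis, baselineParams)
  if (noiseSd > 0) y <- y + stats::rnorm(length(wn), sd = noiseSd)
  y
}

#' Phantom ROI configuration
#'
#' @param tissue,preparation sample-type labels
#' @param roiShape `c(rows, cols)`, positive; default 96 x 96 (a desk-scale
#'   stand-in for full 480 x 480 acquisitions)
#' @param bandLibrary band data.frame, default [defaultBandLibrary()]
#' @param baselineParams default [defaultBaselineParams()]
#' @param noiseSd additive detector noise sd (absorbance)
#' @param amplitudeJitter sdlog of the per-pixel multiplicative log-normal
#'   intensity factor applied to the band component (mean fixed at 1)
#' @param maskParams list: `nEllipses`, `axisFrac` (semi-axis range as a
#'   fraction of the image half-size), `holeFraction` (FF morphological
#'   holes; fraction of mask area carved out), `holeRadius` range in pixels
#' @param seed integer; identical seeds give bit-identical ROIs
#' @param roiId label stored in the cube metadata
#' @return config list for [generateRoi()]
#' @export
phantomConfig <- function(tissue = "kidney", preparation = "FF",
                          roiShape = c(96L, 96L),
                          bandLibrary = defaultBandLibrary(tissue, preparation),
                          baselineParams = defaultBaselineParams(),
                          noiseSd = 0.0015,
                          amplitudeJitter = 0.10,
                          maskParams = list(
                            nEllipses = 3L, axisFrac = c(0.5, 0.9),
                            holeFraction = if (preparation == "FF") 0.15 else 0,
                            holeRadius = c(3, 8)),
                          seed = 1L,
                          roiId = sprintf("%s_%s_roi1", tissue, preparation)) {
  stopifnot(all(roiShape >= 8L), noiseSd >= 0,
            maskParams$holeFraction >= 0, maskParams$holeFraction <= 1)
  list(tissue = tissue, preparation = preparation,
       roiShape = as.integer(roiShape), bandLibrary = bandLibrary,
       baselineParams = baselineParams, noiseSd = noiseSd,
       amplitudeJitter = amplitudeJitter, maskParams = maskParams,
       seed = as.integer(seed), roiId = roiId)
}

# union-of-ellipses tissue mask with optional carved holes; uses current RNG
genPhantomMask <- function(shape, maskParams) {
  nr <- shape[1L]; nc <- shape[2L]
  rr <- matrix(seq_len(nr), nr, nc)
  cc <- matrix(seq_len(nc), nr, nc, byrow = TRUE)
  mask <- matrix(FALSE, nr, nc)
  for (i in seq_len(maskParams$nEllipses)) {
    cr <- stats::runif(1, 0.35, 0.65) * nr
    ccen <- stats::runif(1, 0.35, 0.65) * nc
    a <- stats::runif(1, maskParams$axisFrac[1L], maskParams$axisFrac[2L]) * nr / 2
    b <- stats::runif(1, maskParams$axisFrac[1L], maskParams$axisFrac[2L]) * nc / 2
    mask <- mask | (((rr - cr) / a)^2 + ((cc - ccen) / b)^2 <= 1)
  }
  holes <- matrix(FALSE, nr, nc)
  hf <- maskParams$holeFraction
  if (hf > 0) {
    target <- round(hf * sum(mask))
    carved <- 0L
    iter <- 0L
    while (carved < target && iter < 1000L) {
      iter <- iter + 1L
      idx <- sample.int(length(mask), 1L, prob = as.numeric(mask))
      hr <- ((idx - 1L) %% nr) + 1L
      hc <- ((idx - 1L) %/% nr) + 1L
      rad <- stats::runif(1, maskParams$holeRadius[1L], maskParams$holeRadius[2L])
      disk <- ((rr - hr)^2 + (cc - hc)^2) <= rad^2
      newly <- disk & mask
      carved <- carved + sum(newly)
      mask[newly] <- FALSE
      holes <- holes | newly
    }
  }
  if (all(mask) || !any(mask))
    stop("degenerate phantom mask (all tissue or all background)")
  list(mask = mask, holes = holes)
}

#' Generate one phantom ROI with ground truth
#'
#' On-mask pixels carry the band spectra scaled by a per-pixel log-normal
#' intensity factor; off-mask pixels carry baseline plus noise only.
#' Identical seeds give bit-identical output.
#'
#' @param config list from [phantomConfig()]
#' @return list with `cube` (\linkS4class{HyperspectralCube}) and `truth`:
#'   the true `mask` and `holes`, the band table augmented with analytic
#'   second-derivative center depths (`d2Depth = -A 8ln2 / fwhm^2`) and
#'   analytic `-d2` window integrals, the baseline, and the config.
#' @export
generateRoi <- function(config) {
  axis <- SpectralAxis(950, 1800, 2)
  withSeed(config$seed, {
    mk <- genPhantomMask(config$roiShape, config$maskParams)
    nTissue <- sum(mk$mask)
    jit <- if (config$amplitudeJitter > 0) {
      sdl <- config$amplitudeJitter
      stats::rlnorm(nTissue, meanlog = -sdl^2 / 2, sdlog = sdl)
    } else rep(1, nTissue)
    nr <- config$roiShape[1L]; nc <- config$roiShape[2L]
    K <- length(axis)
    npx <- nr * nc
    m <- matrix(stats::rnorm(npx * K, sd = config$noiseSd), npx, K)
    bl <- evalBaseline(axis, config$baselineParams)
    m <- m + matrix(bl, npx, K, byrow = TRUE)
    bs <- bandSum(axis, config$bandLibrary)
    tIdx <- which(mk$mask)
    if (length(tIdx)) m[tIdx, ] <- m[tIdx, ] + outer(jit, bs)
    cube <- new("HyperspectralCube", data = array(m, c(nr, nc, K)),
                axis = axis,
                meta = list(tissue = config$tissue,
                            preparation = config$preparation,
                            roi_id = config$roiId, seed = config$seed))
    bands <- config$bandLibrary
    if (!is.null(bands) && nrow(bands)) {
      bands$d2Depth <- -bands$amplitude * GAUSS_D2_FACTOR / bands$fwhm^2
      hw <- 8
      bands$analyticIntegral <- 2 * bands$amplitude * GAUSS_D2_FACTOR * hw /
        bands$fwhm^2 * exp(-4 * log(2) * (hw / bands$fwhm)^2)
    }
    list(cube = cube,
         truth = list(mask = mk$mask, holes = mk$holes, bands = bands,
                      baseline = bl, config = config))
  })
}

#' Generate a full phantom study
#'
#' Builds `length(tissues) * length(preparations) * nRois` ROIs. Paired
#' FF/FFPE configurations share tissue band centers, and the FFPE amide-I
#' amplitudes encode the planted integral reductions.
#'
#' @param tissues,preparations sample-type grid
#' @param nRois ROIs per sample type (default 8)
#' @param roiShape,noiseSd,amplitudeJitter passed to [phantomConfig()]
#' @param seed master seed; ROI `i` uses `seed + i` (stable enumeration
#'   order: tissue, then preparation, then ROI index)
#' @param outDir if non-NULL, cubes are written there via [writeCube()]
#'   together with a JSON truth manifest and a YAML study config
#' @param amideReduction optional named vector overriding the planted
#'   per-tissue amide-I reductions (see [defaultBandLibrary()])
#' @return list with `cubes` (list of \linkS4class{HyperspectralCube}),
#'   `truths`, `manifest` (data.frame), `trueReductions` (per tissue/band
#'   planted integral reduction fractions), and `paths` when written
#' @export
generateStudy <- function(tissues = c("kidney", "liver"),
                          preparations = c("FF", "FFPE"),
                          nRois = 8L, roiShape = c(96L, 96L),
                          noiseSd = 0.0015, amplitudeJitter = 0.10,
                          seed = 1L, outDir = NULL,
                          amideReduction = NULL) {
  stopifnot(nRois >= 1L)
  cubes <- list(); truths <- list()
  manifest <- list(); k <- 0L
  for (ti in tissues) for (pr in preparations) {
    red <- if (!is.null(amideReduction) && pr == "FFPE")
      amideReduction[[ti]] else NULL
    lib <- if (pr == "FFPE")
      defaultBandLibrary(ti, pr, amideReduction = red)
    else defaultBandLibrary(ti, pr)
    for (r in seq_len(nRois)) {
      k <- k + 1L
      roiId <- sprintf("%s_%s_roi%d", ti, pr, r)
      cfg <- phantomConfig(ti, pr, roiShape = roiShape, bandLibrary = lib,
                           noiseSd = noiseSd,
                           amplitudeJitter = amplitudeJitter,
                           seed = seed + k, roiId = roiId)
      out <- generateRoi(cfg)
      cubes[[roiId]] <- out$cube
      truths[[roiId]] <- out$truth
      manifest[[k]] <- data.frame(tissue = ti, preparation = pr,
                                  roi_id = roiId, seed = seed + k,
                                  stringsAsFactors = FALSE)
    }
  }
  manifest <- do.call(rbind, manifest)

  red <- list()
  for (ti in intersect(tissues, c("kidney", "liver"))) {
    if (!all(c("FF", "FFPE") %in% preparations)) break
    ff <- cubes[[sprintf("%s_FF_roi1", ti)]]
    libFF <- truths[[sprintf("%s_FF_roi1", ti)]]$bands
    libPE <- truths[[sprintf("%s_FFPE_roi1", ti)]]$bands
    shared <- intersect(libFF$label, libPE$label)
    red[[ti]] <- data.frame(
      tissue = ti, band_label = shared,
      reduction = 1 - libPE$amplitude[match(shared, libPE$label)] /
        libFF$amplitude[match(shared, libFF$label)],
      stringsAsFactors = FALSE)
  }
  trueReductions <- if (length(red)) do.call(rbind, red) else NULL
  res <- list(cubes = cubes, truths = truths, manifest = manifest,
              trueReductions = trueReductions)

  if (!is.null(outDir)) {
    if (!dir.exists(outDir)) dir.create(outDir, recursive = TRUE)
    paths <- character(0)
    for (roiId in names(cubes)) {
      p <- writeCube(cubes[[roiId]], file.path(outDir, roiId))
      paths <- c(paths, p)
    }
    manifestTruth <- lapply(names(truths), function(id) {
      tr <- truths[[id]]
      list(roi_id = id, tissue = tr$config$tissue,
           preparation = tr$config$preparation, seed = tr$config$seed,
           n_tissue_pixels = sum(tr$mask),
           bands = tr$bands)
    })
    jf <- file.path(outDir, "truth_manifest.json")
    jsonlite::write_json(manifestTruth, jf, auto_unbox = TRUE, digits = NA)
    yf <- file.path(outDir, "study_config.yaml")
    yaml::write_yaml(list(tissues = tissues, preparations = preparations,
                          n_rois = nRois, roi_shape = roiShape,
                          noise_sd = noiseSd,
                          amplitude_jitter = amplitudeJitter, seed = seed),
                     yf)
    res$paths <- c(paths, jf, yf)
  }
  row.names(res$manifest) <- NULL
  res
}
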