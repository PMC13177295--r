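## Cube, mask and pixel-set I/O.
##
## Cubes are stored as a multi-page TIFF (one grayscale page per
## wavenumber; values affinely rescaled to [0, 1] for storage with the
## scale/offset recorded in a JSON header) plus a CSV wavenumber sidecar.
## The 32-bit quantization error (~2e-10 of the data range) is far below
## float32 resolution, so write -> read round-trips are identical at
## float32 precision.

#' Write a hyperspectral cube
#'
#' Writes `<path>.tif`, `<path>.json` (shape, scale/offset, metadata) and
#' `<path>_wavenumbers.csv`.
#'
#' @param cube a \linkS4class{HyperspectralCube}
#' @param path output path prefix (no extension)
#' @return the TIFF path, invisibly
#' @export
writeCube <- function(cube, path) {
  d <- cubeData(cube)
  lo <- min(d); hi <- max(d)
  scale <- if (hi > lo) hi - lo else 1
  pages <- lapply(seq_len(dim(d)[3L]), function(k) (d[, , k] - lo) / scale)
  tif <- paste0(path, ".tif")
  suppressWarnings(tiff::writeTIFF(pages, tif, bits.per.sample = 32L,
                                   compression = "none", reduce = FALSE))
  hdr <- list(rows = dim(d)[1L], cols = dim(d)[2L], K = dim(d)[3L],
              offset = lo, scale = scale, meta = cubeMeta(cube),
              axis_step = axisStep(spectralAxis(cube)))
  jsonlite::write_json(hdr, paste0(path, ".json"), auto_unbox = TRUE,
                       digits = NA)
  utils::write.csv(data.frame(wavenumber = wavenumbers(spectralAxis(cube))),
                   paste0(path, "_wavenumbers.csv"), row.names = FALSE)
  invisible(tif)
}

#' Read a hyperspectral cube written by [writeCube()]
#'
#' @param path the path prefix used when writing
#' @return a \linkS4class{HyperspectralCube}
#' @export
readCube <- function(path) {
  tif <- paste0(path, ".tif")
  hdrf <- paste0(path, ".json")
  wnf <- paste0(path, "_wavenumbers.csv")
  if (!file.exists(tif)) stop("cube file not found: ", tif)
  if (!file.exists(hdrf)) stop("cube header sidecar not found: ", hdrf)
  if (!file.exists(wnf)) stop("wavenumber axis sidecar not found: ", wnf)
  hdr <- jsonlite::read_json(hdrf, simplifyVector = TRUE)
  wn <- utils::read.csv(wnf)$wavenumber
  pages <- tiff::readTIFF(tif, all = TRUE)
  if (length(pages) != length(wn))
    stop(sprintf("axis sidecar length (%d) does not match cube pages (%d)",
                 length(wn), length(pages)))
  arr <- simplify2array(pages) * hdr$scale + hdr$offset
  axis <- new("SpectralAxis", values = wn, step = hdr$axis_step)
  meta <- hdr$meta
  new("HyperspectralCube", data = arr, axis = axis,
      meta = if (is.null(meta)) list() else as.list(meta))
}

#' Write / read a tissue mask as single-page uint8 TIFF
#'
#' The Otsu threshold and masking wavenumber travel in a JSON sidecar.
#'
#' @param mask a \linkS4class{TissueMask}
#' @param path path prefix (no extension)
#' @export
writeMask <- function(mask, path) {
  tiff::writeTIFF(maskMatrix(mask) * 1, paste0(path, ".tif"),
                  bits.per.sample = 8L)
  jsonlite::write_json(list(threshold = maskThreshold(mask),
                            band_wn = mask@bandWn),
                       paste0(path, ".json"), auto_unbox = TRUE, digits = NA)
  invisible(paste0(path, ".tif"))
}

#' @rdname writeMask
#' @export
readMask <- function(path) {
  m <- tiff::readTIFF(paste0(path, ".tif")) > 0.5
  hdr <- jsonlite::read_json(paste0(path, ".json"), simplifyVector = TRUE)
  new("TissueMask", mask = m, threshold = hdr$threshold, bandWn = hdr$band_wn)
}

#' Write / read a sampled pixel set as CSV
#'
#' Columns: `roi_id`, `row`, `col`, then one column per wavenumber
#' (`wn_<value>`).
#'
#' @param pset a \linkS4class{PixelSpectrumSet}
#' @param path CSV file path
#' @export
writePixelSet <- function(pset, path) {
  sp <- pixelSpectra(pset)
  colnames(sp) <- paste0("wn_", wavenumbers(spectralAxis(pset)))
  df <- cbind(pixelCoords(pset), as.data.frame(sp))
  attrLine <- sprintf("# seed=%d step=%g", pset@seed,
                      axisStep(spectralAxis(pset)))
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(attrLine, con)
  utils::write.csv(df, con, row.names = FALSE)
  invisible(path)
}

#' @rdname writePixelSet
#' @export
readPixelSet <- function(path) {
  first <- readLines(path, n = 1L)
  seed <- as.integer(sub(".*seed=(\\d+).*", "\\1", first))
  step <- as.numeric(sub(".*step=([0-9.]+).*", "\\1", first))
  df <- utils::read.csv(path, skip = 1L, check.names = FALSE)
  wnCols <- grep("^wn_", names(df))
  wn <- as.numeric(sub("^wn_", "", names(df)[wnCols]))
  axis <- new("SpectralAxis", values = wn, step = step)
  new("PixelSpectrumSet",
      spectra = as.matrix(df[, wnCols, drop = FALSE]),
      coords = df[, c("roi_id", "row", "col"), drop = FALSE],
      axis = axis, seed = seed)
}
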