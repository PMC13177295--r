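#' Build a uniform wavenumber axis
#'
#' @param minWn,maxWn axis limits in cm^-1 (`maxWn > minWn`)
#' @param step grid spacing in cm^-1; the range must be an integer multiple
#'   of `step` (within 1e-6 relative tolerance), otherwise construction is
#'   rejected.
#' @return a \linkS4class{SpectralAxis} with `round((maxWn-minWn)/step)+1`
#'   points.
#' @examples
#' length(wavenumbers(SpectralAxis(950, 1800, 2)))  # 426
#' @export
SpectralAxis <- function(minWn, maxWn, step) {
  stopifnot(is.numeric(minWn), is.numeric(maxWn), is.numeric(step))
  if (maxWn <= minWn) stop("maxWn must exceed minWn")
  if (step <= 0) stop("step must be positive")
  n <- (maxWn - minWn) / step
  if (abs(n - round(n)) > 1e-6 * max(1, abs(n)))
    stop(sprintf("range %g..%g is not divisible by step %g", minWn, maxWn, step))
  values <- minWn + step * seq.int(0L, round(n))
  new("SpectralAxis", values = values, step = step)
}

#' Nearest grid point on an axis
#'
#' Requested wavenumbers are looked up on the grid by nearest neighbour;
#' exact ties are broken toward the lower wavenumber.
#'
#' @param axis a \linkS4class{SpectralAxis}
#' @param wn wavenumber(s) in cm^-1, must lie within the axis range (within
#'   half a step of either end)
#' @return integer index (vector) into `wavenumbers(axis)`
#' @export
nearestIndex <- function(axis, wn) {
  v <- wavenumbers(axis)
  if (any(wn < v[1L] - axis@step / 2 | wn > v[length(v)] + axis@step / 2))
    stop("requested wavenumber outside axis range")
  # tie toward lower wavenumber: floor at exact half-step
  idx <- floor((wn - v[1L]) / axis@step + 0.5)
  # floor(x + 0.5) rounds half up; detect exact half grid positions and pull down
  frac <- (wn - v[1L]) / axis@step
  tie <- abs(frac - (floor(frac) + 0.5)) < 1e-12
  idx[tie] <- floor(frac[tie])
  as.integer(pmin(pmax(idx, 0L), length(v) - 1L)) + 1L
}

#' Trim an axis symmetrically
#' @param axis a \linkS4class{SpectralAxis}
#' @param perSide number of grid points to drop from each end
#' @return the trimmed \linkS4class{SpectralAxis}
#' @keywords internal
trimAxis <- function(axis, perSide) {
  v <- wavenumbers(axis)
  if (length(v) <= 2L * perSide + 2L) stop("axis too short to trim")
  new("SpectralAxis", values = v[(perSide + 1L):(length(v) - perSide)],
      step = axis@step)
}

# run code with a private RNG state, leaving the caller's stream untouched
withSeed <- function(seed, code) {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
  } else {
    on.exit(rm(".Random.seed", envir = globalenv()), add = TRUE)
  }
  set.seed(as.integer(seed %% .Machine$integer.max))
  force(code)
}
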