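#' Construct a Raman spectrum
#'
#' A `raman_spectrum` bundles a strictly increasing wavenumber grid with
#' intensities and the laser-line reference intensity recorded alongside the
#' acquisition.  The reference is the normalization constant that makes
#' spectra comparable across samples measured at (slightly) different laser
#' powers; see [normalize_to_reference()].
#'
#' @param wavenumbers Numeric vector of wavenumbers (cm^-1), strictly
#'   increasing.
#' @param intensities Numeric vector of intensities (arbitrary units), same
#'   length as `wavenumbers`.
#' @param reference_intensity Positive scalar; laser-line intensity proxy.
#' @return An object of class `raman_spectrum`: a list with elements
#'   `wavenumbers`, `intensities` and `reference_intensity`.
#' @examples
#' s <- raman_spectrum(seq(377, 1720, by = 4), rnorm(336), 1)
#' s
#' @export
raman_spectrum <- function(wavenumbers, intensities, reference_intensity = 1) {
  wavenumbers <- as.numeric(wavenumbers)
  intensities <- as.numeric(intensities)
  if (length(wavenumbers) == 0L)
    stop("spectrum must contain at least one point", call. = FALSE)
  if (length(wavenumbers) != length(intensities))
    stop("`wavenumbers` and `intensities` must have equal length",
         call. = FALSE)
  if (length(wavenumbers) > 1L && any(diff(wavenumbers) <= 0))
    stop("`wavenumbers` must be strictly increasing", call. = FALSE)
  if (length(reference_intensity) != 1L || !is.finite(reference_intensity) ||
      reference_intensity <= 0)
    stop("`reference_intensity` must be a positive finite scalar",
         call. = FALSE)
  structure(
    list(wavenumbers = wavenumbers, intensities = intensities,
         reference_intensity = as.numeric(reference_intensity)),
    class = "raman_spectrum"
  )
}

#' @export
print.raman_spectrum <- function(x, ...) {
  cat(sprintf(
    "<raman_spectrum> %d points, %.0f-%.0f cm^-1, reference %.4g\n",
    length(x$wavenumbers), min(x$wavenumbers), max(x$wavenumbers),
    x$reference_intensity))
  invisible(x)
}

#' Spectral map container
#'
#' An H x W grid of spectra sharing one wavenumber axis -- the unit of one
#' sample's confocal Raman measurement.  Pixels are stored row-major: pixel
#' (i, j) is row `(i - 1) * width + j` of the intensity matrix.
#'
#' @param wavenumbers Shared wavenumber grid, strictly increasing.
#' @param intensities Numeric matrix, `height * width` rows (pixels, row-major
#'   order) by `length(wavenumbers)` columns.
#' @param reference_intensities Positive per-pixel laser-line reference
#'   intensities, length `height * width`.
#' @param height,width Map dimensions in pixels.
#' @param sample_id Sample label.
#' @param class Class label, `"normal"` or `"rod"`.
#' @return An object of class `spectral_map`.
#' @seealso [simulate_map()], [map_spectrum()] to pull out one pixel.
#' @export
spectral_map <- function(wavenumbers, intensities, reference_intensities,
                         height, width, sample_id = "sample",
                         class = c("normal", "rod")) {
  class <- match.arg(class)
  wavenumbers <- as.numeric(wavenumbers)
  intensities <- as.matrix(intensities)
  if (length(wavenumbers) > 1L && any(diff(wavenumbers) <= 0))
    stop("`wavenumbers` must be strictly increasing", call. = FALSE)
  if (height < 1L || width < 1L)
    stop("map dimensions must be >= 1", call. = FALSE)
  n_px <- as.integer(height) * as.integer(width)
  if (nrow(intensities) != n_px || ncol(intensities) != length(wavenumbers))
    stop(sprintf(
      "intensity matrix must be %d pixels x %d wavenumbers", n_px,
      length(wavenumbers)), call. = FALSE)
  if (length(reference_intensities) != n_px ||
      any(!is.finite(reference_intensities)) ||
      any(reference_intensities <= 0))
    stop("`reference_intensities` must be positive, one per pixel",
         call. = FALSE)
  structure(
    list(wavenumbers = wavenumbers, intensities = intensities,
         reference_intensities = as.numeric(reference_intensities),
         height = as.integer(height), width = as.integer(width),
         sample_id = as.character(sample_id), class = class),
    class = "spectral_map"
  )
}

#' @export
print.spectral_map <- function(x, ...) {
  cat(sprintf(
    "<spectral_map> %s (%s): %d x %d pixels, %d wavenumbers (%.0f-%.0f cm^-1)\n",
    x$sample_id, x$class, x$height, x$width, length(x$wavenumbers),
    min(x$wavenumbers), max(x$wavenumbers)))
  invisible(x)
}

#' Extract one pixel of a map as a `raman_spectrum`
#'
#' @param map A [spectral_map()].
#' @param pixel Row-major pixel index (1-based).
#' @return A [raman_spectrum()].
#' @export
map_spectrum <- function(map, pixel) {
  stopifnot(inherits(map, "spectral_map"))
  n_px <- map$height * map$width
  if (pixel < 1L || pixel > n_px)
    stop(sprintf("`pixel` must be in 1..%d", n_px), call. = FALSE)
  raman_spectrum(map$wavenumbers, map$intensities[pixel, ],
                 map$reference_intensities[pixel])
}
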