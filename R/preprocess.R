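# Normalization, baseline correction and band-window integration.

# Integration weights reproducing the composite trapezoid rule:
# sum(w * y) == trapz(x, y).
trapz_weights <- function(x) {
  n <- length(x)
  if (n < 2L) stop("need at least 2 points to integrate", call. = FALSE)
  dx <- diff(x)
  w <- numeric(n)
  w[1] <- dx[1] / 2
  w[n] <- dx[n - 1] / 2
  if (n > 2L) w[2:(n - 1)] <- (dx[-(n - 1)] + dx[-1]) / 2
  w
}

# Composite Simpson weights on a uniform grid (odd point count); falls back
# to trapezoid on the final interval when the count is even.
simpson_weights <- function(x) {
  n <- length(x)
  dx <- diff(x)
  if (n < 3L || max(abs(dx - dx[1])) > 1e-8 * dx[1])
    return(trapz_weights(x))
  m <- if (n %% 2L == 1L) n else n - 1L
  w <- numeric(n)
  h <- dx[1]
  w[1:m] <- h / 3 * c(1, rep(c(4, 2), length.out = m - 2L), 1)
  if (m < n) { # trailing trapezoid panel
    w[n - 1L] <- w[n - 1L] + h / 2
    w[n] <- h / 2
  }
  w
}

# Nearest-grid-point snapping of a window, inclusive at both ends.
snap_window_idx <- function(wn, window) {
  n <- length(wn)
  if (window$hi < wn[1] || window$lo > wn[n])
    stop(sprintf("window '%s' [%g, %g] lies outside the spectrum grid",
                 window$name, window$lo, window$hi), call. = FALSE)
  lo_i <- which.min(abs(wn - window$lo))
  hi_i <- which.min(abs(wn - window$hi))
  idx <- lo_i:hi_i
  if (length(idx) < 3L)
    stop(sprintf(
      "window '%s' intersects the grid in %d point(s); need >= 3",
      window$name, length(idx)), call. = FALSE)
  idx
}

# Narrow windows cannot accommodate 2 * edge_points disjoint edge regions;
# cap at a third of the window so the two edges never cover it entirely.
cap_edge_points <- function(edge_points, n_points) {
  max(1L, min(as.integer(edge_points), n_points %/% 3L))
}

#' Crop a spectrum to a wavenumber region
#'
#' Retains the grid points with `lo <= wavenumber <= hi`.  The default region
#' 377-1720 cm^-1 is the working range of the whole analysis.
#'
#' @param spectrum A [raman_spectrum()].
#' @param lo,hi Region bounds (cm^-1).
#' @return The cropped [raman_spectrum()]; reference intensity preserved.
#' @export
crop <- function(spectrum, lo = 377, hi = 1720) {
  stopifnot(inherits(spectrum, "raman_spectrum"))
  keep <- spectrum$wavenumbers >= lo & spectrum$wavenumbers <= hi
  if (!any(keep))
    stop(sprintf("no grid points in [%g, %g]", lo, hi), call. = FALSE)
  raman_spectrum(spectrum$wavenumbers[keep], spectrum$intensities[keep],
                 spectrum$reference_intensity)
}

#' Normalize a spectrum to its laser-line reference intensity
#'
#' Divides intensities by the attached reference intensity and resets the
#' reference to 1, making the operation idempotent.  This removes
#' acquisition-to-acquisition laser-power fluctuations; two spectra that
#' differ only by an overall power scale become identical.
#'
#' @param spectrum A [raman_spectrum()] with positive reference intensity.
#' @return The normalized [raman_spectrum()].
#' @export
normalize_to_reference <- function(spectrum) {
  stopifnot(inherits(spectrum, "raman_spectrum"))
  ref <- spectrum$reference_intensity
  if (!is.finite(ref) || ref <= 0)
    stop("reference intensity must be positive", call. = FALSE)
  raman_spectrum(spectrum$wavenumbers, spectrum$intensities / ref, 1)
}

# Fit the removal line within wn[idx]: either through the mean point of the
# first and last `edge_points` grid points ("edges"), or least squares
# through every point in the window ("least_squares").
fit_baseline_line <- function(wn, y, idx, edge_points,
                              method = c("edges", "least_squares")) {
  method <- match.arg(method)
  if (method == "least_squares") {
    cf <- stats::lm.fit(cbind(1, wn[idx]), y[idx])$coefficients
    return(list(intercept = cf[1], slope = cf[2]))
  }
  m <- length(idx)
  ep <- as.integer(edge_points)
  i1 <- idx[seq_len(ep)]
  i2 <- idx[m - ep + seq_len(ep)]
  x1 <- mean(wn[i1]); y1 <- mean(y[i1])
  x2 <- mean(wn[i2]); y2 <- mean(y[i2])
  slope <- (y2 - y1) / (x2 - x1)
  list(intercept = y1 - slope * x1, slope = slope)
}

#' Linear baseline subtraction
#'
#' Fits a straight line to the edges of the window `[lo, hi]` -- through the
#' mean wavenumber/intensity of the first and last `edge_points` grid points
#' inside the window -- and subtracts it from the whole spectrum.  Applied
#' with the default full-range window this is the global background removal;
#' band integration applies the same construction locally per window (see
#' [band_area()]).
#'
#' @param spectrum A [raman_spectrum()].
#' @param lo,hi Fitting window (cm^-1); defaults to the full grid range.
#' @param edge_points Number of grid points averaged at each window end; the
#'   window must contain at least `2 * edge_points` points.
#' @param method `"edges"` (robust mean-of-edges line, the default) or
#'   `"least_squares"` (line through all window points).
#' @return The baseline-subtracted [raman_spectrum()].
#' @export
linear_baseline_subtract <- function(spectrum, lo = NULL, hi = NULL,
                                     edge_points = 5,
                                     method = c("edges", "least_squares")) {
  stopifnot(inherits(spectrum, "raman_spectrum"))
  method <- match.arg(method)
  wn <- spectrum$wavenumbers
  if (is.null(lo)) lo <- wn[1]
  if (is.null(hi)) hi <- wn[length(wn)]
  idx <- which(wn >= lo & wn <= hi)
  if (length(idx) < 2L * edge_points)
    stop(sprintf(
      "window [%g, %g] holds %d grid points; need >= 2 * edge_points = %d",
      lo, hi, length(idx), 2L * as.integer(edge_points)), call. = FALSE)
  line <- fit_baseline_line(wn, spectrum$intensities, idx, edge_points,
                            method)
  raman_spectrum(wn, spectrum$intensities - (line$intercept +
                                             line$slope * wn),
                 spectrum$reference_intensity)
}

# Vectorized workhorse: band areas for a pixels-by-wavenumbers matrix.
# Local edge-mean baseline per pixel, trapezoid (or Simpson) integration.
band_area_matrix <- function(Y, wn, window, edge_points = 5, clamp = TRUE,
                             rule = c("trapezoid", "simpson")) {
  rule <- match.arg(rule)
  idx <- snap_window_idx(wn, window)
  m <- length(idx)
  ep <- cap_edge_points(edge_points, m)
  i1 <- idx[seq_len(ep)]
  i2 <- idx[m - ep + seq_len(ep)]
  x1 <- mean(wn[i1]); x2 <- mean(wn[i2])
  y1 <- rowMeans(Y[, i1, drop = FALSE])
  y2 <- rowMeans(Y[, i2, drop = FALSE])
  slope <- (y2 - y1) / (x2 - x1)
  icpt <- y1 - slope * x1
  x <- wn[idx]
  w <- if (rule == "simpson") simpson_weights(x) else trapz_weights(x)
  area <- as.vector(Y[, idx, drop = FALSE] %*% w) -
    (icpt * sum(w) + slope * sum(w * x))
  if (clamp) area <- pmax(area, 0)
  area
}

#' Integrated band area over a window
#'
#' Integrates the spectrum over `[lo, hi]` (nearest-grid-point snapped,
#' inclusive) after removing a local straight baseline fitted through the
#' window edges, by the composite trapezoid rule on the native grid.  Noise
#' can push areas negative; by default they are clamped at zero for ratio
#' stability (`clamp = FALSE` restores exact linearity in the spectrum).
#'
#' For windows too narrow to hold `2 * edge_points` points, the edge regions
#' are shrunk to a third of the window (at least one point each).
#'
#' @param spectrum A [raman_spectrum()].
#' @param window A [band_window()] overlapping the grid in >= 3 points.
#' @param edge_points Points averaged per window edge for the local baseline.
#' @param clamp Clamp negative areas at 0 (default `TRUE`).
#' @param rule `"trapezoid"` (default) or `"simpson"`.
#' @return The integrated area (arb. units * cm^-1).
#' @examples
#' wn <- seq(377, 1720, by = 4)
#' y <- exp(-4 * log(2) * (wn - 960)^2 / 15^2)
#' band_area(raman_spectrum(wn, y), band_window("nu1PO4", 960, 907, 990))
#' @export
band_area <- function(spectrum, window, edge_points = 5, clamp = TRUE,
                      rule = c("trapezoid", "simpson")) {
  stopifnot(inherits(spectrum, "raman_spectrum"),
            inherits(window, "band_window"))
  band_area_matrix(matrix(spectrum$intensities, nrow = 1),
                   spectrum$wavenumbers, window, edge_points, clamp,
                   match.arg(rule))
}

#' Extract all band areas of one spectrum
#'
#' Computes one [band_area()] per window, each with its own local baseline;
#' overlapping windows are permitted and integrated independently.
#'
#' @param spectrum A [raman_spectrum()].
#' @param windows List of [band_window()] with unique names; defaults to
#'   [default_band_windows()].
#' @inheritParams band_area
#' @return Named numeric vector of areas, one per window.
#' @export
extract_all_bands <- function(spectrum, windows = default_band_windows(),
                              edge_points = 5, clamp = TRUE,
                              rule = c("trapezoid", "simpson")) {
  rule <- match.arg(rule)
  nm <- vapply(windows, `[[`, character(1), "name")
  if (anyDuplicated(nm))
    stop("duplicate window names: ",
         paste(unique(nm[duplicated(nm)]), collapse = ", "), call. = FALSE)
  areas <- vapply(windows, function(w)
    band_area(spectrum, w, edge_points, clamp, rule), numeric(1))
  names(areas) <- nm
  areas
}

#' Band areas for every pixel of a map
#'
#' The per-spectrum chain (laser-line normalization, global linear baseline
#' over the full grid, local per-window baseline, trapezoid integration)
#' applied to a whole [spectral_map()] with matrix arithmetic.  Produces the
#' per-spectrum band-area table that feeds [biomarker_table()].
#'
#' @param map A [spectral_map()].
#' @param windows List of uniquely named [band_window()].
#' @param normalize Divide each pixel by its reference intensity first.
#' @param global_baseline Remove the full-range edge-fitted line first.
#' @inheritParams band_area
#' @return A data frame: `spectrum_id`, `sample_id`, `class`, one numeric
#'   column per band window.
#' @export
extract_map_bands <- function(map, windows = default_band_windows(),
                              normalize = TRUE, global_baseline = TRUE,
                              edge_points = 5, clamp = TRUE,
                              rule = c("trapezoid", "simpson")) {
  stopifnot(inherits(map, "spectral_map"))
  rule <- match.arg(rule)
  nm <- vapply(windows, `[[`, character(1), "name")
  if (anyDuplicated(nm))
    stop("duplicate window names: ",
         paste(unique(nm[duplicated(nm)]), collapse = ", "), call. = FALSE)

  wn <- map$wavenumbers
  Y <- map$intensities
  if (normalize) Y <- Y / map$reference_intensities
  if (global_baseline) {
    n <- length(wn)
    ep <- as.integer(edge_points)
    if (n < 2L * ep)
      stop("grid too short for the global baseline edge regions",
           call. = FALSE)
    i1 <- seq_len(ep); i2 <- n - ep + seq_len(ep)
    x1 <- mean(wn[i1]); x2 <- mean(wn[i2])
    y1 <- rowMeans(Y[, i1, drop = FALSE])
    y2 <- rowMeans(Y[, i2, drop = FALSE])
    slope <- (y2 - y1) / (x2 - x1)
    icpt <- y1 - slope * x1
    Y <- Y - outer(slope, wn) - icpt
  }

  out <- data.frame(
    spectrum_id = sprintf("%s_px%d", map$sample_id,
                          seq_len(nrow(Y))),
    sample_id = map$sample_id, class = map$class,
    stringsAsFactors = FALSE)
  for (k in seq_along(windows))
    out[[nm[k]]] <- band_area_matrix(Y, wn, windows[[k]], edge_points,
                                     clamp, rule)
  out
}

#' Band-area table for a whole cohort
#'
#' [extract_map_bands()] applied to every map of a [simulate_cohort()] result
#' (or any list of maps with a manifest), row-bound.
#'
#' @param cohort A `raman_cohort`.
#' @inheritParams extract_map_bands
#' @return A data frame, one row per spectrum across all maps.
#' @export
cohort_band_table <- function(cohort, windows = default_band_windows(),
                              normalize = TRUE, global_baseline = TRUE,
                              edge_points = 5, clamp = TRUE,
                              rule = c("trapezoid", "simpson")) {
  stopifnot(inherits(cohort, "raman_cohort"))
  rule <- match.arg(rule)
  do.call(rbind, lapply(cohort$maps, extract_map_bands, windows = windows,
                        normalize = normalize,
                        global_baseline = global_baseline,
                        edge_points = edge_points, clamp = clamp,
                        rule = rule))
}
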