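#' Simulation configuration
#'
#' Collects every knob of the synthetic cohort generator.  The defaults are
#' the study conditions the package emulates: a 377-1720 cm^-1 axis at
#' 4 cm^-1 spacing (336 points), 3 normal and 4 ROD specimens, one
#' 150 x 150-pixel confocal map (22,500 spectra) per specimen, a shallow
#' linear fluorescence background, additive Gaussian detector noise, and a
#' per-spectrum laser-line reference intensity.  Smaller maps are used for
#' exploratory work and tests; pass `map_height`/`map_width` accordingly.
#'
#' @param axis_min,axis_max,axis_step Wavenumber axis (cm^-1).  The grid is
#'   `seq(axis_min, axis_max, by = axis_step)`.
#' @param n_normal_samples,n_rod_samples Specimens per class.
#' @param map_height,map_width Map dimensions in pixels.
#' @param baseline_slope,baseline_intercept Linear background: intensity =
#'   `baseline_intercept + baseline_slope * wavenumber` (arb. units).
#' @param noise_sd Standard deviation of additive Gaussian noise (arb.
#'   units); 0 disables noise.
#' @param reference_intensity_mean,reference_intensity_cv Mean and
#'   coefficient of variation of the log-normal per-spectrum laser-line
#'   reference intensity.
#' @param spatial_sd Standard deviation of an optional smooth spatial
#'   log-amplitude field modulating band intensities across a map (texture);
#'   0 (the default) disables it.
#' @param spatial_range Smoothing window (pixels, odd) of the spatial field.
#' @param bands Band library, a list of [band_spec()].
#' @param seed Integer seed making cohorts reproducible; `NULL` leaves the
#'   R random-number stream untouched.
#' @return An object of class `sim_config`.
#' @examples
#' cfg <- sim_config(map_height = 4, map_width = 4, seed = 1)
#' length(sim_axis(cfg))
#' @export
sim_config <- function(axis_min = 377, axis_max = 1720, axis_step = 4,
                       n_normal_samples = 3, n_rod_samples = 4,
                       map_height = 150, map_width = 150,
                       baseline_slope = -2e-4, baseline_intercept = 0.6,
                       noise_sd = 0.02,
                       reference_intensity_mean = 1,
                       reference_intensity_cv = 0.05,
                       spatial_sd = 0, spatial_range = 5,
                       bands = default_band_library(),
                       seed = NULL) {
  if (axis_step <= 0 || axis_max <= axis_min)
    stop("axis must satisfy axis_min < axis_max and axis_step > 0",
         call. = FALSE)
  if (n_normal_samples < 0 || n_rod_samples < 0)
    stop("sample counts must be >= 0", call. = FALSE)
  if (map_height < 1 || map_width < 1)
    stop("map dimensions must be >= 1", call. = FALSE)
  if (noise_sd < 0)
    stop("`noise_sd` must be >= 0 (use exactly 0 for no noise)",
         call. = FALSE)
  if (reference_intensity_mean <= 0 || reference_intensity_cv < 0)
    stop("reference intensity mean must be > 0 and cv >= 0", call. = FALSE)
  if (spatial_sd < 0) stop("`spatial_sd` must be >= 0", call. = FALSE)
  if (!is.list(bands) || !all(vapply(bands, inherits, logical(1), "band_spec")))
    stop("`bands` must be a list of band_spec objects", call. = FALSE)
  nm <- vapply(bands, `[[`, character(1), "name")
  if (anyDuplicated(nm)) stop("band names must be unique", call. = FALSE)
  structure(
    list(axis_min = axis_min, axis_max = axis_max, axis_step = axis_step,
         n_normal_samples = as.integer(n_normal_samples),
         n_rod_samples = as.integer(n_rod_samples),
         map_height = as.integer(map_height),
         map_width = as.integer(map_width),
         baseline_slope = baseline_slope,
         baseline_intercept = baseline_intercept,
         noise_sd = noise_sd,
         reference_intensity_mean = reference_intensity_mean,
         reference_intensity_cv = reference_intensity_cv,
         spatial_sd = spatial_sd, spatial_range = as.integer(spatial_range),
         bands = bands,
         seed = if (is.null(seed)) NULL else as.integer(seed)),
    class = "sim_config"
  )
}

#' Wavenumber axis of a configuration
#'
#' @param config A [sim_config()].
#' @return Numeric vector `seq(axis_min, axis_max, by = axis_step)`.
#' @export
sim_axis <- function(config) {
  seq(config$axis_min, config$axis_max, by = config$axis_step)
}

#' @export
print.sim_config <- function(x, ...) {
  cat(sprintf(
    paste0("<sim_config> axis %g-%g step %g (%d pts); %d normal + %d ROD ",
           "maps of %d x %d; noise_sd %g; seed %s\n"),
    x$axis_min, x$axis_max, x$axis_step, length(sim_axis(x)),
    x$n_normal_samples, x$n_rod_samples, x$map_height, x$map_width,
    x$noise_sd, if (is.null(x$seed)) "none" else x$seed))
  invisible(x)
}

# Log-normal draws with mean 1 and the given coefficient(s) of variation.
# cv = 0 degenerates to the constant 1 (still consumes one draw per entry so
# random streams do not depend on which CVs happen to be zero).
rlnorm_unit_mean <- function(n, cv) {
  sdlog <- sqrt(log1p(cv^2))
  stats::rlnorm(n, meanlog = -sdlog^2 / 2, sdlog = sdlog)
}

#' Draw per-sample band effects
#'
#' One specimen's multiplicative band-amplitude effects: independent
#' log-normal draws with unit mean and each band's `sample_cv`.  These model
#' the between-patient heterogeneity visible as distinct per-sample clusters
#' in biomarker scatter plots.
#'
#' @param sample_id Sample label.
#' @param class_label `"normal"` or `"rod"`.
#' @param bands Band library (list of [band_spec()]).
#' @return An object of class `sample_effects` with a named positive
#'   `band_multipliers` vector.
#' @export
sample_effects <- function(sample_id, class_label = c("normal", "rod"),
                           bands = default_band_library()) {
  class_label <- match.arg(class_label)
  cvs <- vapply(bands, `[[`, numeric(1), "sample_cv")
  mult <- rlnorm_unit_mean(length(bands), cvs)
  names(mult) <- vapply(bands, `[[`, character(1), "name")
  structure(
    list(sample_id = as.character(sample_id), class_label = class_label,
         band_multipliers = mult),
    class = "sample_effects"
  )
}
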