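# Synthetic bone Raman spectra, maps and cohorts.
#
# Signal model for one spectrum:
#   I(nu) = baseline(nu)
#         + sum_b  m_b * f_b * A_b(class) * exp(-4 ln2 (nu - c_b)^2 / w_b^2)
#         + N(0, noise_sd)
# where m_b is the specimen's log-normal band multiplier (sample_cv) and
# f_b a per-spectrum log-normal factor (spectrum_cv), both unit-mean.
# A laser-line reference intensity is drawn per spectrum and attached.

gauss_profile <- function(wn, center, fwhm) {
  exp(-4 * log(2) * (wn - center)^2 / fwhm^2)
}

#' Simulate one Raman spectrum
#'
#' Draws one synthetic spectrum from the band model: linear background plus
#' unit-height Gaussian profiles scaled by the class mean amplitude, the
#' specimen's band multipliers and a fresh per-spectrum log-normal factor,
#' plus additive Gaussian noise.  Uses (and advances) R's global random
#' stream; seed upstream with `set.seed()` for reproducibility.
#'
#' @param bands Band library (list of [band_spec()]).
#' @param effects A [sample_effects()] for the specimen the spectrum belongs
#'   to.
#' @param config A [sim_config()] (axis, baseline, noise, reference).
#' @param extra_multipliers Optional named per-band multipliers (used by
#'   [simulate_map()] for spatial texture); default none.
#' @return A [raman_spectrum()].
#' @examples
#' set.seed(1)
#' eff <- sample_effects("s1", "rod")
#' s <- simulate_spectrum(default_band_library(), eff, sim_config())
#' @export
simulate_spectrum <- function(bands, effects, config,
                              extra_multipliers = NULL) {
  stopifnot(inherits(effects, "sample_effects"),
            inherits(config, "sim_config"))
  wn <- sim_axis(config)
  y <- config$baseline_intercept + config$baseline_slope * wn

  amp_field <- if (effects$class_label == "rod") "mean_amplitude_rod"
               else "mean_amplitude_normal"
  scv <- vapply(bands, `[[`, numeric(1), "spectrum_cv")
  f <- rlnorm_unit_mean(length(bands), scv)
  for (i in seq_along(bands)) {
    b <- bands[[i]]
    amp <- b[[amp_field]] * effects$band_multipliers[[b$name]] * f[i]
    if (!is.null(extra_multipliers) && b$name %in% names(extra_multipliers))
      amp <- amp * extra_multipliers[[b$name]]
    if (amp != 0)
      y <- y + amp * gauss_profile(wn, b$center, b$fwhm)
  }
  if (config$noise_sd > 0)
    y <- y + stats::rnorm(length(wn), 0, config$noise_sd)

  sdlog <- sqrt(log1p(config$reference_intensity_cv^2))
  ref <- stats::rlnorm(1, meanlog = log(config$reference_intensity_mean) -
                            sdlog^2 / 2, sdlog = sdlog)
  raman_spectrum(wn, y, ref)
}

# Smooth unit-mean multiplier field (H x W): moving-average-smoothed white
# noise, rescaled to sd `spatial_sd` on the log scale, exponentiated.
smooth_field <- function(h, w, spatial_sd, spatial_range) {
  raw <- matrix(stats::rnorm(h * w), h, w)
  k <- max(1L, spatial_range)
  if (k > 1L && h > 1L && w > 1L) {
    kern <- rep(1 / k, k)
    raw <- apply(raw, 2, function(col)
      stats::filter(col, kern, circular = TRUE))
    raw <- t(apply(raw, 1, function(row)
      stats::filter(row, kern, circular = TRUE)))
    raw <- matrix(as.numeric(raw), h, w)
  }
  s <- stats::sd(raw)
  if (s > 0) raw <- raw / s * spatial_sd else raw[] <- 0
  exp(raw - spatial_sd^2 / 2)
}

#' Simulate a confocal Raman map
#'
#' Generates an H x W grid of independent [simulate_spectrum()] draws for one
#' specimen.  With `spatial_sd > 0` in the configuration, a smooth per-band
#' spatial field additionally modulates band amplitudes, giving maps the
#' patchy texture of real tissue images; the field is off by default and
#' purely cosmetic.
#'
#' A 1 x 1 map consumes the random stream exactly as one
#' [simulate_spectrum()] call, so pixel draws are reproducible at any map
#' size given the same upstream seed.
#'
#' @param sample A [sample_effects()].
#' @param config A [sim_config()].
#' @return A [spectral_map()].
#' @export
simulate_map <- function(sample, config) {
  stopifnot(inherits(sample, "sample_effects"),
            inherits(config, "sim_config"))
  h <- config$map_height; w <- config$map_width
  n_px <- h * w
  wn <- sim_axis(config)

  fields <- NULL
  if (config$spatial_sd > 0) {
    fields <- lapply(config$bands, function(b)
      smooth_field(h, w, config$spatial_sd, config$spatial_range))
    names(fields) <- vapply(config$bands, `[[`, character(1), "name")
  }

  Y <- matrix(0, n_px, length(wn))
  refs <- numeric(n_px)
  for (px in seq_len(n_px)) {
    extra <- NULL
    if (!is.null(fields)) {
      i <- (px - 1L) %/% w + 1L
      j <- (px - 1L) %% w + 1L
      extra <- vapply(fields, function(f) f[i, j], numeric(1))
    }
    s <- simulate_spectrum(config$bands, sample, config,
                           extra_multipliers = extra)
    Y[px, ] <- s$intensities
    refs[px] <- s$reference_intensity
  }
  spectral_map(wn, Y, refs, h, w, sample_id = sample$sample_id,
               class = sample$class_label)
}

#' Simulate a labelled cohort of Raman maps
#'
#' Draws fresh [sample_effects()] for `n_normal_samples` normal and
#' `n_rod_samples` ROD specimens, then one map per specimen.  With the
#' default configuration this is 3 + 4 maps of 22,500 spectra each (157,500
#' spectra).  Identical configurations (including `seed`) give bit-identical
#' cohorts.
#'
#' @param config A [sim_config()]; must request at least one specimen of each
#'   class (the downstream classifier needs both).
#' @return An object of class `raman_cohort`: list of `maps`, a `manifest`
#'   data frame (`sample_id`, `class`) and the `config`.
#' @examples
#' co <- simulate_cohort(sim_config(map_height = 2, map_width = 2, seed = 1))
#' co$manifest
#' @export
simulate_cohort <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  if (config$n_normal_samples < 1L || config$n_rod_samples < 1L)
    stop("cohort needs at least one specimen of each class", call. = FALSE)
  if (!is.null(config$seed)) set.seed(config$seed)

  ids <- c(sprintf("normal_%d", seq_len(config$n_normal_samples)),
           sprintf("rod_%d", seq_len(config$n_rod_samples)))
  classes <- c(rep("normal", config$n_normal_samples),
               rep("rod", config$n_rod_samples))

  # all sample effects drawn before any map, so the per-specimen biology
  # does not depend on map size
  effects <- Map(function(id, cl) sample_effects(id, cl, config$bands),
                 ids, classes)
  maps <- lapply(effects, simulate_map, config = config)
  names(maps) <- ids

  structure(
    list(maps = maps,
         manifest = data.frame(sample_id = ids, class = classes,
                               stringsAsFactors = FALSE),
         config = config),
    class = "raman_cohort"
  )
}

#' @export
print.raman_cohort <- function(x, ...) {
  n_px <- vapply(x$maps, function(m) m$height * m$width, numeric(1))
  cat(sprintf(
    "<raman_cohort> %d maps (%d normal, %d ROD), %d spectra total\n",
    length(x$maps), sum(x$manifest$class == "normal"),
    sum(x$manifest$class == "rod"), sum(n_px)))
  invisible(x)
}
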