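# Synthetic spectrum / map / cohort generator.

test_that("default band library matches the seven-band protocol", {
  lib <- default_band_library()
  centers <- vapply(lib, `[[`, numeric(1), "center")
  expect_setequal(centers, c(430, 960, 1005, 1074, 1275, 1609, 1660))
  expect_length(lib, 7L)

  phe <- lib[vapply(lib, function(b) b$center %in% c(1005, 1609),
                    logical(1))]
  for (b in phe)
    expect_gt(b$mean_amplitude_rod, b$mean_amplitude_normal)

  # mineral/carbonate bands drop in ROD while the amide (matrix) references
  # stay put
  by_name <- setNames(lib, vapply(lib, `[[`, character(1), "name"))
  for (nm in c("nu2PO4", "nu1PO4", "nu1CO3"))
    expect_lt(by_name[[nm]]$mean_amplitude_rod,
              by_name[[nm]]$mean_amplitude_normal)
  for (nm in c("amideI", "amideIII"))
    expect_equal(by_name[[nm]]$mean_amplitude_rod,
                 by_name[[nm]]$mean_amplitude_normal)

  for (b in lib) {
    expect_gt(b$fwhm, 0)
    expect_true(b$center >= 377 && b$center <= 1720)
  }
})

test_that("band_spec validates its invariants", {
  expect_error(band_spec("x", 200, 10, 1, 1), "377")
  expect_error(band_spec("x", 960, -1, 1, 1), "fwhm")
  expect_error(band_spec("x", 960, 10, -1, 1), "amplitudes")
  expect_error(band_spec("x", 960, 10, 1, 1, sample_cv = -0.1),
               "variation")
})

test_that("null signal produces an identically-zero trace", {
  bands <- list(band_spec("b", 960, 15, 0, 0))
  cfg <- sim_config(baseline_slope = 0, baseline_intercept = 0,
                    noise_sd = 0, bands = bands)
  set.seed(1)
  s <- simulate_spectrum(bands, sample_effects("s", "normal", bands), cfg)
  expect_identical(s$intensities, rep(0, length(sim_axis(cfg))))
})

test_that("a single noise-free band integrates to the Gaussian closed form", {
  A <- 1.7; w <- 15
  bands <- list(band_spec("b", 960, w, A, A))
  cfg <- sim_config(baseline_slope = 0, baseline_intercept = 0,
                    noise_sd = 0, reference_intensity_cv = 0,
                    bands = bands)
  set.seed(3)
  eff <- sample_effects("s", "normal", bands)      # sample_cv 0 -> mult 1
  s <- simulate_spectrum(bands, eff, cfg)
  got <- pracma::trapz(s$wavenumbers[s$wavenumbers >= 870 &
                                       s$wavenumbers <= 1050],
                       s$intensities[s$wavenumbers >= 870 &
                                       s$wavenumbers <= 1050])
  expect_lt(abs(got - gaussian_area(A, w)) / gaussian_area(A, w), 0.01)
})

test_that("identical seeds give bit-identical spectra, maps and cohorts", {
  cfg <- sim_config(map_height = 3, map_width = 2, seed = 11)
  bands <- cfg$bands
  set.seed(5)
  eff <- sample_effects("s", "rod", bands)
  set.seed(9); s1 <- simulate_spectrum(bands, eff, cfg)
  set.seed(9); s2 <- simulate_spectrum(bands, eff, cfg)
  expect_identical(s1, s2)

  c1 <- simulate_cohort(cfg)
  c2 <- simulate_cohort(cfg)
  expect_identical(c1$manifest, c2$manifest)
  expect_identical(c1$maps, c2$maps)
})

test_that("a 1x1 map equals one simulate_spectrum call on the same stream", {
  cfg <- sim_config(map_height = 1, map_width = 1)
  set.seed(21)
  eff <- sample_effects("s", "normal", cfg$bands)
  set.seed(33)
  m <- simulate_map(eff, cfg)
  set.seed(33)
  s <- simulate_spectrum(cfg$bands, eff, cfg)
  expect_identical(as.numeric(m$intensities[1, ]), s$intensities)
  expect_identical(m$reference_intensities[1], s$reference_intensity)
})

test_that("map geometry and noise-driven area variance behave", {
  cfg <- sim_config(map_height = 10, map_width = 10, seed = 2)
  set.seed(2)
  eff <- sample_effects("s", "rod", cfg$bands)
  m <- simulate_map(eff, cfg)
  expect_equal(dim(m$intensities), c(100L, length(sim_axis(cfg))))

  areas <- extract_map_bands(m)
  expect_gt(var(areas$nu1PO4), 0)
  expect_gt(var(areas$amideI), 0)
})

test_that("cohorts have the requested size and manifest", {
  co <- simulate_cohort(sim_config(n_normal_samples = 1, n_rod_samples = 1,
                                   map_height = 2, map_width = 2,
                                   seed = 4))
  expect_length(co$maps, 2L)
  expect_equal(nrow(co$manifest), 2L)
  expect_equal(sum(vapply(co$maps, function(m) m$height * m$width,
                          numeric(1))), 8)
  expect_setequal(co$manifest$class, c("normal", "rod"))

  expect_error(simulate_cohort(sim_config(n_rod_samples = 0)),
               "each class")
})

test_that("default configuration matches the study geometry", {
  cfg <- sim_config()
  expect_equal(cfg$n_normal_samples + cfg$n_rod_samples, 7L)
  expect_equal(cfg$map_height * cfg$map_width, 22500L)
  expect_gt(length(sim_axis(cfg)), 300)   # >300 grid points in 377-1720
  # 7 maps x 22,500 = 157,500 spectra
  expect_equal(7 * cfg$map_height * cfg$map_width, 157500)
})

test_that("the spatial field option modulates maps smoothly and optionally", {
  cfg_off <- sim_config(map_height = 6, map_width = 6, seed = 8)
  cfg_on <- sim_config(map_height = 6, map_width = 6, seed = 8,
                       spatial_sd = 0.3)
  m_off <- simulate_cohort(cfg_off)$maps[[1]]
  m_on <- simulate_cohort(cfg_on)$maps[[1]]
  expect_false(identical(m_off$intensities, m_on$intensities))
  expect_equal(dim(m_on$intensities), dim(m_off$intensities))
})
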