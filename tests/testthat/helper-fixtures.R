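# Shared fixtures and independent oracles.

# Closed-form area of a unit-height Gaussian of height A and FWHM w:
# integral A * exp(-4 ln2 (x - c)^2 / w^2) dx = A * w * sqrt(pi / ln 16)
gaussian_area <- function(A, fwhm) A * fwhm * sqrt(pi / log(16))

gaussian_trace <- function(wn, center, fwhm, A = 1) {
  A * exp(-4 * log(2) * (wn - center)^2 / fwhm^2)
}

default_axis <- function() seq(377, 1720, by = 4)

# Tiny cohort for structural tests: 1 + 1 specimens, small maps.
tiny_cohort <- function(seed = 1, h = 2, w = 2) {
  simulate_cohort(sim_config(n_normal_samples = 1, n_rod_samples = 1,
                             map_height = h, map_width = w, seed = seed))
}

# Brute-force majority-vote error: enumerate all 2^N correctness outcomes,
# sum the probability of those with fewer than N/2 correct spectra.
# Deliberately free of binomial coefficients.
brute_force_majority_error <- function(p, N) {
  outcomes <- as.matrix(expand.grid(rep(list(c(0, 1)), N)))
  k <- rowSums(outcomes)
  sum(ifelse(k < N / 2, p^k * (1 - p)^(N - k), 0))
}

# The calibration cohort used by the synthetic-preset checks: roughly 2,000
# spectra per class (3 x 676 normal, 4 x 676 ROD).
preset_cohort <- function(seed = 42) {
  simulate_cohort(sim_config(map_height = 26, map_width = 26, seed = seed))
}

biomarker_cols <- c("mineral_to_matrix", "carbonate_to_matrix", "calcium",
                    "phenylalanine")
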