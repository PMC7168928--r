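# Exact binomial majority-vote analysis.

test_that("majority_error handles the elementary cases exactly", {
  for (p in c(0.1, 0.5, 0.783, 0.99))
    expect_equal(majority_error(p, 1), 1 - p)
  for (N in c(1, 3, 7, 15, 101))
    expect_equal(majority_error(0.5, N), 0.5, tolerance = 1e-12)
  # the 11-spectra Type II error at the single-spectrum sensitivity
  expect_equal(round(majority_error(0.783, 11), 4), 0.0174)
})

test_that("majority_error validates p and N", {
  expect_error(majority_error(0.8, 4), "odd")
  expect_error(majority_error(0, 3), "0, 1")
  expect_error(majority_error(1, 3), "0, 1")
  expect_error(majority_error(0.8, 0), "positive integer")
})

test_that("closed form equals brute-force enumeration over all 2^N outcomes", {
  for (N in c(1, 3, 7, 11, 15))
    for (p in seq(0.1, 0.9, by = 0.2))
      expect_equal(majority_error(p, N), brute_force_majority_error(p, N),
                   tolerance = 1e-13)
})

test_that("closed form matches the binomial distribution function", {
  # independent library oracle, including the log-gamma path (N > 60)
  for (N in c(11, 61, 101, 1001))
    for (p in c(0.55, 0.783, 0.837, 0.95))
      expect_equal(majority_error(p, N), pbinom((N - 1) / 2, N, p),
                   tolerance = 1e-12)
})

test_that("majority_correct complements majority_error", {
  for (N in c(1, 5, 11, 75))
    for (p in c(0.2, 0.5, 0.837))
      expect_equal(majority_error(p, N) + majority_correct(p, N), 1,
                   tolerance = 1e-12)
})

test_that("majority_error is strictly decreasing in p for fixed N", {
  ps <- seq(0.05, 0.95, by = 0.05)
  for (N in c(3, 9, 15)) {
    q <- vapply(ps, majority_error, numeric(1), N = N)
    expect_true(all(diff(q) < 0))
  }
})

test_that("minimal_odd_n finds the protocol's replicate numbers", {
  expect_equal(minimal_odd_n(0.783, 0.05), 7L)
  expect_equal(minimal_odd_n(0.837, 0.05), 5L)
  expect_equal(minimal_odd_n(0.99, 0.05), 1L)
  expect_error(minimal_odd_n(0.4, 0.05), "chance")
  expect_error(minimal_odd_n(0.51, 1e-6, n_max = 11), "no odd N")
})

test_that("error curves are paired, monotone and anchored at N = 1", {
  cur <- error_curves(0.7, 0.7, n_max = 15)
  expect_equal(cur$q1, cur$q2)

  cur2 <- error_curves(0.837, 0.783, n_max = 15)
  expect_equal(cur2$q1[1], 1 - 0.837)
  expect_equal(cur2$q2[1], 1 - 0.783)
  expect_true(all(diff(cur2$q1) < 0))
  expect_true(all(diff(cur2$q2) < 0))
  # brute-force confirmation of the whole curve up to N = 15
  for (i in seq_len(nrow(cur2)))
    expect_equal(cur2$q2[i], brute_force_majority_error(0.783, cur2$N[i]),
                 tolerance = 1e-13)
})

test_that("the N-spectra confusion report is closed-form consistent", {
  r <- n_spectra_confusion(0.837, 0.783, 4 / 7, 11)
  expect_equal(round(100 * r$accuracy, 1), 98.8)
  expect_equal(r$sensitivity, 1 - majority_error(0.783, 11))
  expect_equal(r$specificity, 1 - majority_error(0.837, 11))
  expect_equal(r$tp + r$fp + r$fn + r$tn, 1)

  # N = 1 reproduces the single-spectrum rates
  r1 <- n_spectra_confusion(0.837, 0.783, 4 / 7, 1)
  expect_equal(r1$sensitivity, 0.783)
  expect_equal(r1$specificity, 0.837)

  # perfect per-spectrum classification -> identity confusion matrix
  rp <- n_spectra_confusion(1 - 1e-12, 1 - 1e-12, 4 / 7, 3)
  expect_equal(rp$accuracy, 1, tolerance = 1e-9)
  expect_equal(rp$fp, 0, tolerance = 1e-9)
})

test_that("Monte-Carlo simulation agrees with the closed form", {
  exact <- majority_error(0.783, 11)
  mc <- monte_carlo_majority(0.783, 11, reps = 2e5, seed = 123)
  expect_lt(abs(mc$estimate - exact), 3 * mc$se)

  mc2 <- monte_carlo_majority(1 - 1e-9, 3, reps = 1e4, seed = 1)
  expect_equal(mc2$estimate, 0)

  mc3 <- monte_carlo_majority(0.783, 11, reps = 1e4, seed = 77)
  mc4 <- monte_carlo_majority(0.783, 11, reps = 1e4, seed = 77)
  expect_identical(mc3, mc4)
})

test_that("aggregate_analysis bundles the replicate-number readouts", {
  inp <- structure(list(p1 = 0.837, p2 = 0.783, prevalence = 4 / 7,
                        alpha = 0.05), class = "aggregation_inputs")
  a <- aggregate_analysis(inp, n_eval = 11, n_max = 21)
  expect_equal(a$n_star_type1, 5L)   # from p1 = specificity
  expect_equal(a$n_star_type2, 7L)   # from p2 = sensitivity
  expect_equal(nrow(a$curves), 11L)
  expect_s3_class(a$n_spectra_report, "diagnostic_report")
})
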