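# Single-spectrum classification and diagnostic metrics.

make_clouds <- function(n, sep, seed = 1, p = 4) {
  set.seed(seed)
  X <- rbind(matrix(rnorm(n * p), n, p),
             matrix(rnorm(n * p, mean = sep), n, p))
  list(X = as.data.frame(X), y = rep(c("normal", "rod"), each = n))
}

test_that("well-separated clouds are classified near-perfectly", {
  d <- make_clouds(100, sep = 5)
  for (k in c(2, 10)) {
    sc <- crossval_scores(d$X, d$y, k = k, seed = 3)
    expect_gte(diagnostic_report(sc)$accuracy, 0.99)
  }
  # svm route on the same clouds (features standing in for spectra)
  sc <- crossval_scores(d$X, d$y, k = 10, seed = 3, classifier = "svm",
                        spectra = as.matrix(d$X), n_components = 3)
  expect_gte(diagnostic_report(sc)$accuracy, 0.99)
})

test_that("shuffled labels collapse accuracy to the majority prevalence", {
  d <- make_clouds(300, sep = 3)
  set.seed(11)
  y_null <- sample(rep(c("normal", "rod"), times = c(240, 360)))
  sc <- crossval_scores(d$X, y_null, k = 10, seed = 5)
  acc <- diagnostic_report(sc)$accuracy
  prev_major <- 0.6
  se <- sqrt(prev_major * (1 - prev_major) / length(y_null))
  expect_lt(abs(acc - prev_major), 3 * se + 0.03)
})

test_that("cross-validation partitions and reproduces exactly", {
  d <- make_clouds(50, sep = 4)     # 100 spectra
  sc <- crossval_scores(d$X, d$y, k = 10, seed = 9)
  expect_equal(nrow(sc), 100L)
  expect_equal(as.vector(table(sc$fold)), rep(10L, 10))
  expect_equal(anyDuplicated(sc$spectrum_id), 0L)

  sc2 <- crossval_scores(d$X, d$y, k = 10, seed = 9)
  expect_identical(sc, sc2)

  sc3 <- crossval_scores(d$X, d$y, k = 10, seed = 10)
  expect_false(identical(sc$fold, sc3$fold))
})

test_that("sample-wise folding holds out whole specimens", {
  d <- make_clouds(60, sep = 4)
  sid <- rep(sprintf("s%d", 1:6), each = 20)
  sc <- crossval_scores(d$X, d$y, k = 3, seed = 2, fold_by = "sample",
                        sample_ids = sid)
  for (s in unique(sid))
    expect_length(unique(sc$fold[sc$sample_id == s]), 1L)
})

test_that("fit_logit_lda guards its preconditions", {
  d <- make_clouds(5, sep = 5)
  expect_error(fit_logit_lda(d$X, d$y), "at least 10")

  d2 <- make_clouds(30, sep = 5)
  X_collinear <- cbind(d2$X, V5 = d2$X[[1]])
  expect_error(fit_logit_lda(X_collinear, d2$y), "singular")
  # jitter remediation unblocks the fit
  set.seed(1)
  expect_s3_class(fit_logit_lda(X_collinear, d2$y, jitter_sd = 1e-3),
                  "rod_classifier")
})

test_that("pca_reduce captures variance and projects train-centred", {
  set.seed(8)
  v <- rnorm(30)
  X1 <- outer(rnorm(40), v)                     # rank-1
  b1 <- pca_reduce(X1, 2)
  expect_gte(b1$sdev[1]^2 / sum(b1$sdev^2), 0.999)

  X <- matrix(rnorm(60 * 30), 60, 30)
  b <- pca_reduce(X, 10)
  # training mean projects to the origin
  expect_equal(as.numeric(project_pca(b, matrix(colMeans(X), 1))),
               rep(0, 10), tolerance = 1e-10)

  # reconstruction error non-increasing in the number of components
  errs <- vapply(c(2, 5, 10, 20), function(nc) {
    bb <- pca_reduce(X, nc)
    R <- bb$scores %*% t(bb$rotation)
    sum((sweep(X, 2, bb$center) - R)^2)
  }, numeric(1))
  expect_true(all(diff(errs) <= 1e-8))

  expect_error(pca_reduce(X, 61), "n_components")
})

test_that("svm scoring is insensitive to a duplicated feature column", {
  d <- make_clouds(80, sep = 4)
  X <- as.matrix(d$X)
  f1 <- fit_linear_svm(X, d$y)
  f2 <- fit_linear_svm(cbind(X, X[, 1]), d$y)
  p1 <- score_to_class(predict_odds(f1, X))
  p2 <- score_to_class(predict_odds(f2, cbind(X, X[, 1])))
  expect_equal(mean(p1 == d$y), mean(p2 == d$y), tolerance = 0.01)
})

test_that("diagnostic metrics reproduce the printed-counts confusion table", {
  r <- diagnostic_report_from_counts(tp = 70470, fp = 11205,
                                     fn = 19530, tn = 56295)
  expect_equal(round(100 * r$accuracy, 1), 80.5)
  expect_equal(round(100 * r$sensitivity, 1), 78.3)
  expect_equal(round(100 * r$fpr, 1), 16.6)
  expect_equal(round(100 * r$prevalence, 2), 57.14)
  # cells that the printed table misreports, per the identities:
  expect_equal(round(100 * r$precision, 1), 86.3)
  expect_equal(round(100 * r$npv, 1), 74.2)
  expect_equal(round(100 * r$fnr, 1), 21.7)
})

test_that("diagnostic identities hold on random confusion matrices", {
  set.seed(17)
  for (i in 1:50) {
    cells <- rpois(4, lambda = 40) + 1
    r <- diagnostic_report_from_counts(cells[1], cells[2], cells[3],
                                       cells[4])
    total <- sum(cells)
    expect_equal(r$accuracy, (r$tp + r$tn) / total)
    expect_equal(r$sensitivity, r$tp / (r$tp + r$fn))
    expect_equal(r$specificity, r$tn / (r$fp + r$tn))
    expect_equal(r$fpr, 1 - r$specificity)
    expect_equal(r$fnr, 1 - r$sensitivity)
    expect_equal(r$fdr, 1 - r$precision)
    expect_equal(r$for_rate, 1 - r$npv)
    probs <- c(r$prevalence, r$accuracy, r$precision, r$sensitivity,
               r$specificity, r$fdr, r$for_rate, r$npv, r$fpr, r$fnr)
    expect_true(all(probs >= 0 & probs <= 1))
  }
})

test_that("all-correct and symmetric confusion tables behave", {
  r <- diagnostic_report_from_counts(50, 0, 0, 50)
  expect_equal(r$accuracy, 1)
  expect_equal(r$fpr, 0)
  expect_equal(r$fnr, 0)

  r2 <- diagnostic_report_from_counts(25, 25, 25, 25)
  expect_equal(r2$accuracy, 0.5)
  expect_equal(r2$sensitivity, 0.5)
  expect_equal(r2$specificity, 0.5)

  # zero denominator -> NA, not 0
  r3 <- diagnostic_report_from_counts(0, 0, 10, 10)
  expect_true(is.na(r3$precision))
  expect_true(is.na(r3$fdr))
})

test_that("scores, predicted classes and counts are consistent", {
  scored <- data.frame(
    true_class = c("rod", "rod", "normal", "normal", "rod", "normal"),
    score = c(2.0, 0.5, 0.8, 1.0, 1.2, 1.5))  # tie at 1 -> normal
  r <- diagnostic_report(scored)
  expect_equal(c(r$tp, r$fn, r$tn, r$fp), c(2, 1, 2, 1))
  expect_equal(score_to_class(1.0), "normal")

  # p1 / p2 extraction is exactly (specificity, sensitivity)
  inp <- aggregation_inputs(r)
  expect_equal(inp$p1, r$specificity)
  expect_equal(inp$p2, r$sensitivity)
})
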