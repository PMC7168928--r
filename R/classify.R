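# Single-spectrum supervised classification.
#
# Both classifiers emit scores on the posterior-odds scale,
# score = P(rod) / P(normal), so downstream majority-vote aggregation is
# classifier-agnostic: score > 1 predicts ROD, score <= 1 predicts normal
# (ties, a measure-zero event, go conservatively to normal).

as_class_factor <- function(labels) {
  f <- factor(as.character(labels), levels = c("normal", "rod"))
  if (anyNA(f))
    stop("labels must be 'normal' or 'rod'", call. = FALSE)
  f
}

#' Predicted class from an odds score
#'
#' @param score Numeric odds-scale score(s).
#' @return Character vector, `"rod"` where `score > 1`, else `"normal"`.
#' @export
score_to_class <- function(score) {
  ifelse(score > 1, "rod", "normal")
}

#' Fit a linear discriminant with logit (odds) scoring
#'
#' Fits a two-class linear discriminant on the four biomarker ratios (or any
#' feature matrix) and maps its posterior through the logistic link:
#' the returned scores are odds `P(rod) / P(normal)`, with the decision
#' threshold at 1.
#'
#' @param features Numeric matrix or data frame of features.
#' @param labels Class labels, `"normal"` / `"rod"`; at least 10 spectra of
#'   each class.
#' @param jitter_sd Standard deviation of optional Gaussian jitter added to
#'   the features, a remediation for singular within-class covariance
#'   (default 0 = off).
#' @return An object of class `rod_classifier`; score new data with
#'   [predict_odds()].
#' @export
fit_logit_lda <- function(features, labels, jitter_sd = 0) {
  X <- as.matrix(features)
  storage.mode(X) <- "double"
  y <- as_class_factor(labels)
  if (any(table(y) < 10L))
    stop("need at least 10 spectra per class", call. = FALSE)
  if (jitter_sd > 0)
    X <- X + stats::rnorm(length(X), 0, jitter_sd)

  # pooled within-class covariance must be invertible for a discriminant
  Sw <- Reduce(`+`, lapply(levels(y), function(lv) {
    Xl <- X[y == lv, , drop = FALSE]
    (nrow(Xl) - 1) * stats::cov(Xl)
  })) / (nrow(X) - 2)
  if (rcond(Sw) < 1e-12)
    stop(paste("within-class covariance is singular;",
               "drop collinear features or set jitter_sd > 0"),
         call. = FALSE)

  fit <- MASS::lda(X, grouping = y)
  structure(list(fit = fit, type = "lda", features = colnames(X)),
            class = "rod_classifier")
}

#' PCA dimensionality reduction
#'
#' Mean-centers the spectra matrix and projects onto the leading
#' `n_components` variance directions.  The basis (rotation + center) is
#' retained so held-out folds can be projected with the training-fold basis
#' only.
#'
#' @param spectra Numeric matrix, spectra in rows (cropped, normalized,
#'   baseline-corrected).
#' @param n_components Number of components to keep (default 20); must not
#'   exceed the matrix rank bound `min(nrow - 1, ncol)`.
#' @return An object of class `pca_basis` with `scores`, `rotation`,
#'   `center` and `sdev`.
#' @seealso [project_pca()]
#' @export
pca_reduce <- function(spectra, n_components = 20) {
  X <- as.matrix(spectra)
  max_rank <- min(nrow(X) - 1L, ncol(X))
  if (n_components < 1L || n_components > max_rank)
    stop(sprintf("`n_components` must be in 1..%d for a %d x %d matrix",
                 max_rank, nrow(X), ncol(X)), call. = FALSE)
  p <- stats::prcomp(X, center = TRUE, scale. = FALSE, rank. = n_components)
  structure(list(scores = p$x, rotation = p$rotation, center = p$center,
                 sdev = p$sdev),
            class = "pca_basis")
}

#' Project new spectra onto a fitted PCA basis
#'
#' @param basis A [pca_reduce()] result.
#' @param spectra Numeric matrix of new spectra (same wavenumber columns).
#' @return Score matrix, `nrow(spectra)` x `n_components`.
#' @export
project_pca <- function(basis, spectra) {
  stopifnot(inherits(basis, "pca_basis"))
  X <- as.matrix(spectra)
  sweep(X, 2, basis$center) %*% basis$rotation
}

#' Fit a linear SVM with logistic odds calibration
#'
#' Trains a linear support vector machine and calibrates its decision values
#' through a logistic regression fitted on the training data, so scores land
#' on the same posterior-odds scale (threshold 1) as [fit_logit_lda()].
#'
#' @param features Numeric matrix of (reduced) features.
#' @param labels Class labels, `"normal"` / `"rod"`, both present.
#' @param cost SVM cost parameter (default 1).
#' @return An object of class `rod_classifier`.
#' @export
fit_linear_svm <- function(features, labels, cost = 1) {
  X <- as.matrix(features)
  storage.mode(X) <- "double"
  y <- as_class_factor(labels)
  if (any(table(y) < 1L))
    stop("both classes must be present", call. = FALSE)
  fit <- e1071::svm(X, y, kernel = "linear", cost = cost, scale = FALSE)
  d <- as.numeric(attr(predict(fit, X, decision.values = TRUE),
                       "decision.values"))
  # logistic calibration learns the decision-value sign and scale; perfect
  # separation just saturates the odds, which is harmless for thresholding
  cal <- suppressWarnings(
    stats::glm((y == "rod") ~ d, family = stats::binomial()))
  structure(list(fit = fit, cal = cal, type = "svm"),
            class = "rod_classifier")
}

#' Odds-scale scores for new data
#'
#' @param object A `rod_classifier` from [fit_logit_lda()] or
#'   [fit_linear_svm()].
#' @param newdata Feature matrix / data frame matching the training features.
#' @return Positive numeric scores, odds `P(rod) / P(normal)`.
#' @export
predict_odds <- function(object, newdata) {
  stopifnot(inherits(object, "rod_classifier"))
  X <- as.matrix(newdata)
  storage.mode(X) <- "double"
  if (object$type == "lda") {
    post <- predict(object$fit, X)$posterior
    return(as.numeric(post[, "rod"] /
                        pmax(post[, "normal"], .Machine$double.xmin)))
  }
  d <- as.numeric(attr(predict(object$fit, X, decision.values = TRUE),
                       "decision.values"))
  eta <- coef(object$cal)[1] + coef(object$cal)[2] * d
  exp(pmin(pmax(eta, -500), 500))
}

# Stratified fold assignment: within each class, shuffled balanced labels
# 1..k.  Retried once if some training split would miss a class entirely.
stratified_folds <- function(y, k) {
  assign_once <- function() {
    fold <- integer(length(y))
    for (lv in levels(y)) {
      idx <- which(y == lv)
      fold[idx] <- sample(rep_len(seq_len(k), length(idx)))
    }
    fold
  }
  fold <- assign_once()
  bad <- function(f) any(vapply(seq_len(k), function(i)
    length(unique(y[f != i])) < nlevels(y), logical(1)))
  if (bad(fold)) {
    warning("a training split lacked a class; re-stratifying folds",
            call. = FALSE)
    fold <- assign_once()
    if (bad(fold))
      stop("cannot build folds with both classes in every training split",
           call. = FALSE)
  }
  fold
}

#' Cross-validated odds scores for every spectrum
#'
#' Stratified k-fold cross-validation: each fold's classifier is trained on
#' the other k-1 folds and scores the held-out spectra, so every spectrum is
#' scored exactly once by a model that never saw it.  For the
#' `"svm"` classifier the PCA basis is also refitted within each training
#' fold and the held-out spectra are projected with it, avoiding any
#' leakage through the reduction step.
#'
#' Folds are randomized by spectrum within class (the protocol's design).
#' Because all spectra of one specimen share that specimen's biology, an
#' optional `fold_by = "sample"` mode holds out whole specimens instead.
#'
#' @param features Biomarker feature data frame / matrix (used by
#'   `classifier = "lda"`).
#' @param labels Class labels, `"normal"` / `"rod"`.
#' @param k Number of folds (default 10, >= 2).
#' @param seed Integer seed for the fold assignment; `NULL` uses the current
#'   random stream.
#' @param classifier `"lda"` (linear discriminant on the features) or
#'   `"svm"` (PCA + linear SVM on `spectra`).
#' @param spectra Preprocessed spectra matrix, required for `"svm"`.
#' @param n_components PCA components for `"svm"` (default 20).
#' @param cost SVM cost parameter.
#' @param fold_by `"spectrum"` (default) or `"sample"` (grouped folds;
#'   requires `sample_ids`).
#' @param sample_ids,spectrum_ids Optional identifier vectors carried into
#'   the result.
#' @return A data frame of class `scored_spectra`: `spectrum_id`,
#'   `sample_id`, `true_class`, `score`, `fold`.
#' @export
crossval_scores <- function(features, labels, k = 10, seed = NULL,
                            classifier = c("lda", "svm"), spectra = NULL,
                            n_components = 20, cost = 1,
                            fold_by = c("spectrum", "sample"),
                            sample_ids = NULL, spectrum_ids = NULL) {
  classifier <- match.arg(classifier)
  fold_by <- match.arg(fold_by)
  y <- as_class_factor(labels)
  n <- length(y)
  if (k < 2L) stop("`k` must be >= 2", call. = FALSE)
  if (classifier == "svm") {
    if (is.null(spectra))
      stop("`spectra` matrix is required for the svm classifier",
           call. = FALSE)
    spectra <- as.matrix(spectra)
    if (nrow(spectra) != n)
      stop("`spectra` rows must match `labels`", call. = FALSE)
  }
  if (!is.null(seed)) set.seed(seed)

  if (fold_by == "sample") {
    if (is.null(sample_ids))
      stop("`fold_by = \"sample\"` requires `sample_ids`", call. = FALSE)
    sid <- as.character(sample_ids)
    samples <- unique(sid)
    if (k > length(samples)) {
      warning(sprintf("k reduced to the %d available samples",
                      length(samples)), call. = FALSE)
      k <- length(samples)
    }
    sample_fold <- setNames(sample(rep_len(seq_len(k), length(samples))),
                            samples)
    fold <- as.integer(sample_fold[sid])
    for (i in seq_len(k))
      if (length(unique(y[fold != i])) < nlevels(y))
        stop("sample-wise folds leave a training split without a class; ",
             "reduce k", call. = FALSE)
  } else {
    fold <- stratified_folds(y, k)
  }

  score <- numeric(n)
  for (i in seq_len(k)) {
    tr <- fold != i
    te <- !tr
    if (!any(te)) next
    if (classifier == "lda") {
      fit <- fit_logit_lda(features[tr, , drop = FALSE], y[tr])
      score[te] <- predict_odds(fit, features[te, , drop = FALSE])
    } else {
      basis <- pca_reduce(spectra[tr, , drop = FALSE], n_components)
      fit <- fit_linear_svm(basis$scores, y[tr], cost = cost)
      score[te] <- predict_odds(fit,
                                project_pca(basis,
                                            spectra[te, , drop = FALSE]))
    }
  }

  out <- data.frame(
    spectrum_id = if (is.null(spectrum_ids)) sprintf("sp%d", seq_len(n))
                  else as.character(spectrum_ids),
    sample_id = if (is.null(sample_ids)) NA_character_
                else as.character(sample_ids),
    true_class = as.character(y),
    score = score,
    fold = fold,
    stringsAsFactors = FALSE)
  class(out) <- c("scored_spectra", "data.frame")
  out
}

#' Diagnostic report from scored spectra
#'
#' Thresholds scores at 1 (ROD = condition positive) and tabulates the
#' confusion counts with the ten standard diagnostic metrics.
#'
#' @param scored A `scored_spectra` data frame (columns `true_class`,
#'   `score`), e.g. from [crossval_scores()].
#' @return A `diagnostic_report`; see [diagnostic_report_from_counts()].
#' @export
diagnostic_report <- function(scored) {
  if (!all(c("true_class", "score") %in% names(scored)))
    stop("`scored` needs `true_class` and `score` columns", call. = FALSE)
  truth <- as_class_factor(scored$true_class)
  if (nlevels(droplevels(truth)) < 2L)
    stop("need at least one spectrum of each condition", call. = FALSE)
  pred <- score_to_class(scored$score)
  diagnostic_report_from_counts(
    tp = sum(truth == "rod" & pred == "rod"),
    fp = sum(truth == "normal" & pred == "rod"),
    fn = sum(truth == "rod" & pred == "normal"),
    tn = sum(truth == "normal" & pred == "normal"))
}

#' Diagnostic report from confusion counts
#'
#' Builds the full diagnostic report (prevalence, accuracy, precision,
#' sensitivity, specificity, FDR, false omission rate, NPV, FPR, FNR) from
#' the four confusion cells, ROD being the condition positive.  Counts may
#' be non-integer: the majority-vote analysis reuses this constructor on
#' probability masses.  Metrics with a zero denominator are reported as
#' `NA`, never as 0.
#'
#' @param tp,fp,fn,tn Confusion cells (true/false positives/negatives),
#'   >= 0.
#' @return An object of class `diagnostic_report`.
#' @examples
#' r <- diagnostic_report_from_counts(70470, 11205, 19530, 56295)
#' r$accuracy     # 0.805
#' @export
diagnostic_report_from_counts <- function(tp, fp, fn, tn) {
  cells <- c(tp = tp, fp = fp, fn = fn, tn = tn)
  if (any(!is.finite(cells)) || any(cells < 0))
    stop("confusion cells must be finite and >= 0", call. = FALSE)
  total <- tp + fp + fn + tn
  safe_div <- function(num, den) if (den > 0) num / den else NA_real_
  r <- list(
    tp = tp, fp = fp, fn = fn, tn = tn,
    prevalence = safe_div(tp + fn, total),
    accuracy = safe_div(tp + tn, total),
    precision = safe_div(tp, tp + fp),
    sensitivity = safe_div(tp, tp + fn),
    specificity = safe_div(tn, fp + tn),
    npv = safe_div(tn, tn + fn))
  r$fdr <- 1 - r$precision
  r$for_rate <- 1 - r$npv
  r$fpr <- 1 - r$specificity
  r$fnr <- 1 - r$sensitivity
  structure(r, class = "diagnostic_report")
}

#' @export
print.diagnostic_report <- function(x, digits = 1, ...) {
  pct <- function(v) if (is.na(v)) "NA" else sprintf(paste0("%.", digits,
                                                            "f%%"), 100 * v)
  cat("<diagnostic_report> (ROD = condition positive)\n")
  cat(sprintf("  counts: tp %.6g  fp %.6g  fn %.6g  tn %.6g\n",
              x$tp, x$fp, x$fn, x$tn))
  cat(sprintf("  prevalence %s  accuracy %s\n", pct(x$prevalence),
              pct(x$accuracy)))
  cat(sprintf("  sensitivity %s  specificity %s\n", pct(x$sensitivity),
              pct(x$specificity)))
  cat(sprintf("  precision %s  npv %s\n", pct(x$precision), pct(x$npv)))
  cat(sprintf("  fdr %s  for %s  fpr %s  fnr %s\n", pct(x$fdr),
              pct(x$for_rate), pct(x$fpr), pct(x$fnr)))
  invisible(x)
}

#' Aggregation inputs from a diagnostic report
#'
#' Extracts the two per-spectrum probabilities the majority-vote analysis
#' consumes: `p1`, the probability a normal spectrum scores below 1 (the
#' specificity), and `p2`, the probability a ROD spectrum scores above 1
#' (the sensitivity), together with the ROD prevalence and the target error
#' probability.
#'
#' @param report A [diagnostic_report()].
#' @param alpha Target error probability (default 0.05).
#' @return A list of class `aggregation_inputs`: `p1`, `p2`, `prevalence`,
#'   `alpha`.
#' @export
aggregation_inputs <- function(report, alpha = 0.05) {
  stopifnot(inherits(report, "diagnostic_report"))
  vals <- c(p1 = report$specificity, p2 = report$sensitivity,
            prevalence = report$prevalence, alpha = alpha)
  if (any(is.na(vals)) || any(vals <= 0) || any(vals >= 1))
    stop("p1, p2, prevalence and alpha must all lie strictly in (0, 1)",
         call. = FALSE)
  structure(list(p1 = vals[["p1"]], p2 = vals[["p2"]],
                 prevalence = vals[["prevalence"]], alpha = alpha),
            class = "aggregation_inputs")
}
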