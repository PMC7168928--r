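# End-to-end orchestration: simulate -> preprocess/extract -> biomarkers ->
# classify -> aggregate, with optional file outputs and a checksum manifest.

#' Pipeline configuration
#'
#' @param sim A [sim_config()] controlling the synthetic cohort (use its
#'   `seed` for the data stream).
#' @param windows Band windows, default [default_band_windows()].
#' @param classifier `"lda4"` (linear discriminant on the four biomarker
#'   ratios) or `"pca20_lsvm"` (PCA to `n_components` + linear SVM on full
#'   preprocessed spectra).
#' @param folds Cross-validation folds (default 10).
#' @param seed Classifier seed (fold assignment); independent of the
#'   cohort's `sim$seed`, so changing it never changes the synthetic data.
#' @param alpha Target error probability for the minimal-N search.
#' @param n_eval Odd N of the reported N-spectra confusion matrix.
#' @param n_max_curve Largest odd N of the error curves.
#' @param n_components PCA components for the SVM route.
#' @param phe_bands Phenylalanine numerator convention, see
#'   [compute_biomarkers()].
#' @param output_dir Optional directory for delimited/JSON artifacts.
#' @return An object of class `pipeline_config`.
#' @export
pipeline_config <- function(sim = sim_config(),
                            windows = default_band_windows(),
                            classifier = c("lda4", "pca20_lsvm"),
                            folds = 10, seed = 1, alpha = 0.05,
                            n_eval = 11, n_max_curve = 51,
                            n_components = 20,
                            phe_bands = c("both", "phe1005"),
                            output_dir = NULL) {
  structure(
    list(sim = sim, windows = windows,
         classifier = match.arg(classifier),
         folds = as.integer(folds), seed = as.integer(seed), alpha = alpha,
         n_eval = as.integer(n_eval),
         n_max_curve = as.integer(n_max_curve),
         n_components = as.integer(n_components),
         phe_bands = match.arg(phe_bands),
         output_dir = output_dir),
    class = "pipeline_config")
}

# Preprocessed (normalized, globally baseline-subtracted) spectra matrix of
# a whole cohort; rows align with cohort_band_table().
cohort_spectra_matrix <- function(cohort, edge_points = 5) {
  mats <- lapply(cohort$maps, function(m) {
    wn <- m$wavenumbers
    Y <- m$intensities / m$reference_intensities
    n <- length(wn)
    ep <- as.integer(edge_points)
    i1 <- seq_len(ep); i2 <- n - ep + seq_len(ep)
    x1 <- mean(wn[i1]); x2 <- mean(wn[i2])
    y1 <- rowMeans(Y[, i1, drop = FALSE])
    y2 <- rowMeans(Y[, i2, drop = FALSE])
    slope <- (y2 - y1) / (x2 - x1)
    Y - outer(slope, wn) - (y1 - slope * x1)
  })
  do.call(rbind, mats)
}

#' Run the whole analysis pipeline
#'
#' Simulates (or accepts) a cohort, extracts band areas and biomarkers,
#' cross-validates the configured single-spectrum classifier, and feeds the
#' resulting (p1, p2) into the exact majority-vote analysis.  Deterministic
#' given the two seeds (`sim$seed` for the data, `seed` for the folds).
#' With `output_dir` set, writes the feature table, scored spectra, metrics,
#' error-curve table and a checksum manifest.
#'
#' @param config A [pipeline_config()].
#' @param cohort Optional pre-built `raman_cohort` (skips simulation).
#' @return An object of class `pipeline_result`: `features`, `scored`,
#'   `report` ([diagnostic_report()]), `aggregation`
#'   ([aggregate_analysis()]), `manifest` (when files were written) and
#'   `counts` (spectra at each stage).
#' @export
run_pipeline <- function(config, cohort = NULL) {
  stopifnot(inherits(config, "pipeline_config"))
  if (is.null(cohort)) cohort <- simulate_cohort(config$sim)
  n_spectra <- sum(vapply(cohort$maps, function(m)
    m$height * m$width, numeric(1)))
  message(sprintf("cohort: %d maps, %d spectra", length(cohort$maps),
                  n_spectra))

  bands <- cohort_band_table(cohort, windows = config$windows)
  features <- biomarker_table(bands, phe_bands = config$phe_bands)
  valid <- features$valid
  message(sprintf("features: %d valid spectra (%d excluded)", sum(valid),
                  sum(!valid)))

  if (config$classifier == "lda4") {
    scored <- crossval_scores(
      features[valid, biomarker_names], features$class[valid],
      k = config$folds, seed = config$seed, classifier = "lda",
      sample_ids = features$sample_id[valid],
      spectrum_ids = features$spectrum_id[valid])
  } else {
    spectra <- cohort_spectra_matrix(cohort)[valid, , drop = FALSE]
    scored <- crossval_scores(
      features[valid, biomarker_names], features$class[valid],
      k = config$folds, seed = config$seed, classifier = "svm",
      spectra = spectra, n_components = config$n_components,
      sample_ids = features$sample_id[valid],
      spectrum_ids = features$spectrum_id[valid])
  }

  report <- diagnostic_report(scored)
  agg <- aggregate_analysis(aggregation_inputs(report, config$alpha),
                            n_eval = config$n_eval,
                            n_max = config$n_max_curve)

  manifest <- NULL
  if (!is.null(config$output_dir)) {
    dir.create(config$output_dir, recursive = TRUE, showWarnings = FALSE)
    paths <- c(
      features = file.path(config$output_dir, "features.csv"),
      scored = file.path(config$output_dir, "scored.csv"),
      metrics = file.path(config$output_dir, "metrics.json"),
      curves = file.path(config$output_dir, "error_curves.csv"))
    write_features(features, paths[["features"]])
    data.table::fwrite(scored, paths[["scored"]])
    metrics <- c(unclass(report)[c("tp", "fp", "fn", "tn", "prevalence",
                                   "accuracy", "precision", "sensitivity",
                                   "specificity", "fdr", "for_rate", "npv",
                                   "fpr", "fnr")],
                 list(p1 = agg$p1, p2 = agg$p2, alpha = agg$alpha,
                      n_star_type1 = agg$n_star_type1,
                      n_star_type2 = agg$n_star_type2,
                      n_eval = agg$n_eval,
                      n_eval_accuracy = agg$n_spectra_report$accuracy))
    write_metrics(metrics, paths[["metrics"]])
    data.table::fwrite(agg$curves, paths[["curves"]])
    manifest <- data.frame(artifact = names(paths), path = unname(paths),
                           md5 = unname(tools::md5sum(unname(paths))),
                           stringsAsFactors = FALSE)
    data.table::fwrite(manifest,
                       file.path(config$output_dir, "manifest.csv"))
  }

  structure(
    list(config = config, features = features, scored = scored,
         report = report, aggregation = agg, manifest = manifest,
         counts = list(spectra = n_spectra, valid = sum(valid),
                       excluded = sum(!valid))),
    class = "pipeline_result")
}

#' @export
print.pipeline_result <- function(x, ...) {
  cat("<pipeline_result>\n")
  cat(sprintf("  %d spectra (%d valid), classifier %s, %d-fold CV\n",
              x$counts$spectra, x$counts$valid, x$config$classifier,
              x$config$folds))
  cat(sprintf("  single-spectrum accuracy %.1f%% (sens %.1f%%, spec %.1f%%)\n",
              100 * x$report$accuracy, 100 * x$report$sensitivity,
              100 * x$report$specificity))
  cat(sprintf("  minimal odd N at alpha %g: Type I %d, Type II %d\n",
              x$aggregation$alpha, x$aggregation$n_star_type1,
              x$aggregation$n_star_type2))
  invisible(x)
}
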