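# Delimited-text file contracts.
#
# Map matrix: one CSV per map; first column `reference_intensity`, remaining
# columns the wavenumber grid (header = wavenumbers), one row per pixel in
# row-major order.  Feature tables: CSV with spectrum_id / sample_id / class
# plus numeric columns.  Metrics: flat JSON, probabilities both as full-
# precision fractions and 1-decimal percent.  Configs: YAML.

#' Write / read a spectral map as delimited text
#'
#' @param map A [spectral_map()].
#' @param path Output CSV path.
#' @return `write_map` returns `path` invisibly; `read_map` returns a
#'   [spectral_map()].
#' @export
write_map <- function(map, path) {
  stopifnot(inherits(map, "spectral_map"))
  # %.17g renders doubles with round-trip precision, so read_map restores
  # bit-identical numerics
  fmt <- function(x) sprintf("%.17g", x)
  dt <- data.table::data.table(reference_intensity =
                                 fmt(map$reference_intensities))
  M <- data.table::as.data.table(apply(map$intensities, 2, fmt))
  data.table::setnames(M, as.character(map$wavenumbers))
  data.table::fwrite(cbind(dt, M), path)
  invisible(path)
}

#' @rdname write_map
#' @param height,width Map dimensions; inferred as a single row-strip when
#'   omitted.
#' @param sample_id,class Sample metadata to attach.
#' @export
read_map <- function(path, height = NULL, width = NULL,
                     sample_id = "sample", class = c("normal", "rod")) {
  class <- match.arg(class)
  dt <- data.table::fread(path, header = TRUE)
  if (names(dt)[1] != "reference_intensity")
    stop("first column must be `reference_intensity`", call. = FALSE)
  wn_chr <- names(dt)[-1]
  wn <- suppressWarnings(as.numeric(wn_chr))
  if (anyNA(wn))
    stop("non-numeric wavenumber header column(s): ",
         paste(wn_chr[is.na(wn)], collapse = ", "), call. = FALSE)
  bad <- which(diff(wn) <= 0)
  if (length(bad))
    stop(sprintf(
      "wavenumber header must be strictly increasing; offending column '%s'",
      wn_chr[bad[1] + 1L]), call. = FALSE)
  M <- as.matrix(dt[, -1, with = FALSE])
  if (!is.numeric(M))
    stop("non-numeric intensity cells found", call. = FALSE)
  n_px <- nrow(M)
  if (is.null(height) || is.null(width)) {
    height <- 1L; width <- n_px
  }
  spectral_map(wn, M, dt$reference_intensity, height, width,
               sample_id = sample_id, class = class)
}

feature_required_cols <- c("spectrum_id", "sample_id", "class")

#' Write / read a per-spectrum feature table
#'
#' @param features Data frame with columns `spectrum_id`, `sample_id`,
#'   `class` plus numeric feature columns.
#' @param path CSV path.
#' @return `write_features` returns `path` invisibly; `read_features` the
#'   validated data frame.
#' @export
write_features <- function(features, path) {
  missing_cols <- setdiff(feature_required_cols, names(features))
  if (length(missing_cols))
    stop("feature table lacks required column(s): ",
         paste(missing_cols, collapse = ", "), call. = FALSE)
  data.table::fwrite(features, path)
  invisible(path)
}

#' @rdname write_features
#' @export
read_features <- function(path) {
  df <- as.data.frame(data.table::fread(path, header = TRUE))
  missing_cols <- setdiff(feature_required_cols, names(df))
  if (length(missing_cols))
    stop("feature file lacks required column(s): ",
         paste(missing_cols, collapse = ", "), call. = FALSE)
  df
}

#' Write / read a flat metrics file
#'
#' Metrics are stored as flat JSON.  Every probability-like entry (value in
#' \[0, 1\]) is accompanied by a `<name>_pct` twin rounded to one decimal
#' percent -- the reporting convention of the study tables -- so rounding
#' comparisons are explicit.
#'
#' @param metrics Named list (or `diagnostic_report`) of scalar values.
#' @param path JSON path.
#' @return `write_metrics` returns `path` invisibly; `read_metrics` a named
#'   list.
#' @export
write_metrics <- function(metrics, path) {
  m <- unclass(metrics)
  if (is.null(names(m)) || any(!nzchar(names(m))))
    stop("metrics must be a fully named list", call. = FALSE)
  out <- list()
  for (nm in names(m)) {
    v <- m[[nm]]
    if (!is.numeric(v) || length(v) != 1L) next
    out[[nm]] <- v
    if (is.finite(v) && v >= 0 && v <= 1)
      out[[paste0(nm, "_pct")]] <- round(100 * v, 1)
  }
  jsonlite::write_json(out, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname write_metrics
#' @export
read_metrics <- function(path) {
  jsonlite::fromJSON(path)
}

#' Serialize / restore a simulation configuration
#'
#' YAML round-trip of a [sim_config()], bands included; reading re-runs the
#' constructors, so invariants are re-validated.
#'
#' @param config A [sim_config()].
#' @param path YAML path.
#' @return `write_config` returns `path` invisibly; `read_config` a
#'   [sim_config()].
#' @export
write_config <- function(config, path) {
  stopifnot(inherits(config, "sim_config"))
  x <- unclass(config)
  x$bands <- lapply(x$bands, unclass)
  yaml::write_yaml(x, path)
  invisible(path)
}

#' @rdname write_config
#' @export
read_config <- function(path) {
  x <- yaml::read_yaml(path)
  x$bands <- lapply(x$bands, function(b) do.call(band_spec, b))
  do.call(sim_config, x)
}

#' Write a whole cohort to a directory
#'
#' One map CSV per specimen plus `manifest.csv` (`sample_id`, `class`,
#' `path`, `height`, `width`) and the generating configuration as
#' `config.yaml`.
#'
#' @param cohort A `raman_cohort`.
#' @param dir Output directory (created if needed).
#' @return The manifest data frame, invisibly.
#' @export
write_cohort <- function(cohort, dir) {
  stopifnot(inherits(cohort, "raman_cohort"))
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  manifest <- cohort$manifest
  manifest$path <- file.path(dir, paste0(manifest$sample_id, ".csv"))
  manifest$height <- vapply(cohort$maps, `[[`, integer(1), "height")
  manifest$width <- vapply(cohort$maps, `[[`, integer(1), "width")
  for (i in seq_len(nrow(manifest)))
    write_map(cohort$maps[[i]], manifest$path[i])
  data.table::fwrite(manifest, file.path(dir, "manifest.csv"))
  write_config(cohort$config, file.path(dir, "config.yaml"))
  invisible(manifest)
}
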