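# The four clinically motivated biomarker ratios.
#
# mineral-to-matrix  = area(nu1PO4)  / area(amideI)
# carbonate-to-matrix= area(nu1CO3)  / area(amideI)
# calcium            = area(nu2PO4)  / area(amideIII)
# phenylalanine      = [area(phe1005) (+ area(phe1609))] / area(amideIII)
#
# Mineral and carbonate are referenced to amide I, calcium and phenylalanine
# to amide III, matching the polarization-sensitivity pairing of the
# measurement protocol.  The protocol defines the phenylalanine content as
# "phenylalanine / amide III" while measuring two phenylalanine bands; by
# default both band areas are summed (all measured aromatic signal), with a
# switch for the 1005 cm^-1 band alone.

required_band_names <- c("nu2PO4", "nu1PO4", "phe1005", "nu1CO3",
                         "amideIII", "phe1609", "amideI")

#' Biomarker ratios from one spectrum's band areas
#'
#' Converts the seven band areas into the four biomarker ratios.  Records
#' whose amide denominators fall below `epsilon` are returned flagged
#' invalid (with a reason) rather than producing infinities; downstream
#' tables exclude them and report the count.
#'
#' @param areas Named numeric vector containing at least the seven default
#'   band areas (`nu2PO4`, `nu1PO4`, `phe1005`, `nu1CO3`, `amideIII`,
#'   `phe1609`, `amideI`).
#' @param epsilon Smallest admissible denominator area (normalized-area
#'   units); default `1e-12`.
#' @param phe_bands `"both"` (default: 1005 + 1609 cm^-1 areas) or
#'   `"phe1005"` for the single-band numerator.
#' @return A list with `mineral_to_matrix`, `carbonate_to_matrix`,
#'   `calcium`, `phenylalanine`, logical `valid` and `reason` (NA when
#'   valid).
#' @examples
#' a <- c(nu1PO4 = 2, amideI = 1, nu1CO3 = 0.5, nu2PO4 = 0.3,
#'        amideIII = 0.6, phe1005 = 0.1, phe1609 = 0.05)
#' compute_biomarkers(a)
#' @export
compute_biomarkers <- function(areas, epsilon = 1e-12,
                               phe_bands = c("both", "phe1005")) {
  phe_bands <- match.arg(phe_bands)
  missing_bands <- setdiff(required_band_names, names(areas))
  if (length(missing_bands))
    stop("missing band area(s): ", paste(missing_bands, collapse = ", "),
         call. = FALSE)
  if (epsilon <= 0) stop("`epsilon` must be > 0", call. = FALSE)

  den_ok <- areas[["amideI"]] >= epsilon && areas[["amideIII"]] >= epsilon
  if (!den_ok) {
    bad <- c("amideI", "amideIII")[c(areas[["amideI"]] < epsilon,
                                     areas[["amideIII"]] < epsilon)]
    return(list(mineral_to_matrix = NA_real_,
                carbonate_to_matrix = NA_real_, calcium = NA_real_,
                phenylalanine = NA_real_, valid = FALSE,
                reason = paste0("denominator below epsilon: ",
                                paste(bad, collapse = ", "))))
  }
  phe_num <- areas[["phe1005"]] +
    if (phe_bands == "both") areas[["phe1609"]] else 0
  list(mineral_to_matrix = areas[["nu1PO4"]] / areas[["amideI"]],
       carbonate_to_matrix = areas[["nu1CO3"]] / areas[["amideI"]],
       calcium = areas[["nu2PO4"]] / areas[["amideIII"]],
       phenylalanine = phe_num / areas[["amideIII"]],
       valid = TRUE, reason = NA_character_)
}

#' Biomarker feature table from a band-area table
#'
#' Vectorized [compute_biomarkers()] over the per-spectrum band-area table of
#' [extract_map_bands()] / [cohort_band_table()].  Rows with an amide
#' denominator below `epsilon` are flagged `valid = FALSE` with NA ratios;
#' their count is reported via `message()`.
#'
#' @param band_table Data frame with `spectrum_id`, `sample_id`, `class` and
#'   the seven band-area columns.
#' @inheritParams compute_biomarkers
#' @return A data frame: `spectrum_id`, `sample_id`, `class`, the four ratio
#'   columns and `valid`.
#' @export
biomarker_table <- function(band_table, epsilon = 1e-12,
                            phe_bands = c("both", "phe1005")) {
  phe_bands <- match.arg(phe_bands)
  missing_bands <- setdiff(required_band_names, names(band_table))
  if (length(missing_bands))
    stop("missing band area column(s): ",
         paste(missing_bands, collapse = ", "), call. = FALSE)
  if (epsilon <= 0) stop("`epsilon` must be > 0", call. = FALSE)

  valid <- band_table$amideI >= epsilon & band_table$amideIII >= epsilon
  phe_num <- band_table$phe1005 +
    if (phe_bands == "both") band_table$phe1609 else 0

  out <- data.frame(
    spectrum_id = band_table$spectrum_id,
    sample_id = band_table$sample_id,
    class = band_table$class,
    mineral_to_matrix = ifelse(valid, band_table$nu1PO4 / band_table$amideI,
                               NA_real_),
    carbonate_to_matrix = ifelse(valid,
                                 band_table$nu1CO3 / band_table$amideI,
                                 NA_real_),
    calcium = ifelse(valid, band_table$nu2PO4 / band_table$amideIII,
                     NA_real_),
    phenylalanine = ifelse(valid, phe_num / band_table$amideIII, NA_real_),
    valid = valid,
    stringsAsFactors = FALSE)
  rownames(out) <- NULL
  n_bad <- sum(!valid)
  if (n_bad > 0)
    message(sprintf(
      "%d of %d spectra excluded (amide denominator below epsilon)",
      n_bad, nrow(out)))
  out
}

biomarker_names <- c("mineral_to_matrix", "carbonate_to_matrix", "calcium",
                     "phenylalanine")
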