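Package: ramanrod
Title: Raman Spectral Biomarkers and Replicate-Number Analysis for Renal
    Osteodystrophy
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.com",
           role = c("aut", "cre"))
Description: Tools for assessing renal osteodystrophy (ROD) from confocal
    Raman microspectroscopy of bone.  Simulates bone Raman spectra, maps and
    cohorts with realistic band structure; performs laser-line normalization,
    linear baseline correction and band-window integration; derives the four
    clinically motivated biomarker ratios (mineral-to-matrix,
    carbonate-to-matrix, calcium and phenylalanine content); classifies single
    spectra by linear discriminant logit scoring or PCA plus linear
    support-vector machine with stratified cross-validation; and computes
    exact binomial majority-vote error probabilities over N independent
    spectra, including the minimal odd N needed to classify a sample at a
    target error probability.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    MASS,
    e1071,
    data.table,
    ggplot2,
    graphics,
    jsonlite,
    pracma,
    stats,
    tools,
    utils,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
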