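---
title: "From single Raman spectra to sample-level ROD calls: methods and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{From single Raman spectra to sample-level ROD calls: methods and design notes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(ramanrod)
```

## The problem

Renal osteodystrophy (ROD) — the bone disorder of chronic kidney disease —
is diagnosed today by invasive biopsy plus histomorphometry.  Confocal Raman
microspectroscopy of bone offers a label-free alternative: band-area ratios
such as the mineral-to-matrix ratio respond to the disease.  A *single*
Raman spectrum, however, classifies bone only at roughly 80% accuracy, far
too weak for a diagnosis.  The question this package answers quantitatively
is: **how many independent spectra does one need so that a majority vote
over their single-spectrum calls reaches a target error probability?**

The chain is: spectra → band areas → four biomarker ratios → a
cross-validated single-spectrum classifier giving a per-spectrum odds score
→ an exact binomial analysis of the majority vote over N spectra.

## The majority-vote model

Let a single spectrum from a normal sample score below the threshold (odds
1) with probability $p_1$ (the single-spectrum specificity), and a spectrum
from a ROD sample score above it with probability $p_2$ (the sensitivity).
A sample measured with $N$ independent spectra ($N$ odd) is called ROD when
more than $N/2$ spectra score above 1.  The vote errs exactly when fewer
than $N/2$ spectra are individually correct, so the Type I error (normal
sample called ROD) and Type II error (ROD sample called normal) are exact
binomial tails:

$$Q_\mathrm{I}(N) = \sum_{k = 0}^{k < N/2} \binom{N}{k} p_1^{\,k} (1 - p_1)^{N - k},
\qquad
Q_\mathrm{II}(N) = \sum_{k = 0}^{k < N/2} \binom{N}{k} p_2^{\,k} (1 - p_2)^{N - k}.$$

`majority_error()` evaluates these sums exactly (no normal approximation):
direct binomial coefficients up to $N = 60$, log-gamma accumulation above
to avoid overflow.  Even $N$ is rejected rather than given a tie-break —
the decision rule is only defined for odd $N$.  `minimal_odd_n(p, alpha)`
scans $N = 1, 3, 5, \dots$ for the first $N$ with error strictly below
`alpha` and requires $p > 0.5$, because a per-spectrum classifier no better
than chance cannot be rescued by voting.

```{r}
minimal_odd_n(0.783, 0.05)   # sensitivity side
minimal_odd_n(0.837, 0.05)   # specificity side
round(100 * n_spectra_confusion(0.837, 0.783, 4/7, 11)$accuracy, 1)
```

With the published single-spectrum probabilities $p_1 = 0.837$ and
$p_2 = 0.783$, 5 and 7 spectra respectively suffice for a 5% error
probability, and an 11-spectrum vote reaches ~99% accuracy.  One labelling
subtlety deserves a flag: under the equations above, Type I (driven by
$p_1 = 0.837$) needs **5** spectra and Type II (driven by $p_2 = 0.783$)
needs **7** — the reverse pairing of the summary sentence in the source
protocol, which attaches 7 to Type I.  We reproduce both numbers and follow
the equations' assignment rather than silently choosing either reading.

Correctness of the tails is established two independent ways in the test
suite: brute-force enumeration of all $2^N$ outcomes for $N \le 15$
(machine precision) and a seeded 200,000-rep Monte-Carlo vote simulation
(`monte_carlo_majority()`, agreement within 3 standard errors).

## Band integration and the biomarker ratios

Each spectrum is normalized to its laser-line reference intensity,
corrected by a global linear background over 377–1720 cm⁻¹, and integrated
over seven windows (cm⁻¹): nu2 phosphate 395–469, nu1 phosphate 907–990,
phenylalanine 970–1040, nu1 carbonate 1033–1135, amide III 1215–1332,
phenylalanine 1543–1574, amide I 1625–1725.  Within each window a local
straight baseline is fitted through the mean of the first and last
`edge_points = 5` grid points and the residual is integrated with the
composite trapezoid rule on the native grid (Simpson weights are available
via `rule = "simpson"`; a least-squares line via
`method = "least_squares"`).  The mean-of-edges construction was chosen as
the default because it is deterministic and robust to single-pixel noise;
integration rule and baseline method are configurable because the protocol
itself does not pin them down.

Two window-level quirks of the protocol are kept deliberately:

* the **1609 cm⁻¹ phenylalanine window is 1543–1574** — printed reversed in
  the protocol and *not containing* its nominal band center.  We store it
  sorted ascending and integrate it literally.  At 4 cm⁻¹ spacing it spans
  only 9 grid points, so `band_area()` shrinks its edge regions to a third
  of the window instead of failing (the standalone
  `linear_baseline_subtract()` keeps the strict `2 * edge_points`
  precondition).
* the **phenylalanine 970–1040 window overlaps the phosphate 907–990
  window**; both are integrated independently, each with its own local
  baseline, which lets the phosphate shoulder bleed into the
  phenylalanine edge region.  This cross-talk is part of the protocol as
  written, not an artifact to engineer away.

The four ratios are mineral-to-matrix = nu1PO4/amide I, carbonate-to-matrix
= nu1CO3/amide I, calcium = nu2PO4/amide III and phenylalanine =
(phe 1005 + phe 1609)/amide III.  The protocol defines the phenylalanine
content as "phenylalanine / amide III" while measuring two phenylalanine
bands and never stating which enters the numerator; we default to the sum
(all measured aromatic signal) and expose `phe_bands = "phe1005"` for the
single-band convention.  Ratios are scale-invariant by construction, and a
spectrum whose amide denominators fall below `epsilon = 1e-12`
(normalized-area units) is flagged invalid and excluded with a logged
count, never divided through.

Noise can drive windowed areas negative; they are clamped at zero by
default for ratio stability.  Clamping breaks exact linearity of the
integrator, so the linearity and translation-invariance properties are
tested with `clamp = FALSE`.

A known bias worth stating: windows whose edges lie on a band's tails
(amide I most visibly, whose window is also truncated by the 1717 cm⁻¹ end
of the default grid) under-estimate the ideal Gaussian area by a
class-independent factor.  Because every ratio compares such areas across
classes, the bias largely cancels; the closed-form 1%-accuracy checks in
the tests therefore use bands fully contained in their windows.

## Single-spectrum classification

`fit_logit_lda()` fits a two-class linear discriminant (via `MASS::lda`) on
the four ratios and returns posterior odds $P(\mathrm{ROD}) /
P(\mathrm{normal})$ — the "logit score" with decision threshold 1; a score
of exactly 1 goes conservatively to normal.  `crossval_scores()` performs
stratified 10-fold cross-validation so every spectrum is scored once by a
model that never saw it.  The alternative full-spectrum route reduces the
preprocessed spectra to 20 principal components and trains a linear SVM
(`e1071::svm`), whose decision values are calibrated through a training-fold
logistic regression onto the same odds scale.  The PCA basis is refitted
inside each training fold and held-out spectra are projected with it — the
protocol is silent here and refitting is the leakage-free choice.

Folds are randomized per spectrum within class, which matches the source
protocol but lets spectra of the same specimen appear in both training and
test folds; since specimen-level effects are real, `fold_by = "sample"`
offers grouped folds holding out whole specimens.  With only 7 specimens
the grouped estimate is noisy, which is presumably why the original
protocol randomized by spectrum; both modes are first-class.

`diagnostic_report()` tabulates the confusion counts (ROD = condition
positive) and the ten standard metrics, with zero-denominator metrics
reported as `NA` rather than 0.  Two printed-table inconsistencies in the
source are documented rather than repaired: the published single-spectrum
table's precision/NPV/FNR (and its specificity, 83.7% vs 83.4% from its own
counts) do not follow from its printed counts, and the 11-spectra table's
"FOR" cell actually holds the Type II error fraction.  Our reports always
follow the definitional identities; tests assert only the self-consistent
cells.

## The synthetic cohort generator

No raw spectra from the original study are deposited, so the package ships
a generator that emulates the study conditions: 3 normal + 4 ROD specimens,
one 150 × 150 map (22,500 spectra) per specimen, a 377–1720 cm⁻¹ axis at
4 cm⁻¹ spacing (336 points).  Each spectrum is a linear background plus
seven Gaussian bands plus additive Gaussian noise, with a per-spectrum
log-normal laser-line reference attached.  Band amplitudes are modulated by
two unit-mean log-normal factors: a per-specimen multiplier (`sample_cv`,
the between-patient heterogeneity that produces distinct per-sample
1-sigma ellipses) and a per-spectrum factor (`spectrum_cv`, local tissue
variation).  Gaussian lineshapes were chosen for their closed-form area
(the oracle used throughout the tests); the generator is structured so
other lineshapes could be added, but none is needed for the analyses here.

The protocol gives no quantitative effect sizes, so the default band
library was calibrated once, as the package's own "paper-like" preset, to
land the 10-fold LDA accuracy in the published ~80% regime on a cohort of
roughly 2,000 spectra per class: ROD/normal amplitude ratios of 0.75 for
the phosphate and carbonate bands, 2.19 for the phenylalanine bands, flat
amide references, `spectrum_cv` 0.24 (0.27 for phenylalanine), `sample_cv`
0.08 (0.10), `noise_sd` 0.02 on a unit-reference intensity scale, and a
shallow decreasing background.  Across seeds this yields 0.79–0.81 LDA
accuracy with the correct biomarker directions (phenylalanine up in ROD;
mineral-to-matrix, carbonate-to-matrix and calcium down).

What the generator does **not** emulate: PMMA embedding residue,
fluorescence beyond a straight line, cosmic rays, detector nonlinearity,
polarization effects, or spatial correlation of tissue composition (an
optional smoothed field, `spatial_sd`, adds visual texture but is off by
default and cosmetic).  One consequence is visible in the results: on
synthetic data the full-spectrum PCA(20)+LSVM route reaches ~99% accuracy,
a much larger margin over the 4-ratio LDA than the modest real-data
improvement, because the simulated spectra carry the band amplitudes with
no nuisance structure beyond white noise.  Passing the synthetic-preset
tests therefore demonstrates that the pipeline machinery is correct and
calibrated, not that real bone spectra would behave identically.

## Problem sizes and determinism

The test suite and worked examples use scaled-down cohorts — 26 × 26-pixel
maps (676 spectra per specimen, ≈2,000 per class) for the
calibration-regime checks and 8 × 8 maps for structural end-to-end tests —
sizes at which every statistical property asserted is already stable.  The
full 150 × 150 study geometry is the generator default and runs in minutes
if wanted.  All randomness flows through explicit seeds: the cohort's
`sim_config(seed=)`, the classifier's fold seed, and Monte-Carlo seeds are
independent, so changing the classifier seed never changes the synthetic
data.  Identical configurations produce bit-identical cohorts, and the
file formats round-trip numerics exactly (`%.17g`).

## Limitations

* The majority-vote model assumes the N spectra are independent and share
  the single-spectrum probabilities $p_1, p_2$; spectra taken close
  together in one specimen are positively correlated, so real replicate
  requirements are best read as lower bounds.
* $p_1$ and $p_2$ are plugged in as point estimates; their sampling
  uncertainty is not propagated into $Q(N)$.
* Spectrum-wise cross-validation leaks specimen identity (see above);
  grouped folds are provided but noisy at 7 specimens.
* The synthetic preset reproduces the published *accuracy regime*, not the
  published spectra; all quantitative claims about real bone rest on the
  closed-form analysis of the published confusion probabilities.
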