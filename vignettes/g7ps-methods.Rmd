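---
title: "Methods behind the galectin-7 prediction score pipeline"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods behind the galectin-7 prediction score pipeline}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(g7ps)
```

# The problem

Advanced oral squamous cell carcinoma (OSCC) is treated with preoperative
chemotherapy and/or radiotherapy followed by surgery. A marker measurable in
the diagnostic biopsy that predicts whether the tumor will respond would let
oncologists skip toxic preoperative regimens in patients unlikely to
benefit. This package implements, end to end, a discovery-and-validation
pipeline for such a marker: label-free LC-MS peptide screening on
formalin-fixed biopsy tissue, immunohistochemical (IHC) quantification of the
winning protein (galectin-7), a two-feature linear prediction score (G7PS),
and survival stratification of the predicted groups.

Patients are grouped by RECIST response: group R (resistant; stable or
progressive disease) versus group S (sensitive; partial or complete
response). The package ships the 86-patient cohort table (18 learning cases,
68 test cases) and the 20-peptide differential-peak table as plain-CSV
fixtures; everything the pipeline reports about them is recomputed at run
time.

# LC-MS screening

## Peak alignment

`align_peaks()` turns per-run peak lists (sample, replicate, m/z, retention
time, charge, intensity) into a peak-by-sample matrix by greedy centroid
clustering. Observations are processed in descending intensity order; an
observation joins the nearest cluster whose intensity-weighted centroid is
within ±0.5 m/z and ±0.4 min at the same charge, and seeds a new cluster
otherwise. The tolerances are the conventional values for this instrument
setup and are exposed as parameters. Deterministic tie-breaking (by m/z, RT,
sample, replicate) makes the result invariant to the input row order, which
the test suite asserts under shuffles. Duplicate runs of a sample are
averaged; a sample with no observation in a cluster gets intensity 0 rather
than `NA`, because label-free data cannot distinguish absence from detection
failure and rank-based statistics handle zeros naturally.

The full image-registration machinery of dedicated label-free platforms is
deliberately not reproduced: given per-run peak lists, centroid clustering
with the same tolerances delivers the same contract (an aligned peak ×
sample matrix with serial ids ordered by total intensity).

## Normalization

`normalize_intensities()` rescales each sample column so that its median
over the peaks detected in every sample matches the grand median of that
fully-detected submatrix. The reference is self-referential, so the
normalization is defined up to a single global factor; everything downstream
(ranks, AUC, R/S ratios) is invariant to that factor, which the tests check
explicitly. All-zero columns are left unscaled with a warning.

## Per-peak statistics

`compute_peak_statistics()` reports, per peak, the two-sided Mann-Whitney
P-value (exact by enumeration when both groups have at most 12 samples and
no ties, otherwise the tie-corrected normal approximation), the ROC AUC in
the orientation "probability a random sensitive-group intensity exceeds a
random resistant-group intensity" (ties count 1/2), its direction-free
version `auc_sym = max(auc, 1 - auc)`, and the ratio of group means
`mean_R / mean_S` (flagged undefined when `mean_S = 0`). A Welch t-test is
available behind a flag, but the screening statistic defaults to the rank
test, which matches how the staining measurements are compared later in the
pipeline and is the safer choice for skewed intensity data.

## The selection funnel

`funnel_filter()` applies four nested stages: (1) P < 0.05 and
`auc_sym` > 0.7; (2) Mascot identification score > 50 (unannotated peaks
fail); (3) exclusion of abundant structural-protein families (keratin,
fibrinogen, collagen, histone, matched case-insensitively against the
protein description); (4) R/S ratio ≤ 0.5, i.e. markers suppressed in the
resistant group. The symmetric AUC in stage 1 keeps markers elevated in
either group eligible; the directional value is retained for reporting.
Survivor sets are recorded at every stage and are subsets of the previous
stage by construction.

## Stepwise discriminant selection

`stepwise_discriminant_select()` is a forward-backward stepwise search
minimizing Wilks' lambda, with partial F-to-enter 3.84 and F-to-remove 2.71
(the common statistical-package defaults), deterministic ties toward the
smaller peak id, and skipping (with a warning) of candidates that make the
within-group scatter singular. For nested sets of sizes p and p+1 with g
groups and n samples the partial F is
`((n - g - p) / (g - 1)) * (lambda_p / lambda_{p+1} - 1)`.

Two properties of this procedure matter for interpreting results at the
discovery scale of n = 9 + 9. First, with the conventional thresholds the
null is not strongly protected: with 20 pure-noise candidates the best
entry statistic is the maximum of 20 correlated F(1, 16) draws, so one or
two spurious entries are common (the test suite calibrates this by
simulation and asserts the simulated behavior, not an idealized zero).
Second, when two true markers are redundant proxies of the group label, the
second marker's partial F given the first clears 3.84 in only about 84% of
idealized replicates, so stepwise recovers *a* marker essentially always
but recovers *both* only in a majority of runs. This is inherent to
stepwise selection at this sample size, not an implementation artifact.

The analysis drivers log-transform intensities (`log1p`) before the
discriminant step, the standard treatment for lognormal label-free
intensities; the funnel statistics stay rank-based on the raw scale.

# IHC quantification

`separate_dab()` performs color deconvolution with fixed H-DAB stain
vectors (hematoxylin `[0.650, 0.704, 0.286]`, DAB `[0.269, 0.568, 0.778]`,
third channel their normalized cross product). Pixels are converted to
optical density `OD = -log10((value + 1) / 256)` and projected onto the
stain basis; the DAB coordinate, clipped at zero, is the staining signal.
Stain-vector estimation from the image is out of scope.

`compute_g7s()` thresholds the DAB OD within a tissue mask — Otsu's
threshold by default, a fixed override for calibrated batches — and reports
the *area fraction* of supra-threshold pixels. The stained-area measure is
defined as an area fraction rather than an intensity-weighted ratio because
the cohort table's G7S column behaves as a percentage in [0, 100]; the
intensity-weighted variant is available behind `weighted = TRUE`.
`compute_g7n()` is the nuclear share of the stained area (stained pixels
inside nuclei over all stained tissue pixels, 0 when nothing is stained),
using the same threshold as the G7S measurement of that image. Nucleus
segmentation of real images is out of scope: masks are inputs, and the
synthetic generator provides exact ones. All thresholds are logged in the
measurement row for reproducibility.

`grade_g7nl()` grades the nuclear fraction with cuts at 0.15 and 0.40
(weak / positive / strongly positive), the boundaries themselves grading 1.
Raising a fixed threshold can only shrink the stained set, so G7S is
monotone non-increasing in the threshold — asserted as a property test.

# The prediction score

The G7PS is the linear score
`G7PS = b0 + b1 * G7S + b2 * G7NL`, with G7S on the percent scale (0-100)
and G7NL the 0/1/2 grade; `G7PS < 0` predicts resistance and `G7PS >= 0`
predicts sensitivity (the boundary classifies as sensitive). IHC fractions
are multiplied by 100 exactly at this module boundary.

Two routes produce a model object:

* `recover_published_model()` — ordinary least squares of the cohort
  table's printed prediction scores on (G7S, G7NL) over all 86 records.
  The published formula is displayed only as a low-resolution figure in its
  original source, so the coefficients are treated as recoverable data
  rather than transcribed constants; on the packaged table the recovery is
  essentially exact (all residuals < 0.03, the rounding precision of the
  printed scores) and the intercept −1.97 is pinned by the three patients
  with G7S = 0 and G7NL = 0.
* `fit_discriminant()` — Fisher's two-group linear discriminant with equal
  priors and pooled within-group covariance, calibrated so the midpoint of
  the group mean scores sits at 0 with group S positive. Its coefficients
  differ from the recovered ones by an overall scale (discriminant scores
  are defined up to scaling) but agree in sign and in learning-set
  classification, which the tests verify, along with proportionality to the
  `MASS::lda` reference.

`evaluate_predictions()` counts the confusion matrix with resistance as the
positive class. `optimal_cutoff()` finds the Youden-optimal single-marker
operating point by scanning every midpoint between adjacent distinct sorted
values (plus ±∞), breaking ties toward higher specificity and then the
lower cutoff; an exhaustive-search oracle cross-checks it on randomized
small datasets.

# Survival

`kaplan_meier()`, `logrank_test()` and `five_year_survival()` are written
from first principles (product-limit estimator with Greenwood variance;
Mantel-Cox statistic with hypergeometric variances referred to chi-square
with 1 df), with the `survival` package serving as an independent oracle in
the tests, alongside a stratum-permutation reference and a type-I-error
calibration under the null. Times are in months, 5 years = 60 months, and
subjects censored exactly at an event time count as at risk for that event
(events-first tie convention). The study's individual survival times are
not published, so stratum-level outcomes are exercised through the
calibrated generator below, never asserted as recomputations of the study.

# Synthetic data generators

All generators are pure functions of their parameters and an integer seed,
and each returns a ground-truth object (serialized losslessly to JSON with
17 significant digits) so recovery can be scored.

* `generate_peak_dataset()` draws lognormal intensities; the coefficient of
  variation defaults to 0.5 because the shipped peptide table's group SDs
  scale roughly with their means (CV ≈ 0.4-1.0). Informative peaks have
  `mean_R = ratio_rs * mean_S` with `ratio_rs` defaulting to 0.4, inside
  the 0.25-0.49 range of the shipped differential peptides. Base positions
  are resampled until same-charge peaks are separated by more than 1.2 m/z
  or 1.0 min, so each true peak is a resolvable species — the generator
  models distinct peptide ions, not overlapping isobars. Duplicate runs are
  drawn independently at the full CV. It does not simulate profile-mode
  spectra, isotope envelopes, retention-time drift between runs, or
  missingness mechanisms beyond the intensity model, so alignment tests
  show tolerance bookkeeping is correct, not that real chromatographic
  drift is handled.
* `generate_ihc_image()` paints an elliptical tissue region, elliptical
  nuclei (sizes adapted to the requested nuclear-staining budget, with an
  overlap-corrected coverage target), and allocates exact pixel budgets of
  DAB staining inside and outside nuclei to hit the target G7S and G7N;
  hematoxylin counterstains unstained tissue and Gaussian noise (SD 4 on
  the 8-bit scale) is added. Infeasible target combinations (nuclear
  stained area beyond the attainable nucleus coverage) raise an error
  naming the constraint. The images make area-fraction recovery testable;
  they do not attempt realistic tissue texture, uneven staining, or
  out-of-focus artifacts, so passing recovery tests does not validate the
  thresholding on real slides.
* `generate_survival_cohort()` draws exponential event times with rate
  `-log(s5) / 60` per stratum (defaults 0.752 and 0.999; exactly 1.0 has no
  exponential rate), uniform early censoring on (0, 120) months for a
  configurable fraction of subjects and administrative censoring at 120
  months otherwise.

# Problem sizes and runtime choices

The test suite exercises alignment at 100 true peaks × 18 samples × 2 runs,
stepwise behavior at 20 candidates over 20 planted-marker seeds and 100
null replicates, the IHC recovery grid at 24 (G7S, G7N) cells × 3 seeds on
160 × 160 images (with the headline recovery examples at the default
512 × 512), survival calibration at n = 500-2000 with 1000 null log-rank
replicates, and the full in-table reproduction of the scoring results.
These sizes keep the whole suite within seconds to a couple of minutes
while leaving every statistical assertion comfortably powered.

# Known limitations

* The funnel's published peak counts at cohort scale (tens of thousands of
  input peaks) cannot be checked without the undeposited raw data; the
  package substitutes planted-marker recovery on generated data.
* Stepwise selection at n = 9 + 9 is unstable by nature (see above); the
  selected set should be read as "one representative of each redundant
  marker cluster", which is exactly how the pipeline's final marker was
  chosen from its candidate pair.
* The IHC module quantifies given masks; it does not segment nuclei, and
  the hematoxylin-channel Otsu helper is a convenience, not a validated
  segmenter.
* Survival conclusions about the real cohort are out of reach without the
  individual times; the module's correctness is established against
  independent implementations and closed-form calibrations instead.
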