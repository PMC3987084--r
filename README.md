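# g7ps

Predicting chemo-/radiotherapy resistance in oral squamous cell carcinoma
(OSCC) from galectin-7 immunostaining, as a tested R pipeline.

Preoperative chemotherapy and/or radiotherapy helps only the subset of OSCC
patients whose tumors respond; a biopsy-measurable predictor of resistance
would spare the rest the toxicity. This package implements the full
discovery-and-validation pipeline for such a predictor and ships the
underlying 86-patient cohort and 20-peptide tables as machine-readable
fixtures:

* **LC-MS screening** (`align_peaks`, `normalize_intensities`,
  `compute_peak_statistics`, `funnel_filter`,
  `stepwise_discriminant_select`): greedy centroid alignment of label-free
  peak lists (±0.5 m/z, ±0.4 min), median normalization, Mann-Whitney/ROC
  statistics per peak, the four-stage selection funnel
  (P < 0.05 & AUC > 0.7 → Mascot > 50 → abundant-protein exclusion →
  R/S ratio ≤ 0.5), and stepwise Wilks'-lambda discriminant selection.
* **IHC quantification** (`separate_dab`, `compute_g7s`, `compute_g7n`,
  `grade_g7nl`): H-DAB color deconvolution, the stained-area fraction G7S,
  the nuclear staining share G7N, and its ordinal grade G7NL
  (cuts 0.15 / 0.40).
* **The prediction score** (`recover_published_model`, `fit_discriminant`,
  `g7ps_score`, `evaluate_predictions`, `optimal_cutoff`): the linear score
  `G7PS = b0 + b1·G7S + b2·G7NL`, where `G7PS < 0` predicts resistance,
  with coefficients recovered from the cohort table by least squares or
  refit as a Fisher discriminant, plus confusion-matrix evaluation and
  Youden-optimal cutoffs.
* **Survival** (`kaplan_meier`, `logrank_test`, `five_year_survival`):
  product-limit estimation with Greenwood variance and the Mantel-Cox
  log-rank test, written from first principles and cross-checked against
  the `survival` package in the tests.
* **Synthetic data** (`generate_peak_dataset`, `generate_ihc_image`,
  `generate_survival_cohort`): seeded generators with ground-truth objects
  for every pipeline stage, so the parts whose raw study data are not
  deposited remain fully testable.

## Worked example

Recover the prediction score from the bundled cohort table and evaluate it
on the 68 test cases:

```r
library(g7ps)
cohort <- load_cohort_table()
model  <- recover_published_model(cohort)
print(model)
#> G7PS model (recovered_ols, n = 86):
#>   score = -1.9688 + 0.0581 * G7S -1.2456 * G7NL
#>   score < 0 predicts resistance; score >= 0 predicts sensitivity

test_cases <- subset(cohort, cohort == "test")
scores <- g7ps_score(model, test_cases$g7s_percent, test_cases$g7nl_grade)
evaluate_predictions(classify_g7ps(scores), test_cases$group)
#> confusion (resistant = positive): TP 24  FN 1  TN 17  FP 26
#> sensitivity 96.0%  specificity 39.5%  (cutoff 0)
```

The recovered intercept −1.97 is pinned by the three patients with
G7S = 0 and G7NL = 0, and the maximum absolute residual against the printed
scores is 0.008 — the recovery is exact to the table's rounding. The test
cohort's 96.0% sensitivity means 24 of 25 resistant tumors are flagged
before treatment; the 39.5% specificity reflects the score's deliberate
bias toward not missing resistant disease.

The numbered scripts under `analysis/` run the complete story — cohort
validation, a synthetic LC-MS screen with planted markers, IHC recovery at
the group-median staining levels, the scoring reproduction above, and
survival stratification — writing their tables under `results/`:

```sh
Rscript analysis/01_cohort_tables.R
Rscript analysis/02_ms_screen.R
# ...
```

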