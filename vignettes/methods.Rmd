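---
title: "Methods: multi-layer PBMC cohort analysis and its synthetic test-bed"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: multi-layer PBMC cohort analysis and its synthetic test-bed}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(mecfsomics)
```

This vignette is the package's own account of the statistics it implements:
the models, the assumptions behind them, the choices we made where the
underlying methodology left the design open, and what the synthetic-data
generator does and does not establish about real data.

## 1. The bioenergetic profile

### Model

An extracellular-flux plate measures oxygen consumption rate (OCR,
pmol O₂/min) and extracellular acidification rate (ECAR, mpH/min)
simultaneously in every well, in three sections (basal, after injection 1,
after injection 2) of three measurement cycles each. Three injection
schemes partition the wells:

* **A** — oligomycin (ATP-synthase inhibitor), then rotenone + antimycin A
  (complex I/III inhibitors);
* **B** — FCCP (uncoupler), then rotenone + antimycin A;
* **C** — oligomycin, then 2-deoxy-D-glucose (glycolysis inhibitor), read
  on the ECAR channel.

The residual OCR after rotenone/antimycin is non-mitochondrial; everything
mitochondrial is measured relative to that floor. The 14 subject-level
parameters follow the standard mito/glycolysis stress-test algebra given in
the README; the identity

> basal mitochondrial respiration = ATP-linked respiration + proton leak

holds *exactly* by construction (both terms come from the same scheme-A
well), and the test suite asserts it as an identity rather than to a
tolerance.

### Section summaries

A section's three cycles collapse to one value per well under a
configurable policy. Default: **mean** for the basal section, the
**extreme** reached for post-inhibitor sections (minimum after oligomycin,
rotenone/antimycin and 2-DG; maximum after FCCP). The extremes convention
matches vendor report generators and is robust to injection lag — the first
post-injection cycle often has not reached the new plateau. The policy is a
plain argument (`summary_policy()`), so mean-everywhere or any mixture is
one call away.

### Aggregation and cross-scheme ratios

Well-level parameters are pooled per subject into a mean and a sample SD
(n − 1; a single well leaves SD undefined, deliberately `NA`). Two
parameters combine schemes that live in *different wells* — ATP-linked /
maximal respiration, and the basal OCR/ECAR ratio — so no well pairing
exists; both are computed from subject-level means and carry no SD. Ratios
with non-positive denominators are flagged undefined (`NA`), never silently
numeric; negative corrected values arising from noise are retained, not
clipped, because clipping would bias group means upward.

### Group statistics

Each parameter is compared between patients and controls on subject-level
means with a two-sample **Student (pooled-variance)** t-test; Welch's test
sits behind a flag. We report the fold change (patient mean / control
mean), the raw p, and the Bonferroni-adjusted p across the 14 parameters.
Both are reported because with 14 parameters and cohorts of this size a
raw p around 0.04 does not survive ×14 adjustment; significance labelling
at the raw level is a screening convention for exploratory cohorts and is
documented as such rather than hidden. Calibrator wells (layout group
`calibrator`, the inter-experiment reference sample) are profiled but
excluded from all group statistics.

## 2. The proteomics screen

The inclusion filter (≥ 2 unique peptides **and** ≥ 5 quantitative scans,
both inclusive) runs before anything else and is idempotent.

**Data-derived thresholds.** The fold-change criterion is anchored to
control-group technical+biological variability: per-protein CV over control
samples, then `upper = 1 + 2 × median(CV)` and `lower = 1/upper`. The
reciprocal (rather than `1 − 2 × median(CV)`, available behind the
`symmetric` flag) makes the criterion symmetric on the log scale, and with
a median CV of 0.06 reproduces the conventional 1.12 / 0.89 pair
(1/1.12 = 0.8929 prints as 0.89). Full precision is used in
classification; rounding is display-only. `upper × lower = 1` holds to
machine precision and is asserted in the tests.

**Test and classification.** Two open choices had to be fixed: the fold
change is the **ratio of arithmetic group means on the linear scale**
(keeping published-style FC tables interpretable), while the t-test runs on
**log2 abundances** (TMT intensities are closer to log-normal, and the
pooled-variance t is better behaved there). Threshold comparisons are
**inclusive** (≥ upper, ≤ lower): published DAP lists contain boundary rows
with printed FCs exactly at the thresholds, which strict inequalities at
printed precision would exclude. A DAP must pass both the FC and the
p < 0.05 criteria.

**Subset summaries.** The mitochondrial summary takes a gene list
(MitoCarta-style; a small curated example list ships with the package,
real analyses should supply the full list) and reports the subset median
FC — a check that differential hits are not a bulk shift in mitochondrial
mass. The pathway test is a one-sample Student t of member proteins' log2
FCs against 0; this is the minimal reading of a "group p-value of the
pathway's proteins" and is flagged as an interpretation. All-zero member
FCs return p = 1 (no evidence), not an error. CD-marker comparisons are
reported without thresholding, as a composition check.

## 3. Metabolomics preprocessing

The pipeline order is fixed and recorded:
`qc_filter → impute_min5 → glog_transform → pareto_scale`, with the FC
screen on raw concentrations and the t/FDR screen + PCA on the scaled
matrix. Rationale for the split: the published 1.3 / 0.77 screen bounds
live on the natural concentration scale, while test statistics benefit from
variance stabilisation.

* **QC filter** — two rules (QC-replicate CV ≤ 0.25, missingness ≤ 0.3 by
  default), applied per compound, LC and FIA compounds independently. This
  is a deliberately simple surrogate for full kit-QC software and is
  labelled as such; it is not claimed to reproduce any particular
  commercial filter cascade.
* **Imputation** — missing cells are left-censored readings below the
  limit of detection, replaced by min(observed)/5 *per compound*. The rule
  presumes left-censoring; it would be inappropriate for values missing at
  random.
* **glog** — `log2((x + √(x² + a²))/2)`, strictly increasing, ≈ log2(x)
  for x ≫ a, finite at 0. The offset `a` defaults to (smallest positive
  value in the matrix)/10; the methodology literature names the transform
  but not the offset, so the choice is exposed as an argument and recorded
  in the preprocessing report.
* **Pareto scaling** — centre, divide by √SD; columns end with mean 0 and
  SD √(original SD). Zero-variance compounds are centred only, with a
  warning.
* **FC screen** — strict inequalities (> 1.3, < 0.77), matching the printed
  wording of the convention; a compound at exactly 1.3 is not flagged.
* **t/FDR** — per-compound Student t with Benjamini–Hochberg adjustment
  (`stats::p.adjust`; the test suite checks it against an independent
  brute-force step-up). Compounds at raw p < 0.05 but above the FDR level
  are reported as "nominal only" rather than dropped.
* **PCA** — SVD of the already-scaled samples × compounds matrix, no
  further centring; loadings orthonormal to 1e-10 in the tests.

## 4. Clinical scores

FSMC total is *defined* as motor + cognitive and enforced; the severe-
fatigue label uses total > 63. Item-level scoring (FSMC items, SF-36
items, the COMPASS-31 weighting scheme) is out of scope — the package
operates on domain scores, which is the level at which such cohorts are
analysed; COMPASS-31 weighted totals are taken as inputs. Pearson
correlations use the exact t transform `t = r√((n−2)/(1−r²))`, two-sided
throughout (sidedness is rarely stated in the questionnaire literature;
two-sided is the conservative default). Missing questionnaires are handled
pairwise-complete, so each pair reports its own n. No multiple-testing
correction is applied to correlation tables by default (raw p's are the
exploratory convention); a BH option exists.

## 5. The synthetic-cohort generator

### What it emulates

The generator's defaults are the study conditions the package is built
around: **6 patients vs 4 controls**, three injection schemes, 3 × 3
cycles per well, and a patient effect entering *only* through the
ATP-linked fraction of basal mitochondrial respiration, scaled by
`coupling_effect` (default 0.87) — so the induced group coupling-efficiency
fold change equals 0.87 in expectation, and no other parameter is
systematically affected. The replicate-well count per subject and scheme is
not something small exploratory studies report; the default of 8 is a
plausible 96-well layout choice, configurable, and not presented as
anyone's actual value.

Noise is **multiplicative log-normal** at every level: flux data are
positive and heteroscedastic, and a CV parameterisation matches how
variability is discussed for such assays. Well-level noise CV defaults to
0.05; between-subject variation (CV 0.08 on overall metabolic magnitude,
SD 0.02 on the ATP-linked fraction) makes subject-level t-tests honestly
calibrated rather than driven by replicate noise alone. Cell counts per
well are a lab constant, not a computational one, and are not modelled —
traces are already rate units.

Proteins: log-normal baselines, channel noise CV 0.06 (which makes the
derived FC thresholds land near 1.12 / 0.89, as in the emulated design),
13 up-spikes at FC 1.5 and 9 down-spikes at FC 0.7 among 3300 by default,
peptide/scan metadata drawn so ~10% of proteins fail the inclusion filter
(spiked proteins always survive it, so recovery is well defined).
Metabolites: 408 compounds (42 LC / 366 FIA proportions), left-censoring at
a per-compound LOD placed at the `missing_rate` quantile (default 1.2%) —
missing-not-at-random by construction, which is exactly what the min/5
imputation rule presumes. Questionnaires: a latent severity (patients
shifted +3 SD), instruments affine in severity with noise calibrated so
corr(score, severity) = `questionnaire_corr` (default 0.93) *before*
clamping to instrument ranges, with group means matching the packaged
reference summaries; SF-36 domains load negatively.

Two consequences of the construction are worth stating because the test
suite relies on them. First, FSMC total = motor + cognitive has a *higher*
severity correlation than either subscale (two noisy measurements of the
same latent variable; ≈ 0.96 when each subscale is at 0.93), so the
FSMC-total–COMPASS correlation is approximately 0.96 × 0.93 ≈ 0.90 before
clamping — the tests check the median over seeds against the wide
recovery band rather than a point value. Second, clamping at instrument
floors (healthy controls sit at the FSMC floor of 10 and near 0 on
COMPASS-31) attenuates correlations; heavy clamping is recorded in the
generator's run log as a warning, not an error.

### What passing tests do and do not show

The generator draws independent log-normal noise with no plate-position
effects, no batch structure, no TMT channel interference or ratio
compression, no correlated metabolite blocks, and no instrument drift.
Parameter recovery and type-I calibration on this test-bed therefore show
that the *estimators and decision rules* are implemented correctly and are
calibrated under their own assumptions — they do not show robustness to the
systematic artefacts of real plates and real mass spectrometry, and the
surrogate QC filter is not claimed to reproduce any specific commercial
filter's retention count on real data.

### Determinism

Every generator derives its RNG stream from `spec$seed` plus a fixed
per-layer offset, restoring the caller's RNG state afterwards: identical
specs give byte-identical tables, and generating one layer never perturbs
another. The pipeline's MANIFEST hashes every artifact so reruns can be
compared at the byte level.

## 6. Numerical choices and degenerate inputs

* Ratios with non-positive denominators → `NA` + (where subject-level)
  warnings; never silent numbers.
* Identical groups in any t-test → t = 0, p = 1 (zero pooled variance with
  equal means is "no evidence", not an error); zero pooled variance with
  *unequal* means → p = 0 with an infinite t, flagged by sign.
* Degenerate FC thresholds (control CV 0) → (1, 1) with a warning; every
  p-passing protein then counts as a DAP, which the boundary tests pin
  down.
* Oracle tolerances: algebraic identities are asserted exactly; everything
  recomputed through an independent brute-force path (well parameters,
  t statistics, Pearson r/p, BH) is checked at 1e-12 (1e-14 for BH, which
  differs from `p.adjust` only in floating-point association order).
* Row-wise t-statistics for the 3300-protein screen are vectorised in
  matrix form; the suite verifies them against `t.test(var.equal = TRUE)`.

## 7. Problem sizes used by the checks

The simulation-backed checks run at the cohort scale the defaults define:
20 cohorts for effect-recovery summaries (coupling-efficiency FC band
0.82–0.92 around the induced 0.87; spiked-DAP recovery ≥ 20/22 median),
75 null cohorts × 14 parameters (≥ 1000 tests) for flux type-I calibration,
20 × 1000-protein null tables for screen calibration, and 11 cohorts of
n = 200 for the questionnaire correlation band. These sizes give the
Monte-Carlo summaries comfortable margins relative to their bands while
keeping the default test run quick on a laptop.

## 8. Known limitations

* The 14-parameter set is reconstructed from the standard stress-test
  algebra; laboratories differ in whether spare capacity and glycolytic
  reserve are ratios or differences. Defaults follow the ratio convention;
  the difference forms can be obtained from the emitted components.
* No instrument-level corrections (background wells, pH drift, O₂
  diffusion), no ECAR→proton-efflux conversion, no per-cell normalisation.
* The proteomics screen starts from protein-level abundances;
  spectral search, PSM aggregation and isoform inference are upstream.
* Whether a published FC was a ratio of means or a mean of ratios, and
  whether its t-test ran on log or linear abundances, is usually unstated;
  our defaults (ratio of means; t on log2) are documented interpretations,
  and both are configurable.
* The COMPASS-31 weighting scheme is not implemented; weighted totals are
  inputs.
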