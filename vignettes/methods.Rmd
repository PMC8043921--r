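---
title: "Methods: PET radiomics, model building and internal validation"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: PET radiomics, model building and internal validation}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(petradiomics)
```

This vignette is the package's account of its science: the models and
procedures it implements, the assumptions behind them, the numerical
choices made where the underlying conventions are genuinely open, and what
the synthetic-data tests do and do not demonstrate about real data.

## The prediction problem

Patients with locally advanced esophageal cancer receive neoadjuvant
chemoradiotherapy followed by surgery; roughly a fifth to a quarter achieve
a pathologic complete response (pCR, Mandard tumor regression grade 1 — no
residual vital tumor cells). Predicting pCR before surgery matters because
complete responders might be candidates for organ-preserving follow-up
instead of esophagectomy. The package models pCR (grade 1 vs. 2–5) with
logistic regression from three information sources: clinical covariates
(histology, clinical T-stage), radiomic features of the pre-treatment
¹⁸F-FDG PET tumor volume, and immunohistochemistry markers (HER2, CD44)
from pre-treatment biopsies. The working hypothesis is that imaging
phenotype and biopsy markers carry *complementary* information — imaging
summarizes the whole tumor burden, a biopsy samples one site's biology.

## Radiomic feature extraction

Input is a 3D SUV volume (body-weight-normalized uptake, dimensionless)
and a binary tumor mask on the same grid; all geometry is computed in
millimetres from the voxel spacing. `extract_all()` produces exactly 101
features in seven families (19 morphology, 2 local intensity, 18 intensity
statistics, 25 GLCM, 16 GLRLM, 16 GLSZM, 5 NGTDM). The family membership
follows the canonical IBSI feature lists, filled to each family's stated
count; since only nine features are pinned by name from the outside
(SUVmax, SUVpeak, SUVmean, volume, TLG, elongation, Moran's I, Geary's C,
inverse variance, information correlation 2, coarseness, long-run low
gray-level emphasis), the exact membership of the remaining features is an
explicit convention, recorded in `feature_dictionary()`.

Numerical choices that matter:

* **Discretization** (unstated in the source convention): fixed-bin-size
  with width 0.5 SUV, the common PET practice; level = ⌊(SUV − min)/w⌋ + 1
  with the top value clamped. A fixed-bin-number variant is available. All
  texture families operate on the discretized ROI, which makes them
  invariant to intensity shifts under fixed bin number (tested).
* **Directional aggregation**: GLCM and GLRLM are computed over the 13
  unique 3D directions at Chebyshev distance 1 and features are *averaged
  over directions* (default); a merged-matrix variant is configurable.
  The direction set is closed under 90° rotations, so direction-averaged
  features are rotation-invariant on isotropic grids (tested to 1e-8).
* **Iso-surface**: mesh volume and surface area come from a marching-
  tetrahedra surface (six tetrahedra per grid cube sharing the main
  diagonal) of the occupancy field smoothed with a small Gaussian
  (σ = 0.7 voxel), intersected at level 0.5 with linear edge
  interpolation, and oriented outward so the divergence theorem gives the
  enclosed volume. The smoothing step places vertices with sub-voxel
  accuracy: on a digitized sphere of radius 10 mm at 1 mm spacing the mesh
  volume is within ~1% and the area within ~2% of the analytic values,
  whereas a purely binary midpoint mesh overestimates the area of oblique
  surfaces by >25%. Tiny ROIs whose smoothed field never reaches 0.5 fall
  back to the binary field; single-voxel ROIs have no meaningful mesh and
  return flagged `NA` mesh metrics.
* **Spatial autocorrelation**: Moran's I and Geary's C use inverse
  Euclidean distance weights over all in-mask voxel pairs, computed
  exactly (chunked, no N×N matrix) up to 20,000 voxels; larger ROIs use a
  deterministic intensity-stratified systematic subsample of that size,
  flagged in the output. Two algebraic identities pin the implementation:
  any two-voxel ROI with distinct values has I = −1 and C = 1 exactly.
* **Undefined features** (correlation with one gray level, NGTDM busyness
  with one gray tone, mesh metrics on one voxel, …) are reported as `NA`
  with a named flag — never silently zeroed — so downstream screening can
  exclude them. The NGTDM coarseness reciprocal is guarded at ε = 1e-12
  and flagged when the guard caps it.
* **SUVpeak**: the 1 cm³ sphere (radius 6.204 mm) mean includes every
  image voxel within the radius, background included, which is why a
  constant ROI in a large constant field returns the constant, while an
  isolated hot voxel is averaged down.

Every texture and autocorrelation feature is validated against an
independent naive-enumeration oracle (plain scalar loops written from the
definitions) on 200 random ≤5×5×5 masked grids at tolerance 1e-8.

## Feature reduction

Redundancy among the 101 features is removed before modelling:
agglomerative clustering with average linkage on the distance 1 − |ρ|,
where ρ is the Spearman rank correlation between features across patients.
The absolute value makes redundancy sign-agnostic (a feature and its
negation are perfectly redundant); the signed variant is available since
the underlying convention is not pinned. The dendrogram is cut at 60% of
the maximum linkage height — read as: clusters are the subtrees entirely
below 0.6·h_max, the standard dendrogram-cut semantics. From each cluster
the feature with the smallest univariable likelihood-ratio p value (1-df
χ², against the intercept-only model) is the representative; ties break
lexicographically for reproducibility; representatives with p ≥ 0.2 are
dropped. Patient-axis clustering for heatmaps uses the same machinery on
the transposed per-feature Z-scored table.

## The twelve-model suite

* M1 — clinical reference: histology + clinical T-stage.
* M2 — radiomic reference: LASSO-selected features from the screened
  representatives. The L1 path is tuned by stratified 5-fold
  cross-validated deviance at `lambda.min` (the tuning rule is not pinned
  by the source convention; the sparser 1-SE rule is a config option), and
  the final model is refit *unpenalized* on the selected set, so the
  reported AIC and log-likelihood are those of an ordinary logistic fit.
  An empty LASSO selection is allowed and flagged; the pipeline falls back
  to the best screened representative.
* M3 = M1 ∪ M2; M4–M6 add HER2; M7–M9 add CD44; M10–M12 add both.

Marker models use complete cases for the markers involved (missing HER2
status excluded, never imputed). Clinical covariates are dichotomized at
the standard strata (adenocarcinoma vs squamous; T1–2 vs T3–4a; N0–1 vs
N2–3). Separation is detected and flagged rather than silently penalized
(no Firth fallback by default). The suite asserts AIC = 2k − 2LL and the
nesting property (adding covariates never lowers in-sample LL) across all
twelve fits.

## Internal validation

Each model is validated by Harrell's bootstrap optimism correction:
resample patients with replacement (stratified on outcome, which removes
most one-class resamples), refit, measure performance on the resample
(boot-apparent) and on the original data (boot-test); optimism is the mean
difference and corrected = apparent − optimism. Six measures are tracked:
Nagelkerke R² (Cox–Snell scaled by its attainable maximum), Brier score,
Mann–Whitney AUC (ties count one half), discrimination slope (mean
predicted risk in events minus non-events), and logistic recalibration
coefficients — slope from refitting the outcome on logit(p̂), intercept as
calibration-in-the-large with the slope fixed at 1, the convention that
matches reporting separate intercept and slope columns.

Two refit policies are shipped, because whether the original selection
steps were repeated inside each resample is not recoverable from the
source convention: `"fixed"` (default) refits the coefficients of the
fixed covariate set; `"pipeline"` re-runs a caller-supplied selection
inside every resample and therefore charges selection optimism too — the
recommended choice when selection is data-driven.

Numerical details: bootstrap refits that fail (one-class outcome after
resampling, rank deficiency) are dropped and counted, with a hard error
above 20% failures; probabilities inside the internal measure computation
are clipped to [0.5/n, 1 − 0.5/n] so separated refits yield
large-but-bounded test measures instead of divergent calibration
intercepts; per-measure optimism is averaged NA-aware (an intercept-only
model has no defined calibration slope, but its Brier/R²/AUC optimism is
still ~0). The reference repetition count is B = 20,000; tests and
examples use B ≤ 1,000, at which the corrected AUC of a fixed cohort is
stable to well under 0.01 (tested at B = 200 vs 400).

A caution established by the package's own simulations: with ten pure-noise
predictors at n = 60 the optimism correction removes *most* but not all of
the apparent discrimination (apparent AUC ≈ 0.74 on average, corrected
≈ 0.59 across replicate datasets, single datasets ranging ~0.4–0.7). This
residual optimism at extreme events-per-variable ratios is a known property
of the estimator, which is why the validation tests assert the estimator's
central tendency over replicate datasets rather than a single draw.

## Biomarker statistics

HER2 is dichotomized from the immunohistochemistry score: 0 → negative,
3+ → positive, 1+/2+ resolved by FISH amplification, missing when FISH is
unavailable. CD44 (and cytosolic HIF1α, PTCH1) arrive as already
dichotomized immuno-reactivity scores; the cut point lives outside the
main convention and is therefore a config field, not a constant. Diagnostic
metrics of 2×2 tables come with exact Clopper–Pearson intervals and
NA-flags for empty margins. The Fisher exact test uses the two-sided
point-probability convention (sum of all tables with point probability ≤
observed, within 1e-7 relative tolerance) — the convention of mainstream
statistical software — and is verified against full hypergeometric
enumeration. One recorded mismatch: the published CD44 × T-stage table
{(1,15),(5,22)} yields p ≈ 0.386 under this convention while the source
prints 0.35; the package follows the standard convention and documents the
discrepancy rather than resolving it. Cluster–covariate association uses
the contingency χ² test, switching to the exact test (flagged) when more
than 20% of expected cell counts fall below 5.

## The synthetic cohort generator

The generator defines the conditions under which the pipeline is tested:

* **Phantoms**: an ellipsoid of constant baseline SUV plus a smoothed
  Gaussian random field (correlation length 6 mm, amplitude 1.2 SUV by
  default) and white noise (0.3 SUV), clipped at 0 since SUV is
  nonnegative. A Gaussian random field was chosen because the texture and
  autocorrelation families quantify exactly the kind of controllable
  spatial correlation it provides. Defaults (40³ voxels at 2 mm, radii
  16/13/11 mm, base SUV 6) give a tumor of ~9.4 cm³ — a realistic locally
  advanced esophageal primary.
* **Feature tables**: Gaussian copula with one latent factor per block and
  a global factor, targeting within-block Spearman ρ = 0.85 and
  between-block ρ = 0.1 across 7 blocks by default, emulating the tightly
  correlated feature clusters of real extractions. Target Spearman
  correlations convert to latent Pearson correlations via 2·sin(πρ/6);
  a structure with between > within is rejected as non-PSD, naming the
  offending block.
* **Cohorts**: n = 96 with pCR prevalence 21/96, HER2 positivity 18/94,
  CD44 positivity 27/43, squamous histology 8/96, T3–4a 85/96, N2–3
  28/96 — the marginals of the modelled study population. Outcomes are
  drawn Bernoulli(expit(Xβ)) under user-specified true coefficients; an
  `NA` intercept is calibrated by root-finding so the marginal event rate
  matches the target prevalence. Markers are independent of the radiomic
  features by default, mirroring the observed lack of association between
  patient clusters and marker status; dependence is opt-in. Because no
  per-patient feature values are published, synthetic effect sizes are
  free parameters chosen for testability (e.g. β_HER2 = −2 in the
  parameter-recovery tests), not for fidelity.
* **Fixture cohorts**: `fixture_cohort()` reconstructs per-patient tables
  consistent with *every* published marginal and two-way count (response ×
  Mandard grade, HER2 × response, HER2 × T-stage, CD44 × response, CD44 ×
  T-stage, the six HER2+/CD44+ double positives being non-responders, …);
  cross-classifications that were never published are filled
  deterministically. These files are labelled synthetic: they are one
  cohort among those compatible with the published counts, not source
  data.

What passing tests show — and do not show — about real data: the synthetic
phantoms have no scanner point-spread function, no reconstruction
artifacts, no physiologic background uptake, and masks are exact
ellipsoids rather than expert delineations; the cohort generator draws
covariates independently except where specified. Tests therefore verify
the *correctness* of the computations (against oracles and closed forms)
and the *statistical behaviour* of the procedures (calibration, optimism,
recovery) under known truth — they do not certify predictive performance
on clinical data, which the modelled study itself estimates from a private
96-patient cohort and which is not reproducible here.

## Problem sizes used in tests

Oracle equivalence runs 200 random ≤5×5×5 grids; reduction recovery uses
n = 500 patients × 35 features; bootstrap properties use n = 60–120 with
B = 150–500 (8 replicate datasets for the overfit experiment); calibration
recovery uses n = 10⁵; parameter recovery uses 30 cohorts of n = 2000.
These sizes were chosen so each property is measured with comfortable
Monte-Carlo margin while the whole suite stays desk-scale.

## Known limitations

* The 101-feature dictionary beyond the nine externally pinned names is a
  documented convention, not a certified reproduction of any particular
  extraction software.
* Mesh metrics inherit a small negative volume bias (≲1–4% at 2 mm
  spacing) from the σ = 0.7-voxel smoothing of the occupancy field; it
  vanishes with resolution.
* Moran's I/Geary's C beyond 20,000 voxels are subsampled estimates.
* The optimism correction leaves residual optimism at extreme
  events-per-variable ratios (see above); external validation is the only
  remedy the literature offers.
* DICOM ingestion, CT texture, partial-volume correction and delineation
  tooling are out of scope; images enter as reconstructed NIfTI volumes
  with given masks.
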