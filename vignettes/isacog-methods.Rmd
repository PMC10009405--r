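---
title: "Quantifying impaired self-awareness of cognition: methods and design"
author: "isacog package"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Quantifying impaired self-awareness of cognition: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(isacog)
```

## The problem

Patients with Parkinson's disease (PD) may under-report cognitive
difficulties relative to what objective testing shows — impaired
self-awareness of cognitive deficits (ISAcog), a partial form of
anosognosia. Quantifying it requires two measurements on a common scale:
an objective one (a neuropsychological battery) and a subjective one (a
self-report questionnaire), both standardized against the same healthy
reference group. This package implements that measurement pipeline end to
end, together with the group statistics and the voxel-wise mapping of
ISAcog onto brain metabolism images that a cohort study of this design
uses.

## Objective cognition: battery z-scores

The battery has ten tests, two per domain: attention (digit span
forwards/backwards), executive functions (modified Wisconsin Card Sorting
Test errors, alternating verbal fluency), language (Boston Naming Test,
semantic fluency), memory (PANDA and MMSE delayed recall) and
visual-spatial abilities (PANDA cubes, MMSE pentagons). Every raw score
is converted to a z-score controlled for age and education,

$$z = \frac{\mathrm{raw} - \mu(\mathrm{age}, \mathrm{edu})}{\sigma},$$

sign-flipped for error counts (mWCST errors is the only
`higher_is_worse` test) so that higher z always means better cognition.
Tests with published norms use a `NormTable` entry whose conditional mean
is linear in age and education with a fixed residual SD — the shape a
printed norm table takes once interpolated; the entries ship as an
editable CSV (`inst/extdata/default_norms.csv`) because the specific
published tables are instrument- and language-version-dependent and must
be swappable. Tests without published norms (BNT, the PANDA and MMSE
subtests) are scored against the study's own control sample
(`buildControlReference()`): by construction the controls then re-score
to mean 0 and SD 1 exactly, which the tests assert without tolerance.

Missing tests are a hard error, not an occasion for imputation: the
classification below needs the complete ten-score profile, and silent
proration would change what the overall score means.

The overall cognition z-score is the arithmetic mean of the ten test
z-scores. With exactly two tests per domain it coincides with the mean of
the five domain means, a property the test suite checks.

## Level II classification of mild cognitive impairment

A test is *impaired* when its z lies at or below −1.5 (the boundary is
inclusive). MCI is diagnosed when at least two distinct tests are
impaired — whether within one domain or across domains; the two arms of
the published rule reduce to a count over distinct tests, which is how
`classifyMci()` implements it. Subtypes: `single_domain` when all
impaired tests fall in one domain, `multiple_domain` otherwise;
*amnestic* when the memory domain is hit. The classifier is verified
against a brute-force oracle that enumerates the impaired set directly,
on 10,000 random profiles.

Since each of the ten battery entries counts as a distinct test, two
impaired subtests of the same instrument (e.g. both MMSE subtests used
here) count as two tests; the battery layout fixes this interpretation.

Screening follows the study design: BDI-2 (depression) above 21 excludes
(21 itself is included), and dementia is an input flag — it is a clinical
diagnosis, not something this package computes.

## Subjective cognition and the ISAcog statistic

The Cognitive Failures Questionnaire (CFQ) has 25 items rated 0–4, total
0–100, higher = more self-reported failures. The total is standardized
against the controls' mean and SD and multiplied by −1 so that, like the
battery z-scores, higher means better (subjective) cognition. Then

$$\mathrm{ISAcog}_{\mathrm{signed}} = z_{\mathrm{cognition}} -
z_{\mathrm{CFQ,adj}},$$

negative when the subject rates their cognition better than testing
shows, i.e. impaired awareness. Because published prose tends to say
"higher ISAcog" for *more* impairment while this formula makes impairment
negative, `isacogScore()` carries both fields: the signed score and its
negation `isacogMagnitude` (higher = more impaired awareness). The
magnitude scale is the canonical one in all correlations and imaging
regressions, and every output labels the convention explicitly. ISAcog is
dimensional; no cutoff is applied.

## Behavioral statistics

Group comparisons follow the standard nonparametric rules: Mann–Whitney
U for two groups (exact for small untied samples, normal approximation
with tie and continuity correction otherwise — `wilcox.test`'s own
switch), Kruskal–Wallis H for three; Fisher's exact test for 2-group
categorical tables and chi-squared otherwise, with an override flag.
Post-hoc pairwise U tests after a three-group omnibus use the
Bonferroni-adjusted threshold α/3 (0.0167 at the conventional 0.05,
reported to 4 dp). Partial correlations are Pearson on OLS residuals
(p from the t transform with df = n − k − 2); a rank variant
(residualized midranks) is available by flag because study reports often
leave the type unstated. A variable fully explained by the covariates has
a numerically-zero residual; its partial correlation is defined as 0.

## Voxel-wise mapping

Volumes (stand-ins for spatially normalized, smoothed FDG-PET) are
globally normalized by proportional scaling: each volume is multiplied by
`grand_mean / its in-mask mean`, with grand mean 50 — the conventional
default of the mapping software this emulates; any positive target is
accepted. The analysis mask keeps voxels whose across-subject mean
uptake exceeds 0.2 × grand mean (the usual implicit masking rule,
flagged as a convention in outputs), intersected with any user mask.

The GLM regresses each in-mask voxel on ISAcog (magnitude convention)
plus nuisance covariates — age, binary-coded sex, BDI-2, UPDRS-III and
LEDD for patients; age, sex and BDI-2 for controls. Disease duration is
deliberately not a covariate (collinear with UPDRS-III). The t-map of
the ISAcog coefficient is thresholded at the uncorrected p < 0.005
cluster-forming threshold, components are labeled under 18-connectivity
(faces + edges, the common convention; 6 and 26 by flag), and
cluster-level family-wise-error p values come from Freedman–Lane
permutation: volumes are residualized on the covariates, residual rows
are permuted, the model is refit, and the maximum cluster statistic per
permutation forms the null distribution, with

$$p_{\mathrm{FWE}} = \frac{1 + \#\{\max_{\mathrm{perm}} \ge
\mathrm{observed}\}}{1 + n_{\mathrm{perm}}}.$$

Cluster *extent* is the default statistic; cluster *mass* (sum of
supra-threshold |t| excess) is available by flag and is the better choice
when an effect saturates a compact region, since extent then ties with
permutation maxima. Permutation inference replaces the random-field
theory correction of the original software: RFT's smoothness estimation
is a heavy dependency with no tractable oracle at desk scale, whereas the
permutation scheme is exact under exchangeability and testable by
simulation — the suite verifies the family-wise error rate on 200 null
replicates and minimum-p behavior on planted effects. Both directions are
always computed and labeled; with the magnitude convention, the
"metabolism decreases as awareness worsens" finding appears in the
negative direction.

Follow-up: significant clusters become volumes of interest whose
per-subject mean uptake is extracted from the scaled stack and correlated
with ISAcog per subgroup (partial correlations, same covariates);
a specificity rerun substitutes the overall cognition z-score for ISAcog
to verify clusters are awareness-specific; and a region-level structural
analysis restricts itself to atlas labels intersecting the significant
clusters, correlating each region's structural scalar (e.g. mean
cortical thickness) with ISAcog, Holm-corrected across regions. The
structural analysis is region-level, not vertex-level: surface
estimation is out of scope and region means are the right granularity
for a restricted-search null check. Degenerate inputs are handled
explicitly: empty supra-threshold sets yield an empty (not error)
result, perfect noiseless fits cap |t| with a flag, subgroups too small
for the covariate set are skipped with a logged reason, and permutation
with fewer than 7 subjects is refused outright.

## The synthetic cohort generator

Because the original patient data are unavailable, the package ships a
first-class generator that plants known ground truth:

* **Cohort structure** — 30 controls, 40 PD-NC, 23 PD-MCI by default,
  the composition of the emulated study; ages 55–80, education 8–18
  years.
* **Latent cognition** — per subject and domain,
  `group shift + general factor + domain deviation`; variance components
  0.3/0.2/0.5 (general/domain/test) give within-domain test correlations
  of 0.5 and between-domain correlations of 0.3, typical of
  neuropsychological batteries. Raw scores are
  `norm mean + (latent + test noise) × norm SD`, inverted for the error
  count test. Default shifts: controls 0; PD-NC −0.3 SD in attention,
  executive and language; PD-MCI −2 SD everywhere.
* **Awareness** — CFQ items come from a discretized latent-normal model
  (four cutpoints binning a unit-variance latent into 0–4, preserving
  the ordinal scale with controllable location); the item latent tracks
  latent cognition *plus* the group's awareness offset, so the group's
  mean ISAcog magnitude approximately equals the offset (the ordinal
  item mapping attenuates it somewhat): 0 for controls and PD-NC,
  +1 SD for PD-MCI.
* **Volumes** — desk-scale grids (24 × 28 × 24 at 4 mm isotropic rather
  than the full 128/155/128 at 1.2 mm) keep permutation inference in
  minutes while preserving the analysis conventions: 6 mm FWHM Gaussian
  smoothing of the noise field, proportional scaling to grand mean 50.
  Each volume is `baseline + slope × ISAcog × mask + smoothed noise`;
  the default effect mask is a midline box (a stand-in for a medial
  frontal/cingulate region). `calibrateEffectSlope()` solves the slope
  analytically for a target voxel-wise correlation from the
  smoothed-noise SD, so "effect size r ≈ 0.6" is a closed-form setting,
  not a tuned number. In `simulateStudy()` the coupling applies to
  patients only, so the control regression is null by construction.

What the generator does **not** emulate: PET physics and frame dynamics,
registration error, spatially structured (non-stationary) noise,
anatomically shaped regions, item-level CFQ responses of real
questionnaires (only totals are calibrated), and any dependence of the
awareness offset on covariates. Passing tests therefore demonstrate the
*procedures* are correct and calibrated under clean planted truth — not
that real acquisitions meet these assumptions.

## Numerical choices

* Smoothing kernels are truncated at 3σ and column-normalized, so each
  input voxel distributes exactly unit mass and the in-volume sum is
  conserved without zero padding; σ = FWHM/(2√(2 ln 2)) per axis in mm,
  converted to voxels via the affine (anisotropic voxels handled per
  axis).
* The GLM residualizes the regressor and data against nuisance columns
  via QR; the permutation loop reuses the decomposition so each
  permutation costs two small matrix products.
* Cluster labelling is breadth-first search in C++ (Rcpp), verified
  exactly against a pure-R flood fill.
* t values at perfect fits are capped at 10⁸ and flagged rather than
  returned as Inf.
* Covariates are not centered by default (centering does not change the
  regressor's t-map); a centering flag exists.
* All randomness flows through explicit seeds; equal seeds give
  byte-identical cohorts, volumes and permutation draws.

## Problem sizes in the test suite

The suite exercises the permutation machinery at sizes chosen to make
Monte-Carlo bands tight while keeping a full run in minutes on one core:
200 null replicates on a 20 × 22 × 20 grid with n = 40 and 200
permutations for the family-wise-error check; 25 seeded replicates at
the calibrated effect size for planted-cluster recovery (Dice ≥ 0.5)
and specificity; 10,000 random profiles for the classifier oracle; five
6 × 6 × 6 stacks at n = 30 for the closed-form GLM oracle.

## Known limitations

* Permutation exchangeability is assumed across subjects; the
  Freedman–Lane scheme is approximate (though standard) in the presence
  of nuisance covariates.
* With 200 permutations the p-value resolution is 1/201 ≈ 0.005; studies
  wanting finer resolution should raise `n_perm` (the package warns
  below 500).
* The cluster-extent statistic is integer-valued; on small smooth-noise
  grids its permutation null distribution has heavy ties, so the attained
  family-wise error sits below (never above) the nominal level — the
  usual conservatism of discrete permutation tests. The cluster-mass
  statistic, being continuous, is closer to exact.
* The 2-of-10 impairment rule has a substantial base rate: with
  realistic between-test correlation, roughly one in six cognitively
  normal subjects crosses it by chance, which is a property of the
  criterion itself and visible in the generator's null simulations.
* The linear-in-age/education default norms are synthetic placeholders;
  real deployments should supply their instrument's norm tables via the
  CSV config.
* The published correlation between ISAcog and depression is
  sign-ambiguous given the signed definition; the package reports both
  conventions explicitly rather than guessing.
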