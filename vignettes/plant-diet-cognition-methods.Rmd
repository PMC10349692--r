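---
title: "Methods: plant-based diet indices, cognitive composites and the synthetic cohort"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: plant-based diet indices, cognitive composites and the synthetic cohort}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(pdicog)
```

This vignette documents the statistical procedures implemented in
`pdicog`, the modelling assumptions behind the synthetic cohort generator,
and the design decisions taken where the underlying methodology leaves a
choice open. It states no empirical result beyond what the package's test
suite and acceptance script compute.

## 1. Diet-index scoring

### Quintile scores

For each of the 18 food groups, participants are ranked into
*cohort-specific* quintiles of daily intake and scored 1–5. The scorer is
defined through the empirical CDF: a participant whose intake has CDF value
$F$ receives score $s$ iff $F \in ((s-1)/5,\; s/5]$. Implementation uses
exact integer arithmetic on ties-max ranks
($s = \lceil 5r/n \rceil$ with $r$ the number of intakes $\le$ the
participant's), so no floating-point boundary can misassign a score.

**Tie handling.** Identical intakes always receive identical scores — the
score implied by their shared CDF value. Food-group intakes in elderly
cohorts are heavily tied at zero (non-consumers of fish, legumes, nuts can
be 15–35% of a cohort), and a rank-breaking rule would assign different
scores to identical diets. A consequence worth knowing: with, say, 40%
zeros, the zero block has CDF 0.4 and scores 2, leaving score 1 unused.
The alternative — spreading ties across quintiles — was rejected because
index scores are meant to be functions of the reported diet alone. A
degenerate all-constant group scores 1 for everyone with a logged warning.

With tie-free intakes and $n$ divisible by 5 every score is used exactly
$n/5$ times, each group's score mean is exactly 3, and every index has
cohort mean exactly $18 \times 3 = 54$ — the analytic identity the
acceptance script recomputes.

### Scheme directions and index algebra

Raw indices sum 18 scores, reversed groups contributing $6 - s$. Useful
invariants follow (all property-tested on random cohorts): each raw index
lies in $[18, 90]$; per participant,
$\mathrm{hPDI} + \mathrm{uPDI} - 2A_r = 72$ where $A_r$ is the reversed
animal-group sum; and
$\mathrm{PDI} - \mathrm{uPDI} = 2H - 42$ with $H$ the healthy-plant score
sum.

### Energy adjustment

The residual method is applied to the *summed* index (not per group before
ranking): regress index on total energy, keep the residual, and re-centre
at the prediction for the cohort-mean energy. With an intercept in the
model the re-centring constant is exactly the raw-index mean, so the
adjusted index preserves the cohort mean and is numerically orthogonal to
energy (tested to $|r| < 10^{-8}$). A constant energy vector makes the
adjustment undefined; the index is returned unchanged with a warning.

### Tertiles

Exposure categories T1 < T2 < T3 are empirical-CDF cut points on the
**energy-adjusted** index, since that is the analysed exposure
(`tertiles_on = "raw"` offers the alternative; whether the original
analyses categorized before or after adjustment is not documented, so the
switch exists). Ties share a label; tie-free values give sizes differing by
at most 1. Observed unequal sizes (e.g. 226/202/230 in a cohort of 658)
arise only from duplicated adjusted values.

## 2. Cognitive composites

Each of the 12 tests is standardized as
$Z = (x - \bar{x}_{\text{baseline}})/s_{\text{baseline}}$, with the
baseline parameters estimated on the analysis cohort *after* exclusions
(sample SD, $n-1$). Follow-up scores reuse the baseline parameters, so
change scores live on the baseline scale. Timed scores (TMT, Stroop) are
sign-reversed inside the composites.

Three quantities are derived per participant on the raw scale *before*
standardization: the Stroop I–II mean time, Stroop interference, and the
TMT B/A ratio. Two of these required decisions the source methodology
leaves open:

- **Stroop interference** defaults to the ratio form
  $\text{III}/\tfrac{1}{2}(\text{I}+\text{II})$, the convention in Dutch
  ageing cohorts using the Stroop Colour-Word test; the difference form
  $\text{III}-\tfrac{1}{2}(\text{I}+\text{II})$ is available via
  `stroop_interference = "difference"`.
- **TMT executive measure** is the B/A ratio (reversed), reading the
  composite definition literally.

Composites are complete-case: a participant missing any component is `NA`
for that composite (and hence for global cognition), mirroring analyses
that report no imputation. Baseline cohort means of all five composites
are 0 by construction (tested to $10^{-10}$), and global cognition is
exactly the mean of the four domain composites.

## 3. Regression models

All models are ordinary least squares with t-based 95% intervals. Tiers:
crude; model 1 (age, gender, education); model 2 (model 1 + BMI, physical
activity, smoking, alcohol category, margarine). Reference levels: male,
low education, never smoker, light alcohol. The continuous exposure is the
energy-adjusted index divided by 10; tertile exposures emit T2-vs-T1 and
T3-vs-T1 contrasts. Longitudinal models run on the placebo arm only and
add the baseline composite to every tier, including the crude one — the
baseline adjustment is part of the change-score design, not of the
covariate tiers.

Guard rails: designs must have at least 10 more complete cases than
parameters; rank-deficient designs are rejected naming the collinear
columns (silent dropping would misreport the fitted model).

**Alcohol categories.** Light / moderate / excessive thresholds are not
standardized; the package uses ≤ 1, 1–3, and > 3 drinks/day. The cut
points are configuration in the generator and simply levels of a factor in
the models, so any alternative coding can be supplied in the input data.

**Effect modification.** Stratified analyses split at the cohort median of
the stratifier's intake, with exact-median values in the high stratum
(matching "intake ≥ median" labelling). The fully adjusted model is fitted
per stratum; the interaction p comes from a single product term
(continuous exposure × high-stratum indicator) added to the pooled fully
adjusted model — a one-df Wald test, matching a single reported overall
interaction p per index. With a tertile exposure the product spans both
contrasts and a two-df F test is reported instead. Covariates are baseline
values throughout; whether the original models re-measured covariates at
follow-up is unstated, and baseline covariates are the conservative
reading.

## 4. The synthetic cohort generator

The generator emulates the data structure the analysis needs, not any
particular cohort's joint distribution:

- **Intakes**: independent gamma draws per food group (group-specific mean
  and shape; right-skewed), with Bernoulli zero-inflation concentrated on
  episodically consumed groups (legumes 35%, nuts 25%, fish 15%, soft
  drinks 30%, juices/misc. animal 20%, eggs 10%). The distributions are
  stated assumptions — intake distributions are not published at this
  granularity — chosen to stress the quintile scorer with realistic
  ties-at-zero.
- **Energy**: `600 + 300·male + 55·(total servings) + N(0, 200²)` kcal/day,
  giving the positive energy–intake correlation the residual method needs,
  with > 99% of draws inside the plausibility windows so the exclusion
  filter is exercised without dominating.
- **Covariates**: age = 65 + gamma matching mean 72.1 / SD 5.4 (keeping
  the cohort 65+ while matching both moments, which a truncated normal
  would not); 59% male; education 43/24/33%; BMI N(27.2, 3.9²);
  LASA-style activity gamma; smoking 30/11/59%; alcohol category derived
  from simulated alcohol intake.
- **Arm**: independent Bernoulli (placebo fraction 0.5), as in a
  randomized trial; the intervention itself has no simulated effect, since
  the analysis only uses the arm as a subsetting flag.
- **Cognition**: a shared latent ability plus test-specific noise drives
  all 12 tests on their natural scales (e.g. RAVLT immediate 42 ± 9 words,
  TMT-A 45 ± 12 s), with timed tests sign-flipped. The Stroop cards and
  TMT-B are reconstructed from generated *derived* quantities (basic-card
  mean, interference ratio, B/A ratio), so the downstream derivations
  recover the latent structure without ratio-induced attenuation.
  Follow-up adds a latent decline (mean −0.12 Z, SD 0.25 over 2 years)
  and fresh test noise; a configurable fraction (default 5%) misses
  follow-up completely at random.

**Effect injection and calibration.** Configured effects are defined on
the scale the analysis estimates: Z units per 10 points of energy-adjusted
index. The generator scores its own intakes with the package's scoring
path to obtain that exposure, adds
`effect_pdi_cross · x_PDI + fish_modification · x_PDI · 1[fish ≥ median]`
(plus an age gradient, −0.02 Z/year) to latent baseline cognition and
`effect_hpdi_change · x_hPDI` to latent change. The latent ability SD is
then set so each test's total baseline variance is 1. Because baseline
Z-standardization divides by the cohort SD, this calibration makes the
downstream regression slope an unbiased estimate of the configured effect
— the property the parameter-recovery acceptance test verifies (200
replications at n = 600; mean estimate within ±0.02 of the injected 0.12,
CI coverage within [0.92, 0.98]).

`noise_sd_cognition` defaults to 0.5 on the latent scale, i.e. a per-test
reliability of 0.75 — mid-range for published test–retest reliabilities of
these instruments.

**What the generator does not emulate**, and hence what passing tests do
not establish about real data: correlated food-group intakes (true
dietary patterns co-vary), confounding (covariates are independent of
diet, so adjustment is exercised but not stress-tested), differential or
informative missingness, learning effects across test versions, floor and
ceiling effects (the RAVLT recognition and MMSE scales are not truncated
at their ceilings, except MMSE clamped to [0, 30]), and practice-related
non-linear decline.

**A power property worth stating.** Because the outcome is a unit-variance
Z composite, the residual SD of the fully adjusted model is necessarily
close to 1 (≈ 0.88 under the defaults), and the SD of the per-10-point
exposure is ≈ 0.6. A between-stratum slope *difference* of 0.15 at 300
participants per stratum therefore has a standard error near 0.11: the
probability that the high stratum shows the larger estimate is ≈ 0.90, and
one-df interaction power at α = 0.05 is only ≈ 0.25. Detecting
modification of that size reliably needs several times this sample. This
is a property of the design the package emulates, not of the
implementation; the corresponding acceptance check is stricter than this
power allows and is expected to flag it.

## 5. Numerical choices and degenerate inputs

- Quintile/tertile scores via integer arithmetic (no floating-point CDF
  comparisons); quantile cut points are empirical-CDF values, never
  interpolated — scores are ranks.
- Energy bounds are strict inequalities (a male at exactly 800 kcal/day is
  retained), following the printed comparators literally.
- Sample SDs use the $n-1$ denominator everywhere.
- Degenerate inputs fail loudly and by name: all-constant intake groups
  (warning, all score 1), constant energy (warning, no adjustment), zero
  baseline SD (error naming the test), unknown gender or factor levels
  (error), duplicate participant ids (error).
- Gamma age parameters: shape $((\mu - 65)/\sigma)^2$, scale
  $\sigma^2/(\mu - 65)$.

## 6. Problem sizes used by the checks

The test suite exercises: oracle equivalence of the quintile scorer on 500
random vectors (n ≤ 200, 0–60% zeros); index algebra on 1,000 cohorts of
n = 50; parameter recovery over 200 replications at n = 600; type-I-error
calibration over 1,000 replications at n = 300; interaction-test null
calibration over 300 replications at n = 300; and marginal checks of the
generator at n = 10,000. These sizes give Monte-Carlo error comfortably
inside the asserted tolerances for each check.

## 7. Known limitations

- The 190-item questionnaire-to-group mapping is user configuration
  (`aggregate_intake()`); the package ships no food-composition database
  and computes no nutrients.
- The generator draws food groups independently; indices built on
  correlated intakes will have larger variance than the synthetic default.
- MMSE is descriptive only and deliberately excluded from modelling.
- No mixed models, imputation, mediation, or multiple-testing correction —
  matching the analysis design the package implements, where p < 0.05 is
  the stated criterion.
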