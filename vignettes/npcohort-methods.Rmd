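---
title: "Methods: nutrient-profile scoring, dietary exposures and cohort survival models"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: nutrient-profile scoring, dietary exposures and cohort survival models}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(npcohort)
```

`npcohort` implements a complete prospective-cohort analysis of
"less-healthy" food consumption: item-level FSA-Ofcom nutrient-profile
scoring, person-level exposure construction from 7-day diet diaries, a
reproducible exclusion cascade, and Cox proportional-hazards modelling
over exposure quintiles. A synthetic-study generator supplies data with a
known planted truth, so that every claim the package makes about its
estimators is demonstrated by simulation rather than asserted.

## The scoring model

Each item is scored from its composition per 100 g *edible weight*; the
package never rescales nutrient fields, and inputs are deliberately not
rounded before scoring — diary-derived compositions are continuous, and
rounding would manufacture boundary artefacts at the cut-points.

"A" (adverse) points for energy, saturated fat, total sugars and sodium
each count the cut-points of a 10-step table strictly exceeded; "C"
(beneficial) points for fruit/vegetable/nut (FVN) content, non-starch
polysaccharide fibre and protein use 5-point scales, the FVN component
jumping 1 → 2 → 5 at more than 40/60/80% by weight. All tables are
*configuration data* (`default_scoring_tables()`, YAML round-trippable via
`read_scoring_tables()`/`write_scoring_tables()`), so a corrected table is
a data change, not a code change. Strict "more than" semantics are pinned
at every cut-point and exercised by boundary tests: exactly 4.5 g sugars
scores 0 points, 4.5 + ε scores 1.

The total is `A − (FVN + fibre + protein)` with the protein gate: when
`A ≥ 11` and FVN points are below their maximal 5, protein cannot offset A
points. Classification applies the regulatory thresholds — food
less-healthy at score ≥ 4, beverage at ≥ 1 — and any alcoholic beverage is
left unscored, mirroring the model's operational use. The scoring path is
verified item-by-item against an independently coded brute-force oracle on
10,000 random compositions (with extra probability mass placed exactly on
the cut-points), alongside monotonicity and gate-independence property
tests.

Composite items carry their disaggregated FVN weight fraction in the
catalogue (`fvn_pct`); the same strict rule applies to them. Fibre is NSP
fibre throughout; AOAC-style tables are out of scope.

## From diaries to exposures

`build_exposure()` turns participant × day × item × grams records into one
row per participant. Energy per record is `grams × energy_kj / 100`; sums
are routed by classification and divided by the number of *distinct*
observed diary days, so partial diaries (allowed down to one day) scale
correctly. The headline exposure is the proportion of energy from
less-healthy items, with alcoholic-beverage energy excluded from the
denominator because alcohol sits outside the scoring guidelines.
Numerically the denominator is computed as (less-healthy + healthy) energy
— algebraically identical to (total − alcoholic) but guaranteed to keep
the proportion inside [0, 1] to the last ulp.

Two sensitivity exposures are computed alongside: the proportion of food
*weight* that is less-healthy (beverage weight included by default — the
variant exists precisely because heavy beverages may distort it, and a
`include_beverage_weight` switch exposes the choice; the denominator again
excludes alcoholic beverages, by symmetry with the energy version), and
the energy-weighted mean item score over non-alcoholic items, which treats
the scoring system as a continuous dietary index. Fruit-and-vegetable
weight uses the disaggregated FVN fractions and feeds the validation
exposure `quintile_fv`.

**Quintiles.** `assign_quintiles()` sorts ascending with stable
`(value, id)` order and places group *k* on ranks
`(⌈n(k−1)/5⌉, ⌈nk/5⌉]`. Group sizes differ by at most one, boundary ties
break deterministically by participant id, and at n = 22,992 the rule
yields the size pattern {4599, 4598, 4599, 4598, 4598}. Quintiles are
assigned on the post-exclusion analysis set, per outcome.

## Exclusion cascade

`apply_exclusions()` applies, in a fixed and logged order: (1) no
completed diary day; (2) the energy-misreporting trim — participants in
the top or bottom 0.5% of reported energy intake over Schofield-predicted
basal metabolic rate (sex × age-band linear equations in body weight,
bands 18–29/30–59/60+, coefficients held in
`schofield_coefficients()`); (3) prevalent cardiovascular disease
(self-reported angina, heart attack or stroke) for CVD analyses only —
mortality analyses retain these participants and adjust for the flags
instead; (4) missing covariates, dropped rather than imputed. The
percentile convention for the trim is nearest-rank: values strictly below
the `⌊nq⌋+1`-th or strictly above the `n−⌊nq⌋`-th order statistic are
removed, so 1,000 distinct ratios lose exactly 5 per tail, an all-tied
sample loses none, and `trim_fraction = 0` is the identity. Samples below
200 skip the trim with a warning rather than trimming unstable tails.

Sensitivity exclusions (baseline comorbidities, family history of CVD or
diabetes, and a landmark dropping events inside the first two years) chain
after the main cascade; every step appends a
`(step, n_before, n_excluded, n_after)` row to the exclusion log.

## Survival models

All fits are Cox proportional-hazards models via the `survival` package
with **Efron** tie handling — coarse time grids make ties common and Efron
is accurate there; the choice is pinned since nothing in the analysis plan
dictates it. Time zero is study entry and the scale is follow-up years,
with age entering as a continuous covariate rather than as the time scale
(its per-year hazard ratio is then reportable). Confidence intervals are
Wald on the log-HR scale; p-values two-sided; no multiplicity correction
is applied, matching the analysis being reproduced.

Covariate encoding fixes the reference levels: smoking ref = current,
activity ref = inactive, education ref = no qualifications, sex ref =
male; total energy is scaled per 2,000 kJ/day. The quintile exposure
enters as four indicator contrasts against quintile 1 (whose hazard ratio
is 1 by construction), and the **trend test** refits the same
specification with the quintile index 1–5 as a single continuous
covariate, reporting the Wald p for its coefficient.

The **substitution model** replaces the quintile exposure with energy from
less-healthy food, less-healthy beverages and healthy beverages plus total
energy (each per 1,000 kJ/day); holding total energy and the beverage
terms fixed, the less-healthy-food coefficient is the log-HR of
isocalorically swapping healthy for less-healthy food. A rank check
rejects degenerate inputs (e.g. components that sum exactly to the total)
before fitting.

Proportional hazards are checked with scaled Schoenfeld residuals
(`survival::cox.zph`, Kaplan-Meier time transform), one
correlation-with-time test per model term plus the global chi-square;
models with fewer than 10 events skip the test with a warning. Likely
complete separation (diverging coefficients or the fitter's infinite-
coefficient warnings) is flagged on the fit object rather than silently
reported; genuine non-convergence raises an error.

## The synthetic-study generator

The generator is first-class, tested code, not a fixture. Its defaults
describe the study conditions being emulated: 25,639 recruited adults aged
40–79; 0.7% returning no diary and 9.2% of diary-keepers completing fewer
than 7 days; a 150-item catalogue drawn from archetypes (fruit/vegetables,
staples, dairy/meat, processed foods, sugary/diet/alcoholic beverages)
whose nutrient ranges straddle both classification boundaries, with one
pinned anchor item per key archetype guaranteeing coverage even at the
20-item minimum.

Behaviour is driven by a latent per-person *less-healthy affinity*
`a ~ N(0, 1)`. Item selection tilts log-linearly toward less-healthy
archetypes with `a` (`lh_tilt = 0.65`), alcoholic-beverage selection is
proportional to reported alcohol units, portion grams are log-normal and
rescaled so each diary day matches the person's target energy — itself
increasing in `a`, reproducing the observed energy gradient. Covariates
depend on `a` through logistic/linear links whose signs and magnitudes
emulate the published baseline table, including the *reverse-causation
signature*: higher-affinity participants are older, more often male and
current smokers and drink less alcohol, but are **less** likely to be on
antihypertensive or lipid-lowering medication or to report diabetes, and
have lower BMI. Under the defaults the realised affinity-exposure
correlation is 0.80 and quintile gradients match the emulated table to
within sampling noise (checked by tests at n = 8,000).

Outcomes come from Weibull proportional-hazards processes (shape 1 by
default, i.e. exponential; the shape is configurable to stress the PH
diagnostics) for incident CVD and all-cause death, with CVD death a
flagged subset and incident events split into myocardial infarction and
stroke; a fatal-within-30-days flag is carried as metadata but not
modelled. Censoring combines a uniform 18–22-year administrative horizon
(staggered recruitment against a fixed linkage end) with a small
exponential dropout. Baseline rates (0.0300 and 0.0248 per year at the
reference covariate pattern) were calibrated once so a default-scale study
reproduces the emulated magnitudes — about 21% incident CVD in the
~22,900-person CVD analysis set, 28.5% deaths, and ~16 years mean
follow-up — and then frozen. Only overall rates are targeted: per-quintile
event counts are not published for the emulated cohort.

**The planted truth is a null**: the exposure's per-quintile log-HR is 0
for every outcome, while covariate log-HRs take the published adjusted
magnitudes. The flagship full-scale run therefore shows the study's
central interpretive pattern as an executable fact: a strong adverse
unadjusted gradient (confounding), a weakly *protective* Model-1 residual
(the clinical flags are not yet adjusted for), and a Model-2 null.
`truth.json` records every planted parameter next to the data, and all
artefacts are pure functions of `(config, seed)` — regeneration is
byte-identical.

`simulate_cohort()` is the cohort-level shortcut for repeated-simulation
studies: it draws the exposure directly from affinity plus noise matched
to the diary path's affinity-exposure correlation and skips catalogue and
diary generation, which adds nothing when the quantity under study is an
estimator's sampling behaviour.

## Simulation study designs and their sizes

The repeated-simulation checks in the test suite use sizes chosen for
estimator precision on a single CPU:

* *Scoring oracle*: 10,000 random compositions, exact equality required.
* *Parameter recovery*: planted covariate log-HR 0.2, n = 5,000, 200
  replicates; mean bias within ±0.05 and 95% CI coverage in [92%, 98%].
* *Null calibration*: 200 replicates of `simulate_cohort(2000)` under the
  default (confounded, null-exposure) truth, comparing unadjusted, Model-1
  and Model-2 trend-test rejection at α = 0.05. The replicate size is a
  deliberate compromise: the confounded crude trend (≈0.05 per quintile)
  is detected far above the nominal rate already at ~430 events, while the
  residual Model-1 bias from the not-yet-adjusted clinical flags (≈0.01
  per quintile) stays within the 5% ± 2% calibration band at this scale.
  At the full 23,000-person scale that residual bias is itself detectable
  — which is exactly the behaviour the emulated study reported for its
  Model 1 — so calibration of Model 1 is a statement about moderate
  samples, not an asymptotic property. Model 2 adjusts for every planted
  confounder and is calibrated at any scale.
* *Substitution*: 20 replicates at n = 10,000 each, testing the **mean**
  coefficient — a single draw has Monte-Carlo standard error comparable to
  the 0.02 bias bound being asserted, so averaging tests bias rather than
  noise; a planted pure total-energy effect must leave |mean log-HR| <
  0.02 per 1,000 kJ and a planted 0.1 swap effect must be recovered within
  ±0.03.
* *PH diagnostics*: 100 replicates at n = 5,000; global Schoenfeld test
  ≈5% under exact PH and ≥80% power against a log-time interaction
  (log-HR drifting 0.3 + 0.6·log t), simulated in closed form by
  inverting the cumulative hazard.

## Degenerate inputs and numerical choices

Negative nutrients, unknown item classes, duplicate item ids, unresolvable
diary items, non-positive grams and out-of-range diary days all fail fast
with messages naming the offending item and field. Constant exposures make
the design degenerate and error before fitting. Proportions are computed
from component sums (containment in [0, 1] by construction); routed
energies re-add to the total within 1e-9 relative tolerance in property
tests. Quintile boundary values are returned alongside labels; exclusion
logs reconcile exactly row-to-row.

## Limitations

Passing tests demonstrate correct mechanics and calibrated inference *on
data shaped like the generator's output*. Real diet-diary data differ in
ways the generator deliberately does not model: food-composition databases
with correlated measurement error, within-person day-to-day menu
correlation, seasonality, coding error in diary entry, and outcome
ascertainment via record linkage with ICD coding (synthetic outcomes carry
pre-coded flags). The synthetic fruit-and-vegetable analysis is null after
adjustment because the default truth plants no direct diet effect on
hazard — unlike the real-data validation analysis it mirrors, which is
expected to detect a genuine protective association. And because the
planted hazard acts only through the modelled covariates, Model 2 is
correctly specified by construction; real analyses enjoy no such
guarantee, which is why residual confounding can never be excluded there.
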