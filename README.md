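# npcohort

Nutrient-profile scoring and cohort survival analysis for "less-healthy"
food exposures.

## The problem

The UK FSA-Ofcom nutrient profiling model assigns every food or beverage a
numeric score from its composition per 100 g and classifies items above a
threshold as *less-healthy* — the classification used to restrict food
advertising to children. Whether the foods it singles out are actually
associated with prospective cardiovascular disease can be tested in a diet
diary cohort: score every item eaten, build each person's proportion of
energy obtained from less-healthy items, and relate quintile groups of that
exposure to incident CVD and mortality with Cox proportional-hazards
models. `npcohort` implements that full analytic chain for epidemiologists
and nutrition researchers, together with a synthetic-study generator that
emulates the cohort's data structure — including the reverse-causation
confounding pattern in which higher-risk people eat *less* of the
less-healthy food — so every stage is testable end to end without access to
individual-level cohort data.

## The model

Per 100 g edible weight, "A" points accrue for energy (kJ), saturated fat
(g), total sugars (g) and sodium (mg) — each the number of cut-points in a
10-step table strictly exceeded — and "C" points for fruit/vegetable/nut
content (1, 2 or 5 points at >40/>60/>80% by weight), non-starch
polysaccharide fibre and protein (5-step tables):

    score = A_total − (FVN + fibre + protein points)

with the *protein gate*: if `A_total ≥ 11` and FVN points `< 5`, protein
points are not counted. A **food** is less-healthy at `score ≥ 4`, a
**beverage** at `score ≥ 1`; alcoholic beverages are never scored. The
person-level exposure is

    (energy from less-healthy food + energy from less-healthy beverages)
    ───────────────────────────────────────────────────────────────────
           (total energy intake − energy from alcoholic beverages)

averaged over observed diary days, with the cohort divided into quintile
groups. Hazard ratios come from Cox models (Efron ties, Wald 95% CIs) under
three covariate sets: Model 1 (age, sex, education, smoking, physical
activity, alcohol, total energy), Model 2 (Model 1 plus self-reported
clinical risk factors and family history) and Model 2′ (Model 1 plus
non-mediator clinical covariates); the trend test enters the quintile index
as one continuous covariate.

## Worked example

```r
library(npcohort)

# a small synthetic study: 2,000 participants, 120-item catalogue
cfg <- study_config(n_participants = 2000, n_items = 120, seed = 42)
study <- generate_study(cfg)

scored <- score_catalogue(study$catalogue)
#> Scored 120 items: 51 healthy, 61 less-healthy, 8 unscored (alcoholic).

head(scored[, c("item_id", "a_total", "score", "classification")], 4)
#> # A tibble: 4 × 4
#>   item_id       a_total score classification
#>   <chr>           <int> <int> <chr>
#> 1 fruit_veg_001       1    -7 healthy
#> 2 fruit_veg_002       1    -7 healthy
#> 3 fruit_veg_003       1    -8 healthy
#> 4 fruit_veg_004       0    -8 healthy

cohort <- apply_exclusions(study$participants, study$exposure,
                           study$outcomes, analysis = "cvd")
exclusion_log(cohort)
#> # A tibble: 4 × 4
#>   step                                         n_before n_excluded n_after
#> 1 diary: fewer than 1 completed day                2000         16    1984
#> 2 energy:BMR ratio trim                            1984         18    1966
#> 3 prevalent CVD (angina, heart attack, stroke)     1966        155    1811
#> 4 missing covariates                               1811         24    1787

fit <- fit_cox_model(cohort, "incident_cvd", "quintile_energy", "model2")
fit
#> <npc_fit> Cox proportional hazards: incident_cvd ~ quintile_energy (model2)
#>   n = 1787  events = 396
#>   Quintile HRs (ref Q1): Q1 1.00, Q2 1.03, Q3 0.87, Q4 0.81, Q5 0.95
#>   Trend test p = 0.432
```

The exclusion log mirrors the study's flow diagram: diary completeness,
the 0.5% energy-to-basal-metabolic-rate trim (Schofield equations),
prevalent cardiovascular disease (CVD analyses only), then missing
covariates. The fully adjusted fit correctly reports no exposure-outcome
association — the generator's default truth plants a *zero* exposure
effect behind strong confounding, so the unadjusted model shows a spurious
adverse gradient that adjustment removes. `tidy()`, `glance()`,
`autoplot()` and `check_ph()` work on every fitted model; `trend_test()`
and `fit_substitution()` give the trend and isocaloric-substitution
parameterisations, and `fit_cox_model(..., exposure = "quintile_fv")` runs
the fruit-and-vegetable analysis.

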