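make_cohort_inputs <- function(n = 400, seed = 21) {
  cfg <- study_config(n_participants = n, seed = seed)
  participants <- generate_participants(cfg, n = n, missingness = FALSE)
  set.seed(seed + 1)
  exposure <- tibble::tibble(
    participant_id = participants$participant_id,
    n_diary_days = 7L,
    energy_lh_food = runif(n, 1500, 5000),
    energy_lh_bev = runif(n, 0, 500),
    energy_healthy_food = runif(n, 1500, 5000),
    energy_healthy_bev = runif(n, 0, 500),
    energy_alcoholic = runif(n, 0, 600),
    weight_lh = runif(n, 100, 500),
    weight_total = runif(n, 600, 1500),
    fv_weight = runif(n, 50, 600)
  )
  exposure$energy_healthy <- exposure$energy_healthy_food + exposure$energy_healthy_bev
  exposure$energy_total <- exposure$energy_lh_food + exposure$energy_lh_bev +
    exposure$energy_healthy + exposure$energy_alcoholic
  exposure$prop_lh_energy <- (exposure$energy_lh_food + exposure$energy_lh_bev) /
    (exposure$energy_total - exposure$energy_alcoholic)
  exposure$prop_lh_weight <- exposure$weight_lh / exposure$weight_total
  exposure$mean_weighted_score <- runif(n, 0, 12)
  outcomes <- tibble::tibble(
    participant_id = participants$participant_id,
    cvd_event = rbinom(n, 1, 0.2), cvd_time = runif(n, 0.1, 20),
    death_event = rbinom(n, 1, 0.3), death_time = runif(n, 0.1, 20),
    cvd_death_event = 0L, mi_event = 0L, mi_time = 1, stroke_event = 0L,
    stroke_time = 1, fatal_30d = 0L
  )
  list(participants = participants, exposure = exposure, outcomes = outcomes)
}

test_that("Schofield BMR matches the published sex/age-band equations", {
  expect_equal(schofield_bmr("male", 45, 75), 0.048 * 75 + 3.653)
  expect_equal(schofield_bmr("female", 65, 60), 0.038 * 60 + 2.755)
  expect_equal(schofield_bmr("female", 25, 60), 0.062 * 60 + 2.036)
  # vectorised over participants
  expect_equal(
    schofield_bmr(c("male", "female"), c(45, 65), c(75, 60)),
    c(7.253, 5.035)
  )
  expect_error(schofield_bmr("male", 45, 0), "positive")
  expect_error(schofield_bmr("male", 17, 70), ">= 18")
  expect_error(schofield_bmr("other", 45, 70), "male")
})

test_that("the 0.5% energy:BMR trim uses nearest-rank bounds", {
  set.seed(33)
  d <- tibble::tibble(id = 1:1000, ratio = sample(runif(1000, 0.5, 3)))
  out <- trim_energy_bmr(d, ratio)
  expect_identical(nrow(out), 990L)
  kept <- sort(d$ratio)[6:995]
  expect_setequal(out$ratio, kept)
  # all-tied ratios: nothing strictly outside the bounds
  tied <- tibble::tibble(ratio = rep(1.4, 500))
  expect_identical(nrow(trim_energy_bmr(tied, ratio)), 500L)
  # zero trim fraction is the identity
  expect_identical(trim_energy_bmr(d, ratio, trim_fraction = 0), d)
  # too small for trimming: warn, no trim
  small <- tibble::tibble(ratio = runif(150, 0.5, 3))
  expect_warning(out_small <- trim_energy_bmr(small, ratio), "200")
  expect_identical(nrow(out_small), 150L)
  expect_error(trim_energy_bmr(tibble::tibble(ratio = c(1, -2)), ratio),
               "positive")
})

test_that("trim removes floor(nq)..ceiling(nq) per tail for distinct ratios", {
  for (n in c(437, 1000, 2503)) {
    d <- tibble::tibble(ratio = runif(n, 0.5, 3))
    removed <- n - nrow(trim_energy_bmr(d, ratio))
    expect_gte(removed, 2 * floor(n * 0.005))
    expect_lte(removed, 2 * ceiling(n * 0.005))
  }
})

test_that("the exclusion cascade drops prevalent CVD only for the CVD analysis", {
  inp <- make_cohort_inputs()
  cvd <- apply_exclusions(inp$participants, inp$exposure, inp$outcomes, "cvd")
  mort <- apply_exclusions(inp$participants, inp$exposure, inp$outcomes,
                           "mortality")
  log_cvd <- exclusion_log(cvd)
  log_mort <- exclusion_log(mort)
  expect_true(any(grepl("prevalent CVD", log_cvd$step)))
  expect_false(any(grepl("prevalent CVD", log_mort$step)))
  n_prev <- with(inp$participants, sum(angina | heart_attack | stroke))
  expect_gt(n_prev, 0)
  # every prevalent participant surviving earlier steps is removed
  expect_false(any(cvd$angina | cvd$heart_attack | cvd$stroke))
  expect_true(any(mort$angina | mort$heart_attack | mort$stroke))
  # mortality cohort is a superset of the CVD cohort
  expect_true(all(cvd$participant_id %in% mort$participant_id))
})

test_that("exclusion log rows chain and reconcile", {
  inp <- make_cohort_inputs(seed = 22)
  coh <- apply_exclusions(inp$participants, inp$exposure, inp$outcomes, "cvd",
                          drop_comorbid = "all", drop_fh_cvd = TRUE,
                          landmark_years = 2)
  log <- exclusion_log(coh)
  expect_identical(log$n_after, log$n_before - log$n_excluded)
  expect_identical(log$n_before[-1], log$n_after[-nrow(log)])
  expect_identical(log$n_after[nrow(log)], nrow(coh))
  expect_identical(log$n_before[1], nrow(inp$participants))
  # sensitivity exclusions really applied
  expect_false(any(coh$diabetes | coh$past_cancer | coh$hypertension |
                     coh$hypercholesterolemia | coh$bp_medication |
                     coh$lipid_medication | coh$fh_mi | coh$fh_stroke))
  expect_false(any(coh$cvd_event == 1 & coh$cvd_time <= 2))
})

test_that("participants without a diary day are excluded up front", {
  inp <- make_cohort_inputs(seed = 23)
  exposure <- inp$exposure[-(1:15), ]
  coh <- apply_exclusions(inp$participants, exposure, inp$outcomes, "cvd")
  log <- exclusion_log(coh)
  expect_identical(log$n_excluded[grepl("diary", log$step)], 15L)
  # idempotent: re-running on the surviving set removes no-one at diary/trim
  coh2 <- apply_exclusions(
    dplyr::select(coh, dplyr::all_of(names(inp$participants))),
    exposure, inp$outcomes, "cvd", trim_fraction = 0
  )
  log2 <- exclusion_log(coh2)
  expect_identical(sum(log2$n_excluded[grepl("diary|prevalent", log2$step)]), 0L)
})

test_that("quintiles are assigned on the post-exclusion analysis set", {
  inp <- make_cohort_inputs(seed = 24)
  coh <- apply_exclusions(inp$participants, inp$exposure, inp$outcomes, "cvd")
  expect_true(all(c("quintile_energy", "quintile_weight", "quintile_score",
                    "quintile_fv") %in% names(coh)))
  sizes <- as.integer(table(coh$quintile_energy))
  expect_lte(max(sizes) - min(sizes), 1L)
  expect_error(
    apply_exclusions(inp$participants, inp$exposure, inp$outcomes, "lifespan"),
    "must be one of"
  )
})
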