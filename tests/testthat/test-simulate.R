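test_that("a study regenerates bit-identically from (config, seed)", {
  cfg <- study_config(n_participants = 300, n_items = 40, seed = 5)
  s1 <- generate_study(cfg)
  s2 <- generate_study(cfg)
  expect_identical(s1$catalogue, s2$catalogue)
  expect_identical(s1$participants, s2$participants)
  expect_identical(s1$diaries, s2$diaries)
  expect_identical(s1$outcomes, s2$outcomes)

  d1 <- withr::local_tempdir()
  d2 <- withr::local_tempdir()
  generate_study(cfg, dir = d1)
  generate_study(cfg, dir = d2)
  files <- c("catalogue.csv", "participants.csv", "diaries.csv",
             "outcomes.csv", "truth.json", "config.yaml")
  expect_true(all(file.exists(file.path(d1, files))))
  expect_identical(
    unname(tools::md5sum(file.path(d1, files))),
    unname(tools::md5sum(file.path(d2, files)))
  )
})

test_that("even a 20-item catalogue covers both classes and both boundaries", {
  cfg <- study_config(n_participants = 100, n_items = 20, seed = 13)
  cat0 <- generate_catalogue(cfg)
  expect_identical(nrow(cat0), 20L)
  scored <- score_catalogue(cat0, quiet = TRUE)
  expect_gte(sum(scored$classification == "less_healthy" &
                   scored$item_class == "food"), 1L)
  expect_gte(sum(scored$classification == "less_healthy" &
                   scored$item_class == "beverage"), 1L)
  expect_gte(sum(scored$classification == "healthy"), 1L)
  expect_gte(sum(scored$item_class == "alcoholic_beverage"), 1L)
  # fruit/vegetable archetype items never classify as less-healthy
  fv <- scored$classification[cat0$archetype == "fruit_veg"]
  expect_true(all(fv == "healthy"))
})

test_that("covariate-exposure links vanish when confounding is switched off", {
  cfg <- study_config(
    seed = 14,
    confounding = list(
      age = 0, sex_male = 0, smoking_current = 0, education = 0,
      alcohol_log = 0, diabetes = 0, bp_medication = 0, lipid_medication = 0,
      hypertension = 0, hypercholesterolemia = 0, past_cancer = 0,
      fh_mi = 0, fh_stroke = 0, fh_diabetes = 0, prevalent_cvd = 0, bmi = 0
    )
  )
  coh <- simulate_cohort(8000, cfg)
  expect_lt(abs(cor(coh$prop_lh_energy, coh$age)), 0.05)
  expect_lt(abs(cor(coh$prop_lh_energy, coh$sex == "male")), 0.05)
  expect_lt(abs(cor(coh$prop_lh_energy, coh$diabetes)), 0.05)
  expect_lt(abs(cor(coh$prop_lh_energy, coh$bmi)), 0.05)
})

test_that("default confounding reproduces the documented baseline gradients", {
  coh <- simulate_cohort(8000, study_config(seed = 15))
  q <- coh$quintile_energy
  # current smoking and age rise across quintiles; diabetes, medication,
  # alcohol and BMI fall (the reverse-causation signature)
  expect_gt(mean(coh$smoking[q == 5] == "current"),
            mean(coh$smoking[q == 1] == "current"))
  expect_gt(mean(coh$age[q == 5]), mean(coh$age[q == 1]))
  expect_lt(mean(coh$diabetes[q == 5]), mean(coh$diabetes[q == 1]))
  expect_lt(mean(coh$bp_medication[q == 5]), mean(coh$bp_medication[q == 1]))
  expect_lt(mean(coh$alcohol_units[q == 5]), mean(coh$alcohol_units[q == 1]))
  expect_lt(mean(coh$bmi[q == 5]), mean(coh$bmi[q == 1]))
  expect_gt(mean(coh$energy_total[q == 5]), mean(coh$energy_total[q == 1]))
})

test_that("event fractions match the closed form under a flat hazard", {
  cfg <- study_config(seed = 16)
  cfg$hazard$cvd$betas[] <- 0
  cfg$hazard$cvd$rate <- 0.02
  cfg$hazard$cvd$exposure_loghr_per_quintile <- 0
  cfg$hazard$death$rate <- 0
  cfg$censoring <- list(horizon_min = 15, horizon_max = 15, dropout_rate = 0)
  p_expected <- 1 - exp(-0.02 * 15)
  frac <- sapply(16:20, function(s) {
    mean(simulate_cohort(10000, cfg, seed = s)$cvd_event)
  })
  se <- sqrt(p_expected * (1 - p_expected) / (5 * 10000))
  expect_lt(abs(mean(frac) - p_expected), 3 * se)
  coh <- simulate_cohort(10000, cfg)
  expect_true(all(coh$cvd_time[coh$cvd_event == 0] == 15))

  # doubling a small baseline hazard roughly doubles the event fraction
  cfg$hazard$cvd$rate <- 0.002
  lo <- mean(simulate_cohort(10000, cfg, seed = 17)$cvd_event)
  cfg$hazard$cvd$rate <- 0.004
  hi <- mean(simulate_cohort(10000, cfg, seed = 18)$cvd_event)
  expect_gt(hi / lo, 1.6)
  expect_lt(hi / lo, 2.4)
})

test_that("diaries respect the completion pattern and record constraints", {
  cfg <- study_config(n_participants = 2000, n_items = 60, seed = 19)
  parts <- generate_participants(cfg)
  cat0 <- generate_catalogue(cfg)
  diary <- generate_diaries(parts, cat0, cfg)
  expect_true(all(diary$grams > 0))
  expect_true(all(diary$day_index >= 1 & diary$day_index <= 7))
  days <- dplyr::count(dplyr::distinct(diary, participant_id, day_index),
                       participant_id)
  expect_gt(mean(days$n == 7), 0.87)
  expect_lt(mean(days$n == 7), 0.94)
  # a few participants never returned a diary
  expect_gte(nrow(parts) - nrow(days), 1L)
  # energy intake rises with affinity (diet-energy gradient)
  scored <- score_catalogue(cat0, quiet = TRUE)
  ex <- build_exposure(diary, scored, cat0)
  m <- dplyr::inner_join(parts, ex, by = "participant_id")
  expect_gt(cor(m$affinity, m$energy_total), 0.3)
  expect_gt(cor(m$affinity, m$prop_lh_energy), 0.6)
})

test_that("the planted truth is recorded alongside the data", {
  cfg <- study_config(n_participants = 200, n_items = 30, seed = 20)
  study <- generate_study(cfg)
  expect_identical(study$truth$exposure_loghr_per_quintile,
                   c(cvd = 0, death = 0))
  expect_identical(study$truth$baseline$cvd$rate, cfg$hazard$cvd$rate)
  expect_identical(study$truth$seed, cfg$seed)
  expect_identical(study$config, cfg)
})

test_that("config validation rejects impossible settings", {
  expect_error(study_config(n_items = 10), "20")
  expect_error(study_config(censoring = list(horizon_min = -1)), "horizon")
  expect_error(study_config(diary = list(p_incomplete = 1.4)), "probabilities")
})
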