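#' Configuration for a synthetic study
#'
#' Bundles every knob of the synthetic-study generator: sample sizes, diary
#' behaviour, the latent "less-healthy affinity" preference model, the
#' confounding coefficients linking affinity to baseline covariates
#' (including the inverse medication/BMI gradients characteristic of reverse
#' causation), the planted proportional-hazards truth, and censoring.
#' Defaults emulate the structure of a UK population-based cohort of
#' 40-79-year-olds followed ~16 years: n = 25,639 recruited, 90.8% of
#' diary-keepers completing all 7 days, ~21.6% incident CVD in the CVD
#' analysis set and ~28.7% all-cause deaths, and a *zero* planted exposure
#' effect on every hazard so that adjusted analyses should be null while
#' confounding drives the unadjusted gradient.
#'
#' @param n_participants,n_items Cohort and catalogue sizes.
#' @param seed Integer seed; every artefact is a pure function of
#'   (config, seed).
#' @param ... Replacements for any nested default (supplied as named lists
#'   are merged shallowly at the top level).
#' @return A list of class `npc_config`.
#' @export
study_config <- function(n_participants = 25639, n_items = 150, seed = 1L, ...) {
  config <- list(
    n_participants = n_participants,
    n_items = n_items,
    seed = as.integer(seed) %% 1000000000L,
    diary = list(
      p_no_diary = 0.007,     # never returned a single diary day
      p_incomplete = 0.092,   # of diary keepers, fewer than 7 days
      items_per_day = 12,     # mean distinct records per day
      portion_sdlog = 0.4,
      day_energy_cv = 0.12
    ),
    preference = list(
      affinity_sd = 1,
      lh_tilt = 0.65,          # selection tilt toward less-healthy archetypes
      exposure_noise_sd = 0.75, # cohort-level shortcut: corr(affinity, exposure) ~ 0.8
      prop_lh_mean = 0.473,    # marginal proportion-of-energy scale
      prop_lh_sd = 0.118
    ),
    energy = list(base = 7500, male = 1300, per_affinity = 1030,
                  sd = 1800, min = 3000),
    confounding = list(
      age = 0.81, sex_male = 0.33, smoking_current = 0.26,
      education = -0.24, alcohol_log = -0.63,
      diabetes = -0.66, bp_medication = -0.10, lipid_medication = -1.05,
      hypertension = -0.10, hypercholesterolemia = -0.34, past_cancer = 0,
      fh_mi = -0.082, fh_stroke = -0.056, fh_diabetes = -0.034,
      prevalent_cvd = -0.17, bmi = -0.43
    ),
    margins = list(
      age_mean = 58.6, age_sd = 9.2, p_male = 0.435,
      p_smoking_current = 0.118, p_former_given_noncurrent = 0.455,
      p_education = c(none = 0.34, olevel = 0.25, alevel = 0.276, degree = 0.134),
      p_activity = c(inactive = 0.31, mod_inactive = 0.28,
                     mod_active = 0.223, active = 0.187),
      alcohol_meanlog = 0.05, alcohol_sdlog = 0.95, p_alcohol_zero = 0.23,
      p_diabetes = 0.018, p_bp_medication = 0.148, p_lipid_medication = 0.008,
      p_hypertension = 0.20, p_hypercholesterolemia = 0.05,
      p_past_cancer = 0.054, p_fh_mi = 0.355, p_fh_stroke = 0.26,
      p_fh_diabetes = 0.12, p_angina = 0.045, p_heart_attack = 0.025,
      p_stroke = 0.016, bmi_mean = 26.3, bmi_sd = 3.9,
      p_missing_education = 0.008, p_missing_activity = 0.004
    ),
    hazard = list(
      cvd = list(
        shape = 1, rate = 0.0300,
        betas = c(
          age = 0.080, sex_female = -0.654,
          smoking_former = -0.462, smoking_never = -0.580,
          activity_mod_inactive = -0.151, activity_mod_active = -0.139,
          activity_active = -0.151,
          education_olevel = -0.186, education_alevel = -0.128,
          education_degree = -0.261,
          alcohol = -0.012, energy_per2000 = -0.051,
          bp_medication = 0.300, lipid_medication = -0.248,
          past_cancer = 0.174, diabetes = 0.637, hypertension = 0.207,
          hypercholesterolemia = 0.307, fh_mi = 0.174, fh_stroke = 0.068,
          fh_diabetes = 0.086
        ),
        exposure_loghr_per_quintile = 0
      ),
      death = list(
        shape = 1, rate = 0.0248,
        betas = c(
          age = 0.098, sex_female = -0.480,
          smoking_former = -0.300, smoking_never = -0.500,
          activity_mod_inactive = -0.120, activity_mod_active = -0.150,
          activity_active = -0.180,
          education_olevel = -0.080, education_alevel = -0.100,
          education_degree = -0.150,
          alcohol = -0.005, energy_per2000 = -0.030,
          bp_medication = 0.250, lipid_medication = 0,
          past_cancer = 0.500, diabetes = 0.750, hypertension = 0.100,
          hypercholesterolemia = 0.050, fh_mi = 0.050, fh_stroke = 0.030,
          fh_diabetes = 0.050, angina = 0.350, heart_attack = 0.500,
          stroke = 0.600
        ),
        exposure_loghr_per_quintile = 0
      ),
      centering = c(age = 58.6, alcohol = 1.5, energy_per2000 = 4.1),
      p_cvd_death_base = 0.32, p_cvd_death_prev_cvd = 0.30,
      p_cvd_death_age = 0.02,
      mi_fraction = 0.62, p_fatal_30d = 0.307
    ),
    censoring = list(horizon_min = 18, horizon_max = 22, dropout_rate = 0.002)
  )
  dots <- list(...)
  for (nm in names(dots)) {
    if (is.list(dots[[nm]]) && is.list(config[[nm]])) {
      config[[nm]][names(dots[[nm]])] <- dots[[nm]]
    } else {
      config[[nm]] <- dots[[nm]]
    }
  }
  validate_config(config)
  structure(config, class = "npc_config")
}

validate_config <- function(config) {
  probs <- c(
    config$diary$p_no_diary, config$diary$p_incomplete,
    unlist(config$margins[grepl("^p_", names(config$margins))])
  )
  if (any(probs < 0 | probs > 1)) abort("Config probabilities must lie in [0, 1].")
  if (config$censoring$horizon_min <= 0) abort("Censoring horizon must be positive.")
  if (config$hazard$cvd$rate < 0 || config$hazard$death$rate < 0) {
    abort("Baseline hazard rates must be non-negative.")
  }
  if (config$n_items < 20) abort("Need at least 20 catalogue items.")
  invisible(config)
}

# food archetypes: nutrient ranges per 100 g, selection behaviour
.archetypes <- function() {
  tibble(
    archetype = c("fruit_veg", "staple", "dairy_meat", "processed",
                  "sugary_bev", "diet_bev", "alcoholic_bev"),
    item_class = c("food", "food", "food", "food",
                   "beverage", "beverage", "alcoholic_beverage"),
    share = c(0.18, 0.20, 0.15, 0.27, 0.08, 0.05, 0.07),
    lh_tendency = c(-1.0, -0.25, 0.1, 0.75, 1.0, -0.8, 0),
    base_weight = c(1.15, 1.55, 1.00, 0.85, 0.40, 0.30, NA), # alcoholic: from units
    portion_g = c(90, 120, 100, 60, 220, 220, 210),
    energy_lo = c(80, 300, 250, 900, 100, 0, 120),
    energy_hi = c(350, 1600, 1400, 2400, 250, 40, 350),
    satfat_hi = c(0.3, 2, 10, 16, 0.1, 0.05, 0.05),
    sugars_lo = c(1, 0.3, 0, 2, 5, 0, 0),
    sugars_hi = c(12, 6, 6, 45, 13, 1, 8),
    sodium_hi = c(30, 450, 750, 1300, 20, 20, 10),
    fibre_hi = c(4, 4, 0.4, 3, 0.4, 0, 0),
    protein_hi = c(3, 9, 25, 12, 0.5, 0.3, 0.5),
    fvn_hi = c(100, 0, 0, 30, 50, 0, 0)
  )
}

#' Generate a synthetic food-composition catalogue
#'
#' Items are drawn from mixture archetypes (fruit/vegetables, staples,
#' dairy/meat, processed foods, sugary and diet beverages, alcoholic
#' beverages) whose per-100-g nutrient ranges put generated items on both
#' sides of the 4-point food and 1-point beverage thresholds. One anchor
#' item per key archetype is pinned to a fixed composition so that every
#' catalogue of >= 20 items is guaranteed at least one less-healthy food,
#' one less-healthy beverage, one healthy item and one alcoholic beverage.
#'
#' @param config An [study_config()] list.
#' @param seed Overrides `config$seed`.
#' @return A catalogue tibble (`item_id`, `name`, `item_class`, archetype
#'   and the seven per-100-g nutrient columns).
#' @export
generate_catalogue <- function(config = study_config(), seed = config$seed) {
  validate_config(config)
  set.seed(seed + 101L)
  arch <- .archetypes()
  n_items <- config$n_items
  counts <- pmax(1L, round(arch$share * n_items))
  while (sum(counts) != n_items) {
    i <- which.max(counts)
    counts[i] <- counts[i] + sign(n_items - sum(counts))
  }
  rows <- rep(seq_len(nrow(arch)), counts)
  a <- arch[rows, ]
  n <- nrow(a)
  ids <- sprintf("%s_%03d", a$archetype, unlist(lapply(counts, seq_len)))
  cat <- tibble(
    item_id = ids,
    name = ids,
    archetype = a$archetype,
    item_class = a$item_class,
    energy_kj = runif(n, a$energy_lo, a$energy_hi),
    satfat_g = runif(n, 0, a$satfat_hi),
    sugars_g = runif(n, a$sugars_lo, a$sugars_hi),
    sodium_mg = runif(n, 0, a$sodium_hi),
    fibre_g = runif(n, 0, a$fibre_hi),
    protein_g = runif(n, 0, a$protein_hi),
    fvn_pct = ifelse(a$archetype == "fruit_veg", 100, runif(n, 0, a$fvn_hi))
  )
  # anchors: deterministic coverage of both classification boundaries
  anchor <- function(arch_name, ...) {
    i <- which(cat$archetype == arch_name)[1]
    vals <- list(...)
    for (nm in names(vals)) cat[i, nm] <<- vals[[nm]]
  }
  anchor("processed", energy_kj = 2200, satfat_g = 8, sugars_g = 30,
         sodium_mg = 800, fibre_g = 0.5, protein_g = 5, fvn_pct = 0)
  anchor("sugary_bev", energy_kj = 180, satfat_g = 0, sugars_g = 10.5,
         sodium_mg = 5, fibre_g = 0, protein_g = 0, fvn_pct = 0)
  anchor("fruit_veg", energy_kj = 150, satfat_g = 0, sugars_g = 9,
         sodium_mg = 2, fibre_g = 2.5, protein_g = 1, fvn_pct = 100)
  round_cols <- c("energy_kj", "satfat_g", "sugars_g", "sodium_mg",
                  "fibre_g", "protein_g", "fvn_pct")
  cat[round_cols] <- lapply(cat[round_cols], function(x) round(x, 2))
  validate_catalogue(cat)
}

.truncnorm <- function(n, mean, sd, lo, hi) {
  pmin(pmax(rnorm(n, mean, sd), lo), hi)
}

.ordinal_draw <- function(n, probs, shift) {
  # latent logistic with affinity shift; cut-points from marginal probs
  cuts <- qlogis(cumsum(probs)[-length(probs)])
  u <- stats::rlogis(n) + shift
  findInterval(u, cuts) + 1L
}

#' Generate synthetic participants
#'
#' Draws a latent per-person "less-healthy affinity" and baseline covariates
#' with the configured dependence on it: higher-affinity participants are
#' older, more often male and current smokers, less educated, drink less
#' alcohol, and - the reverse-causation signature - are *less* likely to be
#' on medication or carry diagnosed clinical risk and have lower BMI.
#' Physical activity is independent of affinity. A small fraction of
#' education/activity values are set missing.
#'
#' @inheritParams generate_catalogue
#' @param n Overrides `config$n_participants`.
#' @param missingness Generate missing covariate cells (default TRUE).
#' @return A participant tibble including the latent `affinity` column
#'   (also recorded in the study truth).
#' @export
generate_participants <- function(config = study_config(), seed = config$seed,
                                  n = config$n_participants,
                                  missingness = TRUE) {
  validate_config(config)
  set.seed(seed + 202L)
  m <- config$margins; cf <- config$confounding
  a <- rnorm(n, 0, config$preference$affinity_sd)

  sex <- ifelse(runif(n) < plogis(qlogis(m$p_male) + cf$sex_male * a),
                "male", "female")
  age <- .truncnorm(n, m$age_mean + cf$age * a, m$age_sd, 40, 79)
  current <- runif(n) < plogis(qlogis(m$p_smoking_current) + cf$smoking_current * a)
  smoking <- ifelse(current, "current",
                    ifelse(runif(n) < m$p_former_given_noncurrent,
                           "former", "never"))
  education <- names(m$p_education)[
    .ordinal_draw(n, m$p_education, cf$education * a)
  ]
  activity <- names(m$p_activity)[.ordinal_draw(n, m$p_activity, 0)]
  alcohol_units <- ifelse(
    runif(n) < plogis(qlogis(m$p_alcohol_zero) - cf$alcohol_log * a), 0,
    round(rlnorm(n, m$alcohol_meanlog + cf$alcohol_log * a, m$alcohol_sdlog), 1)
  )
  flag <- function(p, beta) runif(n) < plogis(qlogis(p) + beta * a)
  bmi <- round(rnorm(n, m$bmi_mean + cf$bmi * a,
                     sqrt(m$bmi_sd^2 - cf$bmi^2)), 1)
  height <- rnorm(n, ifelse(sex == "male", 1.75, 1.62), 0.065)
  out <- tibble(
    participant_id = sprintf("P%06d", seq_len(n)),
    affinity = a,
    age = round(age, 1),
    sex = sex,
    education = education,
    smoking = smoking,
    activity = activity,
    alcohol_units = alcohol_units,
    bmi = bmi,
    weight_kg = round(pmax(bmi * height^2, 35), 1),
    bp_medication = flag(m$p_bp_medication, cf$bp_medication),
    lipid_medication = flag(m$p_lipid_medication, cf$lipid_medication),
    diabetes = flag(m$p_diabetes, cf$diabetes),
    hypertension = flag(m$p_hypertension, cf$hypertension),
    hypercholesterolemia = flag(m$p_hypercholesterolemia, cf$hypercholesterolemia),
    past_cancer = flag(m$p_past_cancer, cf$past_cancer),
    fh_mi = flag(m$p_fh_mi, cf$fh_mi),
    fh_stroke = flag(m$p_fh_stroke, cf$fh_stroke),
    fh_diabetes = flag(m$p_fh_diabetes, cf$fh_diabetes),
    angina = flag(m$p_angina, cf$prevalent_cvd),
    heart_attack = flag(m$p_heart_attack, cf$prevalent_cvd),
    stroke = flag(m$p_stroke, cf$prevalent_cvd)
  )
  if (missingness) {
    out$education[runif(n) < m$p_missing_education] <- NA
    out$activity[runif(n) < m$p_missing_activity] <- NA
  }
  out
}

#' Generate 7-day diet diaries
#'
#' Each diary-keeping participant contributes up to 7 days of item records.
#' Item selection is a per-person multinomial over archetypes whose log
#' weights are tilted by `lh_tilt * affinity * lh_tendency`, so
#' high-affinity participants pick less-healthy archetypes more often;
#' alcoholic-beverage selection weight is proportional to the participant's
#' reported alcohol units (abstainers never pick them). Portion grams are
#' log-normal around archetype portions and then rescaled so each diary
#' day's energy matches the participant's target intake (which rises with
#' affinity, emulating the observed energy gradient).
#'
#' @inheritParams generate_catalogue
#' @param participants From [generate_participants()].
#' @param catalogue From [generate_catalogue()].
#' @return A diary tibble: `participant_id`, `day_index`, `item_id`, `grams`.
#' @export
generate_diaries <- function(participants, catalogue, config = study_config(),
                             seed = config$seed) {
  validate_config(config)
  set.seed(seed + 303L)
  arch <- .archetypes()
  n <- nrow(participants)
  dcfg <- config$diary; e <- config$energy

  has_diary <- runif(n) >= dcfg$p_no_diary
  n_days <- ifelse(runif(n) < dcfg$p_incomplete,
                   sample(1:6, n, replace = TRUE), 7L)
  energy_target <- pmax(
    e$base + e$male * (participants$sex == "male") +
      e$per_affinity * participants$affinity + rnorm(n, 0, e$sd),
    e$min
  )

  # per-person archetype weights (alcohol scaled by reported units)
  w <- matrix(rep(arch$base_weight, each = n), nrow = n)
  tilt <- config$preference$lh_tilt
  for (j in seq_len(nrow(arch))) {
    w[, j] <- w[, j] * exp(tilt * participants$affinity * arch$lh_tendency[j])
  }
  w[, arch$archetype == "alcoholic_bev"] <- 0.55 * participants$alcohol_units / 1.5
  w <- w / rowSums(w)

  keep <- which(has_diary)
  n_recs <- rpois(length(keep), dcfg$items_per_day * n_days[keep] - n_days[keep]) +
    n_days[keep]
  pid <- rep(keep, n_recs)

  # vectorised archetype draw via inverse CDF on per-person cumulative probs
  cumw <- t(apply(w, 1, cumsum))
  u <- runif(length(pid))
  arch_idx <- rowSums(u > cumw[pid, , drop = FALSE]) + 1L

  # uniform item within archetype
  items_by_arch <- split(seq_len(nrow(catalogue)),
                         match(catalogue$archetype, arch$archetype))
  item_row <- integer(length(pid))
  for (j in seq_len(nrow(arch))) {
    sel <- arch_idx == j
    if (any(sel)) {
      pool <- items_by_arch[[as.character(j)]]
      item_row[sel] <- pool[sample.int(length(pool), sum(sel), replace = TRUE)]
    }
  }

  recs <- tibble(
    participant_id = participants$participant_id[pid],
    day_index = (stats::ave(pid, pid, FUN = seq_along) - 1L) %% n_days[pid] + 1L,
    item_id = catalogue$item_id[item_row],
    grams = rlnorm(length(pid),
                   log(arch$portion_g[arch_idx]), dcfg$portion_sdlog),
    energy_kj100 = catalogue$energy_kj[item_row],
    target = energy_target[pid]
  )
  # rescale each day to its target energy (target jittered per day)
  recs <- recs %>%
    group_by(.data$participant_id, .data$day_index) %>%
    mutate(
      day_energy = sum(.data$grams * .data$energy_kj100 / 100),
      grams = .data$grams * .data$target[1] *
        exp(rnorm(1, 0, dcfg$day_energy_cv)) / pmax(.data$day_energy, 1)
    ) %>%
    ungroup()
  select(recs, "participant_id", "day_index", "item_id", "grams") %>%
    mutate(grams = round(.data$grams, 2))
}

.hazard_lp <- function(data, betas, centering, exposure_loghr, quintile) {
  lp <- numeric(nrow(data))
  lp <- lp + betas[["age"]] * (data$age - centering[["age"]])
  lp <- lp + betas[["sex_female"]] * (data$sex == "female")
  lp <- lp + betas[["smoking_former"]] * (data$smoking == "former") +
    betas[["smoking_never"]] * (data$smoking == "never")
  lp <- lp + betas[["activity_mod_inactive"]] * (data$activity == "mod_inactive") +
    betas[["activity_mod_active"]] * (data$activity == "mod_active") +
    betas[["activity_active"]] * (data$activity == "active")
  lp <- lp + betas[["education_olevel"]] * (data$education == "olevel") +
    betas[["education_alevel"]] * (data$education == "alevel") +
    betas[["education_degree"]] * (data$education == "degree")
  lp <- lp + betas[["alcohol"]] * (data$alcohol_units - centering[["alcohol"]])
  lp <- lp + betas[["energy_per2000"]] *
    (data$energy_total / 2000 - centering[["energy_per2000"]])
  for (nm in c("bp_medication", "lipid_medication", "past_cancer", "diabetes",
               "hypertension", "hypercholesterolemia", "fh_mi", "fh_stroke",
               "fh_diabetes", "angina", "heart_attack", "stroke")) {
    if (nm %in% names(betas)) lp <- lp + betas[[nm]] * data[[nm]]
  }
  lp + exposure_loghr * (quintile - 3)
}

#' Simulate survival outcomes from the planted hazard model
#'
#' Event times for incident CVD and all-cause death are drawn from Weibull
#' proportional-hazards models (`H(t) = rate * t^shape * exp(lp)`) whose
#' linear predictors use the planted log-hazard-ratios in
#' `config$hazard`; the exposure enters as a per-quintile log-HR (default
#' 0). Censoring is administrative (uniform horizon emulating staggered
#' recruitment with a fixed linkage end) plus a small exponential dropout.
#' CVD death is a flagged subset of deaths; incident CVD events are split
#' into myocardial infarction and stroke, and a fatal-within-30-days flag
#' is carried as metadata.
#'
#' @inheritParams generate_diaries
#' @param exposures From [build_exposure()] (for `energy_total` and the
#'   exposure quintile the planted effect acts on). Participants without
#'   exposure rows get outcomes from covariates alone with the energy term
#'   at its centering value.
#' @return Outcome tibble: per participant, `cvd_event`/`cvd_time`,
#'   `mi_event`/`mi_time`, `stroke_event`/`stroke_time`,
#'   `death_event`/`death_time`, `cvd_death_event`, `fatal_30d`.
#' @export
simulate_outcomes <- function(participants, exposures, config = study_config(),
                              seed = config$seed) {
  validate_config(config)
  set.seed(seed + 404L)
  hz <- config$hazard; cen <- config$censoring
  n <- nrow(participants)

  data <- left_join(
    participants,
    select(exposures, "participant_id", "energy_total", "prop_lh_energy"),
    by = "participant_id"
  )
  data$energy_total[is.na(data$energy_total)] <-
    hz$centering[["energy_per2000"]] * 2000
  quintile <- rep(3, n)
  ok <- !is.na(data$prop_lh_energy)
  if (sum(ok) >= 5) quintile[ok] <- assign_quintiles(data$prop_lh_energy[ok])

  draw_time <- function(spec) {
    lp <- .hazard_lp(data, spec$betas, hz$centering,
                     spec$exposure_loghr_per_quintile, quintile)
    u <- rexp(n)
    (u / (spec$rate * exp(lp)))^(1 / spec$shape)
  }
  t_cvd <- draw_time(hz$cvd)
  t_death <- draw_time(hz$death)
  t_drop <- if (cen$dropout_rate > 0) rexp(n, cen$dropout_rate) else rep(Inf, n)
  horizon <- runif(n, cen$horizon_min, cen$horizon_max)

  death_time <- pmin(t_death, t_drop, horizon)
  death_event <- as.integer(t_death <= pmin(t_drop, horizon))
  cvd_time <- pmin(t_cvd, death_time)
  cvd_event <- as.integer(t_cvd <= death_time)

  p_cvd_death <- plogis(
    qlogis(hz$p_cvd_death_base) +
      hz$p_cvd_death_prev_cvd * (data$angina | data$heart_attack | data$stroke) +
      hz$p_cvd_death_age * (data$age - hz$centering[["age"]])
  )
  cvd_death_event <- as.integer(death_event == 1L & runif(n) < p_cvd_death)

  is_mi <- runif(n) < hz$mi_fraction
  fatal <- cvd_event == 1L & runif(n) < hz$p_fatal_30d

  tibble(
    participant_id = participants$participant_id,
    cvd_event = cvd_event,
    cvd_time = round(cvd_time, 4),
    mi_event = as.integer(cvd_event == 1L & is_mi),
    mi_time = round(cvd_time, 4),
    stroke_event = as.integer(cvd_event == 1L & !is_mi),
    stroke_time = round(cvd_time, 4),
    death_event = death_event,
    death_time = round(death_time, 4),
    cvd_death_event = cvd_death_event,
    fatal_30d = as.integer(fatal)
  )
}

#' Generate a complete synthetic study
#'
#' Composes the catalogue, participant, diary and outcome generators, scores
#' the catalogue and builds exposures (needed by the outcome model's energy
#' term), and optionally writes everything to a directory of CSV files plus
#' a `truth.json` recording the planted parameter values and a `config.yaml`
#' echo. Regeneration from the same (config, seed) is byte-identical.
#'
#' @inheritParams generate_catalogue
#' @param dir Output directory (created if needed); `NULL` skips writing.
#' @return Invisibly, a list of class `npc_study`: `catalogue`, `scored`,
#'   `participants`, `diaries`, `exposure`, `outcomes`, `truth`, `config`.
#' @export
generate_study <- function(config = study_config(), dir = NULL,
                           seed = config$seed) {
  validate_config(config)
  catalogue <- generate_catalogue(config, seed)
  participants <- generate_participants(config, seed)
  diaries <- generate_diaries(participants, catalogue, config, seed)
  scored <- score_catalogue(catalogue, quiet = TRUE)
  exposure <- build_exposure(diaries, scored, catalogue)
  outcomes <- simulate_outcomes(participants, exposure, config, seed)

  truth <- list(
    schema_version = "1.0",
    seed = seed,
    exposure_loghr_per_quintile = c(
      cvd = config$hazard$cvd$exposure_loghr_per_quintile,
      death = config$hazard$death$exposure_loghr_per_quintile
    ),
    cvd_betas = as.list(config$hazard$cvd$betas),
    death_betas = as.list(config$hazard$death$betas),
    baseline = list(
      cvd = config$hazard$cvd[c("shape", "rate")],
      death = config$hazard$death[c("shape", "rate")]
    ),
    confounding = config$confounding
  )

  study <- structure(
    list(catalogue = catalogue, scored = scored, participants = participants,
         diaries = diaries, exposure = exposure, outcomes = outcomes,
         truth = truth, config = config),
    class = "npc_study"
  )

  if (!is.null(dir)) {
    if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
    readr::write_csv(catalogue, file.path(dir, "catalogue.csv"))
    readr::write_csv(participants, file.path(dir, "participants.csv"))
    readr::write_csv(diaries, file.path(dir, "diaries.csv"))
    readr::write_csv(outcomes, file.path(dir, "outcomes.csv"))
    jsonlite::write_json(truth, file.path(dir, "truth.json"),
                         auto_unbox = TRUE, digits = NA, pretty = TRUE)
    yaml::write_yaml(unclass(config), file.path(dir, "config.yaml"))
  }
  invisible(study)
}

#' Fast cohort-level simulator for calibration studies
#'
#' Skips the catalogue/diary machinery: the proportion-of-energy exposure is
#' drawn directly from the latent affinity plus noise (matching the
#' affinity-exposure correlation the diary path induces), energy intake from
#' the configured energy model, and outcomes from the planted hazards. The
#' result is an analysis-ready cohort (complete covariates, quintiles
#' assigned) for repeated-simulation studies of estimator calibration -
#' type-I error, power, coverage - where regenerating full diaries every
#' replicate would add nothing but runtime.
#'
#' @inheritParams generate_participants
#' @return A cohort tibble ready for [fit_cox_model()].
#' @export
simulate_cohort <- function(n, config = study_config(), seed = config$seed) {
  config$n_participants <- n
  participants <- generate_participants(config, seed, n = n, missingness = FALSE)
  set.seed(seed + 505L)
  pref <- config$preference; e <- config$energy
  s <- participants$affinity + rnorm(n, 0, pref$exposure_noise_sd)
  s_sd <- sqrt(pref$affinity_sd^2 + pref$exposure_noise_sd^2)
  prop <- pmin(pmax(pref$prop_lh_mean + pref$prop_lh_sd * s / s_sd, 0.02), 0.98)
  energy_total <- pmax(
    e$base + e$male * (participants$sex == "male") +
      e$per_affinity * participants$affinity + rnorm(n, 0, e$sd),
    e$min
  )
  exposure <- tibble(
    participant_id = participants$participant_id,
    prop_lh_energy = prop,
    energy_total = energy_total
  )
  outcomes <- simulate_outcomes(participants, exposure, config, seed)
  cohort <- participants %>%
    left_join(exposure, by = "participant_id") %>%
    left_join(outcomes, by = "participant_id")
  cohort$quintile_energy <- as.integer(assign_quintiles(cohort$prop_lh_energy,
                                                        cohort$participant_id))
  cohort
}
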