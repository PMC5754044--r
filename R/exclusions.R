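#' Schofield equation coefficients
#'
#' Sex- and age-band-specific linear coefficients predicting basal metabolic
#' rate (MJ/day) from body weight (kg). Held as configuration so they can be
#' checked against the source tables without a code change. Bands: 18-29,
#' 30-59, 60+ years. The 18-29 band is unreachable for a 40-79-year cohort
#' but kept for completeness.
#'
#' @return A tibble with columns `sex`, `age_min`, `age_max`, `slope`,
#'   `intercept`.
#' @export
schofield_coefficients <- function() {
  tibble(
    sex = rep(c("male", "female"), each = 3),
    age_min = rep(c(18, 30, 60), 2),
    age_max = rep(c(29, 59, Inf), 2),
    slope = c(0.063, 0.048, 0.049, 0.062, 0.034, 0.038),
    intercept = c(2.896, 3.653, 2.459, 2.036, 3.538, 2.755)
  )
}

#' Basal metabolic rate from the Schofield equations
#'
#' @param sex `"male"`/`"female"` (vectorised).
#' @param age Age in years (>= 18).
#' @param weight_kg Body weight in kg (> 0).
#' @param coefficients Coefficient table, see [schofield_coefficients()].
#' @return BMR in MJ/day.
#' @examples
#' schofield_bmr("male", 45, 75)    # 0.048*75 + 3.653 = 7.253
#' schofield_bmr("female", 65, 60)  # 0.038*60 + 2.755 = 5.035
#' @export
schofield_bmr <- function(sex, age, weight_kg,
                          coefficients = schofield_coefficients()) {
  sex <- as.character(sex)
  if (anyNA(sex) || !all(sex %in% c("male", "female"))) {
    abort("`sex` must be \"male\" or \"female\".")
  }
  if (anyNA(age) || any(age < 18)) {
    abort("`age` must be >= 18 years (cohort is 40-79).")
  }
  if (anyNA(weight_kg) || any(weight_kg <= 0)) {
    abort("`weight_kg` must be positive.")
  }
  n <- max(length(sex), length(age), length(weight_kg))
  sex <- rep_len(sex, n); age <- rep_len(age, n); weight_kg <- rep_len(weight_kg, n)
  band <- findInterval(age, c(18, 30, 60))
  key <- paste(sex, band)
  ck <- paste(coefficients$sex, findInterval(coefficients$age_min, c(18, 30, 60)))
  idx <- match(key, ck)
  coefficients$slope[idx] * weight_kg + coefficients$intercept[idx]
}

# nearest-rank trim bounds: keep order statistics (floor(nq)+1) .. (n-floor(nq))
.trim_bounds <- function(ratio, trim_fraction) {
  n <- length(ratio)
  k <- floor(n * trim_fraction)
  v <- sort(ratio)
  c(lower = v[k + 1L], upper = v[n - k])
}

#' Trim energy-misreporters by the energy:BMR ratio
#'
#' Excludes participants in the top or bottom `trim_fraction` of the
#' distribution of reported energy intake to Schofield-predicted basal
#' metabolic rate. The percentile convention is nearest-rank: values
#' strictly below the `(floor(n*q)+1)`-th or strictly above the
#' `(n-floor(n*q))`-th order statistic are removed, so with distinct values
#' each tail loses between `floor(n*q)` and `ceiling(n*q)` participants and
#' an all-tied sample loses none.
#'
#' @param data Data frame containing the ratio column.
#' @param ratio Column with the energy:BMR ratio (data-masked).
#' @param trim_fraction Fraction trimmed per tail (default 0.005, i.e. 0.5%).
#' @return `data` with trimmed rows removed; the ratio bounds used are kept
#'   in the `"trim_bounds"` attribute.
#' @export
trim_energy_bmr <- function(data, ratio, trim_fraction = 0.005) {
  data <- as_tibble(data)
  r <- dplyr::pull(data, {{ ratio }})
  if (anyNA(r) || any(!is.finite(r)) || any(r <= 0)) {
    abort("Energy:BMR ratios must be finite and positive.")
  }
  if (trim_fraction == 0) {
    return(data)
  }
  if (nrow(data) < 200) {
    warn("Fewer than 200 participants; energy:BMR trim skipped.")
    return(data)
  }
  b <- .trim_bounds(r, trim_fraction)
  out <- data[r >= b[["lower"]] & r <= b[["upper"]], , drop = FALSE]
  attr(out, "trim_bounds") <- b
  out
}

# covariate sets used by the missing-covariate exclusion and the Cox models
.model1_covariates <- c(
  "age", "sex", "education", "smoking", "activity", "alcohol_units",
  "energy_total"
)
.model2_extra <- c(
  "bp_medication", "lipid_medication", "diabetes", "hypertension",
  "hypercholesterolemia", "past_cancer", "fh_mi", "fh_stroke", "fh_diabetes"
)
.model2prime_extra <- c("past_cancer", "fh_mi", "fh_stroke", "fh_diabetes")
.prevalent_cvd_flags <- c("angina", "heart_attack", "stroke")

#' Apply the study exclusion cascade
#'
#' Reproduces the cohort-construction rules, in order: (1) drop participants
#' with no completed diary day (no exposure row); (2) trim the top and
#' bottom `trim_fraction` of the energy:BMR ratio (Schofield equations);
#' (3) for the CVD analysis only, drop prevalent cardiovascular disease
#' (self-reported angina, heart attack or stroke) - mortality analyses
#' retain these participants; (4) drop missing covariates (no imputation).
#' Optional sensitivity exclusions follow: baseline comorbidities
#' (`"metabolic"` = diabetes or past cancer; `"cvd_risk"` = hypertension,
#' hypercholesterolemia or blood-pressure/lipid medication; `"all"` = both),
#' family history of CVD (heart attack or stroke), family history of
#' diabetes, and a landmark excluding participants whose outcome event
#' occurred within the first `landmark_years` of follow-up.
#'
#' Quintile groups are assigned on the post-exclusion analysis set.
#'
#' @param participants Participant covariate table (see
#'   [generate_participants()] for the expected columns).
#' @param exposure Exposure table from [build_exposure()]; participants
#'   absent from it are treated as having completed no diary day.
#' @param outcomes Outcome table (event/time columns per outcome).
#' @param analysis `"cvd"` or `"mortality"`.
#' @param trim_fraction Energy:BMR trim per tail (default 0.005).
#' @param drop_comorbid `"none"`, `"metabolic"`, `"cvd_risk"` or `"all"`.
#' @param drop_fh_cvd,drop_fh_diabetes Drop family-history participants.
#' @param landmark_years If set, exclude participants with the analysis
#'   outcome event inside this many years of follow-up.
#' @return The analysis cohort: participants joined to exposures and
#'   outcomes, quintile columns added, with the per-step exclusion log in
#'   the `"exclusion_log"` attribute (retrieve with [exclusion_log()]).
#' @export
apply_exclusions <- function(participants, exposure, outcomes,
                             analysis = c("cvd", "mortality"),
                             trim_fraction = 0.005,
                             drop_comorbid = c("none", "metabolic", "cvd_risk", "all"),
                             drop_fh_cvd = FALSE,
                             drop_fh_diabetes = FALSE,
                             landmark_years = NULL) {
  analysis <- arg_match(analysis)
  drop_comorbid <- arg_match(drop_comorbid)
  participants <- as_tibble(participants)
  exposure <- as_tibble(exposure)
  outcomes <- as_tibble(outcomes)

  log <- list()
  note <- function(step, before, after) {
    log[[length(log) + 1L]] <<- tibble(
      step = step, n_before = nrow(before),
      n_excluded = nrow(before) - nrow(after), n_after = nrow(after)
    )
  }

  cohort <- left_join(participants, exposure, by = "participant_id")

  kept <- filter(cohort, !is.na(.data$n_diary_days) & .data$n_diary_days >= 1)
  note("diary: fewer than 1 completed day", cohort, kept)
  cohort <- kept

  cohort <- mutate(
    cohort,
    bmr_mj = schofield_bmr(.data$sex, .data$age, .data$weight_kg),
    energy_bmr_ratio = (.data$energy_total / 1000) / .data$bmr_mj
  )
  kept <- trim_energy_bmr(cohort, .data$energy_bmr_ratio, trim_fraction)
  note("energy:BMR ratio trim", cohort, kept)
  cohort <- kept

  if (analysis == "cvd") {
    kept <- filter(cohort, !(.data$angina | .data$heart_attack | .data$stroke))
    note("prevalent CVD (angina, heart attack, stroke)", cohort, kept)
    cohort <- kept
  }

  covars <- c(.model1_covariates, .model2_extra)
  covars <- intersect(
    if (analysis == "mortality") c(covars, .prevalent_cvd_flags) else covars,
    names(cohort)
  )
  # exposure measures are covariates too: a diary of only alcoholic
  # beverages leaves the proportion-of-energy exposure undefined
  covars <- c(covars, intersect(
    c("prop_lh_energy", "prop_lh_weight", "mean_weighted_score", "fv_weight"),
    names(cohort)
  ))
  kept <- cohort[complete.cases(cohort[, covars, drop = FALSE]), , drop = FALSE]
  note("missing covariates", cohort, kept)
  cohort <- kept

  if (drop_comorbid %in% c("metabolic", "all")) {
    kept <- filter(cohort, !(.data$diabetes | .data$past_cancer))
    note("comorbidity: diabetes or past cancer", cohort, kept)
    cohort <- kept
  }
  if (drop_comorbid %in% c("cvd_risk", "all")) {
    kept <- filter(cohort, !(.data$hypertension | .data$hypercholesterolemia |
                               .data$bp_medication | .data$lipid_medication))
    note("comorbidity: hypertension, hyperlipidaemia or medication", cohort, kept)
    cohort <- kept
  }
  if (drop_fh_cvd) {
    kept <- filter(cohort, !(.data$fh_mi | .data$fh_stroke))
    note("family history of CVD", cohort, kept)
    cohort <- kept
  }
  if (drop_fh_diabetes) {
    kept <- filter(cohort, !.data$fh_diabetes)
    note("family history of diabetes", cohort, kept)
    cohort <- kept
  }

  cohort <- left_join(cohort, outcomes, by = "participant_id")

  if (!is.null(landmark_years)) {
    ev <- if (analysis == "cvd") "cvd_event" else "death_event"
    tm <- if (analysis == "cvd") "cvd_time" else "death_time"
    kept <- filter(cohort, !(.data[[ev]] == 1 & .data[[tm]] <= landmark_years))
    note(paste0("event within first ", landmark_years, " years"), cohort, kept)
    cohort <- kept
  }

  cohort <- add_quintiles(cohort)
  attr(cohort, "exclusion_log") <- bind_rows(log)
  cohort
}

#' Retrieve the exclusion log of an analysis cohort
#'
#' @param cohort A cohort returned by [apply_exclusions()].
#' @return A tibble with `step`, `n_before`, `n_excluded`, `n_after`; each
#'   row chains into the next (Fig-1-style flow).
#' @export
exclusion_log <- function(cohort) {
  log <- attr(cohort, "exclusion_log")
  if (is.null(log)) {
    abort("No exclusion log attached; was this cohort built by apply_exclusions()?")
  }
  log
}
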