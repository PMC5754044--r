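.outcome_columns <- list(
  incident_cvd = c(time = "cvd_time", event = "cvd_event"),
  cvd_mortality = c(time = "death_time", event = "cvd_death_event"),
  all_cause_mortality = c(time = "death_time", event = "death_event"),
  incident_mi = c(time = "mi_time", event = "mi_event"),
  incident_stroke = c(time = "stroke_time", event = "stroke_event")
)
.mortality_outcomes <- c("cvd_mortality", "all_cause_mortality")

.exposure_choices <- c(
  "quintile_energy", "quintile_weight", "quintile_score", "quintile_fv",
  "substitution"
)

#' Covariate sets for the adjusted models
#'
#' Model 1: sociodemographic and behavioural risk factors (age, sex,
#' education, smoking, physical activity, alcohol, total dietary energy).
#' Model 2: Model 1 plus self-reported clinical risk factors at baseline
#' (blood-pressure and lipid medication, diabetes, hypertension,
#' hypercholesterolemia, past cancer, family history of heart attack,
#' stroke and diabetes). Model 2' drops the potential mediators, keeping
#' only past cancer and the family-history flags. Mortality outcomes add
#' the prevalent-CVD flags (angina, heart attack, stroke).
#'
#' @param covariate_set `"unadjusted"`, `"model1"`, `"model2"` or
#'   `"model2prime"`.
#' @param outcome Outcome name; mortality outcomes append prevalent CVD.
#' @param adjust_total_energy Keep total dietary energy in the set.
#' @param adjust_bmi Additionally adjust for baseline BMI.
#' @return Character vector of cohort column names.
#' @export
model_covariates <- function(covariate_set = c("unadjusted", "model1", "model2",
                                               "model2prime"),
                             outcome = "incident_cvd",
                             adjust_total_energy = TRUE,
                             adjust_bmi = FALSE) {
  covariate_set <- arg_match(covariate_set)
  covs <- switch(
    covariate_set,
    unadjusted = character(),
    model1 = .model1_covariates,
    model2 = c(.model1_covariates, .model2_extra),
    model2prime = c(.model1_covariates, .model2prime_extra)
  )
  if (!adjust_total_energy) covs <- setdiff(covs, "energy_total")
  if (adjust_bmi && length(covs)) covs <- c(covs, "bmi")
  if (outcome %in% .mortality_outcomes && length(covs)) {
    covs <- c(covs, .prevalent_cvd_flags)
  }
  covs
}

.factor_levels <- list(
  sex = c("male", "female"),
  smoking = c("current", "former", "never"),
  activity = c("inactive", "mod_inactive", "mod_active", "active"),
  education = c("none", "olevel", "alevel", "degree")
)

# release categorical covariates and scale energy per 2,000 kJ/day
.prepare_covariates <- function(data, covs) {
  for (nm in intersect(names(.factor_levels), covs)) {
    data[[nm]] <- factor(as.character(data[[nm]]), levels = .factor_levels[[nm]])
    if (anyNA(data[[nm]])) {
      abort(paste0("Covariate `", nm, "` has values outside its declared levels."))
    }
  }
  if ("energy_total" %in% covs) {
    data$energy_per2000 <- data$energy_total / 2000
  }
  data
}

.term_for <- function(cov) if (cov == "energy_total") "energy_per2000" else cov

#' Encode the design for a Cox model specification
#'
#' Builds the model frame, formula and expanded design matrix for one model
#' specification: the quintile exposure as four indicator contrasts against
#' quintile group 1, categorical covariates with the reference levels used
#' in the source analysis (smoking ref = current, activity ref = inactive,
#' education ref = no qualifications, sex ref = male), total energy scaled
#' per 2,000 kJ/day, age continuous in years.
#'
#' @param cohort Analysis cohort from [apply_exclusions()].
#' @param outcome One of `incident_cvd`, `cvd_mortality`,
#'   `all_cause_mortality`, `incident_mi`, `incident_stroke`.
#' @param exposure One of `quintile_energy`, `quintile_weight`,
#'   `quintile_score`, `quintile_fv`; `exposure_as` controls whether the
#'   quintile enters as indicator contrasts (`"factor"`) or as a single
#'   continuous 1-5 covariate (`"numeric"`, the trend parameterisation).
#' @param covariate_set See [model_covariates()].
#' @param exposure_as `"factor"` or `"numeric"`.
#' @param adjust_total_energy,adjust_bmi Passed to [model_covariates()].
#' @return A list: `data` (model frame), `formula`, `x` (design matrix,
#'   no intercept column), `time`, `event`.
#' @export
encode_design <- function(cohort, outcome = "incident_cvd",
                          exposure = "quintile_energy",
                          covariate_set = "model2",
                          exposure_as = c("factor", "numeric"),
                          adjust_total_energy = TRUE, adjust_bmi = FALSE) {
  exposure_as <- arg_match(exposure_as)
  if (!outcome %in% names(.outcome_columns)) {
    abort(paste0("Unknown outcome `", outcome, "`."))
  }
  if (!exposure %in% setdiff(.exposure_choices, "substitution")) {
    abort(paste0("Unknown quintile exposure `", exposure, "`."))
  }
  cohort <- as_tibble(cohort)
  covs <- model_covariates(covariate_set, outcome, adjust_total_energy, adjust_bmi)
  oc <- .outcome_columns[[outcome]]
  needed <- c(exposure, covs, oc)
  missing <- setdiff(needed, names(cohort))
  if (length(missing)) {
    abort(paste0("Cohort lacks columns: ", paste(missing, collapse = ", ")))
  }
  for (nm in c(exposure, covs)) {
    if (anyNA(cohort[[nm]])) {
      bad <- cohort$participant_id[which(is.na(cohort[[nm]]))[1]]
      abort(paste0(
        "Missing value in `", nm, "` (e.g. participant `", bad,
        "`); exclusions must remove missing covariates first."
      ))
    }
  }

  data <- .prepare_covariates(cohort, covs)
  if (exposure_as == "factor") {
    if (length(unique(data[[exposure]])) < 2L) {
      abort(paste0("Exposure `", exposure, "` has no variation; design is degenerate."))
    }
    data$.exposure <- factor(paste0("Q", data[[exposure]]),
                             levels = paste0("Q", sort(unique(data[[exposure]]))))
  } else {
    data$.exposure <- as.numeric(data[[exposure]])
    if (length(unique(data$.exposure)) < 2L) {
      abort("Quintile labels are constant; trend is undefined.")
    }
  }

  terms <- c(".exposure", vapply(covs, .term_for, character(1)))
  fml <- as.formula(paste(
    "survival::Surv(", oc[["time"]], ",", oc[["event"]], ") ~",
    paste(terms, collapse = " + ")
  ))
  x <- model.matrix(as.formula(paste("~", paste(terms, collapse = " + "))), data)
  list(
    data = data, formula = fml,
    x = x[, -1, drop = FALSE],
    time = data[[oc[["time"]]]], event = data[[oc[["event"]]]]
  )
}

# shared coxph runner with convergence / separation diagnostics
.run_coxph <- function(formula, data, ties = "efron") {
  warnings <- character()
  fit <- withCallingHandlers(
    # x/y kept so Schoenfeld diagnostics never need the calling frame
    survival::coxph(formula, data = data, ties = ties, model = FALSE,
                    x = TRUE, y = TRUE),
    warning = function(w) {
      warnings <<- c(warnings, conditionMessage(w))
      invokeRestart("muffleWarning")
    }
  )
  separation <- any(grepl("infinite|did not converge", warnings)) ||
    any(abs(coef(fit)) > 10, na.rm = TRUE)
  ran_out <- any(grepl("Ran out of iterations", warnings))
  if (ran_out && !separation) {
    abort(paste0(
      "Cox model failed to converge after ", fit$iter, " iterations: ",
      paste(warnings, collapse = "; ")
    ))
  }
  if (separation) {
    warn("Possible complete separation: a coefficient is diverging; estimates flagged.")
  }
  list(fit = fit, separation = separation, warnings = warnings)
}

.term_table <- function(fit) {
  s <- summary(fit)
  ci <- s$conf.int
  tibble(
    term = rownames(s$coefficients),
    estimate = unname(s$coefficients[, "coef"]),
    std.error = unname(s$coefficients[, "se(coef)"]),
    statistic = unname(s$coefficients[, "z"]),
    p.value = unname(s$coefficients[, "Pr(>|z|)"]),
    hr = unname(ci[, "exp(coef)"]),
    conf.low = unname(ci[, "lower .95"]),
    conf.high = unname(ci[, "upper .95"])
  )
}

.new_npc_fit <- function(run, spec, design, trend_p = NA_real_) {
  fit <- run$fit
  terms <- .term_table(fit)
  quintile_hr <- NULL
  if (identical(spec$exposure_as, "factor") && !identical(spec$exposure, "substitution")) {
    qt <- filter(terms, grepl("^\\.exposureQ", .data$term))
    quintile_hr <- bind_rows(
      tibble(quintile = 1L, hr = 1, conf.low = 1, conf.high = 1),
      tibble(
        quintile = as.integer(sub("^\\.exposureQ", "", qt$term)),
        hr = qt$hr, conf.low = qt$conf.low, conf.high = qt$conf.high
      )
    )
  }
  structure(
    list(
      fit = fit,
      spec = spec,
      terms = mutate(terms, term = sub("^\\.exposure", spec$exposure, .data$term)),
      quintile_hr = quintile_hr,
      trend_p = trend_p,
      n = fit$n, n_events = fit$nevent,
      separation = run$separation,
      ph = NULL
    ),
    class = "npc_fit"
  )
}

#' Fit a Cox model on a prepared design
#'
#' Low-level fitting on an already-encoded design (numeric matrix or data
#' frame of covariates), with Efron handling of tied event times and Wald
#' 95% confidence intervals. Non-convergence raises an error carrying the
#' iteration messages; likely complete separation is flagged on the result
#' (`$separation`) with a warning.
#'
#' @param design Numeric matrix or data frame of covariate columns.
#' @param time Positive follow-up times.
#' @param event Event indicator (0/1).
#' @param ties Tie-handling method (default `"efron"`).
#' @return An `npc_fit` object; see [tidy.npc_fit()].
#' @export
fit_cox <- function(design, time, event, ties = "efron") {
  design <- as.data.frame(design)
  if (any(time <= 0)) abort("`time` must be positive.")
  if (!all(event %in% c(0, 1))) abort("`event` must be 0/1.")
  data <- cbind(design, .time = time, .event = event)
  fml <- as.formula(paste(
    "survival::Surv(.time, .event) ~",
    paste(names(design), collapse = " + ")
  ))
  run <- .run_coxph(fml, data, ties)
  spec <- list(outcome = "custom", exposure = "custom", covariate_set = "custom",
               exposure_as = "none")
  .new_npc_fit(run, spec, design)
}

#' Fit a quintile-exposure Cox proportional-hazards model
#'
#' The workhorse of the analysis: hazard of the chosen outcome on quintile
#' groups of a dietary exposure (indicator contrasts against quintile group
#' 1) plus the chosen covariate set, with Efron ties and Wald 95% CIs. The
#' linear-trend test (quintile index 1-5 as a single continuous covariate,
#' Wald p for its coefficient) is fitted alongside and stored as `trend_p`.
#'
#' @inheritParams encode_design
#' @param ties Tie-handling method passed to [survival::coxph()].
#' @param trend Also fit the continuous-quintile trend model (default TRUE).
#' @return An `npc_fit`: list with the underlying `coxph` fit, `terms`
#'   (tidy coefficient table, exposure terms renamed), `quintile_hr`
#'   (reference quintile HR fixed at 1), `trend_p`, `n`, `n_events` and a
#'   `separation` flag. Methods: [tidy.npc_fit()], [glance.npc_fit()],
#'   [autoplot.npc_fit()], [check_ph()].
#' @export
fit_cox_model <- function(cohort, outcome = "incident_cvd",
                          exposure = "quintile_energy",
                          covariate_set = "model2",
                          adjust_total_energy = TRUE, adjust_bmi = FALSE,
                          ties = "efron", trend = TRUE) {
  des <- encode_design(cohort, outcome, exposure, covariate_set,
                       exposure_as = "factor",
                       adjust_total_energy = adjust_total_energy,
                       adjust_bmi = adjust_bmi)
  run <- .run_coxph(des$formula, des$data, ties)
  trend_p <- if (trend) {
    trend_test(cohort, outcome, exposure, covariate_set,
               adjust_total_energy = adjust_total_energy,
               adjust_bmi = adjust_bmi, ties = ties)
  } else {
    NA_real_
  }
  spec <- list(outcome = outcome, exposure = exposure,
               covariate_set = covariate_set, exposure_as = "factor",
               adjust_total_energy = adjust_total_energy, adjust_bmi = adjust_bmi)
  .new_npc_fit(run, spec, des, trend_p = trend_p)
}

#' Linear trend test across quintile groups
#'
#' Refits the model specification with the quintile index (1-5) entered as
#' one continuous covariate and returns the two-sided Wald p-value for its
#' coefficient - the test of an increasing trend across quintile groups.
#'
#' @inheritParams fit_cox_model
#' @return The p-value (numeric scalar) with the trend log-HR and its
#'   standard error as attributes `"coef"` and `"se"`.
#' @export
trend_test <- function(cohort, outcome = "incident_cvd",
                       exposure = "quintile_energy",
                       covariate_set = "model2",
                       adjust_total_energy = TRUE, adjust_bmi = FALSE,
                       ties = "efron") {
  des <- encode_design(cohort, outcome, exposure, covariate_set,
                       exposure_as = "numeric",
                       adjust_total_energy = adjust_total_energy,
                       adjust_bmi = adjust_bmi)
  run <- .run_coxph(des$formula, des$data, ties)
  s <- summary(run$fit)$coefficients
  p <- s[".exposure", "Pr(>|z|)"]
  attr(p, "coef") <- s[".exposure", "coef"]
  attr(p, "se") <- s[".exposure", "se(coef)"]
  p
}

#' Isocaloric substitution model
#'
#' Cox model on the energy components: energy from less-healthy food, energy
#' from less-healthy beverages, energy from healthy beverages, and total
#' dietary energy (each per 1,000 kJ/day), plus the covariate set (its
#' separate total-energy term is dropped as redundant). Holding total energy
#' and the beverage terms fixed, the less-healthy-food coefficient estimates
#' the hazard ratio for isocalorically replacing healthy with less-healthy
#' food.
#'
#' @inheritParams fit_cox_model
#' @return An `npc_fit`; the substitution log-HR per 1,000 kJ/day is the
#'   `energy_lh_food_per1000` term (also stored as `$substitution_loghr`).
#' @export
fit_substitution <- function(cohort, outcome = "incident_cvd",
                             covariate_set = "model2",
                             adjust_total_energy = TRUE, ties = "efron") {
  if (!adjust_total_energy) {
    abort("The substitution model requires the total-energy term.")
  }
  cohort <- as_tibble(cohort)
  covs <- setdiff(model_covariates(covariate_set, outcome), "energy_total")
  energy_terms <- c("energy_lh_food", "energy_lh_bev", "energy_healthy_bev",
                    "energy_total")
  missing <- setdiff(c(energy_terms, covs, .outcome_columns[[outcome]]),
                     names(cohort))
  if (length(missing)) {
    abort(paste0("Cohort lacks columns: ", paste(missing, collapse = ", ")))
  }
  data <- .prepare_covariates(cohort, covs)
  for (nm in energy_terms) {
    data[[paste0(nm, "_per1000")]] <- data[[nm]] / 1000
  }
  terms <- c(paste0(energy_terms, "_per1000"),
             vapply(covs, .term_for, character(1)))
  oc <- .outcome_columns[[outcome]]
  fml <- as.formula(paste(
    "survival::Surv(", oc[["time"]], ",", oc[["event"]], ") ~",
    paste(terms, collapse = " + ")
  ))
  x <- model.matrix(as.formula(paste("~", paste(terms, collapse = "+"))), data)
  if (qr(x)$rank < ncol(x)) {
    abort("Energy terms are collinear (rank-deficient design); substitution model unidentified.")
  }
  run <- .run_coxph(fml, data, ties)
  spec <- list(outcome = outcome, exposure = "substitution",
               covariate_set = covariate_set, exposure_as = "none")
  out <- .new_npc_fit(run, spec, NULL)
  out$substitution_loghr <- unname(coef(run$fit)["energy_lh_food_per1000"])
  out
}

#' Schoenfeld-residual proportional-hazards diagnostics
#'
#' Tests the proportional-hazards assumption of a fitted model with scaled
#' Schoenfeld residuals: a correlation-with-time test per covariate plus the
#' global chi-square test ([survival::cox.zph()]).
#'
#' @param fit An `npc_fit`.
#' @param transform Time transform for the residual correlation (default
#'   `"km"`, the survival-function scale).
#' @return The `npc_fit` with `$ph` set to a tibble `term`, `chisq`, `df`,
#'   `p` (last row `GLOBAL`). If the model has fewer than 10 events the
#'   tests are skipped with a warning and `$ph` stays `NULL`.
#' @export
check_ph <- function(fit, transform = "km") {
  if (!inherits(fit, "npc_fit")) abort("`fit` must be an npc_fit.")
  if (fit$n_events < 10) {
    warn("Fewer than 10 events; proportional-hazards tests skipped.")
    return(fit)
  }
  z <- survival::cox.zph(fit$fit, transform = transform, global = TRUE)
  fit$ph <- tibble(
    term = rownames(z$table),
    chisq = z$table[, "chisq"],
    df = z$table[, "df"],
    p = z$table[, "p"]
  )
  fit
}

#' @export
print.npc_fit <- function(x, ...) {
  cat("<npc_fit> Cox proportional hazards:",
      x$spec$outcome, "~", x$spec$exposure,
      paste0("(", x$spec$covariate_set, ")\n"))
  cat("  n =", x$n, " events =", x$n_events, "\n")
  if (!is.null(x$quintile_hr)) {
    q <- x$quintile_hr
    cat("  Quintile HRs (ref Q1):",
        paste(sprintf("Q%d %.2f", q$quintile, q$hr), collapse = ", "), "\n")
  }
  if (!is.na(x$trend_p)) {
    cat("  Trend test p =", format(as.numeric(x$trend_p), digits = 3), "\n")
  }
  if (isTRUE(x$separation)) cat("  WARNING: possible separation\n")
  invisible(x)
}

#' Tidy a fitted Cox model
#'
#' @param x An `npc_fit`.
#' @param exponentiate Report hazard ratios rather than log-HRs.
#' @param ... Unused.
#' @return A tibble of terms with estimates, Wald standard errors,
#'   statistics, p-values and 95% confidence limits.
#' @export
tidy.npc_fit <- function(x, exponentiate = FALSE, ...) {
  out <- x$terms
  if (exponentiate) {
    out <- mutate(out, estimate = .data$hr,
                  conf.low = .data$conf.low, conf.high = .data$conf.high)
  } else {
    out <- mutate(out,
                  conf.low = .data$estimate - qnorm(0.975) * .data$std.error,
                  conf.high = .data$estimate + qnorm(0.975) * .data$std.error)
  }
  select(out, "term", "estimate", "std.error", "statistic", "p.value",
         "conf.low", "conf.high")
}

#' One-row model summary
#'
#' @param x An `npc_fit`.
#' @param ... Unused.
#' @return A tibble with `n`, `n_events`, `trend_p`, concordance and the
#'   global PH p-value when [check_ph()] has been run.
#' @export
glance.npc_fit <- function(x, ...) {
  tibble(
    n = x$n,
    n_events = x$n_events,
    outcome = x$spec$outcome,
    exposure = x$spec$exposure,
    covariate_set = x$spec$covariate_set,
    trend_p = as.numeric(x$trend_p),
    concordance = unname(x$fit$concordance["concordance"]),
    ph_global_p = if (is.null(x$ph)) NA_real_ else x$ph$p[x$ph$term == "GLOBAL"]
  )
}
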