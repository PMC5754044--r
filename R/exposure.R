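validate_diary <- function(diary, catalogue_ids = NULL) {
  diary <- as_tibble(diary)
  needed <- c("participant_id", "day_index", "item_id", "grams")
  missing <- setdiff(needed, names(diary))
  if (length(missing)) {
    abort(paste0("Diary is missing columns: ", paste(missing, collapse = ", ")))
  }
  if (anyNA(diary$day_index) || any(diary$day_index < 1 | diary$day_index > 7)) {
    abort("`day_index` must lie in 1..7.")
  }
  if (anyNA(diary$grams) || any(diary$grams <= 0)) {
    abort("`grams` must be positive for every diary record.")
  }
  if (!is.null(catalogue_ids)) {
    unknown <- setdiff(unique(diary$item_id), catalogue_ids)
    if (length(unknown)) {
      abort(paste0(
        "Diary references item_id values absent from the catalogue: ",
        paste(head(unknown, 10), collapse = ", ")
      ))
    }
  }
  diary
}

#' Build person-level dietary exposures from diary records
#'
#' Converts participant x day x item x grams diary records, a scored
#' catalogue and the food-composition table into one row of exposure
#' measures per participant. Energy per record is
#' `grams * energy_kj / 100`; energies and weights are routed by the item's
#' classification (less-healthy food, less-healthy beverage, healthy food,
#' healthy beverage, alcoholic beverage) and all per-day quantities are diary
#' totals divided by the number of *distinct* diary days observed, so partial
#' diaries scale correctly.
#'
#' The headline exposure is the proportion of energy from less-healthy items,
#'
#' `(energy from less-healthy food + energy from less-healthy beverages) /
#'  (total energy intake - energy from alcoholic beverages)`,
#'
#' alcohol being outside the scoring guidelines. A weight-based analogue
#' (`prop_lh_weight`, denominator likewise excluding alcoholic beverages;
#' beverage weight included by default) and the energy-weighted mean
#' FSA-Ofcom score of all non-alcoholic items are computed alongside for the
#' sensitivity exposures. Fruit-and-vegetable weight uses the catalogue's
#' disaggregated fruit/vegetable/nut weight fractions.
#'
#' @param diary Data frame with `participant_id`, `day_index` (1-7),
#'   `item_id`, `grams` (> 0).
#' @param scored Scored, classified catalogue from [score_catalogue()].
#' @param catalogue Food-composition table (for energy and FVN fractions).
#' @param include_beverage_weight Include beverage weight in the weight-based
#'   exposure (default `TRUE`).
#' @return A tibble with one row per participant: `n_diary_days`, per-day
#'   energy sums by class (`energy_lh_food`, `energy_lh_bev`,
#'   `energy_healthy_food`, `energy_healthy_bev`, `energy_healthy`,
#'   `energy_alcoholic`, `energy_total`, kJ/day), per-day weights
#'   (`weight_lh`, `weight_total`, `fv_weight`, g/day), `prop_lh_energy`,
#'   `prop_lh_weight` and `mean_weighted_score`.
#' @export
build_exposure <- function(diary, scored, catalogue,
                           include_beverage_weight = TRUE) {
  catalogue <- validate_catalogue(catalogue)
  scored <- as_tibble(scored)
  if (!all(c("item_id", "classification", "score") %in% names(scored))) {
    abort("`scored` must contain item_id, classification and score (see score_catalogue()).")
  }
  diary <- validate_diary(diary, catalogue$item_id)
  if (nrow(diary) == 0L) {
    abort("Diary contains no records.")
  }

  items <- left_join(
    select(scored, "item_id", "classification", "score"),
    select(catalogue, "item_id", "item_class", "energy_kj", "fvn_pct"),
    by = "item_id"
  )

  recs <- diary %>%
    left_join(items, by = "item_id") %>%
    mutate(
      energy = .data$grams * .data$energy_kj / 100,
      is_alc = .data$classification == "unscored",
      is_lh = .data$classification == "less_healthy",
      wt_counts = !.data$is_alc &
        (include_beverage_weight | .data$item_class != "beverage")
    )

  recs %>%
    group_by(.data$participant_id) %>%
    summarise(
      n_diary_days = n_distinct(.data$day_index),
      energy_lh_food = sum(.data$energy[.data$is_lh & .data$item_class == "food"]),
      energy_lh_bev = sum(.data$energy[.data$is_lh & .data$item_class == "beverage"]),
      energy_healthy_food = sum(
        .data$energy[.data$classification == "healthy" & .data$item_class == "food"]
      ),
      energy_healthy_bev = sum(
        .data$energy[.data$classification == "healthy" & .data$item_class == "beverage"]
      ),
      energy_alcoholic = sum(.data$energy[.data$is_alc]),
      energy_total = sum(.data$energy),
      weight_lh = sum(.data$grams[.data$is_lh & .data$wt_counts]),
      weight_nonlh = sum(.data$grams[!.data$is_lh & .data$wt_counts]),
      fv_weight = sum(.data$grams * .data$fvn_pct / 100),
      mean_weighted_score = {
        keep <- !.data$is_alc
        if (sum(.data$energy[keep]) > 0) {
          sum(.data$score[keep] * .data$energy[keep]) / sum(.data$energy[keep])
        } else {
          NA_real_
        }
      },
      .groups = "drop"
    ) %>%
    mutate(
      energy_healthy = .data$energy_healthy_food + .data$energy_healthy_bev,
      weight_total = .data$weight_lh + .data$weight_nonlh,
      across(
        c("energy_lh_food", "energy_lh_bev", "energy_healthy_food",
          "energy_healthy_bev", "energy_healthy", "energy_alcoholic",
          "energy_total", "weight_lh", "weight_nonlh", "weight_total",
          "fv_weight"),
        ~ .x / .data$n_diary_days
      ),
      # total - alcoholic == less-healthy + healthy by construction; summing
      # the parts keeps the proportion inside [0, 1] to the last ulp
      prop_lh_energy = (.data$energy_lh_food + .data$energy_lh_bev) /
        (.data$energy_lh_food + .data$energy_lh_bev + .data$energy_healthy),
      prop_lh_weight = .data$weight_lh / (.data$weight_lh + .data$weight_nonlh)
    ) %>%
    select(-"weight_nonlh")
}

#' Energy-weighted mean FSA-Ofcom score for one participant's records
#'
#' Helper mirroring the sensitivity exposure: the mean of item scores
#' weighted by the energy each item contributed, alcoholic beverages excluded
#' from numerator and denominator.
#'
#' @inheritParams build_exposure
#' @return A tibble `participant_id`, `mean_weighted_score`.
#' @export
mean_energy_weighted_score <- function(diary, scored, catalogue) {
  out <- build_exposure(diary, scored, catalogue)
  if (anyNA(out$mean_weighted_score)) {
    warn("Some participants consumed no non-alcoholic energy; score undefined (NA).")
  }
  select(out, "participant_id", "mean_weighted_score")
}

#' Assign quintile groups
#'
#' Divides values into fifths by ascending rank. Group `k` holds ranks
#' `(ceiling(n*(k-1)/5), ceiling(n*k/5)]` after a stable ascending sort by
#' `(value, id)`, which makes group sizes differ by at most one and splits
#' boundary ties deterministically. At n = 22,992 this yields the size
#' pattern {4599, 4598, 4599, 4598, 4598}.
#'
#' @param x Numeric exposure values (finite).
#' @param ids Tie-breaking identifiers (default input order).
#' @param n_groups Number of groups (default 5).
#' @return Integer group labels (1 = lowest) in input order, with attribute
#'   `"boundaries"`: the exposure value at the upper edge of each of the
#'   first `n_groups - 1` groups.
#' @examples
#' assign_quintiles(1:10) # 1 1 2 2 3 3 4 4 5 5
#' @export
assign_quintiles <- function(x, ids = seq_along(x), n_groups = 5L) {
  if (!is.numeric(x) || anyNA(x) || any(!is.finite(x))) {
    abort("`x` must be finite numeric values with no missing entries.")
  }
  n <- length(x)
  if (n < n_groups) {
    abort(paste0("Need at least ", n_groups, " values to form ", n_groups, " groups."))
  }
  ord <- order(x, ids, method = "radix")
  cuts <- ceiling(n * seq_len(n_groups) / n_groups)
  labels_sorted <- rep(seq_len(n_groups), times = diff(c(0L, cuts)))
  out <- integer(n)
  out[ord] <- labels_sorted
  attr(out, "boundaries") <- x[ord][cuts[-n_groups]]
  out
}

#' Add quintile group columns to an exposure table
#'
#' @param exposure Tibble from [build_exposure()] (or any per-participant
#'   table).
#' @param vars Named character vector mapping new quintile columns to the
#'   exposure columns they rank, defaulting to the four exposure measures
#'   used in the analysis.
#' @return `exposure` with added integer quintile columns; the quintile
#'   boundary values are stored in the `"quintile_boundaries"` attribute.
#' @export
add_quintiles <- function(exposure,
                          vars = c(quintile_energy = "prop_lh_energy",
                                   quintile_weight = "prop_lh_weight",
                                   quintile_score = "mean_weighted_score",
                                   quintile_fv = "fv_weight")) {
  exposure <- as_tibble(exposure)
  missing <- setdiff(unname(vars), names(exposure))
  if (length(missing)) {
    abort(paste0("Exposure table lacks columns: ", paste(missing, collapse = ", ")))
  }
  bounds <- list()
  for (i in seq_along(vars)) {
    q <- assign_quintiles(exposure[[vars[[i]]]], ids = exposure$participant_id)
    exposure[[names(vars)[i]]] <- as.integer(q)
    bounds[[names(vars)[i]]] <- attr(q, "boundaries")
  }
  attr(exposure, "quintile_boundaries") <- bounds
  exposure
}
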