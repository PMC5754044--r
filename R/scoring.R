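#' Component points for one nutrient
#'
#' Returns the number of cut-points strictly exceeded by `value`, capped at
#' the table length. This is the elementary scoring rule of the FSA-Ofcom
#' model: "more than" semantics at every cut-point, no rounding of the input.
#'
#' @param value Nutrient quantity per 100 g edible weight (vectorised, >= 0).
#' @param thresholds Strictly increasing numeric vector of cut-points.
#' @param field Field name used in error messages.
#' @return Integer vector of point counts in `0:length(thresholds)`.
#' @examples
#' component_points(9, 1:10)  # exactly 9 g saturated fat -> 8 points
#' @export
component_points <- function(value, thresholds, field = "value") {
  if (!is.numeric(value) || anyNA(value)) {
    abort(paste0("`", field, "` must be numeric and non-missing."))
  }
  if (any(value < 0)) {
    abort(paste0("`", field, "` must be non-negative (per 100 g edible weight)."))
  }
  if (!is.numeric(thresholds) || length(thresholds) < 1L ||
      is.unsorted(thresholds, strictly = TRUE)) {
    abort("`thresholds` must be a strictly increasing numeric vector.")
  }
  # count of thresholds t with value > t: findInterval with left-open intervals
  as.integer(findInterval(value, thresholds, left.open = TRUE))
}

.item_classes <- c("food", "beverage", "alcoholic_beverage")

.catalogue_nutrients <- c(
  "energy_kj", "satfat_g", "sugars_g", "sodium_mg",
  "fibre_g", "protein_g", "fvn_pct"
)

validate_catalogue <- function(catalogue) {
  catalogue <- as_tibble(catalogue)
  needed <- c("item_id", "item_class", .catalogue_nutrients)
  missing <- setdiff(needed, names(catalogue))
  if (length(missing)) {
    abort(paste0(
      "Catalogue is missing columns: ", paste(missing, collapse = ", ")
    ))
  }
  dup <- unique(catalogue$item_id[duplicated(catalogue$item_id)])
  if (length(dup)) {
    abort(paste0(
      "Catalogue item_id values must be unique; duplicated: ",
      paste(head(dup, 10), collapse = ", ")
    ))
  }
  bad_class <- setdiff(unique(as.character(catalogue$item_class)), .item_classes)
  if (length(bad_class)) {
    abort(paste0(
      "Unknown item_class value(s): ", paste(bad_class, collapse = ", "),
      " (expected food, beverage or alcoholic_beverage)."
    ))
  }
  for (nm in .catalogue_nutrients) {
    v <- catalogue[[nm]]
    if (!is.numeric(v) || anyNA(v)) {
      abort(paste0("Catalogue column `", nm, "` must be numeric and non-missing."))
    }
    if (any(v < 0)) {
      bad <- catalogue$item_id[which(v < 0)[1]]
      abort(paste0(
        "Negative nutrient value in `", nm, "` for item `", bad,
        "`; all nutrients are per 100 g and must be >= 0."
      ))
    }
  }
  if (any(catalogue$fvn_pct > 100)) {
    bad <- catalogue$item_id[which(catalogue$fvn_pct > 100)[1]]
    abort(paste0("`fvn_pct` must lie in [0, 100]; violated by item `", bad, "`."))
  }
  catalogue
}

#' Score food items with the FSA-Ofcom model
#'
#' Computes per-component points and the total score for each catalogue row.
#' "A" points (energy, saturated fat, total sugars, sodium, 0-10 each) are
#' adverse; "C" points (fruit/vegetable/nut content, NSP fibre, protein, 0-5
#' each) are beneficial and subtracted. The protein gate applies: when total
#' A points reach 11 and the FVN component is below its maximal 5 points,
#' protein points cannot be counted. Classification is added separately by
#' [classify_foods()]; [score_catalogue()] composes both with validation.
#'
#' @param catalogue Data frame with columns `item_id`, `item_class`,
#'   `energy_kj`, `satfat_g`, `sugars_g`, `sodium_mg`, `fibre_g`,
#'   `protein_g`, `fvn_pct` (all per 100 g edible weight).
#' @param tables Scoring tables, see [default_scoring_tables()].
#' @return A tibble with one row per item: the component points, `a_total`,
#'   `protein_counted` and `score`.
#' @export
score_foods <- function(catalogue, tables = default_scoring_tables()) {
  catalogue <- validate_catalogue(catalogue)
  validate_scoring_tables(tables)

  a_energy <- component_points(catalogue$energy_kj, tables$energy_kj, "energy_kj")
  a_satfat <- component_points(catalogue$satfat_g, tables$satfat_g, "satfat_g")
  a_sugars <- component_points(catalogue$sugars_g, tables$sugars_g, "sugars_g")
  a_sodium <- component_points(catalogue$sodium_mg, tables$sodium_mg, "sodium_mg")
  a_total <- a_energy + a_satfat + a_sugars + a_sodium

  fvn_count <- component_points(catalogue$fvn_pct, tables$fvn_pct, "fvn_pct")
  c_fvn <- .fvn_point_map[fvn_count + 1L]
  c_fibre <- component_points(catalogue$fibre_g, tables$fibre_g, "fibre_g")
  c_protein <- component_points(catalogue$protein_g, tables$protein_g, "protein_g")

  protein_counted <- !(a_total >= 11L & c_fvn < 5L)
  score <- a_total - (c_fvn + c_fibre + ifelse(protein_counted, c_protein, 0L))

  tibble(
    item_id = catalogue$item_id,
    item_class = as.character(catalogue$item_class),
    a_points_energy = a_energy,
    a_points_satfat = a_satfat,
    a_points_sugars = a_sugars,
    a_points_sodium = a_sodium,
    a_total = a_total,
    c_points_fvn = c_fvn,
    c_points_fibre = c_fibre,
    c_points_protein = c_protein,
    protein_counted = protein_counted,
    score = as.integer(score)
  )
}

#' Classify scored items as healthy / less-healthy
#'
#' Applies the Ofcom regulation thresholds: a food is less-healthy if it
#' scores 4 points or more, a beverage if it scores 1 point or more.
#' Alcoholic beverages are never scored (classification `"unscored"`),
#' reflecting the operational use of the model.
#'
#' @param scored A tibble from [score_foods()] (columns `score`, `item_class`).
#' @return `scored` with a `classification` column
#'   (`"healthy"`, `"less_healthy"` or `"unscored"`).
#' @export
classify_foods <- function(scored) {
  scored <- as_tibble(scored)
  if (!all(c("score", "item_class") %in% names(scored))) {
    abort("`scored` must contain `score` and `item_class` columns.")
  }
  bad_class <- setdiff(unique(as.character(scored$item_class)), .item_classes)
  if (length(bad_class)) {
    abort(paste0("Unknown item_class value(s): ", paste(bad_class, collapse = ", ")))
  }
  mutate(
    scored,
    classification = case_when(
      .data$item_class == "alcoholic_beverage" ~ "unscored",
      .data$item_class == "food" & .data$score >= 4 ~ "less_healthy",
      .data$item_class == "beverage" & .data$score >= 1 ~ "less_healthy",
      TRUE ~ "healthy"
    )
  )
}

#' Score and classify a whole catalogue
#'
#' Validates the catalogue (unique ids, non-negative per-100-g nutrients),
#' scores every item and attaches the less-healthy classification, preserving
#' input order. A summary of class counts is emitted as a message.
#'
#' @inheritParams score_foods
#' @param quiet Suppress the class-count message.
#' @return A tibble of scored, classified items (one row per catalogue row).
#' @examples
#' cat <- tibble::tibble(
#'   item_id = "crisps", name = "crisps", item_class = "food",
#'   energy_kj = 2200, satfat_g = 3, sugars_g = 1, sodium_mg = 600,
#'   fibre_g = 2, protein_g = 5, fvn_pct = 0
#' )
#' score_catalogue(cat, quiet = TRUE)
#' @export
score_catalogue <- function(catalogue, tables = default_scoring_tables(),
                            quiet = FALSE) {
  out <- classify_foods(score_foods(catalogue, tables))
  if (!quiet) {
    tally <- table(factor(out$classification,
                          levels = c("healthy", "less_healthy", "unscored")))
    inform(paste0(
      "Scored ", nrow(out), " items: ",
      tally[["healthy"]], " healthy, ",
      tally[["less_healthy"]], " less-healthy, ",
      tally[["unscored"]], " unscored (alcoholic)."
    ))
  }
  out
}
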