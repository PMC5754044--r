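#' Default FSA-Ofcom scoring tables (2004/05 model)
#'
#' Cut-point tables for the seven scored components of the UK FSA-Ofcom
#' nutrient profiling model, all expressed per 100 g edible weight. A
#' component's points are the number of cut-points *strictly exceeded* by the
#' nutrient value, capped at the table length (10 for "A" nutrients, 5 for
#' "C" nutrients). The fruit/vegetable/nut (FVN) component is special: the
#' three cut-points (40, 60, 80 percent by weight) map to 1, 2 and 5 points
#' respectively - 3 and 4 FVN points do not exist in the model.
#'
#' Tables are configuration data, not code constants: they can be written to
#' and re-read from YAML with [write_scoring_tables()] / [read_scoring_tables()]
#' so a corrected table never requires a code change.
#'
#' @return A named list of numeric vectors, each strictly increasing, with
#'   components `energy_kj`, `satfat_g`, `sugars_g`, `sodium_mg`, `fibre_g`
#'   (non-starch polysaccharide fibre), `protein_g` and `fvn_pct`.
#' @examples
#' tabs <- default_scoring_tables()
#' component_points(1800, tabs$energy_kj) # 5
#' @export
default_scoring_tables <- function() {
  list(
    energy_kj = c(335, 670, 1005, 1340, 1675, 2010, 2345, 2680, 3015, 3350),
    satfat_g  = c(1, 2, 3, 4, 5, 6, 7, 8, 9, 10),
    sugars_g  = c(4.5, 9, 13.5, 18, 22.5, 27, 31, 36, 40, 45),
    sodium_mg = c(90, 180, 270, 360, 450, 540, 630, 720, 810, 900),
    fibre_g   = c(0.7, 1.4, 2.1, 2.8, 3.5),
    protein_g = c(1.6, 3.2, 4.8, 6.4, 8.0),
    fvn_pct   = c(40, 60, 80)
  )
}

# FVN threshold count -> points (3 thresholds exceeded = maximal 5 points)
.fvn_point_map <- c(0L, 1L, 2L, 5L)

.required_table_names <- c(
  "energy_kj", "satfat_g", "sugars_g", "sodium_mg",
  "fibre_g", "protein_g", "fvn_pct"
)

validate_scoring_tables <- function(tables) {
  if (!is.list(tables)) {
    abort("`tables` must be a named list of numeric cut-point vectors.")
  }
  missing <- setdiff(.required_table_names, names(tables))
  if (length(missing)) {
    abort(paste0(
      "Scoring tables are missing components: ",
      paste(missing, collapse = ", ")
    ))
  }
  for (nm in .required_table_names) {
    v <- tables[[nm]]
    if (!is.numeric(v) || length(v) < 1L || anyNA(v)) {
      abort(paste0("Scoring table `", nm, "` must be a numeric vector without NA."))
    }
    if (is.unsorted(v, strictly = TRUE)) {
      abort(paste0("Scoring table `", nm, "` must be strictly increasing."))
    }
  }
  if (length(tables$fvn_pct) != 3L) {
    abort("Scoring table `fvn_pct` must have exactly 3 cut-points (1/2/5 points).")
  }
  invisible(tables)
}

#' Read or write scoring tables as YAML
#'
#' @param path Path to a YAML file holding one ascending numeric sequence per
#'   component, keyed by component name.
#' @param tables A scoring-table list such as [default_scoring_tables()].
#' @return `read_scoring_tables()` returns the validated table list;
#'   `write_scoring_tables()` returns `path` invisibly.
#' @export
read_scoring_tables <- function(path) {
  tables <- yaml::read_yaml(path)
  tables <- lapply(tables, as.numeric)
  validate_scoring_tables(tables)
  tables
}

#' @rdname read_scoring_tables
#' @export
write_scoring_tables <- function(tables, path) {
  validate_scoring_tables(tables)
  yaml::write_yaml(lapply(tables, as.numeric), path)
  invisible(path)
}
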