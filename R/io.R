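#' Read study tables from CSV
#'
#' Thin readr wrappers that re-validate the package's exchange formats: the
#' food-composition catalogue, diary records and participant table (missing
#' covariates encoded as empty cells).
#'
#' @param path CSV file path.
#' @return A validated tibble.
#' @export
read_catalogue <- function(path) {
  validate_catalogue(readr::read_csv(path, show_col_types = FALSE))
}

#' @rdname read_catalogue
#' @export
read_diary <- function(path) {
  validate_diary(readr::read_csv(path, show_col_types = FALSE))
}

#' @rdname read_catalogue
#' @export
read_participants <- function(path) {
  readr::read_csv(path, show_col_types = FALSE)
}

#' Write a table to CSV
#'
#' @param x A tibble (scored catalogue, exposures, cohort, exclusion log...).
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_table <- function(x, path) {
  readr::write_csv(as_tibble(x), path)
  invisible(path)
}

#' Serialise a fitted model to JSON
#'
#' Point estimates, confidence intervals, the trend test and any PH
#' diagnostics, as a machine-readable summary.
#'
#' @param fit An `npc_fit`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_fit_json <- function(fit, path) {
  if (!inherits(fit, "npc_fit")) abort("`fit` must be an npc_fit.")
  out <- list(
    spec = fit$spec,
    n = fit$n, n_events = fit$n_events,
    terms = fit$terms,
    quintile_hr = fit$quintile_hr,
    trend_p = as.numeric(fit$trend_p),
    separation = fit$separation,
    ph = fit$ph
  )
  jsonlite::write_json(out, path, auto_unbox = TRUE, digits = NA,
                       dataframe = "rows", pretty = TRUE)
  invisible(path)
}
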