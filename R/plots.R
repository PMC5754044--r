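#' Forest plot of quintile hazard ratios
#'
#' @param object An `npc_fit` with a quintile exposure.
#' @param ... Unused.
#' @return A ggplot: per-quintile hazard ratios with 95% CIs on a log scale,
#'   reference quintile at 1.
#' @export
autoplot.npc_fit <- function(object, ...) {
  if (is.null(object$quintile_hr)) {
    abort("This fit has no quintile exposure terms to plot.")
  }
  q <- object$quintile_hr
  ggplot2::ggplot(q, ggplot2::aes(x = factor(.data$quintile), y = .data$hr)) +
    ggplot2::geom_hline(yintercept = 1, linetype = "dashed", colour = "grey50") +
    ggplot2::geom_pointrange(
      ggplot2::aes(ymin = .data$conf.low, ymax = .data$conf.high)
    ) +
    ggplot2::scale_y_log10() +
    ggplot2::labs(
      x = "Quintile group of exposure (1 = lowest)",
      y = "Hazard ratio (95% CI)",
      title = paste0(object$spec$outcome, " ~ ", object$spec$exposure,
                     " (", object$spec$covariate_set, ")"),
      subtitle = if (!is.na(object$trend_p)) {
        paste0("trend test p = ", format(as.numeric(object$trend_p), digits = 2))
      }
    ) +
    ggplot2::theme_minimal()
}

#' Flow plot of the exclusion cascade
#'
#' @param cohort A cohort from [apply_exclusions()] (or its log).
#' @return A ggplot bar chart of participants remaining after each step.
#' @export
plot_exclusion_flow <- function(cohort) {
  log <- if (is.data.frame(cohort)) {
    if (!is.null(attr(cohort, "exclusion_log"))) exclusion_log(cohort) else cohort
  } else {
    cohort
  }
  log <- mutate(log, step = factor(.data$step, levels = rev(.data$step)))
  ggplot2::ggplot(log, ggplot2::aes(x = .data$n_after, y = .data$step)) +
    ggplot2::geom_col(fill = "steelblue") +
    ggplot2::geom_text(
      ggplot2::aes(label = paste0("-", .data$n_excluded)),
      hjust = -0.1, size = 3
    ) +
    ggplot2::labs(x = "Participants remaining", y = NULL) +
    ggplot2::theme_minimal()
}

#' Scaled Schoenfeld residuals against time
#'
#' Visual companion to [check_ph()]: smoothed scaled Schoenfeld residuals
#' for the chosen terms; a flat band supports proportional hazards.
#'
#' @param fit An `npc_fit` (PH tests are computed if absent).
#' @param terms Terms to show (default: the exposure contrasts).
#' @return A ggplot.
#' @export
plot_schoenfeld <- function(fit, terms = NULL) {
  if (!inherits(fit, "npc_fit")) abort("`fit` must be an npc_fit.")
  z <- survival::cox.zph(fit$fit, transform = "km")
  keep <- if (is.null(terms)) grep("^\\.exposure", colnames(z$y)) else {
    match(terms, colnames(z$y))
  }
  if (!length(keep) || anyNA(keep)) keep <- seq_len(ncol(z$y))
  df <- purrr::map_dfr(keep, function(j) {
    tibble(time = z$x, residual = z$y[, j], term = colnames(z$y)[j])
  })
  ggplot2::ggplot(df, ggplot2::aes(x = .data$time, y = .data$residual)) +
    ggplot2::geom_point(alpha = 0.15, size = 0.5) +
    ggplot2::geom_smooth(method = "loess", formula = y ~ x, se = TRUE) +
    ggplot2::geom_hline(yintercept = 0, linetype = "dashed") +
    ggplot2::facet_wrap(~term, scales = "free_y") +
    ggplot2::labs(x = "Transformed follow-up time",
                  y = "Scaled Schoenfeld residual") +
    ggplot2::theme_minimal()
}
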