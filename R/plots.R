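# ggplot2 figures mirroring the standard report panels: yearly cohort
# sizes, criterion breakdown, stratified prevalence, insurance splits, and
# county-level covariate scatter plots.

#' Plot yearly cohort sizes
#'
#' @param summary output of [multi_year_summary()] (the `"average"` row is
#'   dropped).
#' @return a ggplot.
#' @export
plot_yearly_cohort <- function(summary) {
  d <- summary[summary$period != "average", , drop = FALSE]
  ggplot2::ggplot(d, ggplot2::aes(x = .data$period, y = .data$cohort_size)) +
    ggplot2::geom_col(fill = "grey40") +
    ggplot2::labs(x = "year", y = "identified chronic-pain cohort",
                  title = "Cohort size by year") +
    ggplot2::theme_minimal()
}

#' Plot the criterion breakdown as stacked shares
#'
#' @param breakdown output of [criterion_breakdown()].
#' @return a ggplot.
#' @export
plot_criterion_breakdown <- function(breakdown) {
  d <- tidyr::pivot_longer(
    breakdown[c("year", "pct_icd_only", "pct_both", "pct_opioid_only")],
    -"year", names_to = "route", values_to = "pct")
  d$route <- factor(d$route,
                    levels = c("pct_icd_only", "pct_both", "pct_opioid_only"),
                    labels = c("ICD-9 only", "both", "opioid only"))
  ggplot2::ggplot(d, ggplot2::aes(x = factor(.data$year), y = .data$pct,
                                  fill = .data$route)) +
    ggplot2::geom_col() +
    ggplot2::scale_fill_grey(start = 0.75, end = 0.25) +
    ggplot2::labs(x = "year", y = "% of cohort",
                  title = "Identification route by year", fill = NULL) +
    ggplot2::theme_minimal()
}

#' Plot a stratified prevalence table
#'
#' Bars of prevalence per stratum; when `sex` and `age_band` are both
#' present, age bands go on the x axis with one line/colour per sex.
#'
#' @param prev a `prevalence_tbl` from [compute_prevalence()].
#' @return a ggplot.
#' @export
plot_prevalence <- function(prev) {
  d <- prev[prev$stratum != "overall", , drop = FALSE]
  if (all(c("sex", "age_band") %in% names(d))) {
    ggplot2::ggplot(d, ggplot2::aes(x = .data$age_band,
                                    y = .data$prevalence_pct,
                                    fill = .data$sex)) +
      ggplot2::geom_col(position = "dodge") +
      ggplot2::scale_fill_grey(start = 0.3, end = 0.7) +
      ggplot2::labs(x = "age band", y = "prevalence (%)",
                    title = "Chronic-pain prevalence by age and sex") +
      ggplot2::theme_minimal() +
      ggplot2::theme(axis.text.x = ggplot2::element_text(angle = 60,
                                                         hjust = 1))
  } else {
    ggplot2::ggplot(d, ggplot2::aes(x = .data$stratum,
                                    y = .data$prevalence_pct)) +
      ggplot2::geom_col(fill = "grey40") +
      ggplot2::labs(x = "stratum", y = "prevalence (%)",
                    title = "Chronic-pain prevalence by stratum") +
      ggplot2::theme_minimal() +
      ggplot2::theme(axis.text.x = ggplot2::element_text(angle = 60,
                                                         hjust = 1))
  }
}

#' @export
autoplot.prevalence_tbl <- function(object, ...) plot_prevalence(object)

#' Plot public/private insurance shares
#'
#' @param split output of [insurance_split()].
#' @return a ggplot.
#' @export
plot_insurance_split <- function(split) {
  id_cols <- setdiff(names(split), c("n", "public_pct", "private_pct"))
  split$group <- if (length(id_cols) == 0) "overall" else
    do.call(paste, c(split[id_cols], sep = "/"))
  d <- tidyr::pivot_longer(split[c("group", "public_pct", "private_pct")],
                           -"group", names_to = "payer", values_to = "pct")
  d$payer <- ifelse(d$payer == "public_pct", "public", "private")
  ggplot2::ggplot(d, ggplot2::aes(x = .data$group, y = .data$pct,
                                  fill = .data$payer)) +
    ggplot2::geom_col(position = "dodge") +
    ggplot2::scale_fill_grey(start = 0.3, end = 0.7) +
    ggplot2::labs(x = NULL, y = "% of cohort",
                  title = "Insurance type within the cohort", fill = NULL) +
    ggplot2::theme_minimal() +
    ggplot2::theme(axis.text.x = ggplot2::element_text(angle = 60, hjust = 1))
}

#' Scatter plot of a county-level outcome against a covariate
#'
#' Adds a least-squares line and annotates Pearson's r and the two-sided p
#' from [corr_t_test()].
#'
#' @param table one row per county (see [county_correlations()]).
#' @param outcome,covariate column names to plot.
#' @return a ggplot.
#' @export
plot_county_correlation <- function(table, outcome, covariate) {
  res <- corr_t_test(table[[covariate]], table[[outcome]])
  lab <- sprintf("r = %.2f, p = %.3g", res$estimate["r"], res$p_value)
  ggplot2::ggplot(table, ggplot2::aes(x = .data[[covariate]],
                                      y = .data[[outcome]])) +
    ggplot2::geom_point() +
    ggplot2::geom_smooth(method = "lm", formula = y ~ x, se = FALSE,
                         colour = "grey30") +
    ggplot2::annotate("text", x = -Inf, y = Inf, hjust = -0.1, vjust = 1.5,
                      label = lab) +
    ggplot2::labs(x = covariate, y = outcome,
                  title = "County-level association") +
    ggplot2::theme_minimal()
}

# dispatch used by render_report(plots = TRUE)
plot_report_table <- function(tab) {
  nms <- names(tab)
  if (inherits(tab, "prevalence_tbl")) return(plot_prevalence(tab))
  if (all(c("period", "cohort_size") %in% nms)) {
    return(plot_yearly_cohort(tab))
  }
  if (all(c("year", "pct_icd_only") %in% nms)) {
    return(plot_criterion_breakdown(tab))
  }
  if (all(c("public_pct", "private_pct") %in% nms)) {
    return(plot_insurance_split(tab))
  }
  NULL
}
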