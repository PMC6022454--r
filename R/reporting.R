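# Report artifacts: yearly cohort summaries with multi-year averages, and
# a deterministic CSV (plus optional chart) renderer with a manifest.

round_half_up <- function(x, digits = 0) {
  f <- 10^digits
  floor(x * f + 0.5) / f
}

#' Multi-year cohort summary with averages
#'
#' Summarises identification results per calendar year and appends an
#' arithmetic-mean row across the years supplied (counts rounded half-up to
#' integers, percentages to one decimal place). Because the yearly pooled
#' opioid-criterion share and the mean of yearly shares are different
#' statistics, the average row reports both (`pct_opioid_criterion` = mean
#' of the yearly shares; `pct_opioid_criterion_pooled` = pooled over years).
#'
#' @param records either cohort records from [identify_cohort()], or a
#'   pre-counted tibble with a `year` column plus either the three route
#'   counts (`icd_only`, `both`, `opioid_only`) or
#'   (`cohort_size`, `opioid_criterion_total`).
#' @param years optional year subset over which to summarise and average.
#' @return tibble with a `period` column (`"2006"`, ..., `"average"`),
#'   counts and percentage columns.
#' @examples
#' printed <- tibble::tibble(
#'   year = c(2006, 2007, 2009, 2010),
#'   cohort_size = c(278059, 341491, 363789, 336878),
#'   opioid_criterion_total = c(43846, 56498, 59985, 63475))
#' multi_year_summary(printed)
#' @export
multi_year_summary <- function(records, years = NULL) {
  if ("classification" %in% names(records)) {
    counts <- criterion_breakdown(records)
  } else {
    counts <- as_tibble(records)
    if (!"year" %in% names(counts)) {
      abort("multi_year_summary: need a 'year' column")
    }
    if (all(c("icd_only", "both", "opioid_only") %in% names(counts))) {
      counts$cohort_size <- counts$icd_only + counts$both + counts$opioid_only
      counts$opioid_criterion_total <- counts$both + counts$opioid_only
    } else if (!all(c("cohort_size", "opioid_criterion_total") %in%
                    names(counts))) {
      abort(paste("multi_year_summary: need either route counts",
                  "(icd_only, both, opioid_only) or",
                  "(cohort_size, opioid_criterion_total)"))
    }
  }
  if (!is.null(years)) counts <- counts[counts$year %in% years, , drop = FALSE]
  if (nrow(counts) == 0) abort("multi_year_summary: no records in the requested years")
  counts <- dplyr::arrange(counts, .data$year)
  counts$pct_opioid_criterion <- round(
    100 * counts$opioid_criterion_total / counts$cohort_size, 1)
  count_cols <- intersect(c("cohort_size", "icd_only", "both", "opioid_only",
                            "opioid_criterion_total"), names(counts))
  pct_cols <- intersect(c("pct_icd_only", "pct_both", "pct_opioid_only",
                          "public_pct", "private_pct"), names(counts))
  avg <- tibble(period = "average")
  for (cc in count_cols) avg[[cc]] <- round_half_up(mean(counts[[cc]]))
  for (pc in pct_cols) avg[[pc]] <- round(mean(counts[[pc]]), 1)
  avg$pct_opioid_criterion <- round(mean(counts$pct_opioid_criterion), 1)
  avg$pct_opioid_criterion_pooled <- round(
    100 * sum(counts$opioid_criterion_total) / sum(counts$cohort_size), 1)
  yearly <- dplyr::mutate(counts, period = as.character(.data$year),
                          .before = 1)
  out <- dplyr::bind_rows(yearly[c("period", count_cols, pct_cols,
                                   "pct_opioid_criterion")], avg)
  out
}

#' Build the standard table set for a cohort
#'
#' Assembles the figure-equivalent tables of a cohort analysis: yearly
#' summary with averages, per-year criterion breakdown, and — when the
#' cohort carries the needed columns — prevalence by sex and age band, by
#' county, and insurance splits overall and by county.
#'
#' @param cohort cohort records, ideally after [attach_demographics()] and
#'   [attach_insurance()].
#' @param census validated census table.
#' @return named list of tibbles.
#' @export
pain_report_tables <- function(cohort, census) {
  qualifying <- cohort[cohort$classification != "none", , drop = FALSE]
  if (nrow(qualifying) == 0) {
    # an empty cohort still renders: zero-count tables, no summary rows
    return(list(yearly_summary = criterion_breakdown(cohort),
                criterion_breakdown = criterion_breakdown(cohort)))
  }
  tables <- list(
    yearly_summary = multi_year_summary(cohort),
    criterion_breakdown = criterion_breakdown(cohort))
  has <- function(...) all(c(...) %in% names(cohort))
  if (has("sex", "age_band")) {
    tables$prevalence_sex_age <- compute_prevalence(cohort, census,
                                                    by = c("sex", "age_band"))
  }
  if (has("county", "sex")) {
    tables$prevalence_county_sex <- compute_prevalence(cohort, census,
                                                       by = c("county", "sex"))
  }
  if (has("insurance")) {
    tables$insurance_by_year <- insurance_split(cohort, by = "year")
    if (has("county")) {
      tables$insurance_by_county <- insurance_split(cohort,
                                                    by = c("year", "county"))
    }
  }
  tables
}

#' Render report tables to a directory
#'
#' Writes every table as `<name>.csv`, an optional chart per table it knows
#' how to draw, and a `manifest.json` listing the produced files. Output is
#' a pure function of the input tables: re-rendering the same tables yields
#' byte-identical CSVs.
#'
#' @param tables named list of data frames (see [pain_report_tables()]).
#' @param out_dir output directory, created if needed.
#' @param plots if `TRUE`, also writes a PNG chart for each table with a
#'   known shape (yearly summary, criterion breakdown, prevalence,
#'   insurance split).
#' @return invisibly, the manifest as a named list.
#' @export
render_report <- function(tables, out_dir, plots = FALSE) {
  if (is.null(names(tables)) || any(!nzchar(names(tables)))) {
    abort("render_report: tables must be a named list")
  }
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  if (!dir.exists(out_dir)) abort(sprintf("cannot create directory %s", out_dir))
  files <- character(0)
  for (nm in names(tables)) {
    tab <- as.data.frame(tables[[nm]])
    # round-trippable flat file: collapse list columns
    for (col in names(tab)) {
      if (is.list(tab[[col]])) {
        tab[[col]] <- vapply(tab[[col]], paste, character(1), collapse = ";")
      }
    }
    path <- file.path(out_dir, paste0(nm, ".csv"))
    readr::write_csv(tab, path, progress = FALSE)
    files <- c(files, basename(path))
    if (plots) {
      p <- try(plot_report_table(tables[[nm]]), silent = TRUE)
      if (!inherits(p, "try-error") && !is.null(p)) {
        ppath <- file.path(out_dir, paste0(nm, ".png"))
        ggplot2::ggsave(ppath, p, width = 7, height = 4.5, dpi = 120)
        files <- c(files, basename(ppath))
      }
    }
  }
  manifest <- list(files = sort(files), n_tables = length(tables))
  jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE)
  invisible(manifest)
}
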