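# Census-denominated stratified prevalence and person-level payer
# attribution. Numerators come from cohort records, denominators from the
# census table; age is analysis_year - birth_year (claims extracts rarely
# carry full dates of birth).

#' Age-band labels in five-year increments
#'
#' @return character vector `"<5", "5-9", ..., "80-84", "85+"`.
#' @export
age_band_levels <- function() {
  c("<5", paste(seq(5, 80, by = 5), seq(9, 84, by = 5), sep = "-"), "85+")
}

#' Assign five-year age bands
#'
#' @param age integer vector of ages in whole years, 0-110.
#' @return factor over [age_band_levels()].
#' @examples
#' assign_age_band(c(4, 52, 90))
#' @export
assign_age_band <- function(age) {
  age <- as.integer(age)
  if (anyNA(age) || any(age < 0) || any(age > 110)) {
    abort("assign_age_band: ages must be whole years in 0-110")
  }
  idx <- pmin(age %/% 5L, 17L) + 1L
  factor(age_band_levels()[idx], levels = age_band_levels())
}

#' Attach demographic strata to cohort records
#'
#' Joins the person table and derives `age` (analysis year minus birth
#' year) and `age_band` for each record's own year.
#'
#' @param cohort records from [identify_cohort()] (or any tibble with
#'   `person_id` and `year`).
#' @param persons validated person table.
#' @return `cohort` with `sex`, `county`, `age`, `age_band` columns added.
#' @export
attach_demographics <- function(cohort, persons) {
  persons <- validate_claims(persons, "person")
  out <- dplyr::left_join(cohort,
                          persons[c("person_id", "sex", "birth_year",
                                    "county")],
                          by = "person_id")
  out$age <- as.integer(out$year) - out$birth_year
  out$age_band <- factor(rep(NA_character_, nrow(out)),
                         levels = age_band_levels())
  known <- !is.na(out$age) & out$age >= 0 & out$age <= 110
  if (any(known)) out$age_band[known] <- assign_age_band(out$age[known])
  out
}

#' Attribute a payer type to each person-year
#'
#' A person-year is labelled with the payer type of the majority of its
#' claims (medical and pharmacy pooled); an exact tie is labelled public.
#'
#' @param person_year_claims tibble with `person_id`, `year` and
#'   `payer_type` columns, one row per claim.
#' @return tibble `person_id`, `year`, `insurance` in `{public, private}`.
#' @export
assign_insurance <- function(person_year_claims) {
  req <- c("person_id", "year", "payer_type")
  if (!all(req %in% names(person_year_claims))) {
    abort("assign_insurance: need columns person_id, year, payer_type")
  }
  if (nrow(person_year_claims) == 0) {
    abort("assign_insurance: at least one claim required")
  }
  dplyr::summarise(
    dplyr::group_by(person_year_claims, .data$person_id, .data$year),
    insurance = ifelse(sum(.data$payer_type == "public") >=
                         sum(.data$payer_type == "private"),
                       "public", "private"),
    .groups = "drop")
}

#' Attach majority-payer insurance labels to cohort records
#'
#' Pools each person-year's medical and pharmacy claims and applies
#' [assign_insurance()].
#'
#' @param cohort records from [identify_cohort()].
#' @param medical,pharmacy the claims the cohort was identified from.
#' @return `cohort` with an `insurance` column.
#' @export
attach_insurance <- function(cohort, medical, pharmacy) {
  claims <- dplyr::bind_rows(
    tibble(person_id = medical$person_id,
           year = claim_year(medical$service_date),
           payer_type = medical$payer_type),
    tibble(person_id = pharmacy$person_id,
           year = claim_year(pharmacy$fill_date),
           payer_type = pharmacy$payer_type))
  dplyr::left_join(cohort, assign_insurance(claims),
                   by = c("person_id", "year"))
}

#' Prevalence percentage
#'
#' @param cases,population counts.
#' @param digits decimal places for display rounding; `NULL` for full
#'   precision.
#' @return `100 * cases / population`, optionally rounded.
#' @examples
#' prevalence_pct(330054, 1119509) # 29.5
#' @export
prevalence_pct <- function(cases, population, digits = 1) {
  p <- 100 * cases / population
  if (is.null(digits)) p else round(p, digits)
}

#' Compute stratified prevalence
#'
#' Counts cohort records per stratum and divides by the census population of
#' that stratum. Strata are any subset of `year`, `sex`, `age_band`,
#' `county`; an overall row (stratum `"overall"`) is always included, using
#' the total census population (per year when `year` is a stratum).
#'
#' @param cohort cohort records carrying the requested stratum columns
#'   (see [attach_demographics()]); excluded-only rows are dropped.
#' @param census validated census table.
#' @param by character subset of `c("year", "sex", "age_band", "county")`.
#' @return a `prevalence_tbl` tibble: stratum columns, `cases`,
#'   `population`, `prevalence_pct` (full precision; round for display).
#' @export
compute_prevalence <- function(cohort, census,
                               by = c("sex", "age_band")) {
  census <- validate_claims(census, "census")
  allowed <- c("year", "sex", "age_band", "county")
  if (!all(by %in% allowed)) {
    abort(sprintf("compute_prevalence: strata must be among {%s}",
                  paste(allowed, collapse = ", ")))
  }
  if ("classification" %in% names(cohort)) {
    cohort <- cohort[cohort$classification != "none", , drop = FALSE]
  }
  missing_cols <- setdiff(by, names(cohort))
  if (length(missing_cols) > 0) {
    abort(sprintf("cohort lacks stratum column(s): %s (see attach_demographics)",
                  paste(missing_cols, collapse = ", ")))
  }
  for (b in setdiff(by, "year")) {  # factors -> character for census joins
    cohort[[b]] <- as.character(cohort[[b]])
  }
  census_by <- setdiff(by, "year")  # one census table serves all years
  denom <- if (length(census_by) == 0) {
    tibble(population = sum(census$population))
  } else {
    dplyr::summarise(dplyr::group_by(census, dplyr::across(dplyr::all_of(census_by))),
                     population = sum(.data$population), .groups = "drop")
  }
  cases <- dplyr::count(cohort, dplyr::across(dplyr::all_of(by)),
                        name = "cases")
  joined <- if (length(census_by) == 0) {
    dplyr::mutate(cases, population = denom$population)
  } else {
    dplyr::left_join(cases, denom, by = census_by)
  }
  if (anyNA(joined$population)) {
    bad <- joined[is.na(joined$population), by, drop = FALSE]
    abort(sprintf("cohort stratum absent from census: %s",
                  paste(utils::capture.output(print(as.data.frame(head(bad)))),
                        collapse = " | ")))
  }
  overall <- if ("year" %in% by) {
    dplyr::mutate(
      dplyr::count(cohort, .data$year, name = "cases"),
      population = sum(census$population))
  } else {
    tibble(cases = nrow(cohort), population = sum(census$population))
  }
  overall <- dplyr::mutate(overall, stratum = "overall")
  joined$stratum <- do.call(paste, c(lapply(by, function(b)
    as.character(joined[[b]])), sep = "/"))
  out <- dplyr::bind_rows(joined, overall)
  out$prevalence_pct <- prevalence_pct(out$cases, out$population,
                                       digits = NULL)
  class(out) <- c("prevalence_tbl", class(out))
  out
}

#' Public/private insurance split of a cohort
#'
#' @param cohort cohort records carrying an `insurance` column
#'   (see [attach_insurance()]); excluded-only rows are dropped.
#' @param by optional grouping columns (e.g. `"year"`, `"county"`, `"sex"`).
#' @return tibble with the grouping columns, `n`, `public_pct`,
#'   `private_pct` (full precision; the two sum to 100 per group).
#' @export
insurance_split <- function(cohort, by = NULL) {
  if (!"insurance" %in% names(cohort)) {
    abort("insurance_split: cohort lacks an 'insurance' column (see attach_insurance)")
  }
  if ("classification" %in% names(cohort)) {
    cohort <- cohort[cohort$classification != "none", , drop = FALSE]
  }
  grouped <- if (is.null(by)) cohort else
    dplyr::group_by(cohort, dplyr::across(dplyr::all_of(by)))
  dplyr::summarise(grouped,
                   n = dplyr::n(),
                   public_pct = 100 * mean(.data$insurance == "public"),
                   private_pct = 100 * mean(.data$insurance == "private"),
                   .groups = "drop")
}
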