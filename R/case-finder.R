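# The two-criterion chronic-pain case finder, evaluated per person per
# calendar year:
#   (1) diagnosis rule — one claim with a highly-likely code, or two claims
#       with likely codes on service dates >= min_separation_days apart;
#   (2) opioid rule — >= min_consecutive_days of dispensing coverage within
#       the year.
# Person-years with only headache/facial-pain/cancer-pain codes and no
# qualifying include pattern are excluded (an include pattern always wins).

claim_year <- function(date) as.integer(format(date, "%Y"))

#' Evaluate the diagnosis criterion for one person-year
#'
#' @param claims medical claims tibble, all for one person and one calendar
#'   year.
#' @param config a [code_config()].
#' @param policy a [finder_policy()].
#' @return list with `icd_flag`, `evidence` (compact string of qualifying
#'   codes and dates, `NA` if none) and `excluded_only_flag`.
#' @export
evaluate_diagnosis_criterion <- function(claims, config = code_config(),
                                         policy = finder_policy()) {
  claims <- validate_claims(claims, "medical")
  if (nrow(claims) == 0) {
    return(list(icd_flag = FALSE, evidence = NA_character_,
                excluded_only_flag = FALSE))
  }
  if (length(unique(claims$person_id)) > 1 ||
      length(unique(claim_year(claims$service_date))) > 1) {
    abort("evaluate_diagnosis_criterion: claims must cover one person and one calendar year")
  }
  long <- tidyr::unnest(claims[c("person_id", "service_date", "icd9_codes")],
                        "icd9_codes")
  long$class <- match_icd9(long$icd9_codes, config)

  hi <- long[long$class == "highly_likely", , drop = FALSE]
  likely <- long[long$class == "likely", , drop = FALSE]
  excluded_present <- any(long$class %in% c("excluded_headache", "cancer_pain"))

  likely_dates <- sort(unique(likely$service_date))
  span <- if (length(likely_dates) >= 2) {
    as.integer(max(likely_dates) - min(likely_dates))
  } else -1L
  likely_ok <- length(likely_dates) >= 2 && span >= policy$min_separation_days

  icd_flag <- nrow(hi) > 0 || likely_ok
  evidence <- if (nrow(hi) > 0) {
    sprintf("highly:%s@%s", hi$icd9_codes[1], hi$service_date[1])
  } else if (likely_ok) {
    lo <- likely[likely$service_date == min(likely_dates), ][1, ]
    hi2 <- likely[likely$service_date == max(likely_dates), ][1, ]
    sprintf("likely:%s@%s;%s@%s", lo$icd9_codes, lo$service_date,
            hi2$icd9_codes, hi2$service_date)
  } else NA_character_
  list(icd_flag = icd_flag, evidence = evidence,
       excluded_only_flag = excluded_present && !icd_flag)
}

# Vectorized diagnosis evaluation over all person-years at once.
# Returns tibble(person_id, year, icd_flag, excluded_only_flag, evidence).
diagnosis_flags <- function(medical, config, policy, years) {
  medical <- dplyr::mutate(medical, year = claim_year(.data$service_date))
  medical <- dplyr::filter(medical, .data$year %in% years)
  if (nrow(medical) == 0) {
    return(tibble(person_id = character(0), year = integer(0),
                  icd_flag = logical(0), excluded_only_flag = logical(0),
                  evidence = character(0)))
  }
  long <- tidyr::unnest(
    medical[c("person_id", "year", "service_date", "icd9_codes")],
    "icd9_codes")
  code_map <- unique(long$icd9_codes)
  cls <- setNames(match_icd9(code_map, config), code_map)
  long$class <- unname(cls[long$icd9_codes])
  long <- dplyr::filter(long, .data$class != "none")
  if (nrow(long) == 0) {
    return(tibble(person_id = character(0), year = integer(0),
                  icd_flag = logical(0), excluded_only_flag = logical(0),
                  evidence = character(0)))
  }
  dplyr::summarise(
    dplyr::group_by(long, .data$person_id, .data$year),
    icd_flag = {
      hi <- .data$class == "highly_likely"
      lk_dates <- unique(.data$service_date[.data$class == "likely"])
      any(hi) || (length(lk_dates) >= 2 &&
                    as.integer(max(lk_dates) - min(lk_dates)) >=
                      policy$min_separation_days)
    },
    excluded_any = any(.data$class %in% c("excluded_headache", "cancer_pain")),
    evidence = {
      hi <- which(.data$class == "highly_likely")
      if (length(hi) > 0) {
        i <- hi[order(.data$service_date[hi])][1]
        sprintf("highly:%s@%s", .data$icd9_codes[i], .data$service_date[i])
      } else {
        lk <- which(.data$class == "likely")
        if (length(lk) >= 2) {
          lk <- lk[order(.data$service_date[lk])]
          i <- lk[1]; j <- lk[length(lk)]
          sprintf("likely:%s@%s;%s@%s", .data$icd9_codes[i],
                  .data$service_date[i], .data$icd9_codes[j],
                  .data$service_date[j])
        } else NA_character_
      }
    },
    .groups = "drop") |>
    dplyr::mutate(excluded_only_flag = .data$excluded_any & !.data$icd_flag) |>
    dplyr::select("person_id", "year", "icd_flag", "excluded_only_flag",
                  "evidence")
}

# Longest within-year opioid coverage run per person-year.
# Returns tibble(person_id, year, max_consecutive_days).
opioid_max_by_year <- function(pharmacy, opioids, policy, years) {
  ph <- pharmacy[is_opioid(pharmacy$drug_id, opioids), , drop = FALSE]
  empty <- tibble(person_id = character(0), year = integer(0),
                  max_consecutive_days = integer(0))
  if (nrow(ph) == 0) return(empty)
  years <- as.integer(years)
  y_start <- as.integer(as.Date(sprintf("%d-01-01", years)))
  y_end <- as.integer(as.Date(sprintf("%d-12-31", years)))
  idx <- split(seq_len(nrow(ph)), ph$person_id)
  out <- purrr::map(names(idx), function(pid) {
    rows <- idx[[pid]]
    starts <- as.integer(ph$fill_date[rows])
    supplies <- as.integer(ph$days_supply[rows])
    if (policy$overlap_policy == "stockpile") {
      sh <- stockpile_shift(starts, supplies, toupper(ph$drug_id[rows]))
      starts <- sh$starts; ends <- sh$ends
    } else {
      ends <- starts + supplies - 1L
    }
    m <- merge_intervals(starts, ends, policy$grace_gap_days)
    runs <- vapply(seq_along(years), function(k) {
      if (policy$clip_to_year) {
        cs <- pmax(m$starts, y_start[k]); ce <- pmin(m$ends, y_end[k])
        ok <- cs <= ce
        if (any(ok)) max(ce[ok] - cs[ok] + 1L) else 0L
      } else {
        ok <- m$starts <= y_end[k] & m$ends >= y_start[k]
        if (any(ok)) max(m$ends[ok] - m$starts[ok] + 1L) else 0L
      }
    }, integer(1))
    tibble(person_id = pid, year = years, max_consecutive_days = runs)
  })
  dplyr::bind_rows(out)
}

#' Identify the chronic-pain cohort
#'
#' Applies both criteria to every person-year in `years` and returns one
#' record per person-year that either qualifies (by diagnosis, opioid
#' exposure, or both) or is explicitly excluded (headache/facial-pain/cancer
#' pain codes only). A person counts once per year no matter how many
#' patterns qualify; qualification in several years yields one record per
#' year.
#'
#' @param medical medical claims tibble.
#' @param pharmacy pharmacy claims tibble.
#' @param persons person table (may omit persons that appear only in
#'   pharmacy claims; those records are flagged `demographics_known = FALSE`).
#' @param config a [code_config()].
#' @param opioids an [opioid_list()].
#' @param policy a [finder_policy()].
#' @param years integer vector of calendar years to evaluate.
#' @return tibble with columns `person_id`, `year`, `icd_flag`,
#'   `opioid_flag`, `classification` (`"icd_only"`, `"opioid_only"`,
#'   `"both"`, or `"none"` for excluded-only rows), `excluded_only_flag`,
#'   `demographics_known`, `evidence`.
#' @export
identify_cohort <- function(medical, pharmacy, persons = NULL,
                            config = code_config(),
                            opioids = opioid_list(),
                            policy = finder_policy(),
                            years) {
  medical <- validate_claims(medical, "medical")
  pharmacy <- validate_claims(pharmacy, "pharmacy")
  if (!is.null(persons)) persons <- validate_claims(persons, "person")
  years <- as.integer(years)

  dx <- diagnosis_flags(medical, config, policy, years)
  op <- opioid_max_by_year(pharmacy, opioids, policy, years)
  op$opioid_flag <- op$max_consecutive_days >= policy$min_consecutive_days
  op <- op[op$opioid_flag, c("person_id", "year", "opioid_flag")]

  rec <- dplyr::full_join(dx, op, by = c("person_id", "year"))
  rec$icd_flag <- !is.na(rec$icd_flag) & rec$icd_flag
  rec$opioid_flag <- !is.na(rec$opioid_flag) & rec$opioid_flag
  rec$excluded_only_flag <- !is.na(rec$excluded_only_flag) &
    rec$excluded_only_flag & !rec$opioid_flag
  rec$classification <- dplyr::case_when(
    rec$icd_flag & rec$opioid_flag ~ "both",
    rec$icd_flag ~ "icd_only",
    rec$opioid_flag ~ "opioid_only",
    TRUE ~ "none")
  rec <- rec[rec$classification != "none" | rec$excluded_only_flag, ,
             drop = FALSE]
  rec$demographics_known <- if (is.null(persons)) NA else
    rec$person_id %in% persons$person_id
  dplyr::arrange(
    rec[c("person_id", "year", "icd_flag", "opioid_flag", "classification",
          "excluded_only_flag", "demographics_known", "evidence")],
    .data$year, .data$person_id)
}

#' Break a cohort down by identification criterion
#'
#' Partitions each year's cohort into the three disjoint identification
#' routes and reports the share that met the opioid criterion at all
#' (`opioid_only + both`). Percentages are of the year's cohort size and are
#' `NA` (absent), not zero, for an empty cohort.
#'
#' @param records cohort records from [identify_cohort()].
#' @param year optional single year; default summarises every year present.
#' @return tibble with one row per year: counts `cohort_size`, `icd_only`,
#'   `both`, `opioid_only`, `opioid_criterion_total` and the matching
#'   `pct_*` percentages.
#' @export
criterion_breakdown <- function(records, year = NULL) {
  if (!is.null(year)) records <- records[records$year %in% year, , drop = FALSE]
  records <- records[records$classification != "none", , drop = FALSE]
  yrs <- if (!is.null(year)) as.integer(year) else
    sort(unique(as.integer(records$year)))
  out <- purrr::map(yrs, function(y) {
    r <- records[records$year == y, , drop = FALSE]
    n <- nrow(r)
    counts <- table(factor(r$classification,
                           levels = c("icd_only", "both", "opioid_only")))
    tibble(year = y, cohort_size = n,
           icd_only = as.integer(counts[["icd_only"]]),
           both = as.integer(counts[["both"]]),
           opioid_only = as.integer(counts[["opioid_only"]]),
           opioid_criterion_total = as.integer(counts[["both"]] +
                                                 counts[["opioid_only"]]))
  })
  out <- dplyr::bind_rows(out)
  if (nrow(out) == 0) {
    out <- tibble(year = integer(0), cohort_size = integer(0),
                  icd_only = integer(0), both = integer(0),
                  opioid_only = integer(0),
                  opioid_criterion_total = integer(0))
  }
  pct <- function(x, n) ifelse(n > 0, 100 * x / n, NA_real_)
  dplyr::mutate(out,
                pct_icd_only = pct(.data$icd_only, .data$cohort_size),
                pct_both = pct(.data$both, .data$cohort_size),
                pct_opioid_only = pct(.data$opioid_only, .data$cohort_size),
                pct_opioid_criterion = pct(.data$opioid_criterion_total,
                                           .data$cohort_size))
}
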