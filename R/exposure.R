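# Opioid exposure-episode construction: fills -> coverage intervals ->
# longest consecutive run within the calendar year. This is the temporal
# core of the opioid criterion, so it is written (and oracle-tested) with
# closed intervals in whole days throughout.

#' Case-finder policy parameters
#'
#' @param min_separation_days minimum service-date separation (days) between
#'   the two diagnoses of the "likely"-code rule; at-least comparator.
#' @param min_consecutive_days minimum length of a continuous opioid
#'   coverage run within the calendar year.
#' @param grace_gap_days uncovered gaps of at most this many days between
#'   coverage intervals are bridged (the merged run includes the gap days).
#'   0 means strictly consecutive coverage.
#' @param overlap_policy `"union"` counts overlapping fills' coverage once;
#'   `"stockpile"` shifts an early same-drug refill to start the day after
#'   the prior fill's coverage ends.
#' @param clip_to_year if `TRUE` (default) coverage runs are clipped to the
#'   calendar year before the consecutive-days test, so a run straddling
#'   New Year qualifies in neither year unless its within-year part is long
#'   enough; if `FALSE` a run qualifies in every year it touches.
#' @return an object of class `finder_policy`.
#' @export
finder_policy <- function(min_separation_days = 30L,
                          min_consecutive_days = 90L,
                          grace_gap_days = 0L,
                          overlap_policy = c("union", "stockpile"),
                          clip_to_year = TRUE) {
  overlap_policy <- match.arg(overlap_policy)
  if (min_separation_days < 1 || min_consecutive_days < 1) {
    abort("finder_policy: durations must be positive")
  }
  if (grace_gap_days < 0) abort("finder_policy: grace_gap_days must be >= 0")
  structure(list(min_separation_days = as.integer(min_separation_days),
                 min_consecutive_days = as.integer(min_consecutive_days),
                 grace_gap_days = as.integer(grace_gap_days),
                 overlap_policy = overlap_policy,
                 clip_to_year = isTRUE(clip_to_year)),
            class = "finder_policy")
}

# Merge sorted closed intervals, bridging uncovered gaps <= grace days.
# starts/ends are integer day numbers; returns a list(starts, ends).
merge_intervals <- function(starts, ends, grace = 0L) {
  if (length(starts) == 0) return(list(starts = integer(0), ends = integer(0)))
  o <- order(starts, ends)
  starts <- starts[o]; ends <- ends[o]
  run_end <- cummax(ends)
  # a new merged interval begins where the gap to everything before exceeds grace
  new_run <- c(TRUE, starts[-1] > head(run_end, -1) + 1L + grace)
  grp <- cumsum(new_run)
  list(starts = as.integer(tapply(starts, grp, min)),
       ends = as.integer(tapply(ends, grp, max)))
}

# Apply the stockpile policy per drug: an early refill starts the day after
# the prior fill's coverage ends. starts are fill dates (integer days).
stockpile_shift <- function(starts, supplies, drugs) {
  ends <- integer(length(starts))
  out_starts <- integer(length(starts))
  for (d in unique(drugs)) {
    idx <- which(drugs == d)
    idx <- idx[order(starts[idx])]
    avail <- -.Machine$integer.max
    for (i in idx) {
      s <- max(starts[i], avail)
      out_starts[i] <- s
      ends[i] <- s + supplies[i] - 1L
      avail <- ends[i] + 1L
    }
  }
  list(starts = out_starts, ends = ends)
}

#' Build an opioid exposure timeline for one person-year
#'
#' Converts pharmacy fills into closed coverage intervals
#' `[fill_date, fill_date + days_supply - 1]` for fills whose drug is on the
#' opioid list, applies the overlap policy, bridges gaps within the grace
#' allowance, and computes the longest continuous run after clipping to the
#' calendar year. Fills dated outside the year are admitted (a late fill in
#' the prior year covers days of this year) but only within-year coverage
#' counts.
#'
#' @param fills pharmacy claims tibble for one person.
#' @param opioids an [opioid_list()].
#' @param policy a [finder_policy()].
#' @param year calendar year under evaluation.
#' @return an `exposure_timeline`: list with `person_id`, `year`,
#'   `intervals` (tibble of closed `start`/`end` dates, merged and clipped)
#'   and `max_consecutive_days`.
#' @examples
#' fills <- tibble::tibble(
#'   person_id = "p1",
#'   fill_date = as.Date(c("2010-01-01", "2010-01-31", "2010-03-02")),
#'   drug_id = "OXYCODONE", days_supply = 30L, payer_type = "public")
#' build_exposure_timeline(fills, opioid_list(), finder_policy(), 2010)
#' @export
build_exposure_timeline <- function(fills, opioids = opioid_list(),
                                    policy = finder_policy(), year) {
  fills <- validate_claims(fills, "pharmacy")
  if (nrow(fills) > 0 && length(unique(fills$person_id)) > 1) {
    abort("build_exposure_timeline: fills span multiple persons")
  }
  person_id <- if (nrow(fills) > 0) fills$person_id[1] else NA_character_
  keep <- is_opioid(fills$drug_id, opioids)
  if (any(!keep)) {
    message(sprintf("ignoring %d non-opioid fill(s)", sum(!keep)))
  }
  fills <- fills[keep, , drop = FALSE]

  year_start <- as.integer(as.Date(sprintf("%d-01-01", year)))
  year_end <- as.integer(as.Date(sprintf("%d-12-31", year)))
  if (nrow(fills) == 0) {
    return(structure(list(person_id = person_id, year = as.integer(year),
                          intervals = tibble(start = as.Date(integer(0)),
                                             end = as.Date(integer(0))),
                          max_consecutive_days = 0L),
                     class = "exposure_timeline"))
  }
  starts <- as.integer(fills$fill_date)
  supplies <- as.integer(fills$days_supply)
  if (policy$overlap_policy == "stockpile") {
    sh <- stockpile_shift(starts, supplies, toupper(fills$drug_id))
    starts <- sh$starts; ends <- sh$ends
  } else {
    ends <- starts + supplies - 1L
  }
  m <- merge_intervals(starts, ends, policy$grace_gap_days)
  if (policy$clip_to_year) {
    cs <- pmax(m$starts, year_start)
    ce <- pmin(m$ends, year_end)
    keep <- cs <= ce
    cs <- cs[keep]; ce <- ce[keep]
    max_run <- if (length(cs)) max(ce - cs + 1L) else 0L
  } else {
    keep <- m$starts <= year_end & m$ends >= year_start
    cs <- m$starts[keep]; ce <- m$ends[keep]
    max_run <- if (length(cs)) max(ce - cs + 1L) else 0L
  }
  structure(list(person_id = person_id, year = as.integer(year),
                 intervals = tibble(start = as.Date(cs, origin = "1970-01-01"),
                                    end = as.Date(ce, origin = "1970-01-01")),
                 max_consecutive_days = as.integer(max_run)),
            class = "exposure_timeline")
}

#' @export
print.exposure_timeline <- function(x, ...) {
  cat(sprintf("<exposure_timeline> person %s, year %d: %d interval(s), max run %d day(s)\n",
              x$person_id, x$year, nrow(x$intervals), x$max_consecutive_days))
  if (nrow(x$intervals) > 0) print(x$intervals)
  invisible(x)
}

#' Apply the opioid criterion to an exposure timeline
#'
#' @param timeline an `exposure_timeline` from [build_exposure_timeline()].
#' @param policy a [finder_policy()].
#' @return `TRUE` iff the longest within-year coverage run is at least
#'   `policy$min_consecutive_days`.
#' @export
evaluate_opioid_criterion <- function(timeline, policy = finder_policy()) {
  timeline$max_consecutive_days >= policy$min_consecutive_days
}
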