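# Independent brute-force oracles for the temporal criteria. These work on
# boolean day grids and a day-by-day supply-bank simulation, deliberately
# avoiding the interval arithmetic used by the implementation.

# Longest consecutive covered run within [year_start, year_end] (integer
# day numbers), from raw fills. overlap: "union" marks each fill's days
# directly; "stockpile" simulates a per-drug supply bank day by day (a unit
# of supply is consumed on the first uncovered day at or after its fill).
grid_max_run <- function(starts, supplies, drugs, overlap, grace,
                         year_start, year_end) {
  if (length(starts) == 0) return(0L)
  lo <- min(starts)
  hi <- max(starts) + sum(supplies) + grace + 2L  # generous upper bound
  days <- lo:hi
  covered <- rep(FALSE, length(days))
  if (overlap == "union") {
    for (i in seq_along(starts)) {
      idx <- (starts[i]:(starts[i] + supplies[i] - 1L)) - lo + 1L
      covered[idx] <- TRUE
    }
  } else {
    for (d in unique(drugs)) {
      sel <- which(drugs == d)
      add <- rep(0L, length(days))
      at <- starts[sel] - lo + 1L
      for (i in seq_along(sel)) add[at[i]] <- add[at[i]] + supplies[sel[i]]
      bank <- 0L
      drug_cov <- rep(FALSE, length(days))
      for (k in seq_along(days)) {
        bank <- bank + add[k]
        if (bank > 0L) {
          drug_cov[k] <- TRUE
          bank <- bank - 1L
        }
      }
      covered <- covered | drug_cov
    }
  }
  # bridge uncovered gaps of length <= grace that sit between covered days
  if (grace > 0L) {
    r <- rle(covered)
    pos <- cumsum(r$lengths) - r$lengths + 1L
    for (j in seq_along(r$lengths)) {
      if (!r$values[j] && r$lengths[j] <= grace &&
          j > 1 && j < length(r$lengths)) {
        covered[pos[j]:(pos[j] + r$lengths[j] - 1L)] <- TRUE
      }
    }
  }
  in_year <- days >= year_start & days <= year_end
  x <- covered[in_year]
  if (!any(x)) return(0L)
  r <- rle(x)
  max(r$lengths[r$values])
}

# day-grid oracle wrapped for a fills tibble and calendar year
oracle_max_run <- function(fills, year, overlap = "union", grace = 0L,
                           opioids = opioid_list()) {
  keep <- toupper(fills$drug_id) %in% opioids$drug_ids
  fills <- fills[keep, , drop = FALSE]
  grid_max_run(as.integer(fills$fill_date), as.integer(fills$days_supply),
               toupper(fills$drug_id), overlap, as.integer(grace),
               as.integer(as.Date(sprintf("%d-01-01", year))),
               as.integer(as.Date(sprintf("%d-12-31", year))))
}

# all-pairs date-difference scan for the diagnosis criterion
oracle_dx_flag <- function(codes, dates, config = code_config(),
                           min_sep = 30L) {
  cls <- match_icd9(codes, config)
  if (any(cls == "highly_likely")) return(TRUE)
  ld <- dates[cls == "likely"]
  if (length(ld) < 2) return(FALSE)
  for (i in seq_along(ld)) {
    for (j in seq_along(ld)) {
      if (abs(as.integer(ld[i] - ld[j])) >= min_sep) return(TRUE)
    }
  }
  FALSE
}

# random fill set generator for fuzzing (fills cluster around one year)
random_fills <- function(n_max = 40L, supply_max = 120L, year = 2010L,
                         opioids = opioid_list()) {
  n <- sample.int(n_max, 1L)
  origin <- as.Date(sprintf("%d-01-01", year))
  tibble::tibble(
    person_id = "fz",
    fill_date = origin + sample(-120:420, n, replace = TRUE),
    drug_id = sample(c(opioids$drug_ids[1:3], "LISINOPRIL"), n,
                     replace = TRUE),
    days_supply = sample.int(supply_max, n, replace = TRUE),
    payer_type = sample(c("public", "private"), n, replace = TRUE))
}

# small convenience builders for hand-made claims
med_claim <- function(person = "p1", date, codes, payer = "public") {
  tibble::tibble(person_id = person, service_date = as.Date(date),
                 icd9_codes = list(codes), payer_type = payer)
}

rx_claim <- function(person = "p1", date, drug = "OXYCODONE", supply = 30L,
                     payer = "public") {
  tibble::tibble(person_id = person, fill_date = as.Date(date),
                 drug_id = drug, days_supply = as.integer(supply),
                 payer_type = payer)
}

default_census_fixture <- function() {
  tibble::tibble(county = "York", sex = c("female", "male"),
                 age_band = "50-54", population = c(100, 100),
                 median_income = 50000, pct_poverty = 10, pct_bachelors = 30)
}

as_tbl_df <- function(x) {
  class(x) <- setdiff(class(x), "prevalence_tbl")
  tibble::as_tibble(x)
}

make_empty_medical <- function() {
  tibble::tibble(person_id = character(0),
                 service_date = as.Date(character(0)),
                 icd9_codes = list(), payer_type = character(0))
}

# compare identified cohort to planted truth; returns number of discordant
# person-years (case status) plus route mismatches among concordant cases
truth_discordance <- function(cohort, truth) {
  found <- cohort[cohort$classification != "none",
                  c("person_id", "year", "classification")]
  m <- dplyr::left_join(truth, found, by = c("person_id", "year"))
  status_bad <- sum((!is.na(m$classification)) != m$is_case)
  route_bad <- sum(m$is_case & !is.na(m$classification) &
                     m$classification != m$planted_route)
  c(status = status_bad, route = route_bad)
}
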