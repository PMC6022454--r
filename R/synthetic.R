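# Seeded synthetic all-payer-claims generator with planted (known)
# chronic-pain status. Every planted pattern is constructed to satisfy or
# fail the two case-finding criteria *by construction*, so the case finder
# can be validated against exact truth labels:
#   icd route    — one highly-likely diagnosis, or two likely diagnoses
#                  >= 30 days apart, and no qualifying opioid run;
#   opioid route — a within-year coverage run >= 90 consecutive days and no
#                  qualifying diagnoses;
#   both         — both patterns;
#   non-cases    — at most one near-miss noise pattern per person-year
#                  (single likely diagnosis; likely pair 1-29 days apart;
#                  opioid run 60-89 days; headache-only diagnoses), plus
#                  neutral background claims.
# Noise patterns are mandatory defaults: the criteria's hard parts are the
# temporal boundaries (30-day separation, 90-day run), and the near misses
# keep them permanently exercised.

.sim_likely_codes <- c("724.2", "724.5", "721.3", "722.10", "719.41",
                       "729.1", "353.0", "715.90", "307.89", "723.1")
.sim_highly_codes <- c("338.0", "338.11", "338.19", "338.21", "338.28",
                       "338.29", "338.4")
.sim_excluded_codes <- c("346.90", "346.00", "784.0", "339.1", "350.2")
.sim_neutral_codes <- c("460", "462", "487.1", "401.9", "786.50", "V70.0",
                        "780.60", "250.00", "493.90", "599.0")
.sim_neutral_drugs <- c("LISINOPRIL", "ATORVASTATIN", "METFORMIN",
                        "OMEPRAZOLE", "AMOXICILLIN")

#' Configuration for the synthetic claims generator
#'
#' Defaults emulate the study conditions the pipeline is meant for: a
#' multi-year insured population with an old-state age structure, 16-county
#' geography, a 29.5% planted chronic-pain prevalence, a case mix dominated
#' by the diagnosis route (84% diagnosis-only, 13% both, 3% opioid-only),
#' and income-linked public-payer probability per county.
#'
#' @param n_persons number of persons.
#' @param years calendar years simulated (claims are generated per year).
#' @param seed integer seed; all generator randomness derives from it.
#' @param county_table counties with `pop_weight` and socioeconomic
#'   covariates; see [default_county_table()].
#' @param age_band_weights named probabilities over [age_band_levels()].
#' @param female_prob probability a person is female.
#' @param prevalence_target per person-year probability of being a planted
#'   case, in `[0, 1)`.
#' @param mix named fractions over `c(icd_only, both, opioid_only)` of the
#'   case routes; must sum to 1.
#' @param noise named probabilities over `c(none, single_likely, close_pair,
#'   short_opioid, excluded_only)` for non-case person-years; must sum to 1.
#'   At most one noise pattern is planted per person-year so that patterns
#'   cannot combine into an accidental qualifying pattern.
#' @param payer_public_base baseline probability a claim is publicly paid.
#' @param payer_income_coef increase in public-payer probability per dollar
#'   of county median income below the across-county mean (links payer mix
#'   to county income).
#' @param background_medical_rate,background_pharmacy_rate Poisson means for
#'   neutral (non-pain, non-opioid) claims per person-year.
#' @param overlapping_fills if `TRUE`, planted opioid runs use overlapping
#'   same-drug fills (early refills), exercising the stockpile/union overlap
#'   policies; patterns still qualify/fail identically under both policies.
#' @param reference_year census reference year for ages and denominators.
#' @return an object of class `sim_config`.
#' @export
sim_config <- function(n_persons = 1000,
                       years = c(2006L, 2007L, 2009L, 2010L),
                       seed = 20100401,
                       county_table = default_county_table(),
                       age_band_weights = default_age_band_weights(),
                       female_prob = 0.513,
                       prevalence_target = 0.295,
                       mix = c(icd_only = 0.84, both = 0.13,
                               opioid_only = 0.03),
                       noise = c(none = 0.55, single_likely = 0.15,
                                 close_pair = 0.10, short_opioid = 0.10,
                                 excluded_only = 0.10),
                       payer_public_base = 0.55,
                       payer_income_coef = 1.5e-5,
                       background_medical_rate = 2,
                       background_pharmacy_rate = 0.5,
                       overlapping_fills = FALSE,
                       reference_year = 2010L) {
  if (nrow(county_table) == 0) abort("sim_config: empty county table")
  if (abs(sum(mix) - 1) > 1e-9) {
    abort("sim_config: case-mix fractions must sum to 1")
  }
  if (abs(sum(noise) - 1) > 1e-9) {
    abort("sim_config: noise fractions must sum to 1")
  }
  probs <- c(female_prob, prevalence_target, mix, noise,
             county_table$pop_weight, age_band_weights)
  if (any(probs < 0 | probs > 1)) {
    abort("sim_config: all probabilities must lie in [0, 1]")
  }
  if (!setequal(names(mix), c("icd_only", "both", "opioid_only"))) {
    abort("sim_config: mix must name icd_only, both, opioid_only")
  }
  structure(list(n_persons = as.integer(n_persons),
                 years = sort(as.integer(years)), seed = as.integer(seed),
                 county_table = county_table,
                 age_band_weights = age_band_weights,
                 female_prob = female_prob,
                 prevalence_target = prevalence_target,
                 mix = mix, noise = noise,
                 payer_public_base = payer_public_base,
                 payer_income_coef = payer_income_coef,
                 background_medical_rate = background_medical_rate,
                 background_pharmacy_rate = background_pharmacy_rate,
                 overlapping_fills = isTRUE(overlapping_fills),
                 reference_year = as.integer(reference_year)),
            class = "sim_config")
}

# county -> per-claim public-payer probability, linked to median income
payer_public_prob <- function(config) {
  ct <- config$county_table
  p <- config$payer_public_base +
    config$payer_income_coef * (mean(ct$median_income) - ct$median_income)
  setNames(pmin(pmax(p, 0.05), 0.95), ct$county)
}

#' Generate a synthetic insured population and its census table
#'
#' Persons are drawn i.i.d. from the configured age/sex/county marginals.
#' The emitted census table holds the exact realized counts per
#' county x sex x age-band stratum (ages at the reference year), so
#' prevalence denominators are self-consistent with the population, plus
#' the configured county covariates.
#'
#' @param config a [sim_config()].
#' @return list with `persons` and `census` tibbles.
#' @export
generate_population <- function(config = sim_config()) {
  set.seed(config$seed)
  n <- config$n_persons
  bands <- age_band_levels()
  band <- sample(bands, n, replace = TRUE, prob = config$age_band_weights)
  lo <- c(0, seq(5, 85, by = 5))[match(band, bands)]
  width <- ifelse(band == "85+", 11L, 5L)
  age <- lo + floor(runif(n) * width)
  persons <- tibble(
    person_id = sprintf("P%06d", seq_len(n)),
    sex = c("male", "female")[1L + (runif(n) < config$female_prob)],
    birth_year = config$reference_year - as.integer(age),
    county = sample(config$county_table$county, n, replace = TRUE,
                    prob = config$county_table$pop_weight))
  grid <- tidyr::expand_grid(county = config$county_table$county,
                             sex = c("female", "male"),
                             age_band = bands)
  counts <- dplyr::count(
    dplyr::mutate(persons,
                  age_band = as.character(assign_age_band(
                    config$reference_year - .data$birth_year))),
    .data$county, .data$sex, .data$age_band, name = "population")
  census <- dplyr::left_join(grid, counts,
                             by = c("county", "sex", "age_band"))
  census$population[is.na(census$population)] <- 0
  census <- dplyr::left_join(
    census,
    config$county_table[c("county", "median_income", "pct_poverty",
                          "pct_bachelors")],
    by = "county")
  list(persons = validate_claims(persons, "person"),
       census = validate_claims(census, "census"))
}

# Build chained (or overlapping) fills realizing an opioid coverage run of
# `len` days starting on day-of-year `start` of `year`. Returns a tibble of
# pharmacy fills. Under both overlap policies the realized continuous
# coverage equals `len` days (non-overlapping chains) or at least `len`
# days (overlapping variant, cases only).
.plant_fills <- function(person_id, year, start, len, drug, overlapping) {
  if (length(person_id) == 0) {
    return(tibble(person_id = character(0), fill_date = as.Date(integer(0)),
                  drug_id = character(0), days_supply = integer(0)))
  }
  if (!overlapping) {
    k <- ceiling(len / 30)
    idx <- rep(seq_along(len), k)
    j <- sequence(k) - 1L
    offs <- j * 30L
    supply <- pmin(30L, len[idx] - offs)
  } else {
    # early refills: 30-day supplies every 25 days; continuous coverage of
    # 25*(k-1)+30 >= len days under union, 30k days under stockpile
    k <- pmax(ceiling((len - 30) / 25) + 1, 1)
    idx <- rep(seq_along(len), k)
    j <- sequence(k) - 1L
    offs <- j * 25L
    supply <- rep(30L, length(idx))
  }
  tibble(person_id = person_id[idx],
         fill_date = as.Date(sprintf("%d-01-01", year[idx])) +
           (start[idx] - 1L) + offs,
         drug_id = drug[idx],
         days_supply = as.integer(supply))
}

# Overlapping near-miss runs keep total supply <= 89 so they fail the
# criterion under both policies: 30 + 30 + 29 supplies at offsets 0/22/45
# give a continuous 74-day union span and an 89-day stockpile span.
.plant_short_overlapping <- function(person_id, year, start, drug) {
  if (length(person_id) == 0) {
    return(tibble(person_id = character(0), fill_date = as.Date(integer(0)),
                  drug_id = character(0), days_supply = integer(0)))
  }
  idx <- rep(seq_along(person_id), each = 3)
  offs <- rep(c(0L, 22L, 45L), length(person_id))
  supply <- rep(c(30L, 30L, 29L), length(person_id))
  tibble(person_id = person_id[idx],
         fill_date = as.Date(sprintf("%d-01-01", year[idx])) +
           (start[idx] - 1L) + offs,
         drug_id = drug[idx],
         days_supply = supply)
}

#' Generate synthetic claims with planted truth labels
#'
#' For every person-year, case status is drawn with probability
#' `prevalence_target` and a route from the case mix; the corresponding
#' qualifying pattern (and only that pattern) is planted. Non-case
#' person-years receive at most one near-miss noise pattern. All
#' person-years additionally receive neutral background claims that match
#' no configured code or drug.
#'
#' @param persons person table from [generate_population()].
#' @param config the same [sim_config()].
#' @return list with `medical`, `pharmacy` (validated claim tibbles) and
#'   `truth` (tibble `person_id`, `year`, `is_case`, `planted_route`).
#' @export
generate_claims <- function(persons, config = sim_config()) {
  set.seed(config$seed + 1L)
  pub_prob <- payer_public_prob(config)
  py <- tidyr::expand_grid(person_id = persons$person_id,
                           year = config$years)
  py <- dplyr::left_join(py, persons[c("person_id", "county", "birth_year")],
                         by = "person_id")
  n <- nrow(py)
  # persons not yet born in an early analysis year generate nothing that year
  alive <- py$year >= py$birth_year
  py$is_case <- runif(n) < config$prevalence_target & alive
  py$route <- "none"
  n_case <- sum(py$is_case)
  py$route[py$is_case] <- sample(names(config$mix), n_case, replace = TRUE,
                                 prob = config$mix)
  py$noise <- "none"
  py$noise[!py$is_case] <- sample(names(config$noise), n - n_case,
                                  replace = TRUE, prob = config$noise)
  py$noise[!alive] <- "none"

  med <- list(); rx <- list()
  payer_for <- function(county) {
    ifelse(runif(length(county)) < pub_prob[county], "public", "private")
  }
  ymd <- function(year, day) as.Date(sprintf("%d-01-01", year)) + (day - 1L)

  # --- diagnosis patterns (cases on the icd or both route) ---------------
  dx <- py[py$route %in% c("icd_only", "both"), , drop = FALSE]
  use_highly <- runif(nrow(dx)) < 0.5
  hi <- dx[use_highly, , drop = FALSE]
  med$highly <- tibble(
    person_id = hi$person_id,
    service_date = ymd(hi$year, sample.int(365, nrow(hi), replace = TRUE)),
    icd9_codes = as.list(sample(.sim_highly_codes, nrow(hi), replace = TRUE)),
    county = hi$county)
  pr <- dx[!use_highly, , drop = FALSE]
  gap <- sample(30:150, nrow(pr), replace = TRUE)
  d1 <- vapply(365L - gap, function(m) sample.int(m, 1L), integer(1))
  med$pair <- tibble(
    person_id = rep(pr$person_id, 2),
    service_date = c(ymd(pr$year, d1), ymd(pr$year, d1 + gap)),
    icd9_codes = as.list(sample(.sim_likely_codes, 2 * nrow(pr),
                                replace = TRUE)),
    county = rep(pr$county, 2))

  # --- opioid patterns (cases on the opioid or both route) ---------------
  op <- py[py$route %in% c("opioid_only", "both"), , drop = FALSE]
  len <- sample(90:150, nrow(op), replace = TRUE)
  ostart <- vapply(365L - len + 1L, function(m) sample.int(m, 1L), integer(1))
  fills <- .plant_fills(op$person_id, op$year, ostart, len,
                        sample(opioid_list()$drug_ids, nrow(op),
                               replace = TRUE),
                        config$overlapping_fills)
  fills$county <- op$county[match(fills$person_id, op$person_id)]
  rx$case <- fills

  # --- near-miss noise (non-cases) ---------------------------------------
  s1 <- py[py$noise == "single_likely", , drop = FALSE]
  med$single <- tibble(
    person_id = s1$person_id,
    service_date = ymd(s1$year, sample.int(365, nrow(s1), replace = TRUE)),
    icd9_codes = as.list(sample(.sim_likely_codes, nrow(s1), replace = TRUE)),
    county = s1$county)

  cp <- py[py$noise == "close_pair", , drop = FALSE]
  cgap <- sample(1:29, nrow(cp), replace = TRUE)
  cd1 <- vapply(365L - cgap, function(m) sample.int(m, 1L), integer(1))
  med$close_pair <- tibble(
    person_id = rep(cp$person_id, 2),
    service_date = c(ymd(cp$year, cd1), ymd(cp$year, cd1 + cgap)),
    icd9_codes = as.list(sample(.sim_likely_codes, 2 * nrow(cp),
                                replace = TRUE)),
    county = rep(cp$county, 2))

  so <- py[py$noise == "short_opioid", , drop = FALSE]
  sdrug <- sample(opioid_list()$drug_ids, nrow(so), replace = TRUE)
  if (config$overlapping_fills) {
    sstart <- vapply(rep(365L - 89L + 1L, nrow(so)),
                     function(m) sample.int(m, 1L), integer(1))
    sfills <- .plant_short_overlapping(so$person_id, so$year, sstart, sdrug)
  } else {
    slen <- sample(60:89, nrow(so), replace = TRUE)
    sstart <- vapply(365L - slen + 1L, function(m) sample.int(m, 1L),
                     integer(1))
    sfills <- .plant_fills(so$person_id, so$year, sstart, slen, sdrug, FALSE)
  }
  sfills$county <- so$county[match(sfills$person_id, so$person_id)]
  rx$noise <- sfills

  ex <- py[py$noise == "excluded_only", , drop = FALSE]
  ed1 <- sample.int(305, nrow(ex), replace = TRUE)
  med$excluded <- tibble(
    person_id = rep(ex$person_id, 2),
    service_date = c(ymd(ex$year, ed1), ymd(ex$year, ed1 + 60L)),
    icd9_codes = as.list(sample(.sim_excluded_codes, 2 * nrow(ex),
                                replace = TRUE)),
    county = rep(ex$county, 2))

  # --- neutral background claims for everyone ----------------------------
  nbg <- rpois(n, config$background_medical_rate)
  nbg[!alive] <- 0L
  bg_idx <- rep(seq_len(n), nbg)
  med$background <- tibble(
    person_id = py$person_id[bg_idx],
    service_date = ymd(py$year[bg_idx],
                       sample.int(365, length(bg_idx), replace = TRUE)),
    icd9_codes = as.list(sample(.sim_neutral_codes, length(bg_idx),
                                replace = TRUE)),
    county = py$county[bg_idx])
  nrx <- rpois(n, config$background_pharmacy_rate)
  nrx[!alive] <- 0L
  rx_idx <- rep(seq_len(n), nrx)
  rx$background <- tibble(
    person_id = py$person_id[rx_idx],
    fill_date = ymd(py$year[rx_idx],
                    sample.int(330, length(rx_idx), replace = TRUE)),
    drug_id = sample(.sim_neutral_drugs, length(rx_idx), replace = TRUE),
    days_supply = sample(c(7L, 10L, 30L), length(rx_idx), replace = TRUE),
    county = py$county[rx_idx])

  medical <- dplyr::bind_rows(med)
  medical$payer_type <- payer_for(medical$county)
  medical$county <- NULL
  pharmacy <- dplyr::bind_rows(rx)
  pharmacy$payer_type <- payer_for(pharmacy$county)
  pharmacy$county <- NULL
  medical <- dplyr::arrange(medical, .data$person_id, .data$service_date)
  pharmacy <- dplyr::arrange(pharmacy, .data$person_id, .data$fill_date)

  truth <- tibble(person_id = py$person_id, year = py$year,
                  is_case = py$is_case,
                  planted_route = ifelse(py$is_case, py$route, "none"))
  list(medical = validate_claims(medical, "medical"),
       pharmacy = validate_claims(pharmacy, "pharmacy"),
       truth = dplyr::arrange(truth, .data$person_id, .data$year))
}

#' Simulate a complete synthetic claims dataset
#'
#' Convenience wrapper: [generate_population()] then [generate_claims()].
#'
#' @param config a [sim_config()].
#' @return list with `persons`, `census`, `medical`, `pharmacy`, `truth`,
#'   and the `config` used.
#' @examples
#' sim <- simulate_claims(sim_config(n_persons = 50, years = 2010, seed = 7))
#' nrow(sim$truth)
#' @export
simulate_claims <- function(config = sim_config()) {
  pop <- generate_population(config)
  cl <- generate_claims(pop$persons, config)
  c(pop, cl, list(config = config))
}

#' Write a simulated dataset to a directory of CSV files
#'
#' Emits `persons.csv`, `medical_claims.csv`, `pharmacy_claims.csv`,
#' `census.csv` and `truth.csv`.
#'
#' @param sim result of [simulate_claims()].
#' @param dir output directory (created if needed).
#' @return invisibly, the written file paths.
#' @export
write_sim_dataset <- function(sim, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  paths <- c(persons = file.path(dir, "persons.csv"),
             medical = file.path(dir, "medical_claims.csv"),
             pharmacy = file.path(dir, "pharmacy_claims.csv"),
             census = file.path(dir, "census.csv"),
             truth = file.path(dir, "truth.csv"))
  write_claims(sim$persons, paths["persons"], "person")
  write_claims(sim$medical, paths["medical"], "medical")
  write_claims(sim$pharmacy, paths["pharmacy"], "pharmacy")
  write_claims(sim$census, paths["census"], "census")
  readr::write_csv(sim$truth, paths["truth"], progress = FALSE)
  invisible(paths)
}
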