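test_that("five-year age banding covers 0-110 with the <5 and 85+ ends", {
  expect_equal(as.character(assign_age_band(c(4, 52, 90))),
               c("<5", "50-54", "85+"))
  expect_equal(as.character(assign_age_band(0)), "<5")
  expect_equal(as.character(assign_age_band(c(84, 85))), c("80-84", "85+"))
  expect_error(assign_age_band(-1), "0-110")
  expect_error(assign_age_band(130), "0-110")
  # every age maps into exactly one of the 18 bands
  bands <- assign_age_band(0:110)
  expect_false(anyNA(bands))
  expect_equal(levels(bands), age_band_levels())
})

test_that("person-year payer attribution is majority rule with ties going public", {
  claims <- tibble::tibble(
    person_id = c(rep("a", 4), rep("b", 2), rep("c", 4)),
    year = 2010L,
    payer_type = c("public", "public", "public", "private",
                   "private", "private",
                   "public", "public", "private", "private"))
  got <- assign_insurance(claims)
  expect_equal(setNames(got$insurance, got$person_id),
               c(a = "public", b = "private", c = "public"))
  expect_error(assign_insurance(claims[0, ]), "at least one claim")
})

test_that("stratified prevalence divides stratum cases by stratum population", {
  cohort <- tibble::tibble(
    person_id = sprintf("p%d", 1:6), year = 2010L,
    classification = "icd_only",
    sex = c("female", "female", "female", "male", "male", "female"),
    age_band = factor(c("50-54", "50-54", "55-59", "50-54", "55-59", "55-59"),
                      levels = age_band_levels()))
  census <- tidyr::expand_grid(county = "York",
                               sex = c("female", "male"),
                               age_band = c("50-54", "55-59"))
  census$population <- c(10, 20, 10, 20)  # f/50-54, f/55-59, m/50-54, m/55-59
  census$median_income <- 50000; census$pct_poverty <- 10
  census$pct_bachelors <- 30
  prev <- compute_prevalence(cohort, census, by = c("sex", "age_band"))
  expect_equal(prev$prevalence_pct[prev$stratum == "female/50-54"],
               100 * 2 / 10)
  expect_equal(prev$prevalence_pct[prev$stratum == "overall"],
               100 * 6 / 60)
  # conservation: stratum cases sum to the cohort size
  expect_equal(sum(prev$cases[prev$stratum != "overall"]), nrow(cohort))
  # row order of the cohort does not matter
  prev2 <- compute_prevalence(cohort[sample(6), ], census,
                              by = c("sex", "age_band"))
  expect_equal(dplyr::arrange(as_tbl_df(prev), stratum),
               dplyr::arrange(as_tbl_df(prev2), stratum))
  # a cohort stratum missing from the census is an error naming the stratum
  cohort_bad <- cohort
  cohort_bad$age_band[1] <- "60-64"
  expect_error(compute_prevalence(cohort_bad, census, by = c("sex", "age_band")),
               "absent from census")
})

test_that("the prevalence pipeline agrees with tables computed from truth labels", {
  sim <- simulate_claims(sim_config(n_persons = 400, years = 2010L,
                                    seed = 88L))
  coh <- identify_cohort(sim$medical, sim$pharmacy, sim$persons, years = 2010L)
  coh <- attach_demographics(coh, sim$persons)
  prev <- compute_prevalence(coh, sim$census, by = c("sex", "age_band"))
  truth_cases <- attach_demographics(
    sim$truth[sim$truth$is_case, c("person_id", "year")], sim$persons)
  prev_truth <- compute_prevalence(truth_cases, sim$census,
                                   by = c("sex", "age_band"))
  expect_equal(dplyr::arrange(as_tbl_df(prev), stratum),
               dplyr::arrange(as_tbl_df(prev_truth), stratum))
  # cases never exceed the realized denominators
  expect_true(all(prev$cases <= prev$population))
})

test_that("a planted sex effect is recovered within binomial error", {
  set.seed(9)
  # plant prevalence 0.35 in females, 0.25 in males directly on labels
  persons <- tibble::tibble(person_id = sprintf("p%d", 1:4000),
                            sex = rep(c("female", "male"), each = 2000),
                            birth_year = 1960L, county = "York")
  is_case <- rbinom(4000, 1, ifelse(persons$sex == "female", 0.35, 0.25)) == 1
  cohort <- attach_demographics(
    tibble::tibble(person_id = persons$person_id[is_case], year = 2010L),
    persons)
  census <- dplyr::count(
    dplyr::mutate(persons, age_band = as.character(assign_age_band(50))),
    county, sex, age_band, name = "population")
  census$median_income <- 45000; census$pct_poverty <- 12
  census$pct_bachelors <- 25
  prev <- compute_prevalence(cohort, census, by = "sex")
  pf <- prev$prevalence_pct[prev$stratum == "female"] / 100
  pm <- prev$prevalence_pct[prev$stratum == "male"] / 100
  expect_lt(abs(pf - 0.35), 3 * sqrt(0.35 * 0.65 / 2000))
  expect_lt(abs(pm - 0.25), 3 * sqrt(0.25 * 0.75 / 2000))
  expect_gt(pf, pm)
})

test_that("insurance splits sum to 100 and aggregate consistently across counties", {
  set.seed(21)
  n <- 1000
  cohort <- tibble::tibble(
    person_id = sprintf("p%d", 1:n), year = 2010L,
    classification = "icd_only",
    county = sample(c("York", "Knox", "Waldo"), n, TRUE),
    insurance = sample(c("public", "private"), n, TRUE,
                       prob = c(0.537, 0.463)))
  overall <- insurance_split(cohort)
  expect_equal(overall$public_pct + overall$private_pct, 100)
  by_county <- insurance_split(cohort, by = "county")
  expect_equal(by_county$public_pct + by_county$private_pct, rep(100, 3))
  # county splits weighted by county cohort size reproduce the overall split
  expect_equal(sum(by_county$public_pct * by_county$n) / sum(by_county$n),
               overall$public_pct)
  all_pub <- insurance_split(dplyr::mutate(cohort, insurance = "public"))
  expect_equal(c(all_pub$public_pct, all_pub$private_pct), c(100, 0))
})

test_that("attach_insurance pools medical and pharmacy claims per person-year", {
  medical <- dplyr::bind_rows(
    med_claim("a", "2010-01-01", "338.29", payer = "private"),
    med_claim("a", "2010-06-01", "460", payer = "public"))
  pharmacy <- rx_claim("a", as.Date("2010-03-01"), payer = "public")
  coh <- tibble::tibble(person_id = "a", year = 2010L,
                        classification = "icd_only")
  got <- attach_insurance(coh, medical, pharmacy)
  expect_equal(got$insurance, "public")  # 2 public vs 1 private
})
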