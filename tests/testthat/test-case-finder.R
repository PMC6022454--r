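test_that("the diagnosis rule honours the one-claim and 30-day-pair forms", {
  # a single highly-likely (338.x) claim qualifies on its own
  one <- evaluate_diagnosis_criterion(med_claim(date = "2010-06-01",
                                                codes = "338.29"))
  expect_true(one$icd_flag)
  expect_match(one$evidence, "^highly:338.29")

  # likely codes 25 days apart fail, 30 days apart qualify (at-least)
  pair25 <- dplyr::bind_rows(med_claim(date = "2010-01-10", codes = "724.2"),
                             med_claim(date = "2010-02-04", codes = "724.2"))
  expect_false(evaluate_diagnosis_criterion(pair25)$icd_flag)
  pair30 <- dplyr::bind_rows(med_claim(date = "2010-01-10", codes = "724.2"),
                             med_claim(date = "2010-02-09", codes = "719.41"))
  expect_true(evaluate_diagnosis_criterion(pair30)$icd_flag)

  # two likely codes on the same date are one diagnosis date, not two
  same_day <- med_claim(date = "2010-01-10", codes = c("724.2", "719.41"))
  expect_false(evaluate_diagnosis_criterion(same_day)$icd_flag)

  # separation uses the extreme dates over all likely claims
  spread <- dplyr::bind_rows(med_claim(date = "2010-01-10", codes = "724.2"),
                             med_claim(date = "2010-01-20", codes = "724.2"),
                             med_claim(date = "2010-03-01", codes = "729.1"))
  expect_true(evaluate_diagnosis_criterion(spread)$icd_flag)
  expect_error(
    evaluate_diagnosis_criterion(dplyr::bind_rows(
      med_claim("a", "2010-01-10", "724.2"),
      med_claim("b", "2010-02-20", "724.2"))),
    "one person")
})

test_that("headache/facial-pain/cancer-pain-only person-years are excluded, but an include pattern wins", {
  migraines <- dplyr::bind_rows(med_claim(date = "2010-01-05", codes = "346.90"),
                                med_claim(date = "2010-03-06", codes = "346.90"))
  res <- evaluate_diagnosis_criterion(migraines)
  expect_false(res$icd_flag)
  expect_true(res$excluded_only_flag)

  cancer <- med_claim(date = "2010-04-01", codes = "338.32")
  res2 <- evaluate_diagnosis_criterion(cancer)
  expect_false(res2$icd_flag)
  expect_true(res2$excluded_only_flag)

  mixed <- dplyr::bind_rows(migraines,
                            med_claim(date = "2010-05-01", codes = "338.29"))
  res3 <- evaluate_diagnosis_criterion(mixed)
  expect_true(res3$icd_flag)
  expect_false(res3$excluded_only_flag)
})

test_that("diagnosis flags match an all-pairs brute-force scan on fuzzed person-years", {
  set.seed(555)
  cfg <- code_config()
  pool <- c("338.29", "338.3", "724.2", "719.41", "346.90", "784.0", "460",
            "401.9")
  for (i in 1:80) {
    n <- sample(1:6, 1)
    codes <- sample(pool, n, replace = TRUE)
    dates <- as.Date("2010-01-01") + sample(0:364, n, replace = TRUE)
    claims <- tibble::tibble(person_id = "p1", service_date = dates,
                             icd9_codes = as.list(codes),
                             payer_type = "public")
    got <- evaluate_diagnosis_criterion(claims, cfg)
    expect_equal(got$icd_flag, oracle_dx_flag(codes, dates, cfg),
                 info = paste(codes, collapse = ","))
  }
})

test_that("raising the separation requirement never turns the flag from false to true", {
  set.seed(99)
  for (i in 1:30) {
    n <- sample(2:6, 1)
    claims <- tibble::tibble(
      person_id = "p1",
      service_date = as.Date("2010-01-01") + sample(0:364, n, TRUE),
      icd9_codes = as.list(sample(c("724.2", "729.1", "460"), n, TRUE)),
      payer_type = "public")
    f30 <- evaluate_diagnosis_criterion(claims,
                                        policy = finder_policy())$icd_flag
    f60 <- evaluate_diagnosis_criterion(
      claims, policy = finder_policy(min_separation_days = 60))$icd_flag
    expect_true(f30 || !f60)
  }
})

test_that("identify_cohort yields one record per qualifying person-year with a consistent classification", {
  persons <- tibble::tibble(person_id = c("p1", "p2", "p3", "p4"),
                            sex = "female", birth_year = 1960L,
                            county = "York")
  medical <- dplyr::bind_rows(
    med_claim("p1", "2010-02-01", "338.29"),          # dx in 2010
    med_claim("p1", "2009-03-01", "338.4"),           # dx in 2009 too
    med_claim("p3", "2010-01-05", "346.90"),          # excluded-only
    med_claim("p3", "2010-04-05", "346.90"))
  pharmacy <- dplyr::bind_rows(
    rx_claim("p1", as.Date("2010-03-01"), supply = 95L),  # both routes 2010
    rx_claim("p2", as.Date("2010-05-01"), supply = 90L),  # opioid only
    rx_claim("p4", as.Date("2010-05-01"), supply = 89L))  # near miss
  coh <- identify_cohort(medical, pharmacy, persons, years = c(2009, 2010))

  p1 <- coh[coh$person_id == "p1", ]
  expect_equal(nrow(p1), 2L)  # one record per qualifying year
  expect_equal(p1$classification[p1$year == 2010], "both")
  expect_equal(p1$classification[p1$year == 2009], "icd_only")
  expect_equal(coh$classification[coh$person_id == "p2"], "opioid_only")
  p3 <- coh[coh$person_id == "p3", ]
  expect_equal(p3$classification, "none")
  expect_true(p3$excluded_only_flag)
  expect_false("p4" %in% coh$person_id)
  # flags and classification agree everywhere
  expect_true(all((coh$icd_flag | coh$opioid_flag) ==
                    (coh$classification != "none")))
  expect_error(identify_cohort(medical, pharmacy,
                               dplyr::bind_rows(persons, persons[1, ]),
                               years = 2010),
               "duplicate person_id")
})

test_that("persons absent from the person table are still evaluable and flagged", {
  pharmacy <- rx_claim("ghost", as.Date("2010-01-01"), supply = 120L)
  coh <- identify_cohort(make_empty_medical(), pharmacy,
                         tibble::tibble(person_id = "p1", sex = "male",
                                        birth_year = 1950L, county = "Knox"),
                         years = 2010)
  expect_equal(coh$classification, "opioid_only")
  expect_false(coh$demographics_known)
})

test_that("criterion breakdown partitions the cohort and reports shares of it", {
  records <- tibble::tibble(
    person_id = sprintf("p%d", 1:117), year = 2010L,
    classification = rep(c("icd_only", "both", "opioid_only"),
                         c(100, 14, 3)))
  b <- criterion_breakdown(records, 2010)
  expect_equal(b$cohort_size, 117L)
  expect_equal(b$icd_only + b$both + b$opioid_only, b$cohort_size)
  expect_equal(b$opioid_criterion_total, 17L)
  expect_equal(round(c(b$pct_icd_only, b$pct_both, b$pct_opioid_only), 1),
               c(85.5, 12.0, 2.6))

  all_icd <- tibble::tibble(person_id = "q", year = 2009L,
                            classification = "icd_only")
  b2 <- criterion_breakdown(all_icd, 2009)
  expect_equal(c(b2$pct_icd_only, b2$pct_both, b2$pct_opioid_only),
               c(100, 0, 0))

  empty <- criterion_breakdown(records[0, ], 2006)
  expect_equal(empty$cohort_size, 0L)
  expect_true(is.na(empty$pct_icd_only))
})
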