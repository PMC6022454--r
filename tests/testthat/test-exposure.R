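day <- function(year, d) as.Date(sprintf("%d-01-01", year)) + (d - 1L)

fills_on_days <- function(days, supply = 30L, drug = "OXYCODONE",
                          year = 2010L) {
  rx_claim("p1", day(year, days), drug = drug, supply = supply)
}

test_that("chained, gapped and overlapping fills produce the day-grid coverage", {
  # three back-to-back 30-day fills: one 90-day run (value from the grid oracle)
  tl <- build_exposure_timeline(fills_on_days(c(1, 31, 61)), year = 2010)
  expect_equal(nrow(tl$intervals), 1L)
  expect_equal(tl$max_consecutive_days, 90L)
  expect_equal(tl$max_consecutive_days,
               oracle_max_run(fills_on_days(c(1, 31, 61)), 2010))

  # one-day gap at day 31 splits the run
  tl2 <- build_exposure_timeline(fills_on_days(c(1, 32)), year = 2010)
  expect_equal(nrow(tl2$intervals), 2L)
  expect_equal(tl2$max_consecutive_days, 30L)
  expect_equal(tl2$max_consecutive_days,
               oracle_max_run(fills_on_days(c(1, 32)), 2010))

  # overlapping same-drug fills: union counts coverage once (44 days),
  # stockpile shifts the refill (60 days); both match the oracle
  ov <- fills_on_days(c(1, 15))
  tl_u <- build_exposure_timeline(ov, policy = finder_policy(), year = 2010)
  expect_equal(tl_u$max_consecutive_days, 44L)
  expect_equal(tl_u$max_consecutive_days, oracle_max_run(ov, 2010, "union"))
  tl_s <- build_exposure_timeline(
    ov, policy = finder_policy(overlap_policy = "stockpile"), year = 2010)
  expect_equal(tl_s$max_consecutive_days, 60L)
  expect_equal(tl_s$max_consecutive_days,
               oracle_max_run(ov, 2010, "stockpile"))

  # stockpiling is per drug: overlapping *different* drugs are not shifted
  two_drugs <- dplyr::bind_rows(fills_on_days(1, drug = "OXYCODONE"),
                                fills_on_days(15, drug = "MORPHINE"))
  tl_d <- build_exposure_timeline(
    two_drugs, policy = finder_policy(overlap_policy = "stockpile"),
    year = 2010)
  expect_equal(tl_d$max_consecutive_days, 44L)
})

test_that("no opioid fills means zero coverage, and non-opioid fills are ignored", {
  expect_equal(build_exposure_timeline(
    rx_claim("p1", character(0))[0, ], year = 2010)$max_consecutive_days, 0L)
  expect_message(
    tl <- build_exposure_timeline(fills_on_days(1, drug = "LISINOPRIL"),
                                  year = 2010),
    "non-opioid")
  expect_equal(tl$max_consecutive_days, 0L)
})

test_that("the 90-day threshold is an at-least comparison", {
  pol <- finder_policy()
  t89 <- build_exposure_timeline(fills_on_days(1, supply = 89L), year = 2010)
  t90 <- build_exposure_timeline(fills_on_days(1, supply = 90L), year = 2010)
  t365 <- build_exposure_timeline(fills_on_days(1, supply = 365L), year = 2010)
  expect_false(evaluate_opioid_criterion(t89, pol))
  expect_true(evaluate_opioid_criterion(t90, pol))
  expect_true(evaluate_opioid_criterion(t365, pol))
})

test_that("coverage is clipped to the calendar year before the 90-day test", {
  # 100 days of coverage straddling New Year: 50 in each year
  straddle <- rx_claim("p1", as.Date("2010-11-12"), supply = 100L)
  t2010 <- build_exposure_timeline(straddle, year = 2010)
  t2011 <- build_exposure_timeline(straddle, year = 2011)
  expect_equal(t2010$max_consecutive_days, 50L)
  expect_equal(t2011$max_consecutive_days, 50L)
  expect_false(evaluate_opioid_criterion(t2010))
  expect_false(evaluate_opioid_criterion(t2011))
  # the unclipped policy credits the full run to every year it touches
  pol_u <- finder_policy(clip_to_year = FALSE)
  expect_equal(build_exposure_timeline(straddle, policy = pol_u,
                                       year = 2011)$max_consecutive_days,
               100L)
  # a fill late in the prior year still covers early days of this year
  late <- rx_claim("p1", as.Date("2009-12-27"), supply = 10L)
  expect_equal(build_exposure_timeline(late, year = 2010)$max_consecutive_days,
               5L)
})

test_that("grace gaps bridge small uncovered holes, including the gap days", {
  gapped <- fills_on_days(c(1, 34))  # covered 1-30 and 34-63, 3-day hole
  expect_equal(build_exposure_timeline(
    gapped, policy = finder_policy(grace_gap_days = 2),
    year = 2010)$max_consecutive_days, 30L)
  expect_equal(build_exposure_timeline(
    gapped, policy = finder_policy(grace_gap_days = 3),
    year = 2010)$max_consecutive_days, 63L)
  expect_equal(oracle_max_run(gapped, 2010, grace = 3L), 63L)
})

test_that("interval construction matches the day-grid oracle on fuzzed fill sets", {
  set.seed(90210)
  for (i in 1:120) {
    fills <- random_fills()
    grace <- sample(0:7, 1)
    for (ovl in c("union", "stockpile")) {
      pol <- finder_policy(grace_gap_days = grace, overlap_policy = ovl)
      tl <- build_exposure_timeline(fills, policy = pol, year = 2010)
      expect_equal(tl$max_consecutive_days,
                   oracle_max_run(fills, 2010, ovl, grace),
                   info = sprintf("case %d policy %s grace %d", i, ovl, grace))
      # timeline invariants: sorted, disjoint, non-adjacent beyond grace
      iv <- tl$intervals
      if (nrow(iv) > 1) {
        expect_true(all(diff(as.integer(iv$start)) > 0))
        gaps <- as.integer(iv$start[-1]) - as.integer(iv$end[-nrow(iv)]) - 1L
        expect_true(all(gaps > grace))
      }
    }
  }
})

test_that("adding a fill never shortens the longest run", {
  set.seed(1234)
  for (i in 1:40) {
    fills <- random_fills(n_max = 10L)
    extra <- random_fills(n_max = 1L)
    base <- build_exposure_timeline(fills, year = 2010)$max_consecutive_days
    more <- build_exposure_timeline(dplyr::bind_rows(fills, extra),
                                    year = 2010)$max_consecutive_days
    expect_gte(more, base)
  }
})
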