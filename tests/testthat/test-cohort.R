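test_that("eligibility schedule follows the printed rollout rules", {
  sched <- assign_eligibility(as.Date(c("1933-09-01", "1933-09-02", "1935-06-15",
                                        "1926-01-01", "1937-01-01", "1940-06-01")))
  expect_equal(as.character(sched$cohort_label),
               c("never_eligible", "catchup_year_1", "catchup_year_2",
                 "never_eligible", "catchup_year_3", "post_2017_rule"))
  expect_equal(sched$eligibility_start[2], as.Date("2013-09-01"))
  expect_equal(sched$eligibility_end[2], as.Date("2014-08-31"))
  expect_equal(sched$eligibility_start[3], as.Date("2014-09-01"))
  expect_equal(sched$eligibility_end[3], as.Date("2015-08-31"))
  expect_true(all(is.na(sched$eligibility_start[c(1, 4)])))
  # post-2017 rule: eligible from the 78th birthday, no earlier than 2017-04-01
  expect_equal(sched$eligibility_start[6], as.Date("2018-06-01"))
  expect_error(assign_eligibility(as.Date("1950-01-01")), "outside supported span")
})

test_that("running-variable centering resolves the straddling week correctly", {
  # 1933-09-02 is a Saturday: its week (Mon Aug 28) holds 2 of 7 eligible days,
  # so the majority rule assigns it to the ineligible side
  expect_identical(center_running_variable(as.Date("1933-09-04")), 0L)
  expect_identical(center_running_variable(as.Date("1933-08-28")), -1L)
  expect_identical(center_running_variable(as.Date("1933-08-21")), -2L)
  expect_identical(center_running_variable(as.Date("1933-08-28"),
                                           straddle_rule = "eligible"), 0L)
  expect_identical(center_running_variable(as.Date("1933-09-04"),
                                           straddle_rule = "eligible"), 1L)
  expect_true(is.na(center_running_variable(as.Date("1933-08-28"),
                                            straddle_rule = "drop")))
  expect_identical(center_running_variable(as.Date("1933-09-04"),
                                           straddle_rule = "drop"), 0L)
  expect_error(center_running_variable(as.Date("1933-09-02")), "Mondays")
  # consecutive Mondays map to consecutive integers under every rule
  mons <- seq(as.Date("1930-01-06"), by = 7, length.out = 400)
  for (rule in c("majority", "eligible", "ineligible")) {
    xs <- center_running_variable(mons, straddle_rule = rule)
    expect_true(all(diff(xs) == 1L))
  }
})

test_that("study cohorts partition on baseline cognitive status", {
  ppl <- make_persons(
    10,
    baseline_dementia = rep(c(TRUE, FALSE), c(3, 7)),
    baseline_cognitive_impairment = rep(c(TRUE, FALSE), c(5, 5))
  )
  no_ci <- build_cohort(ppl, "no_cognitive_impairment")
  dem <- build_cohort(ppl, "living_with_dementia")
  expect_equal(nrow(no_ci), 5)
  expect_equal(nrow(dem), 3)
  expect_length(intersect(no_ci$person_id, dem$person_id), 0)
  # cognitive impairment without dementia excludes from both
  ci_only <- ppl$person_id[ppl$baseline_cognitive_impairment & !ppl$baseline_dementia]
  expect_length(ci_only, 2)
  expect_false(any(ci_only %in% c(no_ci$person_id, dem$person_id)))
  expect_error(build_cohort(ppl, "everyone"))
})

test_that("outcome ascertainment honours windows, grace and event filters", {
  idx <- as.Date("2013-09-01")
  p <- make_persons(1, mci_date = idx + 14)
  expect_equal(ascertain_outcome(p, outcome_spec("mci")), 1L)
  expect_equal(ascertain_outcome(p, outcome_spec("mci", grace_period_weeks = 4)), 0L)

  p2 <- make_persons(1, mci_date = idx + 100, dementia_date = idx + 100 + 61)
  expect_equal(ascertain_outcome(p2, outcome_spec("mci")), 1L)
  expect_equal(ascertain_outcome(p2, outcome_spec("mci_no_dementia_3m")), 0L)
  expect_equal(ascertain_outcome(p2, outcome_spec("mci_no_dementia_6m")), 0L)
  p3 <- make_persons(1, mci_date = idx + 100, dementia_date = idx + 100 + 160)
  expect_equal(ascertain_outcome(p3, outcome_spec("mci_no_dementia_3m")), 1L)
  expect_equal(ascertain_outcome(p3, outcome_spec("mci_no_dementia_6m")), 0L)

  # dementia contributing but not underlying: neither a dementia death nor a
  # dementia-free death, but an all-cause death
  p4 <- make_persons(1, death_date = idx + 300, underlying_cause = "I25",
                     contributing_causes = "I10;F03")
  expect_equal(ascertain_outcome(p4, outcome_spec("death_due_to_dementia")), 0L)
  expect_equal(ascertain_outcome(p4, outcome_spec("death_nondementia")), 0L)
  expect_equal(ascertain_outcome(p4, outcome_spec("death_all_cause")), 1L)
  p5 <- make_persons(1, death_date = idx + 300, underlying_cause = "F01")
  expect_equal(ascertain_outcome(p5, outcome_spec("death_due_to_dementia")), 1L)

  # events outside the follow-up window never count
  p6 <- make_persons(1, mci_date = as.Date("2023-01-01"))
  expect_equal(ascertain_outcome(p6, outcome_spec("mci")), 0L)
  expect_equal(ascertain_outcome(p6, outcome_spec("mci", follow_up_years = 3)), 0L)

  # dementia recorded after death is a data-integrity error
  p7 <- make_persons(1, dementia_date = idx + 400, death_date = idx + 100)
  expect_error(ascertain_outcome(p7, outcome_spec("death_all_cause")),
               "inconsistent event ordering")
})

test_that("follow-up windows nest monotonically", {
  ppl <- gen_cohort(4000, seed = 3)
  prev <- rep(0L, nrow(ppl))
  for (t in c(1L, 3L, 5L, 7L, 9L)) {
    cur <- ascertain_outcome(ppl, outcome_spec("mci", follow_up_years = t))
    expect_true(all(cur >= prev))
    prev <- cur
  }
})

test_that("eligibility in the analysis cohort is the sign of the running variable", {
  ppl <- gen_cohort(4000, seed = 4)
  ac <- analysis_cohort(ppl, "all", "mci")
  expect_true(all(ac$eligible == (ac$centered_wob >= 0)))
  # never-eligible persons are never vaccinated under one-sided noncompliance
  expect_true(all(!ac$vaccinated[!ac$eligible]))
  expect_false(any(is.na(ac$outcome)))
})

test_that("staggered index dates mirror across the threshold", {
  spec1y <- outcome_spec("mci", follow_up_years = 1,
                         index_date_policy = "own_eligibility_date")
  # a never-eligible person born ~2 years before the threshold inherits the
  # index date of the eligible person born ~2 years after it (year-2 window,
  # 2014-09-01): an event in early 2015 is inside that 1-year window, one in
  # early 2016 is not
  p_mirr <- make_persons(1, date_of_birth = as.Date("1931-08-20"),
                         mci_date = as.Date("2015-01-15"))
  expect_equal(ascertain_outcome(p_mirr, spec1y), 1L)
  p_mirr$mci_date <- as.Date("2016-01-15")
  expect_equal(ascertain_outcome(p_mirr, spec1y), 0L)
  # under the program-start policy the same early-2015 event is ascertained
  p_mirr$mci_date <- as.Date("2013-10-15")
  expect_equal(ascertain_outcome(p_mirr, outcome_spec("mci", follow_up_years = 1)), 1L)
  expect_equal(ascertain_outcome(p_mirr, spec1y), 0L)
})
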