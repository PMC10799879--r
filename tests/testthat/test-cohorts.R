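test_that("DOB partitions are contiguous, balanced and complementary", {
  pats <- toy_patients(1000)
  pats$dob <- as.Date("1930-01-01") + sample.int(20000, 1000, replace = TRUE)
  parts <- assign_dob_partitions(pats, k = 100)
  expect_true(all(table(parts$dob_partition) == 10))
  expect_equal(parts$dob_partition[which.min(parts$dob)], 0L)
  expect_equal(parts$dob_partition[which.max(parts$dob)], 99L)
  expect_identical(parts$is_even, parts$dob_partition %% 2 == 0)
  expect_true(all(xor(parts$is_even, !parts$is_even)))
  # contiguity: partition is monotone in dob rank
  o <- order(parts$dob, parts$patient_id)
  expect_true(all(diff(parts$dob_partition[o]) >= 0))
  # uneven division stays within one
  p2 <- assign_dob_partitions(pats[1:103, ], k = 10)
  expect_true(diff(range(table(p2$dob_partition))) <= 1)
  expect_error(assign_dob_partitions(pats[1:5, ], k = 10),
               class = "riskpipe_size_error")
  expect_error(assign_dob_partitions(pats, k = 1), class = "riskpipe_input_error")
})

test_that("rcc pairs each case with gap-exact controls from its own partition", {
  pop <- test_pop(2000, seed = 3)
  cl <- classify_events(pop)
  lab <- build_combined_outcome(cl, c(as.Date("2007-08-16"),
                                      pop$config$calendar_range[2]),
                                patient_ids = pop$patients$patient_id)
  cfg <- rcc_config(k_partitions = 20, seed = 5)
  rcc <- build_rcc(pop, lab, cfg)
  cases <- rcc[rcc$is_case, ]
  ctrls <- rcc[!rcc$is_case, ]
  expect_equal(nrow(ctrls), 4 * nrow(cases))
  # fixed 45-day gap for cases and controls alike
  expect_true(all(rcc$event_date - rcc$time_of_prediction == 45))
  # identical partition distribution of cases and controls
  expect_equal(table(ctrls$dob_partition) / 4, table(cases$dob_partition))
  # per-case controls are distinct and from the case's partition
  chk <- ctrls |> dplyr::group_by(case_id) |>
    dplyr::summarise(dup = anyDuplicated(patient_id) > 0,
                     nparts = dplyr::n_distinct(dob_partition))
  expect_true(all(!chk$dup))
  case_part <- cases$dob_partition[match(chk$case_id, cases$case_id)]
  expect_true(all(ctrls$dob_partition ==
                    cases$dob_partition[match(ctrls$case_id, cases$case_id)]))
  # control pseudo-outcome dates fall within the span of case outcome dates
  spans <- cases |> dplyr::group_by(dob_partition) |>
    dplyr::summarise(lo = min(event_date), hi = max(event_date))
  cc <- dplyr::left_join(ctrls, spans, by = "dob_partition")
  expect_true(all(cc$event_date >= cc$lo & cc$event_date <= cc$hi))
  # reproducibility
  rcc2 <- build_rcc(pop, lab, cfg)
  expect_identical(as.data.frame(rcc), as.data.frame(rcc2))
})

test_that("rcc controls over-represent heavy visit users (visit-weighted draw)", {
  pop <- test_pop(2000, seed = 3)
  cl <- classify_events(pop)
  lab <- build_combined_outcome(cl, c(as.Date("2007-08-16"),
                                      pop$config$calendar_range[2]),
                                patient_ids = pop$patients$patient_id)
  rcc <- build_rcc(pop, lab, rcc_config(k_partitions = 20, seed = 5))
  visits <- pop$events |> dplyr::filter(startsWith(variable, "visit_")) |>
    dplyr::count(patient_id, name = "n_visits")
  nv <- function(ids) {
    out <- visits$n_visits[match(ids, visits$patient_id)]
    ifelse(is.na(out), 0, out)
  }
  ctrl_ids <- rcc$patient_id[!rcc$is_case]
  noncase_ids <- lab$patient_id[lab$component == "none"]
  expect_gt(mean(nv(ctrl_ids)), mean(nv(noncase_ids)))
})

test_that("rcc reports a shortfall instead of silently reusing controls", {
  # two patients share a partition: one case, one eligible control
  pats <- toy_patients(4)
  pats$dob <- as.Date(c("1950-01-01", "1950-06-01", "1970-01-01", "1970-06-01"))
  d <- as.Date("2015-01-01")
  ev <- tibble::tibble(
    patient_id = c(1L, 2L, 2L, 3L, 4L),
    date = c(d, d - 10, d + 10, d, d),
    variable = c("suicide_attempt", "visit_office", "visit_office",
                 "suicide_attempt", "visit_office"),
    code_system = c("ICD9", "visit", "visit", "ICD9", "visit")
  )
  pop <- toy_population(pats, ev)
  cl <- classify_events(pop)
  lab <- build_combined_outcome(cl, c(as.Date("2007-08-16"), as.Date("2022-01-01")),
                                patient_ids = pats$patient_id)
  cfg <- rcc_config(controls_per_case = 4, k_partitions = 2, seed = 1,
                    reuse_controls = FALSE)
  expect_warning(rcc <- build_rcc(pop, lab, cfg), "shortfall")
  sf <- attr(rcc, "shortfall")
  expect_false(is.null(sf))
  expect_true(all(sf$available < sf$requested))
})

test_that("calendar cohort applies lookback inclusion and exclusion window", {
  pats <- toy_patients(5)
  pred <- as.Date("2017-01-01")
  ev <- tibble::tibble(
    patient_id = c(1L, 2L, 3L, 3L, 4L, 5L),
    date = c(pred - 30, pred - 130, pred - 10, pred + 3, pred - 10, pred - 10),
    variable = c("visit_office", "visit_office", "visit_office",
                 "suicide_attempt", "visit_office", "visit_office"),
    code_system = c(rep("visit", 3), "ICD10", "visit", "visit")
  )
  # patient 4: suicide death 100 days after prediction
  deaths <- tibble::tibble(patient_id = 4L, date = pred + 100,
                           cause_codes = "T14.91", code_system = "ICD10")
  pop <- toy_population(pats, ev, deaths = deaths)
  cl <- classify_events(pop)
  coh <- build_calendar_cohort(pop, cl, pred, k_partitions = 2)
  # patient 2's last visit was >3 months before prediction: excluded
  expect_false(2L %in% coh$patient_id)
  expect_true(all(c(1L, 3L, 4L, 5L) %in% coh$patient_id))
  # attempt 3 days after prediction falls in the exclusion week: control
  expect_false(coh$is_case[coh$patient_id == 3L])
  # suicide 100 days after prediction: case
  expect_true(coh$is_case[coh$patient_id == 4L])
  expect_equal(coh$component[coh$patient_id == 4L], "suicide")
  # suicide-target labelling ignores attempts entirely
  ev2 <- dplyr::mutate(ev, date = dplyr::if_else(variable == "suicide_attempt",
                                                 pred + 60, date))
  pop2 <- toy_population(pats, ev2, deaths = deaths)
  coh2 <- build_calendar_cohort(pop2, classify_events(pop2), pred,
                                k_partitions = 2, target = "suicide")
  expect_false(coh2$is_case[coh2$patient_id == 3L])
  expect_true(coh2$is_case[coh2$patient_id == 4L])
  expect_error(build_calendar_cohort(pop, cl, "2050-01-01", k_partitions = 2),
               class = "riskpipe_input_error")
})

test_that("event cohort censors on death only, not on loss to follow-up", {
  pats <- toy_patients(4)
  t0 <- as.Date("2007-07-01")
  ev <- tibble::tibble(
    patient_id = c(1L, 2L, 3L, 3L, 4L),
    date = c(t0 + 4000, t0 + 10, t0 + 20, t0 + 20 + round(6 * 365.25), t0 + 30),
    variable = c("visit_psych", "visit_psych", "visit_psych",
                 "suicide_attempt", "visit_psych"),
    code_system = c("visit", "visit", "visit", "ICD9", "visit")
  )
  # patient 2 dies (non-suicide) 4 years after trigger
  deaths <- tibble::tibble(patient_id = 2L, date = t0 + 10 + round(4 * 365.25),
                           cause_codes = "I21.9", code_system = "ICD10")
  pop <- toy_population(pats, ev, deaths = deaths)
  cl <- classify_events(pop)
  coh <- build_event_cohort(pop, cl, "psych", k_partitions = 2)
  # patient 1's only qualifying visit is after the 3-year initiation window
  expect_false(1L %in% coh$patient_id)
  expect_equal(attr(coh, "excluded_n"), 1L)
  # patient 2: censored at death, ~4 years
  r2 <- coh[coh$patient_id == 2L, ]
  expect_true(r2$censored)
  expect_equal(r2$time_to_event_days, round(4 * 365.25))
  # patient 3: outcome at year 6 despite no visits in between -> event
  r3 <- coh[coh$patient_id == 3L, ]
  expect_false(r3$censored)
  expect_equal(r3$time_to_event_days, round(6 * 365.25))
  # patient 4: no event, no death -> administrative censoring at horizon
  r4 <- coh[coh$patient_id == 4L, ]
  expect_true(r4$censored)
  expect_gte(r4$time_to_event_days, round(9 * 365.25))
})
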