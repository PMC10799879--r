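toy_cohort <- function(n, top = as.Date("2017-01-01")) {
  tibble::tibble(row_id = seq_len(n), patient_id = seq_len(n),
                 time_of_prediction = rep_len(top, n))
}

test_that("binary encoding is presence-based with a fixed column layout", {
  top <- as.Date("2017-01-01")
  coh <- toy_cohort(2)
  vars <- c("a", "b", "c")
  ev <- tibble::tibble(
    patient_id = c(1L, 1L, 1L),
    date = c(top - 10, top - 20, top - 200),
    variable = c("a", "a", "b")
  )
  enc <- encode_binary(ev, coh, vars)
  expect_equal(ncol(enc$x), length(vars) * 8)
  expect_equal(sum(enc$x[1, ]), 2) # two repeats of 'a' in one bin collapse to one
  expect_equal(unname(enc$x[1, "a|bin0"]), 1L)
  expect_equal(unname(enc$x[1, "b|bin2"]), 1L) # ~200 days before lands in bin 2
  expect_equal(sum(enc$x[2, ]), 0) # no events: all-zero row
  # boundary date joins the more recent bin (checked against the day scan)
  sched <- make_time_bins(top)
  evb <- tibble::tibble(patient_id = 1L, date = sched$start[3], variable = "a")
  encb <- encode_binary(evb, toy_cohort(1), "a")
  expect_equal(unname(which(encb$x[1, ] == 1)), 3) # bin 2, zero-based
  # events after the prediction date are a hard leakage failure
  evf <- tibble::tibble(patient_id = 1L, date = top + 5, variable = "a")
  expect_error(encode_binary(evf, toy_cohort(1), "a"),
               class = "riskpipe_leakage_error")
})

test_that("lab categories impute forward then backward and reserve NA for empty windows", {
  top <- as.Date("2017-01-01")
  coh <- toy_cohort(3)
  sched <- make_time_bins(top)
  mid5 <- sched$start[6] + 10 # a date inside bin 5
  meas <- tibble::tibble(
    patient_id = c(1L, 2L),
    date = c(mid5, top - 10),
    lab = "pulse_pressure",
    value = c(60, 40)
  )
  enc <- encode_lab(meas, coh, default_encoding_specs()["pulse_pressure"])
  # patient 1: 'high' measured in bin 5, carried to every other bin; no NA
  high_cols <- paste0("pulse_pressure|bin", 0:7, "|high")
  na_cols <- paste0("pulse_pressure|bin", 0:7, "|NA")
  expect_true(all(enc$x[1, high_cols] == 1))
  expect_true(all(enc$x[1, na_cols] == 0))
  # patient 2: 40 mm Hg is the reference range -> all-zero indicators
  expect_equal(sum(enc$x[2, ]), 0)
  # patient 3: no measurements across the window -> NA in all eight bins
  expect_true(all(enc$x[3, na_cols] == 1))
  expect_equal(sum(enc$x[3, ]), 8)
})

test_that("imputation direction is forward in time first, then backward", {
  top <- as.Date("2017-01-01")
  sched <- make_time_bins(top)
  # two measurements: 'high' in bin 6, 'low' in bin 3
  meas <- tibble::tibble(
    patient_id = 1L,
    date = c(sched$start[7] + 5, sched$start[4] + 5),
    lab = "hemoglobin",
    value = c(17, 10)
  )
  enc <- encode_lab(meas, toy_cohort(1), default_encoding_specs()["hemoglobin"])
  pick <- function(b, lev) unname(enc$x[1, paste0("hemoglobin|bin", b, "|", lev)])
  expect_equal(unname(pick(6, "high")), 1L)
  expect_equal(unname(pick(3, "low")), 1L)
  # bins 4-5 carry bin 6's value forward in time; bins 0-2 carry bin 3 forward
  expect_true(all(vapply(4:5, pick, integer(1), lev = "high") == 1))
  expect_true(all(vapply(0:2, pick, integer(1), lev = "low") == 1))
  # bin 7 has nothing earlier: filled backward from bin 6
  expect_equal(unname(pick(7, "high")), 1L)
})

test_that("surveys encode NA-never-surveyed, reference low band, and item 9 separately", {
  top <- as.Date("2017-01-01")
  coh <- toy_cohort(3)
  meas <- tibble::tibble(
    patient_id = c(1L, 1L, 2L),
    date = rep(top - 50, 3),
    lab = c("phq9_total", "phq9_item9", "phq9_total"),
    value = c(17, 3, 2)
  )
  specs <- default_encoding_specs()[c("phq9_total", "phq9_item9")]
  enc <- encode_surveys(meas, coh, specs)
  expect_equal(unname(enc$x[1, "phq9_total|bin0|mod_severe"]), 1L)
  expect_equal(unname(enc$x[1, "phq9_item9|bin0|q9_3"]), 1L)
  # item 9 is its own variable in the metadata
  expect_setequal(unique(enc$meta$variable), c("phq9_total", "phq9_item9"))
  # patient 2 scored in the lowest band: reference, all-zero for the total
  tot_cols <- enc$meta$column[enc$meta$variable == "phq9_total"]
  expect_equal(sum(enc$x[2, tot_cols] [!grepl("NA", tot_cols)]), 0)
  # patient 3 never surveyed: NA category in all bins
  expect_true(all(enc$x[3, paste0("phq9_total|bin", 0:7, "|NA")] == 1))
  bad <- dplyr::mutate(meas, value = c(40, 3, 2))
  expect_error(encode_surveys(bad, coh, specs),
               class = "riskpipe_validation_error")
})

test_that("imputation never manufactures NA: NA iff zero measurements in window", {
  pop <- test_pop(600, seed = 8)
  cl <- classify_events(pop)
  coh <- build_calendar_cohort(pop, cl, "2017-01-01", k_partitions = 10)
  f <- encode_features(pop, coh)
  sched <- make_time_bins(as.Date("2017-01-01"))
  meas <- derive_pulse_pressure(pop$labs)
  for (v in c("pulse_pressure", "hemoglobin", "phq9_total")) {
    na_cols <- paste0(v, "|bin", 0:7, "|NA")
    any_na <- rowSums(f$x[, na_cols, drop = FALSE]) > 0
    has_meas <- coh$patient_id %in% meas$patient_id[
      meas$lab == v & meas$date >= sched$start[8] & meas$date < sched$end[1]]
    expect_identical(unname(any_na), !has_meas)
    # NA is all-or-nothing across bins
    expect_true(all(rowSums(f$x[, na_cols, drop = FALSE]) %in% c(0, 8)))
  }
})

test_that("design-matrix column count and utilization index follow their definitions", {
  pop <- test_pop(600, seed = 8)
  cl <- classify_events(pop)
  coh <- build_calendar_cohort(pop, cl, "2017-01-01", k_partitions = 10)
  f <- encode_features(pop, coh)
  n_long <- length(pop$config$dx_variables) + length(pop$config$med_variables) + 2
  expect_equal(sum(f$meta$block == "longitudinal"), n_long * 8)
  util <- compute_utilization(f)
  expect_true(all(util >= 0 & util <= 600))
  # direct count for one row
  dx_cols <- f$meta$column[f$meta$block == "longitudinal" &
                             f$meta$variable %in% pop$config$dx_variables]
  expect_equal(util[5], sum(f$x[5, dx_cols]))
  ub <- utilization_bins(f)
  expect_true(all(ub >= 0 & ub <= 8))
  expect_true(all(ub <= pmin(util, 8)))
})

test_that("fine-tuning covariates aggregate any-bin presence into ten values", {
  top <- as.Date("2017-01-01")
  sched <- make_time_bins(top)
  pats <- toy_patients(2, dob = as.Date(c("1990-01-01", "1945-01-01")))
  pats$sex <- c("F", "M")
  ev <- tibble::tibble(
    patient_id = 1L,
    date = sched$start[8] + 3, # ideation only in the most distant bin
    variable = "suicide_ideation",
    code_system = "ICD9"
  )
  pop <- toy_population(pats, ev)
  coh <- tibble::tibble(row_id = 1:2, patient_id = 1:2,
                        time_of_prediction = top)
  f <- encode_features(pop, coh)
  ft <- f$finetune
  expect_equal(ncol(ft), 10)
  expect_equal(ft$suicide_ideation[1], 1L)
  expect_equal(ft$sex_female[1], 1L)
  expect_equal(ft$age_young[1], 1L) # age 27 < 55
  expect_equal(ft$age_old[2], 1L)   # age 72 > 65
  expect_equal(ft$usage[1], 1L)
  # patient 2: no events, reference demographics -> all indicators zero
  expect_equal(ft$usage[2], 0L)
  expect_true(all(ft[2, c("sex_female", "race_black", "ethnicity_hispanic",
                          "age_young", "chronic_pain", "suicide_ideation",
                          "suicide_attempt", "overdose")] == 0))
})

test_that("encoding is row-independent under patient permutation", {
  pop <- test_pop(600, seed = 8)
  cl <- classify_events(pop)
  coh <- build_calendar_cohort(pop, cl, "2017-01-01", k_partitions = 10)
  f1 <- encode_features(pop, coh)
  perm <- withr::with_seed(2, sample(nrow(coh)))
  coh2 <- coh[perm, ]
  coh2$row_id <- seq_len(nrow(coh2))
  f2 <- encode_features(pop, coh2)
  expect_equal(unname(f2$x), unname(f1$x[perm, ]))
  expect_equal(f2$finetune, f1$finetune[perm, ])
})

test_that("demographics enter once by default and can replicate across bins", {
  pop <- test_pop(600, seed = 8)
  cl <- classify_events(pop)
  coh <- build_calendar_cohort(pop, cl, "2017-01-01", k_partitions = 10)[1:50, ]
  f1 <- encode_features(pop, coh)
  expect_equal(sum(f1$meta$block == "demographic"), 6)
  f2 <- encode_features(pop, coh, replicate_demographics = TRUE)
  expect_equal(sum(f2$meta$block == "demographic"), 48)
})

test_that("the full encoder passes the leakage audit", {
  pop <- test_pop(600, seed = 8)
  cl <- classify_events(pop)
  coh <- build_calendar_cohort(pop, cl, "2017-01-01", k_partitions = 10)
  f <- encode_features(pop, coh[1:80, ])
  expect_true(audit_leakage(f, pop))
})
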