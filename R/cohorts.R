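#' Partition patients into date-of-birth cohorts
#'
#' Patients are sorted by date of birth (ties broken by patient id) and split
#' into `k` contiguous partitions whose sizes differ by at most one. Even/odd
#' partition parity drives the train/test protocol.
#'
#' @param patients Tibble with `patient_id` and `dob`.
#' @param k Number of partitions (default 100, must be >= 2).
#' @return `patients` with added `dob_partition` (0..k-1) and `is_even`.
#' @export
assign_dob_partitions <- function(patients, k = 100) {
  if (k < 2) input_error("k must be at least 2")
  n <- nrow(patients)
  if (n < k) {
    abort(sprintf("fewer patients (%d) than partitions (%d)", n, k),
          class = "riskpipe_size_error")
  }
  r <- dob_rank(patients$dob, patients$patient_id)
  patients |>
    mutate(dob_partition = as.integer(floor((r - 1) * k / n)),
           is_even = .data$dob_partition %% 2L == 0L)
}

#' Configure the retrospective nested case-control design
#'
#' @param controls_per_case Controls drawn per case (default 4).
#' @param gap_days Fixed gap between time of prediction and (pseudo-)outcome
#'   date (default 45).
#' @param earliest_outcome_date Cases before this date are excluded so the
#'   full 7.5-year observation window is available (default the analogue of
#'   Aug 16, 2007 for a record system starting Jan 1, 2000).
#' @param reuse_controls May one patient serve as control for several cases?
#'   Within a single case's draw controls are always distinct; across cases
#'   reuse preserves the visit-weighted marginal design (default `TRUE`).
#' @param k_partitions Number of DOB partitions.
#' @param seed RNG seed for control sampling.
#' @return An `rcc_config` list.
#' @export
rcc_config <- function(controls_per_case = 4, gap_days = 45,
                       earliest_outcome_date = "2007-08-16",
                       reuse_controls = TRUE, k_partitions = 100, seed = 1L) {
  if (controls_per_case < 1) config_error("controls_per_case must be >= 1")
  if (gap_days < 0) config_error("gap_days must be >= 0")
  structure(
    list(controls_per_case = as.integer(controls_per_case),
         gap_days = as.integer(gap_days),
         earliest_outcome_date = as.Date(earliest_outcome_date),
         reuse_controls = isTRUE(reuse_controls),
         k_partitions = as.integer(k_partitions), seed = as.integer(seed)),
    class = "rcc_config"
  )
}

#' Build the matched retrospective nested case-control cohort
#'
#' Cases are patients with a combined-outcome event on or after the earliest
#' allowed outcome date; their time of prediction is a fixed gap before the
#' event. For each case, controls are drawn from the case's date-of-birth
#' partition among patients without any outcome event, by sampling patients
#' with probability proportional to their number of medical visits within the
#' span of case outcome dates in that partition (visit-weighted incidence
#' sampling); one of the eligible visits becomes the control's pseudo-outcome
#' date and the same gap defines its time of prediction.
#'
#' @param population An `emr_population`.
#' @param outcomes Combined-outcome labels from [build_combined_outcome()]
#'   covering all patients.
#' @param config An [rcc_config()].
#' @return A cohort tibble (one row per case/control) with a `shortfall`
#'   attribute listing partitions where the eligible pool could not supply the
#'   requested controls.
#' @export
build_rcc <- function(population, outcomes, config = rcc_config()) {
  stopifnot(inherits(config, "rcc_config"))
  parts <- assign_dob_partitions(population$patients, config$k_partitions)
  lab <- outcomes |>
    left_join(select(parts, "patient_id", "dob_partition"), by = "patient_id")
  cases <- lab |>
    filter(.data$component != "none",
           .data$event_date >= config$earliest_outcome_date)
  non_case_ids <- lab$patient_id[lab$component == "none"]
  visit_pool <- population$events |>
    filter(startsWith(.data$variable, "visit_"),
           .data$patient_id %in% non_case_ids) |>
    left_join(select(parts, "patient_id", "dob_partition"), by = "patient_id")

  withr::with_seed(config$seed, {
    out <- vector("list", 0L)
    shortfall <- list()
    for (pt in sort(unique(cases$dob_partition))) {
      pc <- filter(cases, .data$dob_partition == pt)
      span <- range(pc$event_date)
      pool <- visit_pool |>
        filter(.data$dob_partition == pt,
               .data$date >= span[1], .data$date <= span[2])
      by_pat <- split(as.integer(pool$date), pool$patient_id)
      pool_ids <- as.integer(names(by_pat))
      w <- lengths(by_pat)
      active <- rep(TRUE, length(pool_ids))
      ctrl <- vector("list", nrow(pc))
      for (i in seq_len(nrow(pc))) {
        avail <- which(active)
        m <- min(config$controls_per_case, length(avail))
        if (m < config$controls_per_case) {
          shortfall[[length(shortfall) + 1]] <- tibble(
            dob_partition = pt, case_patient_id = pc$patient_id[i],
            requested = config$controls_per_case, available = m)
        }
        if (m == 0L) next
        pick <- if (length(avail) == 1L) avail else
          avail[sample.int(length(avail), m, prob = w[avail])]
        vdate <- vapply(pick, function(j) {
          ds <- by_pat[[j]]
          ds[sample.int(length(ds), 1L)]
        }, integer(1))
        if (!config$reuse_controls) active[pick] <- FALSE
        ctrl[[i]] <- tibble(
          patient_id = pool_ids[pick],
          pseudo_outcome_date = as.Date(vdate, origin = "1970-01-01"),
          case_id = pc$patient_id[i], dob_partition = pt)
      }
      out[[length(out) + 1]] <- list_rbind(ctrl)
    }
    controls <- if (length(out)) list_rbind(out) else
      tibble(patient_id = integer(), pseudo_outcome_date = as.Date(character()),
             case_id = integer(), dob_partition = integer())
  })

  cohort <- bind_rows(
    cases |>
      transmute(.data$patient_id, design_tag = "Rcc",
                time_of_prediction = .data$event_date - config$gap_days,
                is_case = TRUE, component = .data$component,
                event_date = .data$event_date, .data$dob_partition,
                case_id = .data$patient_id),
    controls |>
      transmute(.data$patient_id, design_tag = "Rcc",
                time_of_prediction = .data$pseudo_outcome_date - config$gap_days,
                is_case = FALSE, component = "none",
                event_date = .data$pseudo_outcome_date, .data$dob_partition,
                case_id = .data$case_id)
  ) |>
    mutate(is_even = .data$dob_partition %% 2L == 0L,
           row_id = row_number())
  shortfall <- if (length(shortfall)) list_rbind(shortfall) else NULL
  if (!is.null(shortfall)) {
    warn(sprintf("Rcc control shortfall in %d case draw(s); see attr(,'shortfall')",
                 nrow(shortfall)))
  }
  structure(cohort, shortfall = shortfall)
}

#' Build a calendar-anchored prospective cohort
#'
#' Includes every patient with at least one recorded visit in the lookback
#' window before the prediction date. A patient is a case when the target
#' outcome occurs in the half-open follow-up window starting `exclusion_days`
#' after the prediction date (events inside the exclusion window are ignored,
#' preventing leakage of imminent outcomes).
#'
#' @param population An `emr_population`.
#' @param classified Classified outcome events from [classify_events()].
#' @param prediction_date The calendar anchor (e.g. the analogue of
#'   Jan 1, 2017).
#' @param lookback_months Prior-visit inclusion window (default 3; 4 is also a
#'   supported reading).
#' @param exclusion_days Post-prediction exclusion window (default 7).
#' @param followup_years Outcome follow-up horizon (default 2).
#' @param target `"combined"` or `"suicide"` (suicide-only labels).
#' @param k_partitions Number of DOB partitions.
#' @return A cohort tibble.
#' @export
build_calendar_cohort <- function(population, classified, prediction_date,
                                  lookback_months = 3, exclusion_days = 7,
                                  followup_years = 2,
                                  target = c("combined", "suicide"),
                                  k_partitions = 100) {
  target <- match.arg(target)
  prediction_date <- as.Date(prediction_date)
  cal <- population$config$calendar_range
  if (is.na(prediction_date) || prediction_date < cal[1] || prediction_date >= cal[2]) {
    input_error("prediction_date must lie inside the population's calendar range")
  }
  lb_start <- prediction_date %m-% period(months = as.integer(lookback_months))
  included <- population$events |>
    filter(startsWith(.data$variable, "visit_"),
           .data$date >= lb_start, .data$date < prediction_date) |>
    distinct(.data$patient_id)
  win <- c(prediction_date + exclusion_days,
           prediction_date %m+% years(as.integer(followup_years)))
  ev <- if (target == "suicide") {
    filter(classified, .data$component == "suicide")
  } else {
    classified
  }
  labels <- build_combined_outcome(ev, win, patient_ids = included$patient_id)
  parts <- assign_dob_partitions(population$patients, k_partitions)
  labels |>
    left_join(select(parts, "patient_id", "dob_partition"), by = "patient_id") |>
    transmute(.data$patient_id,
              design_tag = paste0("C", format(prediction_date, "%y")),
              time_of_prediction = prediction_date,
              is_case = .data$component != "none",
              component = .data$component, event_date = .data$event_date,
              .data$dob_partition,
              is_even = .data$dob_partition %% 2L == 0L,
              target = target) |>
    mutate(row_id = row_number())
}

#' Build an event-triggered time-to-event cohort
#'
#' The time of prediction is the first qualifying visit (psychiatric
#' evaluation or office visit) inside the initiation window; time to the
#' combined outcome is measured from it. Follow-up is right-censored on death
#' only — not on the last recorded visit — so patients who drop out of care
#' remain at risk until the administrative horizon.
#'
#' @param population An `emr_population`.
#' @param classified Classified outcome events from [classify_events()].
#' @param trigger `"psych"` (psychiatric evaluation) or `"office"`.
#' @param initiation_start Start of the initiation window (default the
#'   analogue of Jul 1, 2007).
#' @param initiation_years Width of the initiation window (default 3).
#' @param followup_years Follow-up horizon (default 10).
#' @param gap_days Outcomes within this gap after the trigger are ignored
#'   (default 7).
#' @param k_partitions Number of DOB partitions.
#' @return A cohort tibble with `time_to_event_days` and `censored`; the
#'   number of patients without a qualifying visit is reported in
#'   `attr(, "excluded_n")`.
#' @export
build_event_cohort <- function(population, classified,
                               trigger = c("psych", "office"),
                               initiation_start = "2007-07-01",
                               initiation_years = 3, followup_years = 10,
                               gap_days = 7, k_partitions = 100) {
  trigger <- match.arg(trigger)
  vvar <- paste0("visit_", trigger)
  t0 <- as.Date(initiation_start)
  t1 <- t0 %m+% years(as.integer(initiation_years))
  cal_end <- population$config$calendar_range[2]

  first_trigger <- population$events |>
    filter(.data$variable == vvar, .data$date >= t0, .data$date < t1) |>
    group_by(.data$patient_id) |>
    summarise(time_of_prediction = min(.data$date), .groups = "drop")
  excluded_n <- length(setdiff(population$patients$patient_id,
                               first_trigger$patient_id))

  horizon <- first_trigger$time_of_prediction %m+% years(as.integer(followup_years))
  horizon <- pmin(horizon, cal_end)

  prio <- c(suicide = 1L, attempt = 2L, overdose = 3L)
  first_event <- classified |>
    inner_join(first_trigger, by = "patient_id") |>
    filter(.data$date >= .data$time_of_prediction + gap_days) |>
    mutate(prio = prio[.data$component]) |>
    group_by(.data$patient_id) |>
    arrange(.data$date, .data$prio, .data$event_id, .by_group = TRUE) |>
    slice(1) |>
    ungroup() |>
    select("patient_id", event_date = "date", component = "component")

  deaths <- population$deaths |> select("patient_id", death_date = "date")
  parts <- assign_dob_partitions(population$patients, k_partitions)

  first_trigger |>
    mutate(horizon = horizon) |>
    left_join(first_event, by = "patient_id") |>
    left_join(deaths, by = "patient_id") |>
    mutate(
      event_ok = !is.na(.data$event_date) & .data$event_date < .data$horizon,
      censor_date = pmin(.data$horizon,
                         dplyr::coalesce(.data$death_date, .data$horizon)),
      is_case = .data$event_ok & .data$event_date <= .data$censor_date,
      end_date = dplyr::if_else(.data$is_case, .data$event_date, .data$censor_date),
      time_to_event_days = as.integer(.data$end_date - .data$time_of_prediction),
      censored = !.data$is_case
    ) |>
    filter(.data$time_to_event_days > 0) |>
    left_join(select(parts, "patient_id", "dob_partition"), by = "patient_id") |>
    transmute(.data$patient_id,
              design_tag = paste0("Cox", ifelse(trigger == "psych", "MH", "Visit")),
              .data$time_of_prediction, is_case = .data$is_case,
              component = dplyr::if_else(.data$is_case, .data$component,
                                         "none", missing = "none"),
              event_date = dplyr::if_else(.data$is_case, .data$event_date,
                                          as.Date(NA)),
              .data$dob_partition,
              is_even = .data$dob_partition %% 2L == 0L,
              .data$time_to_event_days, censored = .data$censored) |>
    mutate(row_id = row_number()) |>
    structure(excluded_n = excluded_n)
}
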