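#' Default longitudinal diagnosis-variable catalogue
#'
#' The first twenty variables carry clinically meaningful names (mental-health
#' diagnoses, substance use, utilization markers, serious illness); the
#' remainder are anonymous filler diagnoses with decaying prevalence. All are
#' coded per visit as present/absent.
#'
#' @param n Number of diagnosis variables (default 75).
#' @return Character vector of variable names.
#' @export
default_dx_variables <- function(n = 75) {
  core <- c(
    "suicide_ideation", "chronic_pain", "depression", "anxiety", "ptsd",
    "substance_use", "opioid_use", "alcohol_use", "bipolar", "schizophrenia",
    "ed_visit", "metastatic_cancer", "cancer", "tbi", "concussion",
    "homelessness", "personality_disorder", "sleep_disorder", "back_pain",
    "fall_accident"
  )
  if (n <= length(core)) return(core[seq_len(n)])
  c(core, sprintf("dx_%02d", seq(length(core) + 1, n)))
}

default_med_variables <- function() {
  c("med_antidepressant", "med_anxiolytic", "med_opioid", "med_antipsychotic",
    "med_mood_stabilizer", "med_stimulant", "med_sedative", "med_statin",
    "proc_psychotherapy", "proc_mh_eval")
}

#' Default per-visit emission probabilities for longitudinal variables
#'
#' @param dx_variables,med_variables Variable name vectors.
#' @return Tibble with columns `variable`, `type` (dx/med) and `prevalence`
#'   (per-visit emission probability).
#' @export
default_variable_prevalence <- function(dx_variables = default_dx_variables(),
                                        med_variables = default_med_variables()) {
  core_prev <- c(
    suicide_ideation = 0.010, chronic_pain = 0.080, depression = 0.070,
    anxiety = 0.060, ptsd = 0.050, substance_use = 0.030, opioid_use = 0.025,
    alcohol_use = 0.035, bipolar = 0.012, schizophrenia = 0.008,
    ed_visit = 0.060, metastatic_cancer = 0.004, cancer = 0.020, tbi = 0.006,
    concussion = 0.006, homelessness = 0.010, personality_disorder = 0.008,
    sleep_disorder = 0.040, back_pain = 0.070, fall_accident = 0.015
  )
  dx_prev <- vapply(seq_along(dx_variables), function(i) {
    v <- dx_variables[i]
    if (v %in% names(core_prev)) core_prev[[v]] else 0.03 * exp(-0.05 * i) + 0.002
  }, numeric(1))
  med_prev <- c(0.060, 0.030, 0.050, 0.015, 0.010, 0.008, 0.020, 0.080, 0.040, 0.020)
  bind_rows(
    tibble(variable = dx_variables, type = "dx", prevalence = dx_prev),
    tibble(variable = med_variables, type = "med",
           prevalence = med_prev[seq_along(med_variables)])
  )
}

#' Ground-truth risk model for outcome generation
#'
#' The generator draws suicide, suicide-attempt and overdose events from a
#' discrete-time (yearly) Bernoulli hazard whose logit is a linear function of
#' the patient's trailing eight-bin feature state: per-(variable, bin)
#' coefficients shared across components, a per-component age effect (log-odds
#' per decade of age, centred at 65), a per-component healthcare-utilization
#' effect (log-odds per active diagnosis-variable x bin cell) and per-component
#' intercepts. Utilization effects above zero build confounding by healthcare
#' contact into the synthetic data by construction.
#'
#' @param coefficients Tibble with columns `variable`, `bin` (0-7), `beta`.
#' @param age_effect Named numeric, log-odds per decade for components
#'   `suicide`, `attempt`, `overdose`.
#' @param utilization_effect Named numeric per component.
#' @param intercepts Named numeric per component (baseline yearly log-odds);
#'   `-Inf` disables a component.
#' @param recurrence Named logical per component; suicide must be `FALSE`
#'   (terminal and unique), attempts/overdoses may recur across years.
#' @return An object of class `true_risk_model`.
#' @export
true_risk_model <- function(coefficients,
                            age_effect = c(suicide = 0.05, attempt = -0.35, overdose = -0.15),
                            utilization_effect = c(suicide = 0.004, attempt = 0.025, overdose = 0.025),
                            intercepts = c(suicide = -7.6, attempt = -6.6, overdose = -7.2),
                            recurrence = c(suicide = FALSE, attempt = TRUE, overdose = TRUE)) {
  comps <- c("suicide", "attempt", "overdose")
  stopifnot(
    all(c("variable", "bin", "beta") %in% names(coefficients)),
    all(comps %in% names(age_effect)), all(comps %in% names(utilization_effect)),
    all(comps %in% names(intercepts)), all(comps %in% names(recurrence))
  )
  if (isTRUE(recurrence[["suicide"]])) {
    config_error("suicide cannot recur: it is generated at most once per patient")
  }
  if (any(coefficients$bin < 0 | coefficients$bin > 7)) {
    config_error("risk-model coefficient bins must lie in 0..7")
  }
  structure(
    list(coefficients = as_tibble(coefficients)[, c("variable", "bin", "beta")],
         age_effect = age_effect[comps], utilization_effect = utilization_effect[comps],
         intercepts = intercepts[comps], recurrence = recurrence[comps]),
    class = "true_risk_model"
  )
}

#' Default ground-truth risk model
#'
#' Ten variables carry non-zero effects, strongest in the most recent bins
#' (acute predictors), so that support-recovery and parameter-recovery checks
#' have a known sparse target. Prior recorded attempts and overdoses predict
#' later events, mimicking indicator variables.
#'
#' @inheritParams true_risk_model
#' @return A `true_risk_model`.
#' @export
default_risk_model <- function(intercepts = c(suicide = -7.6, attempt = -6.6, overdose = -7.2)) {
  base <- c(
    suicide_attempt = 1.4, suicide_ideation = 1.2, overdose = 0.9,
    depression = 0.6, substance_use = 0.6, opioid_use = 0.5, bipolar = 0.5,
    ptsd = 0.4, chronic_pain = 0.35, metastatic_cancer = 0.5
  )
  profile <- c(0.5, 0.3, 0.2, 0.2, 0.1, 0.1, 0.05, 0.05)
  coefs <- tidyr::expand_grid(variable = names(base), bin = 0:7) |>
    mutate(beta = base[.data$variable] * profile[.data$bin + 1])
  true_risk_model(coefs, intercepts = intercepts)
}

#' Default laboratory and vital-sign specifications
#'
#' Category boundaries follow conventional clinical ranges; only pulse
#' pressure's boundaries (<30, 30-50 reference, 50-70, >70 mm Hg) are fixed
#' by the modelling convention rather than chosen here. Measurement
#' probabilities are per visit.
#'
#' @return A list of per-lab specifications.
#' @export
default_lab_specs <- function() {
  list(
    bp = list(measure_prob = 0.35, systolic_mean = 128, systolic_sd = 15,
              diastolic_mean = 78, diastolic_sd = 10, age_slope = 0.4),
    hemoglobin = list(measure_prob = 0.12, mean = 14, sd = 1.5,
                      breaks = c(-Inf, 8, 12, 16, 18, Inf),
                      labels = c("very_low", "low", "normal", "high", "very_high"),
                      reference = "normal"),
    phq9 = list(psych_prob = 0.30, other_prob = 0.01),
    phq2 = list(psych_prob = 0.10, other_prob = 0.005)
  )
}

#' Configure a synthetic EMR population
#'
#' @param n_patients Number of patients (> 0).
#' @param dob_range Character or Date length-2; dates of birth are uniform here.
#' @param calendar_range Character or Date length-2; all events fall in this
#'   half-open interval.
#' @param n_dx_variables Number of per-visit diagnosis variables (default 75).
#' @param visit_rate_meanlog,visit_rate_sdlog Log-normal distribution of
#'   per-patient yearly visit intensity (homogeneous Poisson within patient).
#' @param variable_prevalence Tibble from [default_variable_prevalence()].
#' @param risk_model A [true_risk_model()].
#' @param lab_specs From [default_lab_specs()].
#' @param icd_changepoint If `TRUE`, recorded attempt/overdose events after
#'   `changepoint_date` are thinned (kept with probability `changepoint_keep`),
#'   mimicking the recording discontinuity at a coding-system changeover;
#'   default off.
#' @param changepoint_date,changepoint_keep Changepoint parameters.
#' @param seed RNG seed; identical config + seed reproduces the population
#'   exactly.
#' @return An object of class `population_config`.
#' @export
population_config <- function(n_patients,
                              dob_range = c("1930-01-01", "1995-12-31"),
                              calendar_range = c("2000-01-01", "2021-12-31"),
                              n_dx_variables = 75,
                              visit_rate_meanlog = log(3),
                              visit_rate_sdlog = 0.8,
                              variable_prevalence = NULL,
                              risk_model = default_risk_model(),
                              lab_specs = default_lab_specs(),
                              icd_changepoint = FALSE,
                              changepoint_date = "2015-10-01",
                              changepoint_keep = 0.5,
                              seed = 1L) {
  dob_range <- as.Date(dob_range)
  calendar_range <- as.Date(calendar_range)
  if (!is.numeric(n_patients) || length(n_patients) != 1 || n_patients < 1) {
    config_error("n_patients must be a positive count")
  }
  if (any(is.na(dob_range)) || any(is.na(calendar_range)) ||
      diff(as.numeric(dob_range)) < 0 || diff(as.numeric(calendar_range)) <= 0) {
    config_error("dob_range and calendar_range must be valid, non-empty date intervals")
  }
  if (dob_range[1] >= calendar_range[2]) {
    config_error("dob_range must precede the end of calendar_range")
  }
  dx_variables <- default_dx_variables(n_dx_variables)
  if (is.null(variable_prevalence)) {
    variable_prevalence <- default_variable_prevalence(dx_variables)
  }
  assert_prob(variable_prevalence$prevalence, "variable_prevalence")
  assert_prob(changepoint_keep, "changepoint_keep")
  if (!inherits(risk_model, "true_risk_model")) {
    config_error("risk_model must be a true_risk_model object")
  }
  structure(
    list(
      n_patients = as.integer(n_patients), dob_range = dob_range,
      calendar_range = calendar_range, dx_variables = dx_variables,
      med_variables = default_med_variables(),
      visit_rate_meanlog = visit_rate_meanlog, visit_rate_sdlog = visit_rate_sdlog,
      variable_prevalence = as_tibble(variable_prevalence),
      risk_model = risk_model, lab_specs = lab_specs,
      icd_changepoint = isTRUE(icd_changepoint),
      changepoint_date = as.Date(changepoint_date),
      changepoint_keep = changepoint_keep,
      seed = as.integer(seed)
    ),
    class = "population_config"
  )
}

# representative ICD strings so the regex classification layer is genuinely
# exercised on synthetic data; dx/med codes deliberately avoid every outcome
# pattern family
build_code_map <- function(config) {
  dx <- config$dx_variables
  bind_rows(
    tibble(variable = dx, code_system = "ICD9",
           code = sprintf("V%02d.1", seq_along(dx))),
    tibble(variable = dx, code_system = "ICD10",
           code = sprintf("Z%02d.8", seq_along(dx))),
    tibble(variable = "suicide_attempt", code_system = c("ICD9", "ICD10"),
           code = c("E950.4", "T14.91")),
    tibble(variable = "overdose", code_system = c("ICD9", "ICD10"),
           code = c("E850.0", "T40.2X1A")),
    tibble(variable = config$med_variables, code_system = "RX",
           code = sprintf("RX%03d", seq_along(config$med_variables))),
    tibble(variable = c("visit_psych", "visit_office", "visit_other"),
           code_system = "visit", code = c("502", "323", "000"))
  )
}

era_system <- function(date, changepoint = as.Date("2015-10-01")) {
  ifelse(date < changepoint, "ICD9", "ICD10")
}

#' Generate a synthetic EMR population
#'
#' Draws patients, a per-patient homogeneous Poisson visit process with
#' log-normal intensity across patients, per-visit diagnosis/medication
#' emissions, lab and survey measurements, background mortality, and outcome
#' events (suicide, suicide attempt, overdose) from the configured ground-truth
#' hazard evaluated yearly on the trailing eight-bin feature state. Suicide is
#' terminal and unique; attempts and overdoses recur and feed back into later
#' feature states. No event postdates death.
#'
#' @param config A [population_config()].
#' @return An `emr_population`: list of tibbles `patients`, `events`, `labs`,
#'   `deaths`, plus the code map and config. The exact per-interval linear
#'   predictors used during generation are retained for [ground_truth()].
#' @export
simulate_population <- function(config) {
  stopifnot(inherits(config, "population_config"))
  withr::with_seed(config$seed, simulate_population_impl(config))
}

simulate_population_impl <- function(config) {
  n <- config$n_patients
  cal0 <- config$calendar_range[1]
  cal1 <- config$calendar_range[2]

  ## ---- patients -----------------------------------------------------------
  dob <- config$dob_range[1] +
    floor(runif(n) * (as.numeric(config$dob_range[2] - config$dob_range[1]) + 1))
  patients <- tibble(
    patient_id = seq_len(n),
    dob = dob,
    sex = ifelse(runif(n) < 0.90, "M", "F"),
    race = sample(c("White", "Black", "Other"), n, TRUE, prob = c(0.75, 0.18, 0.07)),
    ethnicity = ifelse(runif(n) < 0.07, "Hispanic", "NonHispanic"),
    area_index = round(rnorm(n), 3)
  )

  ## ---- visit process ------------------------------------------------------
  entry <- pmax(patients$dob + round(18 * 365.25), cal0)
  span_yrs <- pmax(as.numeric(cal1 - entry) / 365.25, 0)
  lambda <- rlnorm(n, config$visit_rate_meanlog, config$visit_rate_sdlog)
  n_vis <- rpois(n, lambda * span_yrs)
  pid_v <- rep.int(patients$patient_id, n_vis)
  vis_date <- rep(entry, n_vis) +
    floor(runif(sum(n_vis)) * rep(pmax(as.numeric(cal1 - entry), 1), n_vis))
  vtype <- sample(c("visit_psych", "visit_office", "visit_other"),
                  sum(n_vis), TRUE, prob = c(0.12, 0.55, 0.33))
  visits <- tibble(patient_id = pid_v, date = vis_date, variable = vtype)

  ## ---- per-visit diagnosis / medication emissions -------------------------
  emit <- function(prev_tbl) {
    out <- vector("list", nrow(prev_tbl))
    for (i in seq_len(nrow(prev_tbl))) {
      hit <- which(runif(nrow(visits)) < prev_tbl$prevalence[i])
      if (length(hit)) {
        out[[i]] <- tibble(patient_id = visits$patient_id[hit],
                           date = visits$date[hit],
                           variable = prev_tbl$variable[i])
      }
    }
    empty <- tibble(patient_id = integer(), date = as.Date(character()),
                    variable = character())
    bind_rows(empty, list_rbind(out))
  }
  dx_events <- emit(filter(config$variable_prevalence, .data$type == "dx"))
  med_events <- emit(filter(config$variable_prevalence, .data$type == "med"))

  ## ---- labs and surveys ---------------------------------------------------
  labs <- simulate_labs(config, visits, patients)

  ## ---- outcome generation (yearly discrete-time hazard) -------------------
  gen <- generate_outcomes(config, patients, dx_events)
  outcome_events <- gen$outcome_events
  deaths <- gen$deaths
  truth <- gen$truth

  ## ---- assemble, truncating at death --------------------------------------
  death_lookup <- deaths |> select("patient_id", death_date = "date")
  truncate <- function(tbl) {
    tbl |>
      left_join(death_lookup, by = "patient_id") |>
      filter(is.na(.data$death_date) | .data$date <= .data$death_date) |>
      select(-"death_date")
  }
  events <- bind_rows(
    truncate(visits),
    truncate(dx_events),
    truncate(med_events),
    outcome_events
  ) |>
    mutate(code_system = case_when(
      startsWith(.data$variable, "visit_") ~ "visit",
      startsWith(.data$variable, "med_") | startsWith(.data$variable, "proc_") ~ "RX",
      TRUE ~ era_system(.data$date, config$changepoint_date)
    )) |>
    arrange(.data$patient_id, .data$date, .data$variable)
  labs <- truncate(labs) |> arrange(.data$patient_id, .data$date, .data$lab)

  structure(
    list(patients = patients, events = events, labs = labs,
         deaths = arrange(deaths, .data$patient_id),
         code_map = build_code_map(config), config = config),
    truth = truth,
    config_hash = rlang::hash(unclass(config)),
    class = "emr_population"
  )
}

simulate_labs <- function(config, visits, patients) {
  ls <- config$lab_specs
  nv <- nrow(visits)
  age_at <- as.numeric(visits$date - patients$dob[visits$patient_id]) / 365.25
  psych <- visits$variable == "visit_psych"

  bp_idx <- which(runif(nv) < ls$bp$measure_prob)
  sys_v <- rnorm(length(bp_idx), ls$bp$systolic_mean +
                   ls$bp$age_slope * pmax(age_at[bp_idx] - 50, 0), ls$bp$systolic_sd)
  dia_v <- rnorm(length(bp_idx), ls$bp$diastolic_mean, ls$bp$diastolic_sd)
  hgb_idx <- which(runif(nv) < ls$hemoglobin$measure_prob)
  p9_idx <- which(runif(nv) < ifelse(psych, ls$phq9$psych_prob, ls$phq9$other_prob))
  p9_tot <- as.integer(clamp(round(rnorm(length(p9_idx), 5, 5)), 0, 27))
  p9_q9 <- rbinom(length(p9_idx), 3, plogis((p9_tot - 15) / 4))
  p2_idx <- which(runif(nv) < ifelse(psych, ls$phq2$psych_prob, ls$phq2$other_prob))

  bind_rows(
    tibble(patient_id = visits$patient_id[bp_idx], date = visits$date[bp_idx],
           lab = "systolic_bp", value = round(sys_v, 1)),
    tibble(patient_id = visits$patient_id[bp_idx], date = visits$date[bp_idx],
           lab = "diastolic_bp", value = round(dia_v, 1)),
    tibble(patient_id = visits$patient_id[hgb_idx], date = visits$date[hgb_idx],
           lab = "hemoglobin",
           value = round(rnorm(length(hgb_idx), ls$hemoglobin$mean, ls$hemoglobin$sd), 1)),
    tibble(patient_id = visits$patient_id[p9_idx], date = visits$date[p9_idx],
           lab = "phq9_total", value = as.numeric(p9_tot)),
    tibble(patient_id = visits$patient_id[p9_idx], date = visits$date[p9_idx],
           lab = "phq9_item9", value = as.numeric(p9_q9)),
    tibble(patient_id = visits$patient_id[p2_idx], date = visits$date[p2_idx],
           lab = "phq2_total",
           value = as.numeric(clamp(round(rnorm(length(p2_idx), 2, 1.5)), 0, 6)))
  )
}

# trailing-bin presence cells (patient, variable, bin) at time `at`, computed
# from a month-deduplicated event table with integer `mdate`
presence_cells <- function(ev, at) {
  d <- as.integer(at) - ev$mdate
  keep <- d > 0L & d <= 2738L
  if (!any(keep)) {
    return(tibble(patient_id = integer(), variable = character(), bin = integer()))
  }
  tibble(patient_id = ev$patient_id[keep], variable = ev$variable[keep],
         bin = assign_bin_days(d[keep])) |>
    distinct()
}

generate_outcomes <- function(config, patients, dx_events) {
  rm <- config$risk_model
  cal0 <- config$calendar_range[1]
  cal1 <- config$calendar_range[2]
  comps <- c("suicide", "attempt", "overdose")

  # static month-deduplicated dx presence source
  dedup_month <- function(tbl) {
    tbl |>
      mutate(mdate = as.integer(lubridate::floor_date(.data$date, "month"))) |>
      distinct(.data$patient_id, .data$variable, .data$mdate)
  }
  pres_static <- dedup_month(dx_events)
  pres_dynamic <- tibble(patient_id = integer(), variable = character(), mdate = integer())

  dx_set <- config$dx_variables
  beta_tbl <- rm$coefficients
  entry <- pmax(patients$dob + round(18 * 365.25), cal0)

  year_starts <- seq(lubridate::floor_date(cal0, "year"), cal1, by = "year")
  year_starts <- year_starts[year_starts >= cal0 & year_starts < cal1]

  alive_until <- rep(as.Date(NA), nrow(patients)) # death date once drawn
  suicided <- rep(FALSE, nrow(patients))
  out_rows <- list()
  death_rows <- list()
  truth_rows <- list()

  for (yi in seq_along(year_starts)) {
    ys <- year_starts[yi]
    ye <- min(ys %m+% years(1), cal1)
    days_in_year <- as.numeric(ye - ys)
    at_risk <- which(entry <= ys & is.na(alive_until))
    if (!length(at_risk)) next

    cells <- bind_rows(
      presence_cells(pres_static, ys),
      presence_cells(pres_dynamic, ys)
    ) |> distinct()
    util <- cells |>
      filter(.data$variable %in% dx_set) |>
      count(.data$patient_id, name = "util")
    risk <- cells |>
      inner_join(beta_tbl, by = c("variable", "bin")) |>
      group_by(.data$patient_id) |>
      summarise(risk = sum(.data$beta), .groups = "drop")

    idx <- tibble(patient_id = patients$patient_id[at_risk]) |>
      left_join(util, by = "patient_id") |>
      left_join(risk, by = "patient_id") |>
      mutate(util = dplyr::coalesce(.data$util, 0L),
             risk = dplyr::coalesce(.data$risk, 0))
    age_dec <- (as.numeric(ys - patients$dob[at_risk]) / 365.25 - 65) / 10

    lp <- vapply(comps, function(cc) {
      rm$intercepts[[cc]] + rm$age_effect[[cc]] * age_dec +
        rm$utilization_effect[[cc]] * idx$util + idx$risk
    }, numeric(length(at_risk)))
    lp <- matrix(lp, nrow = length(at_risk), dimnames = list(NULL, comps))
    truth_rows[[length(truth_rows) + 1]] <- tibble(
      patient_id = patients$patient_id[at_risk], interval_start = ys,
      lp_suicide = lp[, "suicide"], lp_attempt = lp[, "attempt"],
      lp_overdose = lp[, "overdose"], utilization = idx$util
    )

    # competing risks within the year: earliest drawn date wins for death
    draw_date <- function(k) ys + floor(runif(k) * days_in_year)
    p_suic <- plogis(lp[, "suicide"])
    hit_s <- runif(length(at_risk)) < p_suic
    s_date <- rep(as.Date(NA), length(at_risk))
    s_date[hit_s] <- draw_date(sum(hit_s))

    age_yr <- age_dec * 10 + 65
    q_bg <- clamp(5e-5 * exp(0.1 * (age_yr - 20)), 0, 0.4)
    hit_b <- runif(length(at_risk)) < q_bg
    b_date <- rep(as.Date(NA), length(at_risk))
    b_date[hit_b] <- draw_date(sum(hit_b))

    death_date <- pmin(s_date, b_date, na.rm = TRUE)
    died_suicide <- !is.na(s_date) & (is.na(b_date) | s_date <= b_date)

    new_events <- list()
    for (cc in c("attempt", "overdose")) {
      p_c <- plogis(lp[, cc])
      hit <- runif(length(at_risk)) < p_c
      e_date <- rep(as.Date(NA), length(at_risk))
      e_date[hit] <- draw_date(sum(hit))
      ok <- hit & (is.na(death_date) | e_date <= death_date)
      if (!any(ok)) next
      var <- if (cc == "attempt") "suicide_attempt" else "overdose"
      ev <- tibble(patient_id = patients$patient_id[at_risk][ok],
                   date = e_date[ok], variable = var)
      # recording thinning at the coding-system changepoint (drift scenario)
      if (config$icd_changepoint) {
        late <- ev$date >= config$changepoint_date
        keep <- !late | runif(nrow(ev)) < config$changepoint_keep
        ev <- ev[keep, ]
      }
      new_events[[cc]] <- ev
    }
    new_events <- list_rbind(new_events)
    if (nrow(new_events)) {
      out_rows[[length(out_rows) + 1]] <- new_events
      pres_dynamic <- bind_rows(pres_dynamic, dedup_month(new_events))
    }

    died <- which(!is.na(death_date))
    if (length(died)) {
      gidx <- at_risk[died]
      alive_until[gidx] <- death_date[died]
      suicided[gidx] <- died_suicide[died]
      death_rows[[length(death_rows) + 1]] <- tibble(
        patient_id = patients$patient_id[gidx],
        date = death_date[died],
        suicide = died_suicide[died]
      )
    }
  }

  deaths <- list_rbind(death_rows)
  if (nrow(deaths)) {
    sys <- era_system(deaths$date, config$changepoint_date)
    suic_code <- ifelse(sys == "ICD9", "E950.4",
                        sample(c("X78.XX", "Y87.0", "T14.91"), nrow(deaths), TRUE))
    other_code <- ifelse(sys == "ICD9",
                         sample(c("410.9", "162.9", "496"), nrow(deaths), TRUE),
                         sample(c("I21.9", "C34.90", "J44.9"), nrow(deaths), TRUE))
    deaths <- deaths |>
      mutate(code_system = sys,
             cause_codes = ifelse(.data$suicide, suic_code, other_code)) |>
      select("patient_id", "date", "cause_codes", "code_system")
  } else {
    deaths <- tibble(patient_id = integer(), date = as.Date(character()),
                     cause_codes = character(), code_system = character())
  }

  outcome_events <- if (length(out_rows)) list_rbind(out_rows) else
    tibble(patient_id = integer(), date = as.Date(character()), variable = character())
  list(
    outcome_events = outcome_events,
    deaths = deaths,
    truth = list_rbind(truth_rows)
  )
}

#' Retrieve the exact generating risk scores for a simulated population
#'
#' @param config The [population_config()] used to generate `population`.
#' @param population An `emr_population` from [simulate_population()].
#' @return A list with `linear_predictors` (tibble of per patient-year linear
#'   predictors per component, exactly as evaluated during generation) and
#'   `coefficients` (the configured [true_risk_model()]).
#' @export
ground_truth <- function(config, population) {
  stopifnot(inherits(population, "emr_population"))
  if (!identical(attr(population, "config_hash"), rlang::hash(unclass(config)))) {
    abort("population was not generated from this config",
          class = "riskpipe_provenance_error")
  }
  list(linear_predictors = attr(population, "truth"),
       coefficients = config$risk_model)
}

#' @export
print.emr_population <- function(x, ...) {
  cat("<emr_population>\n")
  cat("  patients:", nrow(x$patients), "\n")
  cat("  events:  ", nrow(x$events), "\n")
  cat("  labs:    ", nrow(x$labs), "\n")
  cat("  deaths:  ", nrow(x$deaths), "\n")
  invisible(x)
}

#' Calibrate outcome intercepts to target cumulative prevalences
#'
#' Runs a pilot simulation under the current config, then solves (per
#' component) for the intercept offset that makes the expected fraction of
#' patients with at least one event over their at-risk years equal the target,
#' using the pilot's realized linear-predictor distribution. One-pass: the
#' small feedback of attempt/overdose events into later feature states is
#' ignored during calibration.
#'
#' @param config A [population_config()].
#' @param targets Named numeric of cumulative prevalence targets per component.
#' @param pilot_n Pilot population size (default `config$n_patients`).
#' @return The config with adjusted intercepts.
#' @export
calibrate_intercepts <- function(config,
                                 targets = c(suicide = 0.003, attempt = 0.015, overdose = 0.009),
                                 pilot_n = NULL) {
  pilot_cfg <- config
  if (!is.null(pilot_n)) pilot_cfg$n_patients <- as.integer(pilot_n)
  pop <- simulate_population(pilot_cfg)
  lp <- attr(pop, "truth")
  ints <- config$risk_model$intercepts
  for (cc in names(targets)) {
    col <- paste0("lp_", cc)
    base <- lp[[col]] - ints[[cc]] # covariate part only
    f <- function(a) {
      p <- plogis(a + base)
      cum <- tapply(log1p(-p), lp$patient_id, sum)
      mean(1 - exp(cum)) - targets[[cc]]
    }
    ints[[cc]] <- stats::uniroot(f, c(-20, 5), tol = 1e-4)$root
  }
  config$risk_model$intercepts <- ints
  config
}

#' Write a population's normalized tables as CSV
#'
#' Emits `patients.csv`, `events.csv`, `labs.csv`, `deaths.csv` with ISO-8601
#' dates, plus `code_map.csv`.
#'
#' @param population An `emr_population`.
#' @param dir Output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_population <- function(population, dir) {
  stopifnot(inherits(population, "emr_population"))
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  utils::write.csv(population$patients, file.path(dir, "patients.csv"), row.names = FALSE)
  utils::write.csv(population$events, file.path(dir, "events.csv"), row.names = FALSE)
  utils::write.csv(population$labs, file.path(dir, "labs.csv"), row.names = FALSE)
  utils::write.csv(population$deaths, file.path(dir, "deaths.csv"), row.names = FALSE)
  utils::write.csv(population$code_map, file.path(dir, "code_map.csv"), row.names = FALSE)
  invisible(dir)
}
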