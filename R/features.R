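#' Default categorical encoding specifications for labs, vitals and surveys
#'
#' Each spec gives the category boundaries (left-closed, right-open), the
#' category labels, the reference level (dropped from the design, so a value
#' in the reference range contributes all-zero indicators) and, for survey
#' instruments, the admissible score range. Pulse pressure uses the fixed
#' convention <30 / 30-50 (reference) / 50-70 / >70 mm Hg.
#'
#' @return Named list of per-variable specs.
#' @export
default_encoding_specs <- function() {
  list(
    pulse_pressure = list(
      breaks = c(-Inf, 30, 50, 70, Inf),
      labels = c("low", "normal", "high", "very_high"), reference = "normal"),
    hemoglobin = list(
      breaks = c(-Inf, 8, 12, 16, 18, Inf),
      labels = c("very_low", "low", "normal", "high", "very_high"),
      reference = "normal"),
    phq9_total = list(
      breaks = c(-Inf, 5, 10, 15, 20, Inf),
      labels = c("minimal", "mild", "moderate", "mod_severe", "severe"),
      reference = "minimal", range = c(0, 27), survey = TRUE),
    phq9_item9 = list(
      breaks = c(-Inf, 1, 2, 3, Inf), labels = c("q9_0", "q9_1", "q9_2", "q9_3"),
      reference = "q9_0", range = c(0, 3), survey = TRUE),
    phq2_total = list(
      breaks = c(-Inf, 3, Inf), labels = c("negative", "positive"),
      reference = "negative", range = c(0, 6), survey = TRUE)
  )
}

#' Derive pulse-pressure measurements from paired blood pressures
#'
#' Pulse pressure = systolic minus diastolic, computed wherever both were
#' recorded for the same patient on the same date.
#'
#' @param labs Long measurement tibble (`patient_id`, `date`, `lab`, `value`).
#' @return `labs` with appended `pulse_pressure` rows.
#' @export
derive_pulse_pressure <- function(labs) {
  bp <- filter(labs, .data$lab %in% c("systolic_bp", "diastolic_bp"))
  if (nrow(bp) == 0 || length(unique(bp$lab)) < 2) return(labs)
  pp <- bp |>
    pivot_wider(id_cols = c("patient_id", "date"), names_from = "lab",
                values_from = "value", values_fn = mean) |>
    filter(!is.na(.data$systolic_bp), !is.na(.data$diastolic_bp)) |>
    transmute(.data$patient_id, .data$date, lab = "pulse_pressure",
              value = .data$systolic_bp - .data$diastolic_bp)
  bind_rows(labs, pp)
}

#' Encode presence/absence of longitudinal variables across the eight bins
#'
#' Cell (variable, bin) is 1 when the patient has at least one event of that
#' variable dated inside the bin (presence coding: repeats are idempotent).
#' Any event dated after a row's time of prediction is a hard leakage error.
#'
#' @param events Event tibble (`patient_id`, `date`, `variable`) already
#'   restricted to observable history.
#' @param cohort Cohort tibble with `row_id`, `patient_id`,
#'   `time_of_prediction`.
#' @param variables Fixed, ordered variable list defining the column layout
#'   (column count is always `length(variables) * 8`).
#' @param strict When `TRUE` (default), any event dated after a row's time of
#'   prediction is a hard leakage failure; pipeline callers that pass a
#'   patient's full stream (rows at several prediction times) disable this and
#'   future events are simply unobservable for that row.
#' @return List with the indicator `x` matrix and its column `meta` tibble.
#' @export
encode_binary <- function(events, cohort, variables, strict = TRUE) {
  joined <- events |>
    filter(.data$variable %in% variables) |>
    inner_join(select(cohort, "row_id", "patient_id", "time_of_prediction"),
               by = "patient_id", relationship = "many-to-many")
  if (!strict) joined <- filter(joined, .data$date < .data$time_of_prediction)
  meta <- tibble(
    variable = rep(variables, each = 8L), bin = rep(0:7, length(variables)),
    block = "longitudinal", level = NA_character_
  ) |>
    mutate(column = paste0(.data$variable, "|bin", .data$bin))
  x <- matrix(0L, nrow = nrow(cohort), ncol = nrow(meta),
              dimnames = list(NULL, meta$column))
  if (nrow(joined)) {
    joined$bin <- assign_bin(joined$date, joined$time_of_prediction)
    joined <- filter(joined, !is.na(.data$bin)) |>
      distinct(.data$row_id, .data$variable, .data$bin)
    i <- match(joined$row_id, cohort$row_id)
    j <- (match(joined$variable, variables) - 1L) * 8L + joined$bin + 1L
    x[cbind(i, j)] <- 1L
  }
  list(x = x, meta = meta)
}

# latest in-bin category per (row, var, bin), imputed forward in time (from
# older to newer bins) then backward; "NA" only when the whole window is empty
encode_categorical <- function(measurements, cohort, specs, strict = TRUE) {
  vars <- names(specs)
  meas <- filter(measurements, .data$lab %in% vars)
  if (!is.numeric(meas$value)) {
    abort(paste0("non-numeric measurement values for: ",
                 paste(head(unique(meas$lab[!is.finite(suppressWarnings(
                   as.numeric(meas$value)))]), 3), collapse = ", ")),
          class = "riskpipe_parse_error")
  }
  for (v in vars) {
    rng <- specs[[v]]$range
    if (!is.null(rng)) {
      vals <- meas$value[meas$lab == v]
      if (any(vals < rng[1] | vals > rng[2])) {
        abort(sprintf("%s scores outside instrument range [%g, %g]",
                      v, rng[1], rng[2]),
              class = "riskpipe_validation_error")
      }
    }
  }

  joined <- meas |>
    inner_join(select(cohort, "row_id", "patient_id", "time_of_prediction"),
               by = "patient_id", relationship = "many-to-many")
  if (!strict) joined <- filter(joined, .data$date < .data$time_of_prediction)
  if (nrow(joined)) {
    joined$bin <- assign_bin(joined$date, joined$time_of_prediction)
    inbin <- joined |>
      filter(!is.na(.data$bin)) |>
      group_by(.data$row_id, .data$lab, .data$bin) |>
      slice_max(order_by = .data$date, n = 1, with_ties = FALSE) |>
      ungroup()
  } else {
    inbin <- tibble(row_id = integer(), lab = character(), bin = integer(),
                    value = numeric())
  }

  grid <- tidyr::expand_grid(row_id = cohort$row_id, lab = vars, bin = 0:7) |>
    left_join(select(inbin, "row_id", "lab", "bin", "value"),
              by = c("row_id", "lab", "bin"))
  filled <- grid |>
    arrange(.data$row_id, .data$lab, dplyr::desc(.data$bin)) |> # chronological
    group_by(.data$row_id, .data$lab) |>
    fill("value", .direction = "downup") |>
    ungroup()

  cols <- list()
  meta <- list()
  for (v in vars) {
    sp <- specs[[v]]
    sub <- filter(filled, .data$lab == v)
    cat <- as.character(cut(sub$value, breaks = sp$breaks, labels = sp$labels,
                            right = FALSE))
    cat[is.na(cat)] <- "NA"
    lev <- c(setdiff(sp$labels, sp$reference), "NA")
    m <- matrix(0L, nrow(cohort), length(lev) * 8L)
    colnames(m) <- paste0(v, "|bin", rep(0:7, each = length(lev)), "|",
                          rep(lev, 8L))
    i <- match(sub$row_id, cohort$row_id)
    keep <- cat %in% lev
    j <- (sub$bin[keep]) * length(lev) + match(cat[keep], lev)
    m[cbind(i[keep], j)] <- 1L
    cols[[v]] <- m
    meta[[v]] <- tibble(
      variable = v, bin = rep(0:7, each = length(lev)),
      block = if (isTRUE(sp$survey)) "survey" else "lab",
      level = rep(lev, 8L), column = colnames(m))
  }
  list(x = do.call(cbind, cols), meta = list_rbind(meta))
}

#' Encode categorical labs and vitals with carry-forward/backward imputation
#'
#' @param measurements Long tibble (`patient_id`, `date`, `lab`, `value`);
#'   run [derive_pulse_pressure()] first if raw blood pressures are present.
#' @param cohort Cohort tibble with `row_id`, `patient_id`,
#'   `time_of_prediction`.
#' @param specs Category specs (non-survey entries of
#'   [default_encoding_specs()]).
#' @return List with indicator matrix `x` and column `meta`.
#' @export
encode_lab <- function(measurements, cohort,
                       specs = default_encoding_specs()[c("pulse_pressure", "hemoglobin")]) {
  encode_categorical(measurements, cohort, specs)
}

#' Encode PHQ survey scores as per-bin categories
#'
#' Total scores and the item-9 answer are separate variables; the lowest score
#' band is the reference, and the `NA` category marks patients never surveyed
#' during the 7.5-year window. Scores outside the instrument range raise a
#' validation error.
#'
#' @inheritParams encode_lab
#' @export
encode_surveys <- function(measurements, cohort,
                           specs = default_encoding_specs()[c("phq9_total", "phq9_item9", "phq2_total")]) {
  encode_categorical(measurements, cohort, specs)
}

encode_demographics <- function(patients, cohort, replicate_bins = FALSE) {
  d <- cohort |>
    select("row_id", "patient_id", "time_of_prediction") |>
    left_join(patients, by = "patient_id") |>
    transmute(
      sex_female = as.integer(.data$sex == "F"),
      race_black = as.integer(.data$race == "Black"),
      race_other = as.integer(.data$race == "Other"),
      ethnicity_hispanic = as.integer(.data$ethnicity == "Hispanic"),
      age_decades = (as.numeric(.data$time_of_prediction - .data$dob) / 3652.5) - 6.5,
      area_index = .data$area_index
    )
  x <- as.matrix(d)
  meta <- tibble(variable = colnames(x), bin = NA_integer_,
                 block = "demographic", level = NA_character_,
                 column = colnames(x))
  if (replicate_bins) {
    x <- x[, rep(seq_len(ncol(x)), each = 8L), drop = FALSE]
    meta <- meta[rep(seq_len(nrow(meta)), each = 8L), ] |>
      mutate(bin = rep(0:7, length.out = dplyr::n()),
             column = paste0(.data$column, "|bin", .data$bin))
    colnames(x) <- meta$column
  }
  list(x = x, meta = meta)
}

#' Healthcare-utilization index of a feature matrix
#'
#' The count of active (diagnosis variable, time bin) indicator cells — with
#' 75 diagnosis variables and 8 bins the possible range is 0 to 600. A proxy
#' for healthcare contact intensity and the key confounder the matched
#' retrospective design absorbs.
#'
#' @param features A `risk_features` object.
#' @return Integer vector, one value per cohort row.
#' @export
compute_utilization <- function(features) {
  sel <- features$meta$block == "longitudinal" &
    features$meta$variable %in% features$dx_variables
  as.integer(rowSums(features$x[, features$meta$column[sel], drop = FALSE]))
}

#' Number of time bins with any diagnosis-coded variable present
#'
#' The bin-level utilization statistic used for subgroup calibration (range
#' 0-8); distinct from [compute_utilization()], which counts variable-bin
#' cells.
#'
#' @param features A `risk_features` object.
#' @return Integer vector in 0..8.
#' @export
utilization_bins <- function(features) {
  sel <- features$meta$block == "longitudinal" &
    features$meta$variable %in% features$dx_variables
  meta <- features$meta[sel, ]
  x <- features$x[, meta$column, drop = FALSE]
  out <- integer(nrow(x))
  for (b in 0:7) {
    cols <- meta$column[meta$bin == b]
    out <- out + as.integer(rowSums(x[, cols, drop = FALSE]) > 0)
  }
  out
}

# the ten fine-tuning covariates: nine 0/1 indicators + the raw usage index
build_finetune <- function(binary, cohort, patients, dx_variables,
                           age_young = 55, age_old = 65) {
  anybin <- function(v) {
    cols <- paste0(v, "|bin", 0:7)
    cols <- intersect(cols, colnames(binary$x))
    if (!length(cols)) return(integer(nrow(binary$x)))
    as.integer(rowSums(binary$x[, cols, drop = FALSE]) > 0)
  }
  d <- cohort |>
    select("row_id", "patient_id", "time_of_prediction") |>
    left_join(patients, by = "patient_id")
  age <- as.numeric(d$time_of_prediction - d$dob) / 365.25
  sel_dx <- binary$meta$variable %in% dx_variables
  usage <- as.integer(rowSums(binary$x[, binary$meta$column[sel_dx], drop = FALSE]))
  tibble(
    sex_female = as.integer(d$sex == "F"),
    race_black = as.integer(d$race == "Black"),
    ethnicity_hispanic = as.integer(d$ethnicity == "Hispanic"),
    age_young = as.integer(age < age_young),
    age_old = as.integer(age > age_old),
    chronic_pain = anybin("chronic_pain"),
    suicide_ideation = anybin("suicide_ideation"),
    suicide_attempt = anybin("suicide_attempt"),
    overdose = anybin("overdose"),
    usage = usage
  )
}

#' Encode a cohort into the eight-bin design matrix
#'
#' Builds the full design for a cohort: the binary longitudinal block
#' (diagnoses, medications/procedures, prior recorded attempts/overdoses),
#' reference-coded categorical labs/vitals with carry-forward/backward
#' imputation, PHQ survey categories, cross-sectional demographics, and the
#' ten fine-tuning covariates. Only events dated strictly before each row's
#' time of prediction are observable; [audit_leakage()] re-derives the binary
#' block to verify this.
#'
#' @param population An `emr_population`.
#' @param cohort A cohort tibble from the cohort builders (must carry
#'   `row_id`, `patient_id`, `time_of_prediction`).
#' @param longitudinal_variables Ordered variable list for the binary block;
#'   defaults to the population's diagnosis + medication variables plus prior
#'   recorded `suicide_attempt`/`overdose` events.
#' @param specs Categorical encoding specs.
#' @param replicate_demographics Replicate cross-sectional columns across the
#'   eight bins (display-style layout) instead of entering them once.
#' @return A `risk_features` object: design matrix `x`, column `meta`,
#'   `finetune` covariates, the `cohort`, and bookkeeping for leakage audits.
#' @export
encode_features <- function(population, cohort, longitudinal_variables = NULL,
                            specs = default_encoding_specs(),
                            replicate_demographics = FALSE) {
  stopifnot(all(c("row_id", "patient_id", "time_of_prediction") %in% names(cohort)))
  cfg <- population$config
  if (is.null(longitudinal_variables)) {
    longitudinal_variables <- c(cfg$dx_variables, cfg$med_variables,
                                "suicide_attempt", "overdose")
  }
  hist_events <- population$events |>
    select("patient_id", "date", "variable") |>
    semi_join(cohort, by = "patient_id")

  binary <- encode_binary(hist_events, cohort, longitudinal_variables,
                          strict = FALSE)
  meas <- derive_pulse_pressure(population$labs) |>
    semi_join(cohort, by = "patient_id")
  lab_specs <- specs[!vapply(specs, function(s) isTRUE(s$survey), logical(1))]
  svy_specs <- specs[vapply(specs, function(s) isTRUE(s$survey), logical(1))]
  labs <- encode_categorical(meas, cohort, lab_specs, strict = FALSE)
  svys <- encode_categorical(meas, cohort, svy_specs, strict = FALSE)
  demo <- encode_demographics(population$patients, cohort,
                              replicate_bins = replicate_demographics)

  structure(
    list(
      x = cbind(binary$x, labs$x, svys$x, demo$x),
      meta = bind_rows(binary$meta, labs$meta, svys$meta, demo$meta),
      finetune = build_finetune(binary, cohort, population$patients,
                                cfg$dx_variables),
      cohort = cohort,
      dx_variables = cfg$dx_variables,
      schedule = "8-bin-3-3-6-6-12-12-24-24"
    ),
    class = "risk_features"
  )
}

#' @export
print.risk_features <- function(x, ...) {
  cat("<risk_features>", nrow(x$x), "rows x", ncol(x$x), "columns\n")
  print(count(x$meta, .data$block))
  invisible(x)
}

#' Audit a feature matrix for outcome-information leakage
#'
#' Re-derives the binary longitudinal block from the population's raw event
#' stream using a brute-force per-row scan restricted to events strictly
#' before each row's time of prediction, and verifies the stored design
#' matches cell for cell — i.e. no feature references an event dated at or
#' after the prediction date.
#'
#' @param features A `risk_features` object.
#' @param population The `emr_population` it was encoded from.
#' @return `TRUE` (invisibly) if clean; aborts with a leakage error otherwise.
#' @export
audit_leakage <- function(features, population) {
  meta <- features$meta |> filter(.data$block == "longitudinal")
  vars <- unique(meta$variable)
  cohort <- features$cohort
  ev <- population$events |>
    filter(.data$variable %in% vars) |>
    semi_join(cohort, by = "patient_id")
  for (i in seq_len(nrow(cohort))) {
    top <- cohort$time_of_prediction[i]
    sched <- make_time_bins(top)
    pe <- ev[ev$patient_id == cohort$patient_id[i] & ev$date < top, ]
    ref <- matrix(0L, 1, nrow(meta), dimnames = list(NULL, meta$column))
    if (nrow(pe)) {
      for (k in seq_len(nrow(pe))) {
        b <- which(pe$date[k] >= sched$start & pe$date[k] < sched$end)
        if (length(b)) {
          ref[1, paste0(pe$variable[k], "|bin", sched$bin[b])] <- 1L
        }
      }
    }
    got <- features$x[i, meta$column, drop = FALSE]
    if (!all(got == ref[1, ])) {
      abort(sprintf("leakage audit failed for row %d (patient %d)",
                    i, cohort$patient_id[i]),
            class = "riskpipe_leakage_error")
    }
  }
  invisible(TRUE)
}
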