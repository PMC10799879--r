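#' Default outcome code-pattern set
#'
#' Anchored, case-insensitive regular expressions classifying ICD-9/ICD-10
#' codes into outcome components. Suicide-related matches are interpreted by
#' context: on a death-cause record they mean death by suicide, on a clinical
#' record a suicide attempt. The ICD-9 overdose family is used exactly as
#' printed in the source convention ('^e8[67]' included), without narrowing.
#'
#' @return A tibble with columns `component` (`suicide_related` / `overdose`),
#'   `code_system` and `pattern`.
#' @export
code_patterns <- function() {
  bind_rows(
    tibble(component = "suicide_related", code_system = "ICD9",
           pattern = "^e95"),
    tibble(component = "suicide_related", code_system = "ICD10",
           pattern = c("^T14.91", "^T3[6789]..X2", "^T[456]..X2",
                       "^X[678]..XX", "^Y87.0")),
    tibble(component = "overdose", code_system = "ICD9",
           pattern = c("^e850", "^e8[67]", "^e935")),
    tibble(component = "overdose", code_system = "ICD10", pattern = "^T40")
  )
}

#' Classify a coded diagnosis or cause-of-death into an outcome component
#'
#' Matching is case-insensitive and anchored at the start of the code string.
#' A suicide-related match on a death-cause record classifies as `suicide`;
#' the same match on a clinical record classifies as `attempt`. Suicide-related
#' patterns take priority over overdose patterns when a code matches both.
#'
#' @param code Character vector of codes (non-empty strings).
#' @param code_system `"ICD9"` or `"ICD10"` (recycled).
#' @param context `"death_cause"` or `"clinical"` (recycled).
#' @param patterns Pattern set from [code_patterns()].
#' @return Character vector over `{"suicide", "attempt", "overdose", "none"}`.
#' @examples
#' classify_code("T14.91", "ICD10", "death_cause") # suicide
#' classify_code("E9509", "ICD9", "clinical")      # attempt
#' @export
classify_code <- function(code, code_system, context = "clinical",
                          patterns = code_patterns()) {
  if (length(code) == 0) return(character())
  if (any(is.na(code) | !nzchar(code))) input_error("codes must be non-empty strings")
  n <- max(length(code), length(code_system), length(context))
  code <- rep_len(code, n)
  code_system <- rep_len(code_system, n)
  context <- rep_len(context, n)
  bad <- !code_system %in% c("ICD9", "ICD10")
  if (any(bad)) {
    input_error(paste0("unknown code_system: ",
                       paste(unique(code_system[bad]), collapse = ", ")))
  }
  if (any(!context %in% c("death_cause", "clinical"))) {
    input_error("context must be 'death_cause' or 'clinical'")
  }
  match_set <- function(comp, sys) {
    pats <- patterns$pattern[patterns$component == comp & patterns$code_system == sys]
    hit <- rep(FALSE, n)
    sel <- code_system == sys
    for (p in pats) {
      hit[sel] <- hit[sel] | grepl(p, code[sel], ignore.case = TRUE)
    }
    hit
  }
  suic <- match_set("suicide_related", "ICD9") | match_set("suicide_related", "ICD10")
  over <- match_set("overdose", "ICD9") | match_set("overdose", "ICD10")
  out <- rep("none", n)
  out[over] <- "overdose"
  out[suic & context == "clinical"] <- "attempt"
  out[suic & context == "death_cause"] <- "suicide"
  out
}

#' Classify a population's recorded events and death causes
#'
#' Maps symbolic variable names to representative ICD strings through the code
#' map, then runs the regex classifier over clinical events and death-cause
#' records, so the pattern layer is genuinely exercised.
#'
#' @param population An `emr_population` (or a list with `events`, `deaths`,
#'   `code_map` tibbles).
#' @param patterns Pattern set from [code_patterns()].
#' @return Tibble of classified outcome events: `patient_id`, `date`,
#'   `component`, `source` (`clinical`/`death_cause`), `event_id` (stable
#'   within-patient order for deterministic tie-breaks).
#' @export
classify_events <- function(population, patterns = code_patterns()) {
  ev <- population$events |>
    inner_join(filter(population$code_map, .data$code_system %in% c("ICD9", "ICD10")),
               by = c("variable", "code_system"))
  clin <- if (nrow(ev)) {
    ev |>
      mutate(component = classify_code(.data$code, .data$code_system, "clinical",
                                       patterns = patterns),
             source = "clinical") |>
      select("patient_id", "date", "component", "source")
  } else {
    tibble(patient_id = integer(), date = as.Date(character()),
           component = character(), source = character())
  }
  dth <- population$deaths
  death <- if (nrow(dth)) {
    dth |>
      mutate(component = classify_code(.data$cause_codes, .data$code_system,
                                       "death_cause", patterns = patterns),
             source = "death_cause") |>
      select("patient_id", "date", "component", "source")
  } else {
    clin[0, ]
  }
  bind_rows(clin, death) |>
    filter(.data$component != "none") |>
    arrange(.data$patient_id, .data$date, .data$component) |>
    group_by(.data$patient_id) |>
    mutate(event_id = row_number()) |>
    ungroup()
}

#' Build the combined outcome by priority within a study window
#'
#' One label per patient per window: death by suicide in the window if any;
#' otherwise the earliest suicide attempt in the window; otherwise the earliest
#' overdose; otherwise `none`. Ties on the same date resolve by component
#' priority (suicide > attempt > overdose) then by within-patient event id, so
#' the label is independent of input row order.
#'
#' @param classified Output of [classify_events()] (all patients), or any
#'   tibble with `patient_id`, `date`, `component`, `event_id`.
#' @param window Length-2 Date vector, half-open `[start, end)`.
#' @param patient_ids Patients to label (default: those present in
#'   `classified`); patients with no in-window events get component `none`.
#' @return Tibble of [OutcomeLabel] rows: `patient_id`, `component`,
#'   `event_date` (`NA` iff `none`), `rule_applied`.
#' @export
build_combined_outcome <- function(classified, window, patient_ids = NULL) {
  window <- as.Date(window)
  if (length(window) != 2 || any(is.na(window)) || window[2] <= window[1]) {
    input_error("window must be a valid half-open [start, end) date interval")
  }
  if (is.null(patient_ids)) patient_ids <- unique(classified$patient_id)
  prio <- c(suicide = 1L, attempt = 2L, overdose = 3L)
  in_window <- classified |>
    filter(.data$date >= window[1], .data$date < window[2],
           .data$component %in% names(prio))
  hits <- if (nrow(in_window) == 0) {
    tibble(patient_id = integer(), component = character(),
           event_date = as.Date(character()), rule_applied = character())
  } else {
    in_window |>
      mutate(prio = prio[.data$component]) |>
      group_by(.data$patient_id) |>
      # winning component first, then its earliest event (suicide is unique)
      filter(.data$prio == min(.data$prio)) |>
      arrange(.data$date, .data$event_id, .by_group = TRUE) |>
      slice(1) |>
      ungroup() |>
      transmute(.data$patient_id, component = .data$component,
                event_date = .data$date,
                rule_applied = c("suicide_in_window", "earliest_attempt",
                                 "earliest_overdose")[.data$prio])
  }
  tibble(patient_id = patient_ids) |>
    left_join(hits, by = "patient_id") |>
    mutate(component = dplyr::coalesce(.data$component, "none"),
           rule_applied = dplyr::coalesce(.data$rule_applied, "no_event"))
}
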