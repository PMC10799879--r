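# Cached fixtures shared across test files (built once per session).
.fixture_cache <- new.env(parent = emptyenv())

cached <- function(key, build) {
  if (!exists(key, envir = .fixture_cache)) {
    assign(key, build(), envir = .fixture_cache)
  }
  get(key, envir = .fixture_cache)
}

test_pop <- function(n = 2000, seed = 3, ...) {
  key <- paste0("pop_", n, "_", seed, "_", rlang::hash(list(...)))
  cached(key, function() simulate_population(population_config(n, seed = seed, ...)))
}

test_classified <- function(pop) classify_events(pop)

# a compact learner profile for desk-scale test cohorts
test_learners <- function() {
  learner_config(rf = list(num_trees = 150L, min_node = 25L),
                 cox = list(nfolds = 3L, nlambda = 30L, lambda_min_ratio = 0.1),
                 glm_lasso = list(nfolds = 3L),
                 mlp = list(hidden = c(24L, 12L), epochs = 12L))
}

# scenario population for the small end-to-end runs: suicide hazard raised so
# the suicide-target models have enough cases at this cohort size
test_run_config <- function(n = 3000, seed = 11) {
  pop_cfg <- population_config(
    n, seed = derive_seed(seed, "population"),
    risk_model = default_risk_model(
      intercepts = c(suicide = -6.0, attempt = -6.6, overdose = -7.2)))
  pipeline_config(seed = seed, population = pop_cfg, learners = test_learners())
}

test_run_dir <- function() {
  cached("run_small_dir", function() {
    file.path(tempdir(), "riskpipe-test-run")
  })
}

test_run <- function() {
  cached("run_small", function() {
    suppressWarnings(suppressMessages(
      run_pipeline(test_run_config(), output_dir = test_run_dir())))
  })
}

# hand-built miniature population for exact-case cohort/outcome tests
toy_population <- function(patients, events = NULL, labs = NULL, deaths = NULL,
                           calendar_range = as.Date(c("2000-01-01", "2022-01-01"))) {
  cfg <- population_config(max(nrow(patients), 1), calendar_range = calendar_range,
                           seed = 1)
  empty_events <- tibble::tibble(patient_id = integer(), date = as.Date(character()),
                                 variable = character(), code_system = character())
  empty_labs <- tibble::tibble(patient_id = integer(), date = as.Date(character()),
                               lab = character(), value = numeric())
  empty_deaths <- tibble::tibble(patient_id = integer(), date = as.Date(character()),
                                 cause_codes = character(), code_system = character())
  structure(
    list(patients = patients,
         events = events %||% empty_events,
         labs = labs %||% empty_labs,
         deaths = deaths %||% empty_deaths,
         code_map = riskpipe:::build_code_map(cfg),
         config = cfg),
    class = "emr_population"
  )
}

toy_patients <- function(n, dob = as.Date("1960-06-15")) {
  tibble::tibble(
    patient_id = seq_len(n),
    dob = rep_len(dob, n),
    sex = rep_len(c("M", "F"), n),
    race = rep_len("White", n),
    ethnicity = rep_len("NonHispanic", n),
    area_index = 0
  )
}

`%||%` <- function(x, y) if (is.null(x)) y else x
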