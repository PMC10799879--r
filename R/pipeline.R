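#' Configure an end-to-end pipeline run
#'
#' Bundles the population config, cohort anchors, learner settings, ensemble
#' registry composition and evaluation settings into one seeded, reproducible
#' run description. Per-stage seeds are derived deterministically from the
#' global seed.
#'
#' @param n_patients Synthetic population size (default 20,000 — the package's
#'   reference desk scale).
#' @param seed Global seed; every stage derives its own stream from it.
#' @param population Optional pre-built [population_config()] (overrides
#'   `n_patients`).
#' @param c15_date,c17_date Calendar anchors of the base-training and
#'   fine-tuning prospective cohorts.
#' @param lookback_months Prior-visit inclusion window for calendar cohorts.
#' @param learners A [learner_config()]; the pipeline profile defaults to a
#'   compact 128/64/32 network appropriate to desk-scale cohorts (the
#'   learner-config default remains the full-scale 1024/512/256
#'   architecture).
#' @param rcc A [rcc_config()].
#' @param drift Also run the temporal-drift scenario: freeze the
#'   suicide-target ensemble at the fine-tuning date, evaluate two years later
#'   against a refreshed fine-tuning.
#' @param drift_date Prediction date of the drift holdout cohort.
#' @param q Top-risk fractions for concentration-of-risk reporting.
#' @return A `pipeline_config`.
#' @export
pipeline_config <- function(n_patients = 20000, seed = 1L, population = NULL,
                            c15_date = "2015-01-01", c17_date = "2017-01-01",
                            lookback_months = 3,
                            learners = learner_config(
                              mlp = list(hidden = c(128L, 64L, 32L), epochs = 20L)),
                            rcc = NULL, drift = FALSE,
                            drift_date = "2019-01-01", q = c(0.01, 0.001)) {
  if (is.null(population)) {
    population <- population_config(n_patients, seed = derive_seed(seed, "population"))
  }
  if (is.null(rcc)) rcc <- rcc_config(seed = derive_seed(seed, "rcc"))
  structure(
    list(population = population, c15_date = as.Date(c15_date),
         c17_date = as.Date(c17_date), lookback_months = lookback_months,
         learners = learners, rcc = rcc, drift = isTRUE(drift),
         drift_date = as.Date(drift_date), q = q, seed = as.integer(seed)),
    class = "pipeline_config"
  )
}

# content-hash-chained stage cache: a stage's key folds its own config hash
# with its upstream stages' keys, so deleting one cached stage regenerates
# only the downstream ones
stage_runner <- function(cache_dir, log_path) {
  force(cache_dir); force(log_path)
  function(name, key_parts, fn) {
    key <- rlang::hash(c(list(stage = name), key_parts))
    path <- if (!is.null(cache_dir)) file.path(cache_dir, paste0(name, "-", key, ".rds"))
    t0 <- proc.time()[["elapsed"]]
    if (!is.null(path) && file.exists(path)) {
      value <- readRDS(path)
      cached <- TRUE
    } else {
      value <- fn()
      cached <- FALSE
      if (!is.null(path)) saveRDS(value, path)
    }
    if (!is.null(log_path)) {
      rec <- list(stage = name, key = key, cached = cached,
                  seconds = round(proc.time()[["elapsed"]] - t0, 2),
                  rows = if (is.data.frame(value)) nrow(value) else NA)
      cat(jsonlite::toJSON(rec, auto_unbox = TRUE), "\n",
          file = log_path, append = TRUE, sep = "")
    }
    list(value = value, key = key)
  }
}

#' Run the full pipeline: simulate, label, cohort, encode, train, stack, evaluate
#'
#' Executes every stage on one seeded synthetic population: outcome
#' classification and combined labels; the matched retrospective (Rcc),
#' two calendar and two event-triggered cohorts; eight-bin encoding; the
#' base-learner suite under the even/odd protocol; the two seven-base
#' ensembles (combined-outcome and suicide targets, each excluding the other
#' target's calendar base); and discrimination / calibration / risk-
#' concentration evaluation on the fine-tuning cohort. Stages are cached
#' content-addressably under `output_dir` and re-running with an identical
#' config reuses them.
#'
#' @param config A [pipeline_config()].
#' @param output_dir Directory for cache, structured run log (JSON lines) and
#'   `metrics.json`; `NULL` disables persistence.
#' @return A `riskpipe_run` list: population, cohorts, base fits, ensembles,
#'   evaluation tables and the headline `metrics`.
#' @export
run_pipeline <- function(config = pipeline_config(), output_dir = NULL) {
  stopifnot(inherits(config, "pipeline_config"))
  cache_dir <- log_path <- NULL
  if (!is.null(output_dir)) {
    cache_dir <- file.path(output_dir, "cache")
    dir.create(cache_dir, recursive = TRUE, showWarnings = FALSE)
    log_path <- file.path(output_dir, "run-log.jsonl")
  }
  run_stage <- stage_runner(cache_dir, log_path)
  pop_cfg <- config$population
  cal_end <- pop_cfg$calendar_range[2]

  st_pop <- run_stage("simulate", list(cfg = unclass(pop_cfg)),
                      function() simulate_population(pop_cfg))
  population <- st_pop$value

  st_out <- run_stage("outcomes", list(up = st_pop$key), function() {
    classified <- classify_events(population)
    labels_all <- build_combined_outcome(
      classified, c(config$rcc$earliest_outcome_date, cal_end),
      patient_ids = population$patients$patient_id)
    list(classified = classified, labels_all = labels_all)
  })
  classified <- st_out$value$classified
  labels_all <- st_out$value$labels_all

  st_coh <- run_stage("cohorts", list(up = st_out$key, rcc = unclass(config$rcc),
                                      c15 = config$c15_date, c17 = config$c17_date,
                                      lb = config$lookback_months), function() {
    list(
      rcc = build_rcc(population, labels_all, config$rcc),
      c15_all = build_calendar_cohort(population, classified, config$c15_date,
                                      config$lookback_months, target = "combined"),
      c15_ndi = build_calendar_cohort(population, classified, config$c15_date,
                                      config$lookback_months, target = "suicide"),
      c17_all = build_calendar_cohort(population, classified, config$c17_date,
                                      config$lookback_months, target = "combined"),
      c17_ndi = build_calendar_cohort(population, classified, config$c17_date,
                                      config$lookback_months, target = "suicide"),
      cox_mh = build_event_cohort(population, classified, "psych"),
      cox_visit = build_event_cohort(population, classified, "office")
    )
  })
  cohorts <- st_coh$value

  st_feat <- run_stage("encode", list(up = st_coh$key), function() {
    lapply(cohorts[c("rcc", "c15_all", "c15_ndi", "c17_all", "cox_mh", "cox_visit")],
           function(coh) encode_features(population, coh))
  })
  feats <- st_feat$value

  st_base <- run_stage("train_bases", list(up = st_feat$key,
                                           learners = unclass(config$learners),
                                           seed = config$seed), function() {
    sd <- function(tag) derive_seed(config$seed, tag)
    list(
      rcc_glm = even_odd_protocol(feats$rcc, "glm_lasso", config = config$learners,
                                  seed = sd("rcc_glm")),
      rcc_rf = even_odd_protocol(feats$rcc, "rf", config = config$learners,
                                 seed = sd("rcc_rf")),
      rcc_mlp = even_odd_protocol(feats$rcc, "mlp", config = config$learners,
                                  seed = sd("rcc_mlp")),
      rcc_nb = even_odd_protocol(feats$rcc, "nb", config = config$learners,
                                 seed = sd("rcc_nb")),
      cox_mh = even_odd_protocol(feats$cox_mh, "cox", config = config$learners,
                                 seed = sd("cox_mh")),
      cox_visit = even_odd_protocol(feats$cox_visit, "cox", config = config$learners,
                                    seed = sd("cox_visit")),
      c15_glm_all = even_odd_protocol(feats$c15_all, "glm_lasso",
                                      config = config$learners, seed = sd("c15_all")),
      c15_glm_ndi = even_odd_protocol(feats$c15_ndi, "glm_lasso",
                                      config = config$learners, seed = sd("c15_ndi"))
    )
  })
  bases <- st_base$value

  st_ens <- run_stage("ensemble", list(up = st_base$key), function() {
    target_feats <- feats$c17_all
    registry_all <- lapply(bases[c("rcc_glm", "rcc_rf", "rcc_mlp", "rcc_nb",
                                   "cox_mh", "cox_visit", "c15_glm_all")],
                           function(f) f$final)
    registry_ndi <- lapply(bases[c("rcc_glm", "rcc_rf", "rcc_mlp", "rcc_nb",
                                   "cox_mh", "cox_visit", "c15_glm_ndi")],
                           function(f) f$final)
    scores_all <- score_base_models(registry_all, target_feats)
    scores_ndi <- score_base_models(registry_ndi, target_feats)
    ft <- target_feats$finetune
    y_all <- as.integer(cohorts$c17_all$is_case)
    y_ndi <- as.integer(cohorts$c17_ndi$is_case[
      match(cohorts$c17_all$patient_id, cohorts$c17_ndi$patient_id)])
    parity <- cohorts$c17_all$is_even
    list(
      ens_all = fit_ensemble(scores_all, ft, y_all, parity, target = "combined"),
      ens_ndi = fit_ensemble(scores_ndi, ft, y_ndi, parity, target = "suicide"),
      scores_all = scores_all, scores_ndi = scores_ndi,
      y_all = y_all, y_ndi = y_ndi, parity = parity
    )
  })
  ens <- st_ens$value

  st_eval <- run_stage("evaluate", list(up = st_ens$key, q = config$q), function() {
    target_feats <- feats$c17_all
    ft <- target_feats$finetune
    # per-base fine-tuned out-of-half AUROC (score + ten covariates)
    base_auroc <- function(scores, y) {
      vapply(colnames(scores), function(nm) {
        m <- fit_ensemble(scores[, nm, drop = FALSE], ft, y, ens$parity)
        auroc(m$oof_score, y)
      }, numeric(1))
    }
    ub <- utilization_bins(target_feats)
    brk <- unique(c(-Inf, 1, unname(quantile(ub[ub > 1], c(1 / 3, 2 / 3))), Inf))
    util_group <- cut(ub, breaks = brk,
                      labels = c("zero_or_one", "low", "medium", "high")[seq_len(length(brk) - 1)])
    comp <- tibble(
      suicide = as.integer(cohorts$c17_all$component == "suicide"),
      attempt = as.integer(cohorts$c17_all$component == "attempt"),
      overdose = as.integer(cohorts$c17_all$component == "overdose"),
      combined = ens$y_all
    )
    list(
      base_auroc_all = base_auroc(ens$scores_all, ens$y_all),
      base_auroc_ndi = base_auroc(ens$scores_ndi, ens$y_ndi),
      ens_all_auroc = auroc(ens$ens_all$oof_score, ens$y_all),
      ens_ndi_auroc = auroc(ens$ens_ndi$oof_score, ens$y_ndi),
      ens_all_auprc = auprc(ens$ens_all$oof_score, ens$y_all),
      ens_ndi_auprc = auprc(ens$ens_ndi$oof_score, ens$y_ndi),
      calibration = calibration(ens$ens_all$oof_score, ens$y_all,
                                subgroups = as.character(util_group)),
      strata = concentration_of_risk(ens$ens_all$oof_score, comp, q = config$q),
      strata_ndi = concentration_of_risk(ens$ens_ndi$oof_score, comp, q = config$q)
    )
  })
  evaluation <- st_eval$value

  drift <- NULL
  if (config$drift) {
    st_drift <- run_stage("drift", list(up = st_ens$key, date = config$drift_date),
                          function() {
      c19 <- build_calendar_cohort(population, classified, config$drift_date,
                                   config$lookback_months, target = "suicide")
      f19 <- encode_features(population, c19)
      registry_ndi <- lapply(bases[c("rcc_glm", "rcc_rf", "rcc_mlp", "rcc_nb",
                                     "cox_mh", "cox_visit", "c15_glm_ndi")],
                             function(f) f$final)
      s19 <- score_base_models(registry_ndi, f19)
      drift_eval(ens$ens_ndi, s19, f19$finetune, as.integer(c19$is_case),
                 c19$is_even, q = config$q)
    })
    drift <- st_drift$value
  }

  metrics <- list(
    n_patients = nrow(population$patients),
    c17_n = nrow(cohorts$c17_all),
    c17_case_fraction_combined = mean(ens$y_all),
    c17_case_fraction_suicide = mean(ens$y_ndi),
    ens_all_auroc = evaluation$ens_all_auroc,
    ens_ndi_auroc = evaluation$ens_ndi_auroc,
    ens_all_auprc = evaluation$ens_all_auprc,
    ens_ndi_auprc = evaluation$ens_ndi_auprc,
    base_auroc_all = as.list(evaluation$base_auroc_all),
    base_auroc_ndi = as.list(evaluation$base_auroc_ndi)
  )
  if (!is.null(output_dir)) {
    jsonlite::write_json(metrics, file.path(output_dir, "metrics.json"),
                         auto_unbox = TRUE, digits = NA)
  }

  structure(
    list(config = config, population = population, classified = classified,
         labels = labels_all, cohorts = cohorts, features = feats,
         base_fits = bases, ensembles = ens[c("ens_all", "ens_ndi")],
         scores = ens[c("scores_all", "scores_ndi")],
         targets = ens[c("y_all", "y_ndi", "parity")],
         evaluation = evaluation, drift = drift, metrics = metrics),
    class = "riskpipe_run"
  )
}

#' @export
print.riskpipe_run <- function(x, ...) {
  cat("<riskpipe_run>\n")
  cat(sprintf("  population: %d patients\n", x$metrics$n_patients))
  cat(sprintf("  C17 cohort: %d rows (combined case fraction %.3f)\n",
              x$metrics$c17_n, x$metrics$c17_case_fraction_combined))
  cat(sprintf("  EnsAll AUROC %.3f | EnsNDI AUROC %.3f\n",
              x$metrics$ens_all_auroc, x$metrics$ens_ndi_auroc))
  invisible(x)
}
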