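#' Calibration table by subgroup
#'
#' Stratifies rows into score bins of fixed width on the log-odds axis and
#' compares the observed event fraction per bin with the probability implied
#' by the logistic score at the bin centre, with exact (Clopper-Pearson)
#' binomial intervals. A model is well calibrated when observed fractions
#' track `plogis(bin centre)`.
#'
#' @param scores Risk scores on the log-odds scale.
#' @param labels 0/1 outcome labels.
#' @param subgroups Optional vector of subgroup labels (default: one group).
#'   Empty subgroups are skipped with a message.
#' @param bin_width Score-bin width in log-odds units (default 0.5).
#' @param min_n Bins with fewer rows are dropped from the table (reporting
#'   floor, default 1 keeps everything).
#' @param conf_level Interval coverage (default 0.95).
#' @return A `risk_calibration` tibble: `subgroup`, `bin_center`, `n`,
#'   `n_events`, `observed`, `expected` (logistic probability at the bin
#'   centre, the plotted reference), `expected_mean` (mean predicted
#'   probability of the rows actually in the bin — the correct binomial
#'   target, free of within-bin discretization bias), `lower`, `upper`.
#' @export
calibration <- function(scores, labels, subgroups = NULL, bin_width = 0.5,
                        min_n = 1L, conf_level = 0.95) {
  check_binary_metric_input(scores, labels)
  if (is.null(subgroups)) subgroups <- rep("all", length(scores))
  alpha <- 1 - conf_level
  tab <- tibble(score = scores, y = as.integer(labels),
                subgroup = as.character(subgroups)) |>
    mutate(bin_center = (floor(.data$score / bin_width) + 0.5) * bin_width) |>
    group_by(.data$subgroup, .data$bin_center) |>
    summarise(n = dplyr::n(), n_events = sum(.data$y),
              expected_mean = mean(plogis(.data$score)), .groups = "drop") |>
    filter(.data$n >= min_n) |>
    mutate(
      observed = .data$n_events / .data$n,
      expected = plogis(.data$bin_center),
      lower = qbeta(alpha / 2, .data$n_events, .data$n - .data$n_events + 1),
      upper = qbeta(1 - alpha / 2, .data$n_events + 1, .data$n - .data$n_events)
    )
  class(tab) <- c("risk_calibration", class(tab))
  tab
}

#' Concentration of risk in top score strata
#'
#' For each top fraction `q`, the ratio of the event fraction inside the
#' top-`q` score stratum to the overall event fraction — the screening-yield
#' multiplier of targeting the riskiest patients. Strata are nested (the top
#' 0.1% is a subset of the top 1%) and the ratio is bounded by the reciprocal
#' of the overall prevalence.
#'
#' @param scores Numeric risk scores.
#' @param labels 0/1 labels, or a data frame of 0/1 columns (one per outcome
#'   component).
#' @param q Top fractions (default 1% and 0.1%).
#' @return A `risk_strata` tibble: `q`, `component`, `n_stratum`, `n_events`,
#'   `stratum_fraction`, `overall_fraction`, `concentration`.
#' @export
concentration_of_risk <- function(scores, labels, q = c(0.01, 0.001)) {
  if (is.data.frame(labels)) {
    comp <- as_tibble(labels)
  } else {
    comp <- tibble(all = as.integer(labels))
  }
  if (any(q <= 0 | q >= 1)) input_error("q must lie in (0, 1)")
  n <- length(scores)
  ord <- order(scores, decreasing = TRUE)
  out <- list()
  for (qq in sort(q, decreasing = TRUE)) {
    k <- floor(qq * n)
    if (k < 1) {
      abort(sprintf("top fraction %g selects fewer than one row of %d", qq, n),
            class = "riskpipe_size_error")
    }
    idx <- ord[seq_len(k)]
    for (cc in names(comp)) {
      y <- comp[[cc]]
      overall <- mean(y)
      strat <- mean(y[idx])
      out[[length(out) + 1]] <- tibble(
        q = qq, component = cc, n_stratum = k, n_events = sum(y[idx]),
        stratum_fraction = strat, overall_fraction = overall,
        concentration = if (overall > 0) strat / overall else NA_real_
      )
    }
  }
  res <- list_rbind(out)
  class(res) <- c("risk_strata", class(res))
  res
}

#' Compare a frozen fine-tuning against a refreshed one on a later cohort
#'
#' The temporal-drift experiment: a stacking model whose coefficients were
#' frozen at an earlier prediction date is applied to a later cohort and
#' compared with a fine-tuning refit on that cohort (out-of-half scored under
#' the even/odd protocol). Reports discrimination and top-strata event counts
#' for both.
#'
#' @param frozen A fitted `risk_ensemble` (coefficients frozen at time T).
#' @param base_scores Base-model score matrix on the later cohort.
#' @param finetune Fine-tuning covariates on the later cohort.
#' @param labels 0/1 outcome labels of the later cohort.
#' @param is_even Even/odd half flags of the later cohort (for the refreshed
#'   refit).
#' @param q Top fractions for event counts.
#' @return Tibble with one row per scenario (`frozen`, `refreshed`): `auroc`
#'   plus `events_top_*` columns.
#' @export
drift_eval <- function(frozen, base_scores, finetune, labels, is_even,
                       q = c(0.01, 0.001)) {
  refreshed <- fit_ensemble(base_scores, finetune, labels, is_even,
                            target = frozen$target)
  score_frozen <- apply_ensemble(frozen, base_scores, finetune)
  score_refresh <- refreshed$oof_score
  one <- function(name, s) {
    cor_tab <- concentration_of_risk(s, labels, q)
    counts <- setNames(cor_tab$n_events,
                       paste0("events_top_", sub("^0\\.", "", format(cor_tab$q))))
    bind_cols(tibble(scenario = name, auroc = auroc(s, labels)),
              as_tibble(as.list(counts)))
  }
  bind_rows(one("frozen", score_frozen), one("refreshed", score_refresh))
}
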