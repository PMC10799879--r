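#' Score a target cohort with a registry of trained base models
#'
#' Applies every registered base model to the target cohort's design without
#' refitting. Cross-design scoring is legitimate because all cohorts share the
#' identical eight-bin schedule; a schedule mismatch is a contract error.
#'
#' @param registry Named list of `risk_model` objects (an `even_odd_fit` may
#'   be supplied; its `final` model is used).
#' @param features The target cohort's `risk_features`.
#' @return Numeric matrix, one column per registry entry.
#' @export
score_base_models <- function(registry, features) {
  stopifnot(length(registry) > 0, !is.null(names(registry)))
  models <- lapply(registry, function(m) {
    if (inherits(m, "even_odd_fit")) m$final else m
  })
  for (nm in names(models)) {
    sched <- models[[nm]]$meta$schedule
    if (!is.na(sched) && !identical(sched, features$schedule)) {
      abort(sprintf("base model '%s' was trained on schedule %s, target uses %s",
                    nm, sched, features$schedule),
            class = "riskpipe_contract_error")
    }
  }
  out <- vapply(models, function(m) predict(m, features), numeric(nrow(features$x)))
  matrix(out, nrow = nrow(features$x), dimnames = list(NULL, names(models)))
}

#' Fine-tune an ensemble by unpenalized logistic stacking
#'
#' Stacks the base-model scores with the ten design-dependent fine-tuning
#' covariates in a plain logistic regression — no cross-validation, no model
#' selection — fitted separately on the even and odd date-of-birth halves.
#' The final coefficients are the average of the two halves; each row's
#' retained score comes from the half it was not trained on. Base scores
#' enter unstandardized, so their coefficients are directly comparable to the
#' published convention (their range is roughly five times that of the binary
#' covariates). Rank-deficient columns are dropped with a message; complete
#' separation triggers a fallback refit with a tiny ridge penalty (1e-6) and
#' a warning.
#'
#' @param base_scores Matrix of base-model scores (columns named).
#' @param finetune Tibble/matrix of the ten fine-tuning covariates.
#' @param labels 0/1 outcome labels on the target cohort.
#' @param is_even Logical half indicator per row.
#' @param target `"combined"` or `"suicide"` tag recorded on the model.
#' @return A `risk_ensemble`: averaged `coefficients` (with intercept),
#'   per-half coefficient sets, and out-of-half `oof_score`.
#' @export
fit_ensemble <- function(base_scores, finetune, labels, is_even,
                         target = "combined") {
  x <- cbind(as.matrix(base_scores), as.matrix(finetune))
  if (is.null(colnames(x)) || anyDuplicated(colnames(x))) {
    input_error("base score and finetune columns must carry unique names")
  }
  y <- as.integer(labels)
  is_even <- as.logical(is_even)
  if (!any(is_even) || !any(!is_even)) {
    abort("a training half is empty", class = "riskpipe_size_error")
  }

  fit_half <- function(idx) {
    df <- as.data.frame(x[idx, , drop = FALSE])
    df$.y <- y[idx]
    fit <- suppressWarnings(glm(.y ~ ., data = df, family = binomial()))
    co <- coef(fit)
    dropped <- names(co)[is.na(co)]
    if (length(dropped)) {
      inform(paste0("rank-deficient fine-tuning design; dropped: ",
                    paste(dropped, collapse = ", ")))
      co[is.na(co)] <- 0
    }
    separated <- !fit$converged || any(abs(co) > 30)
    if (separated) {
      warn("separation detected in unpenalized fine-tuning; refitting with ridge 1e-6")
      rg <- glmnet::glmnet(x[idx, , drop = FALSE], y[idx], family = "binomial",
                           alpha = 0, lambda = 1e-6, standardize = FALSE)
      co <- c(`(Intercept)` = as.numeric(rg$a0),
              setNames(as.numeric(rg$beta), rownames(rg$beta)))
    }
    co
  }
  co_even <- fit_half(which(is_even))
  co_odd <- fit_half(which(!is_even))
  co <- (co_even + co_odd[names(co_even)]) / 2

  lin <- function(cc) drop(cbind(1, x) %*% cc[c("(Intercept)", colnames(x))])
  oof <- numeric(length(y))
  oof[is_even] <- lin(co_odd)[is_even]
  oof[!is_even] <- lin(co_even)[!is_even]

  structure(
    list(coefficients = co, coef_even = co_even, coef_odd = co_odd,
         base_names = colnames(base_scores), finetune_names = colnames(as.matrix(finetune)),
         target = target, oof_score = oof),
    class = "risk_ensemble"
  )
}

#' Apply a fitted ensemble to a cohort
#'
#' Linear combination of base scores and fine-tuning covariates plus
#' intercept; the logistic transform of the returned score is the predicted
#' outcome probability (the reference line of a calibration plot).
#'
#' @param model A `risk_ensemble`.
#' @param base_scores Base-score matrix with the model's base columns.
#' @param finetune Fine-tuning covariates with the model's covariate columns.
#' @return Numeric log-odds score per row.
#' @export
apply_ensemble <- function(model, base_scores, finetune) {
  x <- cbind(as.matrix(base_scores), as.matrix(finetune))
  need <- setdiff(c(model$base_names, model$finetune_names), colnames(x))
  if (length(need)) {
    abort(paste0("ensemble inputs missing columns: ", paste(need, collapse = ", ")),
          class = "riskpipe_contract_error")
  }
  x <- x[, c(model$base_names, model$finetune_names), drop = FALSE]
  cc <- model$coefficients[c("(Intercept)", colnames(x))]
  drop(cbind(1, x) %*% cc)
}

#' @export
print.risk_ensemble <- function(x, ...) {
  cat("<risk_ensemble> target:", x$target, "|", length(x$base_names),
      "base models +", length(x$finetune_names), "fine-tuning covariates\n")
  invisible(x)
}

#' Tidy method for ensembles and linear base models
#'
#' @param x A `risk_ensemble` or linear-kind `risk_model`.
#' @param ... Unused.
#' @return A tibble of terms and estimates; ensemble terms are typed as
#'   `intercept`, `base_model` or `finetune`.
#' @export
tidy.risk_ensemble <- function(x, ...) {
  tibble(
    term = names(x$coefficients),
    estimate = unname(x$coefficients),
    type = dplyr::case_when(
      names(x$coefficients) == "(Intercept)" ~ "intercept",
      names(x$coefficients) %in% x$base_names ~ "base_model",
      TRUE ~ "finetune"
    )
  )
}

#' Glance method for ensembles and base models
#'
#' @param x A `risk_ensemble` or `risk_model`.
#' @param ... Unused.
#' @return A one-row tibble of model-level summaries.
#' @export
glance.risk_ensemble <- function(x, ...) {
  tibble(target = x$target, n_base = length(x$base_names),
         n_finetune = length(x$finetune_names))
}
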