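#' Base-learner hyperparameter configuration
#'
#' Defaults follow the reference settings: random forest with 500 trees,
#' square-root-of-p features per split and a minimum of 100 samples per leaf;
#' a fully connected network with hidden layers of 1024, 512 and 256 rectified
#' linear units; lasso logistic regression with the penalty chosen at the
#' cross-validated deviance minimum (`select = "lambda.1se"` switches to the
#' one-standard-error rule, which recovers a sparse generating support almost
#' exactly and is the right choice when the selected variable set itself is
#' the readout; the minimum predicts better on small cohorts but admits many
#' near-zero spurious terms); Bernoulli naive Bayes with additive smoothing 1.
#'
#' @param ... Named overrides merged into the per-kind defaults, e.g.
#'   `learner_config(mlp = list(hidden = c(16, 8)))`.
#' @return A `learner_config` list.
#' @export
learner_config <- function(...) {
  defaults <- list(
    glm_lasso = list(nfolds = 5L, select = "lambda.min"),
    cox = list(nfolds = 5L, select = "lambda.min", nlambda = 50L,
               lambda_min_ratio = 0.05),
    rf = list(num_trees = 500L, min_node = 100L, mtry = NULL),
    mlp = list(hidden = c(1024L, 512L, 256L), epochs = 30L, batch_size = 256L,
               lr = 1e-3, l2 = 1e-4, val_frac = 0.1, patience = 5L),
    nb = list(smooth = 1)
  )
  over <- list(...)
  for (k in names(over)) defaults[[k]] <- utils::modifyList(defaults[[k]], over[[k]])
  structure(defaults, class = "learner_config")
}

model_kinds <- function() c("glm_lasso", "cox", "rf", "mlp", "nb")
linear_kinds <- function() c("glm_lasso", "cox", "nb")

resolve_target <- function(features, target) {
  if (!is.null(target)) return(target)
  as.integer(features$cohort$is_case)
}

feature_matrix <- function(features) {
  if (inherits(features, "risk_features")) features$x else as.matrix(features)
}

#' Fit a base prediction model
#'
#' One uniform contract over the five learner kinds: lasso-penalized logistic
#' regression, lasso Cox proportional hazards, probability random forest,
#' feed-forward ReLU network, and Bernoulli naive Bayes (binary columns only).
#' Linear kinds expose per-column coefficients on the log-odds (or log-hazard)
#' scale; all kinds score through [predict.risk_model()].
#'
#' @param features A `risk_features` object (or plain design matrix).
#' @param kind One of `"glm_lasso"`, `"cox"`, `"rf"`, `"mlp"`, `"nb"`.
#' @param target Binary 0/1 vector, or for `"cox"` a two-column matrix / data
#'   frame with `time` and `event`; defaults to the cohort's `is_case` flag
#'   (and `time_to_event_days`/`censored` for Cox).
#' @param config A [learner_config()].
#' @param seed RNG seed for the stochastic kinds.
#' @return A `risk_model`.
#' @export
fit_base_model <- function(features, kind = model_kinds(), target = NULL,
                           config = learner_config(), seed = 1L) {
  kind <- match.arg(kind)
  x <- feature_matrix(features)
  if (is.null(colnames(x))) colnames(x) <- paste0("V", seq_len(ncol(x)))

  n_distinct_col <- apply(x[seq_len(min(nrow(x), 2000L)), , drop = FALSE], 2,
                          function(v) length(unique(v)))
  if (all(n_distinct_col == 1L) && all(apply(x, 2, function(v) length(unique(v))) == 1L)) {
    abort(paste0("design is degenerate: all columns constant (e.g. ",
                 paste(head(colnames(x), 3), collapse = ", "), ", ...)"),
          class = "riskpipe_fit_error")
  }

  if (kind == "cox") {
    if (is.null(target)) {
      if (!all(c("time_to_event_days", "censored") %in% names(features$cohort))) {
        input_error("cox kind requires a time-to-event target")
      }
      target <- data.frame(time = features$cohort$time_to_event_days,
                           event = as.integer(!features$cohort$censored))
    }
    if (sum(target$event) == 0) {
      abort("cox fit impossible: no events in target", class = "riskpipe_fit_error")
    }
  } else {
    target <- resolve_target(features, target)
    if (length(unique(target)) < 2) {
      abort("target is single-class; cannot fit", class = "riskpipe_fit_error")
    }
  }

  fit <- withr::with_seed(seed, switch(
    kind,
    glm_lasso = {
      cv <- glmnet::cv.glmnet(x, target, family = "binomial",
                              nfolds = config$glm_lasso$nfolds,
                              type.measure = "deviance")
      s_rule <- config$glm_lasso$select
      co <- coef(cv, s = s_rule)
      list(intercept = co[1, 1], beta = setNames(co[-1, 1], rownames(co)[-1]),
           lambda = cv[[s_rule]])
    },
    cox = {
      y <- survival::Surv(target$time, target$event)
      # a shortened penalty path: the partial-likelihood path at small lambda
      # is by far the most expensive part of the fit and is never selected
      cv <- glmnet::cv.glmnet(x, y, family = "cox", nfolds = config$cox$nfolds,
                              nlambda = config$cox$nlambda,
                              lambda.min.ratio = config$cox$lambda_min_ratio)
      s_rule <- config$cox$select
      co <- coef(cv, s = s_rule)
      list(intercept = 0, beta = setNames(as.numeric(co), rownames(co)),
           lambda = cv[[s_rule]])
    },
    rf = {
      mtry <- config$rf$mtry %||% max(1L, floor(sqrt(ncol(x))))
      obj <- ranger::ranger(
        y = factor(target, levels = c(0, 1)), x = x, probability = TRUE,
        num.trees = config$rf$num_trees, mtry = mtry,
        min.node.size = config$rf$min_node, seed = seed, num.threads = 1,
        verbose = FALSE
      )
      list(object = obj)
    },
    mlp = {
      cf <- config$mlp
      list(object = mlp_fit(x, target, hidden = cf$hidden, epochs = cf$epochs,
                            batch_size = cf$batch_size, lr = cf$lr, l2 = cf$l2,
                            val_frac = cf$val_frac, patience = cf$patience,
                            seed = seed))
    },
    nb = {
      is_bin <- apply(x, 2, function(v) all(v %in% c(0, 1)))
      if (!any(is_bin)) abort("naive Bayes requires binary columns",
                              class = "riskpipe_fit_error")
      xb <- x[, is_bin, drop = FALSE]
      s <- config$nb$smooth
      n1 <- sum(target == 1); n0 <- sum(target == 0)
      p1 <- (colSums(xb[target == 1, , drop = FALSE]) + s) / (n1 + 2 * s)
      p0 <- (colSums(xb[target == 0, , drop = FALSE]) + s) / (n0 + 2 * s)
      w <- log(p1 / (1 - p1)) - log(p0 / (1 - p0))
      beta <- setNames(rep(0, ncol(x)), colnames(x))
      beta[is_bin] <- w
      list(intercept = log(n1 / n0) + sum(log((1 - p1) / (1 - p0))),
           beta = beta)
    }
  ))

  structure(
    list(kind = kind, fit = fit,
         intercept = fit$intercept %||% NA_real_, beta = fit$beta,
         columns = colnames(x), config = config,
         meta = list(
           seed = seed,
           target = if (kind == "cox") "time-to-event" else "binary",
           design_tag = if (inherits(features, "risk_features"))
             features$cohort$design_tag[1] else NA_character_,
           schedule = if (inherits(features, "risk_features"))
             features$schedule else NA_character_,
           support = if (kind %in% c("glm_lasso", "cox"))
             names(fit$beta)[fit$beta != 0] else NULL
         )),
    class = c(paste0("risk_model_", kind), "risk_model")
  )
}

#' Score a cohort with a fitted base model
#'
#' Pure with respect to the model (no state mutation); returns the risk score
#' on the log-odds scale for probabilistic kinds and the linear predictor for
#' Cox. The design columns must match the columns the model was trained on.
#'
#' @param object A `risk_model`.
#' @param features A `risk_features` object or design matrix.
#' @param ... Unused.
#' @return Numeric score vector, one per row.
#' @export
predict.risk_model <- function(object, features, ...) {
  x <- feature_matrix(features)
  if (is.null(colnames(x))) colnames(x) <- paste0("V", seq_len(ncol(x)))
  missing <- setdiff(object$columns, colnames(x))
  if (length(missing)) {
    abort(paste0("design does not match training columns; missing: ",
                 paste(head(missing, 3), collapse = ", ")),
          class = "riskpipe_schema_error")
  }
  x <- x[, object$columns, drop = FALSE]
  switch(
    object$kind,
    rf = {
      p <- predict(object$fit$object, data = x, num.threads = 1)$predictions[, "1"]
      safe_qlogis(p)
    },
    mlp = mlp_logits(object$fit$object$layers, x),
    # linear kinds share (intercept, beta)
    drop(x %*% object$beta) + object$intercept
  )
}

#' @export
print.risk_model <- function(x, ...) {
  cat("<risk_model>", x$kind, "on", length(x$columns), "columns")
  if (!is.null(x$meta$support)) cat("; support", length(x$meta$support))
  cat("\n")
  invisible(x)
}

#' @rdname tidy.risk_ensemble
#' @export
tidy.risk_model <- function(x, ...) {
  if (is.null(x$beta)) {
    abort("tidy() is available for linear model kinds only")
  }
  tibble(term = c("(Intercept)", names(x$beta)),
         estimate = c(x$intercept, unname(x$beta)))
}

#' @rdname glance.risk_ensemble
#' @export
glance.risk_model <- function(x, ...) {
  tibble(kind = x$kind, n_columns = length(x$columns),
         n_support = length(x$meta$support %||% NA))
}

#' Fit a model under the even/odd date-of-birth protocol
#'
#' Two models are trained, one on the even DOB partitions and one on the odd.
#' For metric purposes every row is scored by the model trained on the other
#' half (out-of-half scores). The reported final model is the coefficient
#' average of the two halves for linear kinds; for non-linear kinds the
#' odd-trained model is designated the evaluator.
#'
#' @param features A `risk_features` whose cohort carries `is_even`.
#' @param kind Learner kind, see [fit_base_model()].
#' @param target Optional explicit target (see [fit_base_model()]).
#' @param config A [learner_config()].
#' @param seed RNG seed.
#' @return An `even_odd_fit`: `final` model, per-half models, out-of-half
#'   `oof_score`, and the two train/test AUROCs with their mean (binary
#'   targets only).
#' @export
even_odd_protocol <- function(features, kind, target = NULL,
                              config = learner_config(), seed = 1L) {
  cohort <- features$cohort
  stopifnot("is_even" %in% names(cohort))
  even <- which(cohort$is_even)
  odd <- which(!cohort$is_even)
  if (!length(even) || !length(odd)) {
    abort("a training half is empty", class = "riskpipe_size_error")
  }
  subset_features <- function(idx) {
    f <- features
    f$x <- f$x[idx, , drop = FALSE]
    f$cohort <- f$cohort[idx, ]
    f$finetune <- f$finetune[idx, ]
    f
  }
  sub_target <- function(idx) {
    if (is.null(target)) NULL
    else if (is.data.frame(target)) target[idx, ] else target[idx]
  }
  fit_even <- fit_base_model(subset_features(even), kind, sub_target(even),
                             config, derive_seed(seed, "even"))
  fit_odd <- fit_base_model(subset_features(odd), kind, sub_target(odd),
                            config, derive_seed(seed, "odd"))

  oof <- numeric(nrow(features$x))
  oof[even] <- predict(fit_odd, subset_features(even))
  oof[odd] <- predict(fit_even, subset_features(odd))

  final <- if (kind %in% linear_kinds()) {
    avg <- fit_even
    avg$intercept <- (fit_even$intercept + fit_odd$intercept) / 2
    avg$beta <- (fit_even$beta + fit_odd$beta) / 2
    avg$fit <- list(intercept = avg$intercept, beta = avg$beta)
    avg$meta$support <- names(avg$beta)[avg$beta != 0]
    avg$meta$half <- "averaged"
    avg
  } else {
    out <- fit_odd
    out$meta$half <- "odd-trained evaluator"
    out
  }

  auroc_pair <- if (kind != "cox" && is.null(target)) {
    y <- as.integer(cohort$is_case)
    c(train_even_test_odd = auroc(oof[odd], y[odd]),
      train_odd_test_even = auroc(oof[even], y[even]))
  } else NULL

  structure(
    list(final = final, even_fit = fit_even, odd_fit = fit_odd,
         oof_score = oof, kind = kind,
         auroc_pair = auroc_pair,
         auroc = if (!is.null(auroc_pair)) mean(auroc_pair) else NA_real_),
    class = "even_odd_fit"
  )
}

#' @export
print.even_odd_fit <- function(x, ...) {
  cat("<even_odd_fit>", x$kind)
  if (!is.na(x$auroc)) cat(sprintf("; mean out-of-half AUROC %.3f", x$auroc))
  cat("\n")
  invisible(x)
}
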