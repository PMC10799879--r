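# direct sparse-logistic data generator for recovery checks (independent of
# the EMR generator)
sparse_logit_data <- function(n, p = 100, k = 10, beta = 0.8, intercept = -2.5,
                              seed = 1) {
  withr::with_seed(seed, {
    x <- matrix(rbinom(n * p, 1, 0.15), n, p)
    colnames(x) <- paste0("V", seq_len(p))
    true <- c(rep(beta, k), rep(0, p - k))
    y <- rbinom(n, 1, plogis(intercept + drop(x %*% true)))
    list(x = x, y = y, support = paste0("V", seq_len(k)), true = true,
         intercept = intercept)
  })
}

test_that("lasso logistic regression recovers a sparse generating support", {
  d <- sparse_logit_data(20000)
  # the 1-SE rule is the support-readout setting; the default (deviance
  # minimum) optimizes prediction and admits near-zero spurious terms
  fit <- fit_base_model(d$x, "glm_lasso", d$y,
                        config = learner_config(glm_lasso = list(select = "lambda.1se")),
                        seed = 2)
  sup <- fit$meta$support
  expect_true(all(d$support %in% sup))
  expect_lte(length(setdiff(sup, d$support)), 5)
})

test_that("lasso coefficient bias shrinks as n grows", {
  err <- vapply(c(4000, 20000), function(n) {
    d <- sparse_logit_data(n, seed = 5)
    fit <- fit_base_model(d$x, "glm_lasso", d$y, seed = 2)
    mean(abs(fit$beta[d$support] - 0.8))
  }, numeric(1))
  expect_lt(err[2], err[1])
})

test_that("hyperparameter defaults match the reference settings", {
  cfg <- learner_config()
  expect_equal(cfg$rf$num_trees, 500L)
  expect_equal(cfg$rf$min_node, 100L)
  expect_null(cfg$rf$mtry) # resolved to sqrt(p) at fit time
  expect_equal(cfg$mlp$hidden, c(1024L, 512L, 256L))
  expect_equal(cfg$nb$smooth, 1)
  d <- sparse_logit_data(800, p = 16)
  fit <- fit_base_model(d$x, "rf", d$y,
                        config = learner_config(rf = list(num_trees = 50L)),
                        seed = 3)
  expect_equal(fit$fit$object$num.trees, 50)
  expect_equal(fit$fit$object$mtry, 4) # sqrt(16)
})

test_that("scoring is pure, linear in indicators, and schema-checked", {
  d <- sparse_logit_data(3000, p = 30, k = 5)
  fit <- fit_base_model(d$x, "glm_lasso", d$y, seed = 2)
  s1 <- predict(fit, d$x)
  s2 <- predict(fit, d$x)
  expect_identical(s1, s2)
  # all-reference row scores the intercept
  x0 <- matrix(0L, 1, ncol(d$x), dimnames = list(NULL, colnames(d$x)))
  expect_equal(unname(predict(fit, x0)), fit$intercept)
  # flipping a positively weighted indicator strictly increases the score
  j <- names(which(fit$beta > 0))[1]
  x1 <- x0; x1[1, j] <- 1L
  expect_gt(predict(fit, x1), predict(fit, x0))
  # column mismatch is a schema error
  expect_error(predict(fit, d$x[, -1]), class = "riskpipe_schema_error")
})

test_that("degenerate inputs fail loudly", {
  x <- matrix(0L, 50, 3, dimnames = list(NULL, c("a", "b", "c")))
  y <- rbinom(50, 1, 0.5)
  expect_error(fit_base_model(x, "glm_lasso", y), class = "riskpipe_fit_error")
  d <- sparse_logit_data(200, p = 10)
  expect_error(fit_base_model(d$x, "cox",
                              data.frame(time = rexp(200), event = 0)),
               class = "riskpipe_fit_error")
  expect_error(fit_base_model(d$x, "glm_lasso", rep(1, 200)),
               class = "riskpipe_fit_error")
})

test_that("all five kinds satisfy one fit/score contract", {
  pop <- test_pop(600, seed = 8)
  cl <- classify_events(pop)
  coh <- build_calendar_cohort(pop, cl, "2015-01-01", k_partitions = 10)
  f <- encode_features(pop, coh)
  cfg <- test_learners()
  for (kind in c("glm_lasso", "rf", "mlp", "nb")) {
    # small-fold class-count warnings from cross-validation are expected at
    # this fixture size
    m <- suppressWarnings(fit_base_model(f, kind, config = cfg, seed = 4))
    s <- predict(m, f)
    expect_length(s, nrow(f$x))
    expect_true(all(is.finite(s)), info = kind)
  }
  cox_coh <- build_event_cohort(pop, cl, "office", k_partitions = 10)
  fcox <- encode_features(pop, cox_coh)
  mc <- fit_base_model(fcox, "cox", config = cfg, seed = 4)
  expect_length(predict(mc, fcox), nrow(fcox$x))
})

test_that("even/odd averaging is symmetric and leak-free", {
  # duplicated halves: averaged linear coefficients equal either half's
  d <- sparse_logit_data(400, p = 12, k = 3, seed = 9)
  x2 <- rbind(d$x, d$x)
  y2 <- c(d$y, d$y)
  f <- structure(list(
    x = x2,
    cohort = tibble::tibble(row_id = seq_len(800), is_even = rep(c(TRUE, FALSE),
                                                                 each = 400),
                            is_case = y2 == 1, design_tag = "toy"),
    finetune = tibble::tibble(.rows = 800), schedule = "8-bin-3-3-6-6-12-12-24-24"
  ), class = "risk_features")
  eo <- even_odd_protocol(f, "nb", seed = 1)
  expect_equal(eo$final$beta, eo$even_fit$beta, tolerance = 1e-12)
  expect_equal(eo$final$intercept, eo$even_fit$intercept, tolerance = 1e-12)
  # reported AUROC is the mean of the two half-AUROCs
  expect_equal(eo$auroc, mean(eo$auroc_pair), tolerance = 1e-12)
  # out-of-half provenance: even rows scored by the odd-trained model
  even_rows <- which(f$cohort$is_even)
  expect_equal(eo$oof_score[even_rows],
               unname(predict(eo$odd_fit, x2[even_rows, , drop = FALSE])),
               tolerance = 1e-12)
  odd_rows <- which(!f$cohort$is_even)
  expect_equal(eo$oof_score[odd_rows],
               unname(predict(eo$even_fit, x2[odd_rows, , drop = FALSE])),
               tolerance = 1e-12)
  # empty half errors
  f_bad <- f
  f_bad$cohort$is_even <- TRUE
  expect_error(even_odd_protocol(f_bad, "nb"), class = "riskpipe_size_error")
})

test_that("bernoulli naive Bayes matches an independent reference implementation", {
  skip_if_not_installed("e1071")
  d <- sparse_logit_data(500, p = 8, k = 3, seed = 31)
  fit <- fit_base_model(d$x, "nb", d$y)
  ours <- predict(fit, d$x)
  df <- as.data.frame(lapply(as.data.frame(d$x), factor, levels = c(0, 1)))
  ref <- e1071::naiveBayes(df, factor(d$y, levels = c(0, 1)), laplace = 1)
  p <- predict(ref, df, type = "raw")[, "1"]
  expect_equal(unname(ours), qlogis(p), tolerance = 1e-8)
})
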