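fake_finetune <- function(n, seed = 1) {
  withr::with_seed(seed, {
    tibble::tibble(
      sex_female = rbinom(n, 1, 0.1), race_black = rbinom(n, 1, 0.15),
      ethnicity_hispanic = rbinom(n, 1, 0.07), age_young = rbinom(n, 1, 0.3),
      age_old = rbinom(n, 1, 0.4), chronic_pain = rbinom(n, 1, 0.2),
      suicide_ideation = rbinom(n, 1, 0.05), suicide_attempt = rbinom(n, 1, 0.03),
      overdose = rbinom(n, 1, 0.03), usage = rpois(n, 20)
    )
  })
}

test_that("base-model scoring is shape-stable, deterministic and refit-free", {
  pop <- test_pop(600, seed = 8)
  cl <- classify_events(pop)
  lab <- build_combined_outcome(cl, c(as.Date("2007-08-16"),
                                      pop$config$calendar_range[2]),
                                patient_ids = pop$patients$patient_id)
  rcc <- build_rcc(pop, lab, rcc_config(k_partitions = 10, seed = 2))
  frcc <- encode_features(pop, rcc)
  c15 <- build_calendar_cohort(pop, cl, "2015-01-01", k_partitions = 10)
  f15 <- encode_features(pop, c15)
  m_rcc <- fit_base_model(frcc, "glm_lasso", seed = 3)
  m_nb <- fit_base_model(frcc, "nb", seed = 3)
  # an Rcc-trained model scores a calendar cohort without refitting
  sc <- score_base_models(list(rcc_glm = m_rcc, rcc_nb = m_nb), f15)
  expect_equal(dim(sc), c(nrow(f15$x), 2))
  expect_identical(sc, score_base_models(list(rcc_glm = m_rcc, rcc_nb = m_nb), f15))
  # schedule mismatch is a contract error
  m_bad <- m_rcc
  m_bad$meta$schedule <- "other-schedule"
  expect_error(score_base_models(list(x = m_bad), f15),
               class = "riskpipe_contract_error")
})

test_that("ensemble stacking recovers a known generating weight", {
  withr::with_seed(21, {
    n <- 20000
    scores <- matrix(rnorm(n * 7), n, 7,
                     dimnames = list(NULL, paste0("base_", letters[1:7])))
    ft <- fake_finetune(n)
    y <- rbinom(n, 1, plogis(scores[, "base_a"]))
    ens <- fit_ensemble(scores, ft, y, rep(c(TRUE, FALSE), n / 2))
    co <- ens$coefficients
    expect_lt(abs(co[["base_a"]] - 1), 0.15)
    other <- co[paste0("base_", letters[2:7])]
    expect_true(all(abs(other) < 0.15))
    # structure: 7 base + 10 finetune coefficients + intercept
    expect_length(ens$base_names, 7)
    expect_length(ens$finetune_names, 10)
    expect_length(co, 18)
  })
})

test_that("identical score columns exercise the rank-deficiency path", {
  withr::with_seed(3, {
    n <- 2000
    s <- rnorm(n)
    scores <- cbind(a = s, b = s, c = s)
    ft <- fake_finetune(n)
    y <- rbinom(n, 1, plogis(s))
    expect_message(ens <- fit_ensemble(scores, ft, y, rep(c(TRUE, FALSE), n / 2)),
                   "rank-deficient")
    expect_true(all(is.finite(ens$coefficients)))
    # only one of the duplicate columns carries weight
    expect_equal(sum(abs(ens$coefficients[c("b", "c")]) > 1e-8), 0)
  })
})

test_that("separation triggers the ridge fallback with a warning", {
  n <- 200
  s <- c(rnorm(n / 2, -4), rnorm(n / 2, 4))
  y <- as.integer(s > 0)
  scores <- cbind(only = s)
  ft <- fake_finetune(n)
  ws <- testthat::capture_warnings(
    ens <- fit_ensemble(scores, ft, y, rep(c(TRUE, FALSE), n / 2)))
  expect_true(any(grepl("separation", ws)))
  expect_true(all(is.finite(ens$coefficients)))
})

test_that("applying an ensemble is an affine map with monotone indicators", {
  withr::with_seed(5, {
    n <- 4000
    scores <- matrix(rnorm(n * 2), n, 2, dimnames = list(NULL, c("a", "b")))
    ft <- fake_finetune(n)
    y <- rbinom(n, 1, plogis(scores[, 1] + ft$suicide_ideation))
    ens <- fit_ensemble(scores, ft, y, rep(c(TRUE, FALSE), n / 2))
    # all-zero inputs return the intercept
    z <- apply_ensemble(ens, matrix(0, 1, 2, dimnames = list(NULL, c("a", "b"))),
                        fake_finetune(1) |> dplyr::mutate(dplyr::across(
                          dplyr::everything(), ~0)))
    expect_equal(unname(z), unname(ens$coefficients[["(Intercept)"]]))
    # flipping the ideation aggregate raises the score by its (positive) weight
    expect_gt(ens$coefficients[["suicide_ideation"]], 0)
    f0 <- fake_finetune(1) |> dplyr::mutate(dplyr::across(dplyr::everything(), ~0))
    f1 <- dplyr::mutate(f0, suicide_ideation = 1)
    s0 <- matrix(0, 1, 2, dimnames = list(NULL, c("a", "b")))
    expect_gt(apply_ensemble(ens, s0, f1), apply_ensemble(ens, s0, f0))
    # out-of-half provenance: even rows scored with odd-half coefficients
    x <- cbind(1, scores, as.matrix(ft))
    even <- rep(c(TRUE, FALSE), n / 2)
    manual <- drop(x %*% ens$coef_odd[c("(Intercept)", colnames(scores),
                                        colnames(ft))])
    expect_equal(ens$oof_score[even], manual[even], tolerance = 1e-10)
    # missing columns are a contract error
    expect_error(apply_ensemble(ens, s0[, 1, drop = FALSE], f0),
                 class = "riskpipe_contract_error")
  })
})

test_that("tidy and glance expose ensemble structure", {
  withr::with_seed(6, {
    n <- 1000
    scores <- matrix(rnorm(n * 2), n, 2, dimnames = list(NULL, c("a", "b")))
    ft <- fake_finetune(n)
    y <- rbinom(n, 1, plogis(scores[, 1]))
    ens <- fit_ensemble(scores, ft, y, rep(c(TRUE, FALSE), n / 2),
                        target = "suicide")
    td <- tidy(ens)
    expect_setequal(unique(td$type), c("intercept", "base_model", "finetune"))
    expect_equal(sum(td$type == "finetune"), 10)
    gl <- glance(ens)
    expect_equal(gl$target, "suicide")
    expect_equal(gl$n_base, 2)
  })
})

test_that("a frozen ensemble transfers to a shifted cohort; refreshing re-centres it", {
  withr::with_seed(31, {
    n <- 30000
    make_cohort <- function(shift) {
      scores <- matrix(rnorm(n * 2), n, 2, dimnames = list(NULL, c("a", "b")))
      ft <- fake_finetune(n, seed = round(shift * 10) + 2)
      y <- rbinom(n, 1, plogis(scores[, 1] - 2 + shift))
      list(scores = scores, ft = ft, y = y, parity = rep(c(TRUE, FALSE), n / 2))
    }
    c1 <- make_cohort(0)
    ens <- fit_ensemble(c1$scores, c1$ft, c1$y, c1$parity, target = "suicide")
    # null drift: frozen and refreshed agree within Monte-Carlo error
    c2 <- make_cohort(0)
    rep0 <- drift_eval(ens, c2$scores, c2$ft, c2$y, c2$parity)
    expect_lt(abs(rep0$auroc[1] - rep0$auroc[2]), 0.02)
    # prevalence changepoint: the frozen model's calibration intercept is off
    c3 <- make_cohort(-1.5)
    frozen_score <- apply_ensemble(ens, c3$scores, c3$ft)
    refreshed <- fit_ensemble(c3$scores, c3$ft, c3$y, c3$parity)
    miscal_frozen <- abs(mean(plogis(frozen_score)) - mean(c3$y))
    miscal_refresh <- abs(mean(plogis(refreshed$oof_score)) - mean(c3$y))
    expect_gt(miscal_frozen, 3 * miscal_refresh)
    rep1 <- drift_eval(ens, c3$scores, c3$ft, c3$y, c3$parity)
    expect_equal(rep1$scenario, c("frozen", "refreshed"))
    expect_true(all(is.finite(rep1$auroc)))
  })
})
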