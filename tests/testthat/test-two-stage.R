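test_that("cutoff tuning matches brute force on hand instances", {
  res <- tune_cutoff(
    c(0.1, 0.2, 0.8, 0.9),
    c("short", "short", "prolonged", "prolonged")
  )
  expect_gt(res$cutoff, 0.2)
  expect_lte(res$cutoff, 0.8)
  expect_equal(res$short_sensitivity, 1)
  expect_equal(res$prolonged_sensitivity, 1)

  # degenerate target: everyone may be called prolonged
  res0 <- tune_cutoff(
    c(0.1, 0.2, 0.8, 0.9),
    c("short", "short", "prolonged", "prolonged"),
    target = 0
  )
  expect_equal(res0$prolonged_sensitivity, 1)

  # all scores equal: only the everyone-short rule attains the target
  same <- tune_cutoff(
    rep(0.5, 6), c("short", "short", "short", "short", "prolonged", "prolonged"),
    target = 0.99
  )
  expect_gt(same$cutoff, 0.5)
  expect_equal(same$prolonged_sensitivity, 0)
  expect_equal(same$short_sensitivity, 1)

  # genuinely infeasible: a short encounter carries the maximal score 1
  expect_error(
    tune_cutoff(c(1, 0.5), c("short", "prolonged"), target = 0.99),
    "best attainable"
  )
})

test_that("cutoff tuning agrees with exhaustive enumeration", {
  set.seed(31)
  for (i in 1:150) {
    n <- sample(4:12, 1)
    scores <- round(runif(n, 0, 0.99), 2)
    labels <- ifelse(runif(n) < 0.4, "prolonged", "short")
    if (length(unique(labels)) < 2) next
    target <- sample(c(0.5, 0.8, 0.99, 1), 1)
    got <- tune_cutoff(scores, labels, target)
    want <- oracle_best_cutoff(scores, labels, target)
    expect_equal(got$cutoff, want$cutoff)
    expect_equal(got$short_sensitivity, want$ss)
    expect_equal(got$prolonged_sensitivity, want$ps)
  }
})

test_that("the alternative mode targets prolonged-class sensitivity", {
  res <- tune_cutoff(
    c(0.1, 0.2, 0.8, 0.9), c("short", "short", "prolonged", "prolonged"),
    target = 1, mode = "prolonged_sensitivity"
  )
  expect_lte(res$cutoff, 0.8)
  expect_equal(res$prolonged_sensitivity, 1)
})

test_that("out-of-fold scores are required to come from both classes", {
  expect_error(tune_cutoff(c(.1, .2), c("short", "short")), "both classes")
  expect_error(tune_cutoff(c(.1, 1.2), c("short", "prolonged")), "probabilities")
})

test_that("a separable cohort is gated perfectly", {
  co <- generate_cohort(cohort_spec(n = 1200, separable_mode = TRUE, seed = 21))
  # mtry beyond the encoded feature count is clamped to it: every split
  # considers the deterministic high_risk indicator, so gating is exact
  fit <- fit_two_stage(
    co, los, quick_two_stage_config(seed = 21, mtry = 50)
  )
  expect_equal(fit$cutoff$short_sensitivity, 1)
  expect_equal(fit$cutoff$prolonged_sensitivity, 1)
  held <- generate_cohort(
    cohort_spec(n = 800, separable_mode = TRUE, seed = 22)
  )
  pred <- predict(fit, held)
  expect_equal(pred$is_prolonged, held$high_risk == "yes")
  # every truly short encounter receives a numeric estimate
  expect_true(all(!is.na(pred$los_estimate[held$los < 7])))
})

test_that("stage-2 membership follows the <= tau_r convention", {
  set.seed(23)
  n <- 120
  base <- tibble::tibble(
    x = rnorm(n),
    los = c(
      runif(n - 12, 0.5, 6.5), rep(7, 4),
      runif(6, 8, 30), c(40, 60)
    )
  )
  cfg <- quick_two_stage_config(seed = 23, tau_r = 7)
  fit <- fit_two_stage(base, los, cfg)
  expect_equal(fit$n_stage2, sum(base$los <= 7)) # boundary rows included
  cfg35 <- quick_two_stage_config(seed = 23, tau_r = 35)
  fit35 <- fit_two_stage(base, los, cfg35)
  expect_equal(fit35$n_stage2, sum(base$los <= 35))
})

test_that("degenerate training outcomes are rejected", {
  d <- tibble::tibble(x = rnorm(50), los = runif(50, 0.5, 6))
  expect_error(
    fit_two_stage(d, los, quick_two_stage_config()),
    "both classes"
  )
  expect_error(two_stage_config(tau_c = 7, tau_r = 5), "tau_r")
})

test_that("gated predictions partition every sample", {
  co <- generate_cohort(cohort_spec(n = 900, seed = 25))
  fit <- fit_two_stage(co, los, quick_two_stage_config(seed = 25))
  held <- generate_cohort(cohort_spec(n = 500, seed = 26))
  pred <- predict(fit, held)
  expect_equal(nrow(pred), 500)
  expect_true(all(pred$is_prolonged == is.na(pred$los_estimate)))
  expect_true(all(pred$los_estimate >= 0, na.rm = TRUE))
  expect_error(predict(fit, held[, 1:3]), "missing training column")
})

test_that("stage-2 estimates can exceed the classifier threshold", {
  co <- generate_cohort(cohort_spec(n = 3000, seed = 27))
  fit <- fit_two_stage(co, los, quick_two_stage_config(seed = 27, tau_r = 35))
  pred <- predict(fit, co)
  expect_gt(max(pred$los_estimate, na.rm = TRUE), 7)
})

test_that("a single-threshold sweep reproduces the direct fit", {
  co <- generate_cohort(cohort_spec(n = 800, seed = 28))
  parts <- split_data(co, split_spec(seed = 28))
  cfg <- quick_two_stage_config(seed = 28, tau_r = 21)
  swept <- sweep_regressor_threshold(
    parts$train, parts$test, los,
    config = cfg, taus = 21
  )
  fit <- fit_two_stage(parts$train, los, cfg)
  pred <- impute_gated(predict(fit, parts$test), tau_c = 7)
  expect_equal(
    swept$customized,
    loss_customized(parts$test$los, pred$scored_estimate, 7)
  )
  expect_equal(swept$mae, loss_mae(parts$test$los, pred$scored_estimate))
  expect_error(
    sweep_regressor_threshold(parts$train, parts$test, los,
      config = cfg, taus = c(3, 21)
    ),
    "tau_c"
  )
})

test_that("tidy and glance expose the fitted configuration", {
  co <- generate_cohort(cohort_spec(n = 600, seed = 29))
  fit <- fit_two_stage(co, los, quick_two_stage_config(seed = 29))
  td <- tidy(fit)
  expect_true(all(c("component", "term", "value") %in% names(td)))
  gl <- glance(fit)
  expect_equal(gl$n_train, 600)
  expect_equal(gl$tau_c, 7)
  expect_gte(gl$oof_short_sensitivity, 0.99)
  expect_equal(gl$stage2_transform, "log")
})
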