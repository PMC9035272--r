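test_that("the train/test split is exact, disjoint and reproducible", {
  d <- tibble::tibble(x = 1:9)
  parts <- split_data(d, split_spec(seed = 3))
  expect_equal(nrow(parts$train), 6)
  expect_equal(nrow(parts$test), 3)
  again <- split_data(d, split_spec(seed = 3))
  expect_identical(parts$train, again$train)
  expect_equal(
    sort(c(parts$train$x, parts$test$x)), 1:9
  )
  other <- split_data(d, split_spec(seed = 4))
  expect_false(identical(parts$train$x, other$train$x))
  expect_error(split_data(d[1:2, ], split_spec()), "at least 3")
})

test_that("calibration slope equals the closed form and the lm oracle", {
  expect_equal(calibration_slope(c(1, 2, 3), c(1, 2, 3)), 1)
  expect_equal(calibration_slope(c(2, 4, 6), c(1, 2, 3)), 2)
  set.seed(41)
  y <- rexp(60, 1 / 3)
  p <- y * 0.6 + rnorm(60, sd = 0.5)
  got <- calibration_slope(y, p)
  expect_equal(got, stats::cov(y, p) / stats::var(p))
  expect_equal(got, unname(coef(lm(y ~ p))[2]))
  expect_error(calibration_slope(c(1, 2), c(3, 3)), "constant")
})

test_that("short-class sensitivity counts exactly the truly short", {
  expect_equal(
    sensitivity_short(c(1, 2, 8), estimate = c(1, 9, 8), tau_c = 7), 0.5
  )
  expect_equal(
    sensitivity_short(c(1, 2), estimate = c(3, 4), tau_c = 7), 1
  )
  expect_equal(
    sensitivity_short(c(1, 8), is_prolonged = c(FALSE, TRUE), tau_c = 7), 1
  )
  expect_error(sensitivity_short(c(8, 9), estimate = c(1, 2)), "undefined")
  expect_error(sensitivity_short(c(1, 2), estimate = c(1, 2), is_prolonged = c(FALSE, FALSE)))
})

test_that("AP and AUC match exhaustive enumeration and a reference", {
  cv <- pr_and_roc(c(.9, .8, .2, .1), c(TRUE, FALSE, TRUE, FALSE))
  expect_equal(cv$auc, 0.75) # 3 of 4 discordant-free pairs
  perfect <- pr_and_roc(c(.9, .8, .1, .2), c(TRUE, TRUE, FALSE, FALSE))
  expect_equal(perfect$auc, 1)
  expect_equal(perfect$average_precision, 1)

  # pairwise enumeration oracle with half credit for ties
  auc_oracle <- function(scores, pos) {
    num <- 0
    den <- 0
    for (i in which(pos)) {
      for (j in which(!pos)) {
        den <- den + 1
        num <- num + (scores[i] > scores[j]) + 0.5 * (scores[i] == scores[j])
      }
    }
    num / den
  }
  ap_oracle <- function(scores, pos) {
    thr <- sort(unique(scores), decreasing = TRUE)
    rk <- 0
    ap <- 0
    for (t in thr) {
      sel <- scores >= t
      r <- sum(sel & pos) / sum(pos)
      p <- sum(sel & pos) / sum(sel)
      ap <- ap + (r - rk) * p
      rk <- r
    }
    ap
  }
  set.seed(43)
  for (i in 1:100) {
    n <- sample(4:12, 1)
    scores <- round(runif(n), 1) # force ties
    pos <- runif(n) < 0.5
    if (!any(pos) || all(pos)) next
    got <- pr_and_roc(scores, pos)
    expect_equal(got$auc, auc_oracle(scores, pos))
    expect_equal(got$average_precision, ap_oracle(scores, pos))
    if (requireNamespace("pROC", quietly = TRUE)) {
      ref <- suppressMessages(pROC::auc(pROC::roc(
        response = pos, predictor = scores,
        levels = c(FALSE, TRUE), direction = "<"
      )))
      expect_equal(got$auc, as.numeric(ref))
    }
  }
})

test_that("label-independent scores give chance-level discrimination", {
  set.seed(44)
  n <- 4000
  scores <- runif(n)
  pos <- runif(n) < 0.2
  cv <- pr_and_roc(scores, pos)
  expect_lt(abs(cv$auc - 0.5), 0.03)
  expect_lt(abs(cv$average_precision - mean(pos)), 0.03)
})

test_that("percentile bootstrap is seeded, degenerate on zero variance", {
  d <- tibble::tibble(y = rexp(80, 1 / 3), p = rexp(80, 1 / 3))
  fn <- function(d) loss_mae(d$y, d$p)
  ci1 <- bootstrap_ci(d, fn, B = 300, seed = 5)
  ci2 <- bootstrap_ci(d, fn, B = 300, seed = 5)
  expect_identical(ci1, ci2)
  ci3 <- bootstrap_ci(d, fn, B = 300, seed = 6)
  expect_false(identical(ci1$ci_low, ci3$ci_low))
  expect_lte(ci1$ci_low, ci1$ci_high)

  perfect <- tibble::tibble(y = 1:10, p = 1:10)
  ci0 <- bootstrap_ci(perfect, function(d) loss_mae(d$y, d$p), B = 200)
  expect_equal(c(ci0$ci_low, ci0$ci_high), c(0, 0))
})

test_that("bootstrap interval width shrinks roughly like 1/sqrt(n)", {
  widths <- vapply(c(100, 400, 1600), function(n) {
    set.seed(47)
    d <- tibble::tibble(y = rexp(n, 1 / 3), p = rexp(n, 1 / 3))
    ci <- bootstrap_ci(d, function(d) loss_mae(d$y, d$p), B = 400, seed = 47)
    ci$ci_high - ci$ci_low
  }, numeric(1))
  expect_true(all(diff(widths) < 0))
  # quadrupling n should roughly halve the width
  expect_lt(widths[3], widths[1] / 2.5)
  expect_gt(widths[3], widths[1] / 8)
})

test_that("bootstrap redraws resamples on which the metric is undefined", {
  d <- tibble::tibble(y = c(0, 0, rexp(20, 1 / 3)), p = rexp(22, 1 / 3))
  fn <- function(d) loss_mre(d$y, d$p) # undefined when a zero is resampled
  ci <- bootstrap_ci(d[-(1:2), ], fn, B = 150, seed = 8)
  expect_true(is.finite(ci$estimate))
  expect_equal(ci$n_redrawn, 0L)
})

test_that("cross-validated comparison scores a recoverable linear signal", {
  set.seed(51)
  n <- 150
  d <- tibble::tibble(x = runif(n, 0, 10))
  d$los <- 2 + 0.4 * d$x + rnorm(n, sd = 0.01)
  rep <- crossval_compare(
    d, los,
    grid = comparison_grid(
      algorithms = "penalized_linear", losses = c("mse", "mae")
    ),
    spec = split_spec(cv_folds = 3, seed = 51)
  )
  overall <- rep[rep$bin == "overall" & rep$metric == "mae", ]
  expect_lt(overall$value, 0.05)
  expect_true(all(is.na(rep$error)))
})

test_that("comparison results are invariant to input row order", {
  co <- generate_cohort(cohort_spec(n = 400, seed = 52))
  grid <- comparison_grid(
    algorithms = "tree_ensemble", losses = c("mae", "customized")
  )
  hp <- list(tree_ensemble = list(num.trees = 50, mtry = 3))
  rep1 <- crossval_compare(co, los,
    grid = grid,
    spec = split_spec(cv_folds = 3, seed = 52), hyperparameters = hp
  )
  shuffled <- co[sample(nrow(co)), ]
  rep2 <- crossval_compare(shuffled, los,
    grid = grid,
    spec = split_spec(cv_folds = 3, seed = 52), hyperparameters = hp
  )
  expect_equal(as.data.frame(rep1), as.data.frame(rep2))
})

test_that("a failing grid cell is recorded and the run continues", {
  set.seed(53)
  d <- tibble::tibble(x = rnorm(60), los = c(0, runif(59, 0.5, 10)))
  rep <- crossval_compare(
    d, los,
    grid = comparison_grid(
      algorithms = "penalized_linear", losses = c("mae", "mre")
    ),
    spec = split_spec(cv_folds = 3, seed = 53)
  )
  # the mre cell dies on the zero outcome, the mae rows survive
  expect_true(any(!is.na(rep$error)) || any(rep$metric == "mae"))
})

test_that("two-stage cells are scored with gated imputation", {
  co <- generate_cohort(cohort_spec(n = 500, seed = 54))
  rep <- crossval_compare(
    co, los,
    grid = comparison_grid(
      algorithms = "tree_ensemble", losses = "customized",
      approaches = "two_stage"
    ),
    spec = split_spec(cv_folds = 3, seed = 54),
    config = quick_two_stage_config(seed = 54),
    hyperparameters = list(tree_ensemble = list(num.trees = 50, mtry = 3))
  )
  expect_true("sensitivity_short" %in% rep$metric)
  expect_true(all(is.na(rep$error)))
  preds <- attr(rep, "predictions")[[1]]
  expect_true(any(preds$gated))
  expect_equal(preds$pred[preds$gated], rep(7, sum(preds$gated)))
})

test_that("model evaluation report is internally consistent", {
  co <- generate_cohort(cohort_spec(n = 1200, seed = 55))
  parts <- split_data(co, split_spec(seed = 55))
  fit <- fit_two_stage(parts$train, los, quick_two_stage_config(seed = 55))
  rep <- evaluate_model(fit, parts$test, los, B = 150, seed = 55)
  expect_true(all(
    rep$ci_low <= rep$estimate & rep$estimate <= rep$ci_high,
    na.rm = TRUE
  ))
  expect_true(all(c("average_precision", "auc") %in% rep$metric))
  bins_rows <- rep[rep$metric == "mae" & rep$bin != "overall", ]
  expect_equal(sum(bins_rows$n), nrow(parts$test))
  curves <- attr(rep, "curves")
  expect_s3_class(curves$pr, "tbl_df")
})
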