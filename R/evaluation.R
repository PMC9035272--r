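#' Train/test split specification
#'
#' @param train_fraction Fraction of rows assigned to training
#'   (default 2/3).
#' @param cv_folds Folds for cross-validated model comparison (default 5).
#' @param seed Integer seed making the partition reproducible.
#' @return An object of class `los_split_spec`.
#' @export
split_spec <- function(train_fraction = 2 / 3, cv_folds = 5, seed = 1) {
  check_number(train_fraction, "train_fraction",
    min = 0, max = 1,
    strict_min = TRUE
  )
  if (train_fraction >= 1) abort("`train_fraction` must be < 1.")
  check_number(cv_folds, "cv_folds", min = 2)
  structure(
    list(
      train_fraction = train_fraction, cv_folds = as.integer(cv_folds),
      seed = seed
    ),
    class = "los_split_spec"
  )
}

#' Split a table into training and testing sets
#'
#' Random, disjoint, exhaustive partition with sizes within one row of the
#' exact fractions, reproducible from the seed.
#'
#' @param data A data frame with at least 3 rows.
#' @param spec A [split_spec()].
#' @return A list with tibbles `train` and `test`.
#' @examples
#' split_data(tibble::tibble(x = 1:9), split_spec(seed = 4))
#' @export
split_data <- function(data, spec = split_spec()) {
  stopifnot(is.data.frame(data), inherits(spec, "los_split_spec"))
  n <- nrow(data)
  if (n < 3L) abort("need at least 3 rows to split.")
  n_train <- round(spec$train_fraction * n)
  n_train <- min(max(n_train, 1L), n - 1L)
  idx <- with_seed(
    derive_seed(spec$seed, 11L),
    sample.int(n, n_train)
  )
  list(
    train = tibble::as_tibble(data[sort(idx), , drop = FALSE]),
    test = tibble::as_tibble(data[setdiff(seq_len(n), idx), , drop = FALSE]),
    train_idx = sort(idx)
  )
}

#' Calibration slope of predictions
#'
#' Least-squares slope of the observed outcome regressed on the prediction,
#' `cov(y, y_hat) / var(y_hat)`. A slope of 1 indicates perfect calibration;
#' a slope below 1 indicates that large outcomes are under-predicted (the
#' spread of the predictions is too narrow relative to the truth).
#'
#' @param y_true Observed outcomes (days).
#' @param y_pred Predictions (days); must not be constant.
#' @return The slope (dimensionless).
#' @examples
#' calibration_slope(c(2, 4, 6), c(1, 2, 3)) # 2
#' @export
calibration_slope <- function(y_true, y_pred) {
  check_pair(y_true, y_pred)
  v <- stats::var(y_pred)
  if (!is.finite(v) || v == 0) {
    abort("calibration slope is undefined for constant predictions.")
  }
  stats::cov(y_true, y_pred) / v
}

#' Short-class sensitivity
#'
#' Among encounters whose true stay is short (`y_true < tau_c`), the
#' fraction predicted short: numeric prediction below `tau_c` for a
#' one-stage model, or not gated as prolonged for a two-stage model.
#'
#' @param y_true Observed outcomes (days).
#' @param estimate Numeric predictions (one-stage mode). Supply exactly one
#'   of `estimate` and `is_prolonged`.
#' @param is_prolonged Logical gate flags (two-stage mode).
#' @param tau_c Threshold in days.
#' @return Fraction in \[0, 1\].
#' @examples
#' sensitivity_short(c(1, 2, 8), estimate = c(1, 9, 8), tau_c = 7) # 0.5
#' @export
sensitivity_short <- function(y_true, estimate = NULL, is_prolonged = NULL,
                              tau_c = 7) {
  if (is.null(estimate) == is.null(is_prolonged)) {
    abort("supply exactly one of `estimate` and `is_prolonged`.")
  }
  true_short <- y_true < tau_c
  if (!any(true_short)) {
    abort("short-class sensitivity is undefined: no truly short encounters.")
  }
  predicted_short <- if (!is.null(estimate)) {
    check_pair(y_true, estimate)
    estimate < tau_c
  } else {
    stopifnot(is.logical(is_prolonged), length(is_prolonged) == length(y_true))
    !is_prolonged
  }
  mean(predicted_short[true_short])
}

#' Precision-recall and ROC summaries for the stage-1 classifier
#'
#' Computes the step-wise precision-recall curve with average precision
#' `AP = sum((R_k - R_(k-1)) * P_k)` over descending score thresholds (equal
#' scores grouped into one step), and the ROC curve with AUC computed by the
#' rank (Mann-Whitney) statistic, crediting ties 1/2.
#'
#' @param scores Prolonged-class scores.
#' @param labels `"short"`/`"prolonged"` labels (or logical, `TRUE` =
#'   prolonged); both classes must be present.
#' @return An object of class `los_curves`: a list with
#'   `average_precision`, `auc`, and tibbles `pr` (`cutoff`, `recall`,
#'   `precision`) and `roc` (`cutoff`, `fpr`, `tpr`).
#' @examples
#' pr_and_roc(c(.9, .8, .2, .1), c(TRUE, FALSE, TRUE, FALSE))$auc # 0.75
#' @export
pr_and_roc <- function(scores, labels) {
  labels <- short_prolonged_factor(labels)
  if (length(scores) != length(labels)) {
    abort("`scores` and `labels` must have equal lengths.")
  }
  if (anyNA(scores)) abort("`scores` must not contain missing values.")
  is_p <- labels == "prolonged"
  n_pos <- sum(is_p)
  n_neg <- sum(!is_p)
  if (n_pos == 0L || n_neg == 0L) {
    abort("both classes must be present to compute PR/ROC summaries.")
  }

  # cumulative counts over descending scores, collapsed at tied values
  ord <- order(scores, decreasing = TRUE)
  s <- scores[ord]
  pos_sorted <- is_p[ord]
  last_of_tie <- c(s[-1] != s[-length(s)], TRUE)
  thr <- s[last_of_tie]
  tp <- cumsum(pos_sorted)[last_of_tie]
  fp <- cumsum(!pos_sorted)[last_of_tie]
  recall <- tp / n_pos
  precision <- tp / (tp + fp)
  ap <- sum((recall - c(0, head(recall, -1))) * precision)

  # rank statistic; average ranks credit tied pairs 1/2
  r <- rank(scores)
  auc <- (sum(r[is_p]) - n_pos * (n_pos + 1) / 2) / (n_pos * n_neg)

  structure(
    list(
      average_precision = ap, auc = auc,
      pr = tibble::tibble(cutoff = thr, recall = recall, precision = precision),
      roc = tibble::tibble(
        cutoff = c(Inf, thr), fpr = c(0, fp / n_neg), tpr = c(0, recall)
      )
    ),
    class = "los_curves"
  )
}

#' @export
print.los_curves <- function(x, ...) {
  cat(
    "<los_curves> average precision:", format(x$average_precision, digits = 4),
    "| AUC:", format(x$auc, digits = 4), "\n"
  )
  invisible(x)
}

#' Percentile bootstrap confidence interval for a test-set metric
#'
#' Resamples the rows of `data` with replacement `B` times, recomputes the
#' metric on each resample, and returns the percentile interval. Models are
#' not refit: this quantifies sampling uncertainty of the final test-set
#' estimate. A resample on which the metric is undefined (an error or a
#' non-finite value) is redrawn; the count of redraws is reported.
#'
#' @param data Data frame of per-row quantities the metric needs (e.g.
#'   truth and prediction columns).
#' @param metric_fn Function taking a resampled data frame, returning a
#'   scalar.
#' @param B Number of bootstrap resamples (>= 100).
#' @param level Coverage level (default 0.95).
#' @param seed Integer seed.
#' @return A one-row tibble: `estimate`, `ci_low`, `ci_high`, `b`,
#'   `n_redrawn`.
#' @examples
#' d <- tibble::tibble(y = rnorm(50), p = rnorm(50))
#' bootstrap_ci(d, function(d) loss_mae(abs(d$y), abs(d$p)), B = 200, seed = 2)
#' @export
bootstrap_ci <- function(data, metric_fn, B = 1000, level = 0.95, seed = 1) {
  stopifnot(is.data.frame(data), is.function(metric_fn))
  check_number(B, "B", min = 100)
  check_number(level, "level", min = 0, max = 1, strict_min = TRUE)
  if (level >= 1) abort("`level` must be < 1.")
  n <- nrow(data)
  point <- metric_fn(data)
  stats_b <- numeric(B)
  n_redrawn <- 0L
  with_seed(derive_seed(seed, 77L), {
    for (b in seq_len(B)) {
      repeat {
        val <- tryCatch(
          metric_fn(data[sample.int(n, n, replace = TRUE), , drop = FALSE]),
          error = function(e) NA_real_
        )
        if (is.finite(val)) break
        n_redrawn <- n_redrawn + 1L
        if (n_redrawn > 100L * B) {
          abort("metric undefined on virtually every bootstrap resample.")
        }
      }
      stats_b[b] <- val
    }
  })
  alpha <- (1 - level) / 2
  q <- stats::quantile(stats_b, c(alpha, 1 - alpha), names = FALSE, type = 7)
  tibble::tibble(
    estimate = point, ci_low = q[1], ci_high = q[2],
    b = as.integer(B), n_redrawn = n_redrawn
  )
}

#' Comparison grid for cross-validated model selection
#'
#' The cartesian analytic grid: algorithm families crossed with outcome
#' transforms and modeling approaches, scored by a set of losses on pooled
#' out-of-fold predictions.
#'
#' @param algorithms Character vector of learner families.
#' @param transforms List of transforms (strings or [outcome_transform()]s).
#'   For the two-stage approach the transform applies to stage 2.
#' @param losses Loss identifiers to report.
#' @param approaches Subset of `c("one_stage", "two_stage")`.
#' @return An object of class `los_comparison_grid`.
#' @export
comparison_grid <- function(algorithms = c(
                              "penalized_linear", "tree_ensemble",
                              "feedforward_net"
                            ),
                            transforms = list("identity"),
                            losses = c("mse", "mae", "customized"),
                            approaches = "one_stage") {
  stopifnot(
    length(algorithms) >= 1L, length(transforms) >= 1L,
    length(losses) >= 1L
  )
  approaches <- match.arg(approaches, c("one_stage", "two_stage"),
    several.ok = TRUE
  )
  if (!is.list(transforms)) transforms <- as.list(transforms)
  transforms <- purrr::map(transforms, as_transform)
  structure(
    list(
      algorithms = algorithms, transforms = transforms, losses = losses,
      approaches = approaches
    ),
    class = "los_comparison_grid"
  )
}

# Canonical row order: makes out-of-fold comparison results invariant to
# the order rows arrive in.
canonical_order <- function(data) {
  do.call(order, c(unname(as.list(data)), list(method = "radix")))
}

#' Cross-validated comparison across the analytic grid
#'
#' For every cell of the grid (approach x algorithm x transform), fits the
#' model on each of `cv_folds` training folds and scores the pooled
#' out-of-fold predictions on the day scale with every requested loss
#' (overall and stratified by outcome bin), plus calibration slope and
#' short-class sensitivity. All cells share one fold partition. A failing
#' cell is recorded with its error message and the run continues. Rows are
#' internally put in a canonical order, so results do not depend on the
#' row order of `train`.
#'
#' @param train Training data frame.
#' @param outcome Bare name of the outcome column.
#' @param grid A [comparison_grid()].
#' @param spec A [split_spec()] (its `cv_folds` and `seed` are used).
#' @param config A [two_stage_config()] used for `"two_stage"` cells; its
#'   stage-2 transform and both learner families are overridden per cell.
#' @param tau_c Threshold for the customized loss and sensitivity.
#' @param bins Stratification bins.
#' @param hyperparameters Optional named list keyed by algorithm family,
#'   each element a list of pinned hyperparameter values applied to that
#'   family's learners in every cell.
#' @return An `los_eval_report` tibble: `approach`, `algorithm`,
#'   `transform`, `metric`, `bin`, `n`, `value`, `error`. Pooled
#'   out-of-fold predictions per cell are attached as attribute
#'   `"predictions"`.
#' @export
crossval_compare <- function(train, outcome, grid = comparison_grid(),
                             spec = split_spec(),
                             config = two_stage_config(),
                             tau_c = config$tau_c, bins = los_bins(),
                             hyperparameters = list()) {
  stopifnot(
    is.data.frame(train), inherits(grid, "los_comparison_grid"),
    inherits(spec, "los_split_spec")
  )
  outcome_name <- rlang::as_name(rlang::enquo(outcome))
  train <- train[canonical_order(train), , drop = FALSE]
  y <- train[[outcome_name]]
  folds <- make_folds(nrow(train), spec$cv_folds, derive_seed(spec$seed, 5L))

  cells <- tidyr::expand_grid(
    approach = grid$approaches,
    algorithm = grid$algorithms,
    transform_id = seq_along(grid$transforms)
  )
  all_preds <- list()
  report <- purrr::pmap_dfr(
    cells,
    function(approach, algorithm, transform_id) {
      transform <- grid$transforms[[transform_id]]
      t_label <- transform$kind
      cell_id <- paste(approach, algorithm, t_label, sep = "/")
      res <- tryCatch(
        {
          pred <- rep(NA_real_, nrow(train))
          gated <- rep(FALSE, nrow(train))
          for (k in seq_len(max(folds))) {
            tr <- train[folds != k, , drop = FALSE]
            te <- train[folds == k, , drop = FALSE]
            hp_cell <- hyperparameters[[algorithm]] %||% list()
            if (approach == "one_stage") {
              lspec <- learner_spec(algorithm, "regression",
                hyperparameters = hp_cell,
                cv_folds = spec$cv_folds,
                seed = derive_seed(spec$seed, 1000L + k)
              )
              fit <- fit_one_stage(
                tr, !!rlang::sym(outcome_name), lspec, transform
              )
              pred[folds == k] <- predict(fit, te)
            } else {
              cfg <- config
              cfg$stage2_transform <- transform
              cfg$classifier_spec <- learner_spec(algorithm, "classification",
                hyperparameters = utils::modifyList(
                  config$classifier_spec$hyperparameters, hp_cell
                ),
                cv_folds = spec$cv_folds,
                seed = derive_seed(spec$seed, 2000L + k)
              )
              cfg$regressor_spec <- learner_spec(algorithm, "regression",
                hyperparameters = utils::modifyList(
                  config$regressor_spec$hyperparameters, hp_cell
                ),
                cv_folds = spec$cv_folds,
                seed = derive_seed(spec$seed, 3000L + k)
              )
              fit <- fit_two_stage(tr, !!rlang::sym(outcome_name), cfg)
              p <- impute_gated(predict(fit, te), tau_c = cfg$tau_c)
              pred[folds == k] <- p$scored_estimate
              gated[folds == k] <- p$is_prolonged
            }
          }
          cell <- tibble::tibble(y = y, pred = pred, gated = gated)
          all_preds[[cell_id]] <<- cell
          strat <- stratified_loss(cell, y, pred,
            losses = grid$losses,
            bins = bins, tau_c = tau_c
          )
          slope <- tryCatch(calibration_slope(y, pred), error = function(e) NA_real_)
          sens <- if (approach == "two_stage") {
            sensitivity_short(y, is_prolonged = gated, tau_c = tau_c)
          } else {
            sensitivity_short(y, estimate = pred, tau_c = tau_c)
          }
          dplyr::bind_rows(
            tibble::as_tibble(strat),
            tibble::tibble(
              metric = c("calibration", "sensitivity_short"),
              bin = "overall", n = length(y), value = c(slope, sens)
            )
          )
        },
        error = function(e) {
          tibble::tibble(
            metric = NA_character_, bin = NA_character_,
            n = NA_integer_, value = NA_real_, error = conditionMessage(e)
          )
        }
      )
      if (!"error" %in% names(res)) res$error <- NA_character_
      dplyr::mutate(res,
        approach = approach, algorithm = algorithm, transform = t_label,
        .before = 1
      )
    }
  )
  structure(report,
    class = c("los_eval_report", class(report)),
    predictions = all_preds
  )
}

#' Evaluate a fitted model on held-out data
#'
#' Computes the full test-set report for a one-stage or two-stage model:
#' each requested loss overall and per outcome bin, calibration slope
#' (numeric predictions only), short-class sensitivity, and — for two-stage
#' models — stage-1 average precision and AUC; every metric carries a
#' percentile bootstrap confidence interval (rows resampled, model fixed).
#'
#' @param model A `los_one_stage` or `los_two_stage` fit.
#' @param test Held-out data frame including the outcome column.
#' @param outcome Bare name of the outcome column.
#' @param losses Loss identifiers to report.
#' @param tau_c Threshold (days) for the customized loss and sensitivity;
#'   defaults to the model's configured threshold for two-stage fits.
#' @param bins Stratification bins.
#' @param B,level,seed Bootstrap settings (see [bootstrap_ci()]).
#' @return An `los_eval_report` tibble: `metric`, `bin`, `n`, `estimate`,
#'   `ci_low`, `ci_high`, with the per-row prediction table attached as
#'   attribute `"predictions"`.
#' @export
evaluate_model <- function(model, test, outcome,
                           losses = c("mse", "mae", "customized"),
                           tau_c = NULL, bins = los_bins(),
                           B = 1000, level = 0.95, seed = 1) {
  outcome_name <- rlang::as_name(rlang::enquo(outcome))
  y <- test[[outcome_name]]
  if (is.null(y)) abort(sprintf("outcome column `%s` not found.", outcome_name))
  two_stage <- inherits(model, "los_two_stage")
  tau_c <- tau_c %||% if (two_stage) model$config$tau_c else 7

  if (two_stage) {
    gp <- impute_gated(predict(model, test), tau_c = tau_c)
    cell <- tibble::tibble(
      y = y, pred = gp$scored_estimate, gated = gp$is_prolonged,
      score = gp$score
    )
  } else {
    cell <- tibble::tibble(
      y = y, pred = predict(model, test), gated = FALSE, score = NA_real_
    )
  }

  strat <- stratified_loss(cell, y, pred,
    losses = losses, bins = bins,
    tau_c = tau_c
  )
  ci_of <- function(fn, data) {
    bootstrap_ci(data, fn, B = B, level = level, seed = seed)
  }
  rows <- purrr::pmap_dfr(
    strat[, c("metric", "bin", "n")],
    function(metric, bin, n) {
      sel <- if (bin == "overall") {
        rep(TRUE, nrow(cell))
      } else {
        bins$labels[bin_index(cell$y, bins)] == bin
      }
      sub <- cell[sel, , drop = FALSE]
      if (nrow(sub) == 0L) {
        return(tibble::tibble(
          metric = metric, bin = bin, n = 0L,
          estimate = NA_real_, ci_low = NA_real_, ci_high = NA_real_
        ))
      }
      fn <- function(d) loss_fn(metric, tau_c)(d$y, d$pred)
      ci <- ci_of(fn, sub)
      tibble::tibble(
        metric = metric, bin = bin, n = nrow(sub),
        estimate = ci$estimate, ci_low = ci$ci_low, ci_high = ci$ci_high
      )
    }
  )

  numeric_cell <- cell[!cell$gated, , drop = FALSE]
  slope_fn <- function(d) calibration_slope(d$y, d$pred)
  slope <- ci_of(slope_fn, numeric_cell)
  sens_fn <- function(d) {
    sensitivity_short(d$y, is_prolonged = d$gated, tau_c = tau_c)
  }
  sens <- ci_of(sens_fn, cell)
  extra <- tibble::tibble(
    metric = c("calibration", "sensitivity_short"),
    bin = "overall",
    n = c(nrow(numeric_cell), nrow(cell)),
    estimate = c(slope$estimate, sens$estimate),
    ci_low = c(slope$ci_low, sens$ci_low),
    ci_high = c(slope$ci_high, sens$ci_high)
  )

  if (two_stage) {
    lab <- short_prolonged_factor(y >= tau_c)
    curves <- pr_and_roc(cell$score, lab)
    ap_fn <- function(d) {
      pr_and_roc(d$score, short_prolonged_factor(d$y >= tau_c))$average_precision
    }
    auc_fn <- function(d) {
      pr_and_roc(d$score, short_prolonged_factor(d$y >= tau_c))$auc
    }
    ap <- ci_of(ap_fn, cell)
    auc <- ci_of(auc_fn, cell)
    extra <- dplyr::bind_rows(extra, tibble::tibble(
      metric = c("average_precision", "auc"),
      bin = "overall", n = nrow(cell),
      estimate = c(ap$estimate, auc$estimate),
      ci_low = c(ap$ci_low, auc$ci_low),
      ci_high = c(ap$ci_high, auc$ci_high)
    ))
  } else {
    curves <- NULL
  }

  out <- dplyr::bind_rows(rows, extra)
  structure(out,
    class = c("los_eval_report", class(out)),
    predictions = cell, curves = curves
  )
}
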