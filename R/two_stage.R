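#' Configure a two-stage (hurdle) LOS model
#'
#' The two-stage model first classifies encounters into short versus
#' prolonged stays (stage 1: prolonged defined as `los >= tau_c`), with a
#' probability cutoff tuned on out-of-fold scores so that short-class
#' sensitivity meets a target. Encounters classified short are then passed
#' to a regressor (stage 2) trained only on encounters with
#' `los <= tau_r`; setting `tau_r` above `tau_c` exposes the regressor to
#' rarer, longer stays so it can predict beyond the classifier threshold,
#' while the extreme tail is excluded entirely.
#'
#' @param tau_c Classifier threshold in days (default 7).
#' @param tau_r Regressor training threshold in days (default 35;
#'   must satisfy `tau_r >= tau_c`).
#' @param target_short_sensitivity Required short-class sensitivity for the
#'   stage-1 cutoff (default 0.99).
#' @param stage2_transform Outcome transform for stage-2 training
#'   (default natural log).
#' @param classifier_spec,regressor_spec [learner_spec()]s for the two
#'   stages (default: random forests).
#' @return An object of class `los_two_stage_config`.
#' @examples
#' two_stage_config(tau_r = 21)
#' @export
two_stage_config <- function(tau_c = 7, tau_r = 35,
                             target_short_sensitivity = 0.99,
                             stage2_transform = outcome_transform("log"),
                             classifier_spec = learner_spec(
                               "tree_ensemble", "classification"
                             ),
                             regressor_spec = learner_spec(
                               "tree_ensemble", "regression"
                             )) {
  check_number(tau_c, "tau_c", min = 0, strict_min = TRUE)
  check_number(tau_r, "tau_r", min = tau_c)
  check_number(target_short_sensitivity, "target_short_sensitivity",
    min = 0, max = 1, strict_min = TRUE
  )
  stopifnot(
    inherits(classifier_spec, "los_learner_spec"),
    classifier_spec$task == "classification",
    inherits(regressor_spec, "los_learner_spec"),
    regressor_spec$task == "regression"
  )
  structure(
    list(
      tau_c = tau_c, tau_r = tau_r,
      target_short_sensitivity = target_short_sensitivity,
      stage2_transform = as_transform(stage2_transform),
      classifier_spec = classifier_spec, regressor_spec = regressor_spec
    ),
    class = "los_two_stage_config"
  )
}

#' @export
print.los_two_stage_config <- function(x, ...) {
  cat(
    "<los_two_stage_config> tau_c:", x$tau_c, "| tau_r:", x$tau_r,
    "| target short sensitivity:", x$target_short_sensitivity,
    "| stage-2 transform:", x$stage2_transform$kind, "\n"
  )
  invisible(x)
}

short_prolonged_factor <- function(labels) {
  if (is.logical(labels)) {
    return(factor(ifelse(labels, "prolonged", "short"),
      levels = c("short", "prolonged")
    ))
  }
  f <- factor(as.character(labels), levels = c("short", "prolonged"))
  if (anyNA(f)) abort('labels must be "short"/"prolonged" (or logical).')
  f
}

#' Tune the stage-1 probability cutoff
#'
#' Chooses the cutoff `c*` of the decision rule "classify prolonged iff
#' score >= c*" from out-of-fold prolonged-class probabilities. In the
#' default mode the cutoff maximizes prolonged-class sensitivity subject to
#' short-class sensitivity >= `target` (equivalently, the smallest
#' admissible cutoff is chosen; both sensitivities are monotone in the
#' cutoff). The alternative mode targets prolonged-class sensitivity
#' instead, maximizing short-class sensitivity subject to it.
#'
#' Candidate cutoffs are the distinct score values plus one value above the
#' maximum score (classify everyone short). If only the everyone-short rule
#' meets the target and the maximum score is 1, no admissible cutoff exists
#' in \[0, 1\] and an error reports the best attainable sensitivity.
#'
#' @param scores Out-of-fold prolonged-class probabilities in \[0, 1\].
#'   These must come from cross-validated (never in-fold) predictions.
#' @param labels Vector of `"short"`/`"prolonged"` (or logical, `TRUE` =
#'   prolonged), same length.
#' @param target Target sensitivity (default 0.99).
#' @param mode Which class's sensitivity is constrained.
#' @return A one-row tibble: `cutoff`, `short_sensitivity`,
#'   `prolonged_sensitivity`, `target`, `mode`.
#' @examples
#' tune_cutoff(c(.1, .2, .8, .9), c("short", "short", "prolonged", "prolonged"))
#' @export
tune_cutoff <- function(scores, labels, target = 0.99,
                        mode = c("short_sensitivity", "prolonged_sensitivity")) {
  mode <- match.arg(mode)
  check_number(target, "target", min = 0, max = 1)
  labels <- short_prolonged_factor(labels)
  if (length(scores) != length(labels)) {
    abort("`scores` and `labels` must have equal lengths.")
  }
  if (anyNA(scores) || any(scores < 0 | scores > 1)) {
    abort("`scores` must be probabilities in [0, 1].")
  }
  if (nlevels(droplevels(labels)) != 2L) {
    abort("both classes must be present to tune a cutoff.")
  }
  is_p <- labels == "prolonged"
  cands <- sort(unique(scores))
  mx <- max(scores)
  if (mx < 1) cands <- c(cands, (mx + 1) / 2) # everyone-short rule
  short_sens <- vapply(
    cands, function(c) mean(scores[!is_p] < c), numeric(1)
  )
  prol_sens <- vapply(
    cands, function(c) mean(scores[is_p] >= c), numeric(1)
  )
  if (mode == "short_sensitivity") {
    ok <- which(short_sens >= target)
    if (!length(ok)) {
      abort(sprintf(
        "no cutoff in [0, 1] attains short-class sensitivity %.4g; best attainable is %.4g.",
        target, max(short_sens)
      ))
    }
    pick <- ok[which.max(prol_sens[ok])] # smallest admissible cutoff
  } else {
    ok <- which(prol_sens >= target)
    if (!length(ok)) {
      abort(sprintf(
        "no cutoff attains prolonged-class sensitivity %.4g; best attainable is %.4g.",
        target, max(prol_sens)
      ))
    }
    pick <- ok[which.max(short_sens[ok])] # largest admissible cutoff
  }
  tibble::tibble(
    cutoff = cands[pick],
    short_sensitivity = short_sens[pick],
    prolonged_sensitivity = prol_sens[pick],
    target = target, mode = mode
  )
}

# Out-of-fold prolonged-class scores for cutoff tuning. Uses the same fold
# count as hyperparameter CV but a distinct derived seed stream, so tuning
# is reproducible without reusing in-fold predictions.
oof_scores <- function(data, outcome_name, spec) {
  folds <- make_folds(nrow(data), spec$cv_folds, derive_seed(spec$seed, 31L))
  scores <- numeric(nrow(data))
  for (k in seq_len(max(folds))) {
    spec_k <- spec
    spec_k$seed <- derive_seed(spec$seed, 300L + k)
    fit_k <- fit_learner(
      data[folds != k, , drop = FALSE],
      !!rlang::sym(outcome_name), spec_k
    )
    scores[folds == k] <- predict(fit_k, data[folds == k, , drop = FALSE])
  }
  pmin(pmax(scores, 0), 1)
}

#' Fit the two-stage hurdle model
#'
#' Stage 1 fits the configured classifier on *all* training rows with the
#' binary label `los >= tau_c`, then tunes its probability cutoff on
#' fivefold out-of-fold scores via [tune_cutoff()]. Stage 2 fits the
#' configured regressor on the rows with `los <= tau_r` only, with the
#' outcome transformed per the configuration (natural log by default);
#' rows beyond `tau_r` are excluded from stage 2 entirely.
#'
#' @param data Training data frame: features plus the outcome column.
#' @param outcome Bare name of the outcome column (days, `>= 0`).
#' @param config A [two_stage_config()].
#' @return An object of class `los_two_stage`.
#' @examples
#' co <- generate_cohort(cohort_spec(n = 400, seed = 1))
#' cfg <- two_stage_config(
#'   classifier_spec = learner_spec("tree_ensemble", "classification",
#'     list(num.trees = 50, mtry = 3),
#'     seed = 1
#'   ),
#'   regressor_spec = learner_spec("tree_ensemble", "regression",
#'     list(num.trees = 50, mtry = 3),
#'     seed = 1
#'   )
#' )
#' fit <- fit_two_stage(co, los, cfg)
#' @export
fit_two_stage <- function(data, outcome, config = two_stage_config()) {
  stopifnot(is.data.frame(data), inherits(config, "los_two_stage_config"))
  outcome_name <- rlang::as_name(rlang::enquo(outcome))
  y <- data[[outcome_name]]
  if (is.null(y)) abort(sprintf("outcome column `%s` not found.", outcome_name))
  if (!is.numeric(y) || anyNA(y) || any(y < 0)) {
    abort("the outcome must be numeric, non-missing and >= 0 (days).")
  }
  label <- short_prolonged_factor(y >= config$tau_c)
  if (length(unique(label)) != 2L) {
    abort(sprintf(
      "both classes must be present in training: all outcomes are on one side of tau_c = %g.",
      config$tau_c
    ))
  }
  features <- setdiff(names(data), outcome_name)

  clf_data <- data
  clf_data[[outcome_name]] <- NULL
  clf_data$.label <- label
  classifier <- fit_learner(clf_data, .label, config$classifier_spec,
    features = features
  )
  scores <- oof_scores(clf_data, ".label", config$classifier_spec)
  cutoff <- tune_cutoff(scores, label, config$target_short_sensitivity)

  stage2_rows <- y <= config$tau_r
  if (!any(stage2_rows)) {
    abort(sprintf(
      "stage 2 cannot be fit: no training rows with outcome <= tau_r = %g.",
      config$tau_r
    ))
  }
  regressor <- fit_one_stage(
    data[stage2_rows, , drop = FALSE], !!rlang::sym(outcome_name),
    config$regressor_spec, config$stage2_transform,
    features = features
  )

  structure(
    list(
      config = config, classifier = classifier, cutoff = cutoff,
      regressor = regressor, outcome = outcome_name, features = features,
      n_train = nrow(data), n_stage2 = sum(stage2_rows),
      oof = tibble::tibble(score = scores, label = label)
    ),
    class = "los_two_stage"
  )
}

#' @export
print.los_two_stage <- function(x, ...) {
  cat(
    "<los_two_stage> tau_c:", x$config$tau_c, "| tau_r:", x$config$tau_r,
    "| cutoff:", format(x$cutoff$cutoff, digits = 4), "\n"
  )
  cat(
    "  stage 1:", x$classifier$spec$family, "on", x$n_train,
    "rows; out-of-fold short sensitivity",
    format(x$cutoff$short_sensitivity, digits = 4), "\n"
  )
  cat(
    "  stage 2:", x$regressor$learner$spec$family, "with",
    x$config$stage2_transform$kind, "outcome on", x$n_stage2, "rows\n"
  )
  invisible(x)
}

#' Gated predictions from a two-stage model
#'
#' Each encounter receives exactly one of: a prolonged-stay flag (stage-1
#' score at or above the tuned cutoff; no numeric estimate) or a numeric
#' LOS estimate from stage 2 on the day scale. Stage-2 estimates may exceed
#' `tau_c`, since the regressor was trained on outcomes up to `tau_r`.
#'
#' @param object A fitted `los_two_stage`.
#' @param new_data Feature table with the training schema (extra columns,
#'   including the outcome, are ignored).
#' @param ... Unused.
#' @return A tibble with columns `row_id`, `score` (stage-1 prolonged
#'   probability), `is_prolonged` and `los_estimate` (`NA` on gated rows,
#'   floored at 0 otherwise).
#' @export
predict.los_two_stage <- function(object, new_data, ...) {
  missing_cols <- setdiff(object$features, names(new_data))
  if (length(missing_cols)) {
    abort(paste0(
      "new data is missing training column(s): ",
      paste(missing_cols, collapse = ", ")
    ))
  }
  score <- predict(object$classifier, new_data)
  gated <- score >= object$cutoff$cutoff
  est <- rep(NA_real_, nrow(new_data))
  if (any(!gated)) {
    est[!gated] <- predict(
      object$regressor, new_data[!gated, , drop = FALSE]
    )
  }
  tibble::tibble(
    row_id = seq_len(nrow(new_data)),
    score = score, is_prolonged = gated, los_estimate = est
  )
}

#' Sweep the stage-2 training threshold
#'
#' Refits stage 2 for each candidate `tau_r` (stage 1 and its cutoff are fit
#' once and shared) and evaluates each resulting model on a held-out set:
#' customized loss, MAE (gated rows imputed at `tau_c`), calibration slope,
#' short-class sensitivity and the largest numeric estimate produced. For a
#' tree-ensemble stage 2 the maximum estimate is bounded by the largest
#' training outcome, so raising `tau_r` is the mechanism that lets the model
#' predict beyond the classifier threshold.
#'
#' @param train,test Training and held-out data frames.
#' @param outcome Bare name of the outcome column.
#' @param config A [two_stage_config()]; its `tau_r` is overridden by each
#'   swept value.
#' @param taus Candidate regressor thresholds in days (each `>= tau_c`).
#' @return A tibble with one row per `tau_r`: losses, calibration slope,
#'   short sensitivity, gated fraction and `max_estimate`.
#' @export
sweep_regressor_threshold <- function(train, test, outcome,
                                      config = two_stage_config(),
                                      taus = c(7, 21, 35)) {
  outcome_name <- rlang::as_name(rlang::enquo(outcome))
  if (any(taus < config$tau_c)) {
    abort("every swept threshold must be >= the classifier threshold tau_c.")
  }
  y_test <- test[[outcome_name]]
  y_train <- train[[outcome_name]]
  base_cfg <- config
  base_cfg$tau_r <- max(taus)
  base <- fit_two_stage(train, !!rlang::sym(outcome_name), base_cfg)
  purrr::map_dfr(taus, function(tau) {
    cfg <- config
    cfg$tau_r <- tau
    rows <- y_train <= tau
    fit <- base
    fit$config <- cfg
    fit$n_stage2 <- sum(rows)
    fit$regressor <- fit_one_stage(
      train[rows, , drop = FALSE], !!rlang::sym(outcome_name),
      cfg$regressor_spec, cfg$stage2_transform,
      features = base$features
    )
    pred <- impute_gated(predict(fit, test), tau_c = cfg$tau_c)
    numeric_rows <- !pred$is_prolonged
    slope <- if (sum(numeric_rows) >= 2 &&
      stats::var(pred$los_estimate[numeric_rows]) > 0) {
      calibration_slope(y_test[numeric_rows], pred$los_estimate[numeric_rows])
    } else {
      NA_real_
    }
    tibble::tibble(
      tau_r = tau,
      customized = loss_customized(y_test, pred$scored_estimate, cfg$tau_c),
      mae = loss_mae(y_test, pred$scored_estimate),
      calibration = slope,
      short_sensitivity = sensitivity_short(
        y_test,
        is_prolonged = pred$is_prolonged, tau_c = cfg$tau_c
      ),
      gated_fraction = mean(pred$is_prolonged),
      max_estimate = if (any(numeric_rows)) {
        max(pred$los_estimate[numeric_rows])
      } else {
        NA_real_
      }
    )
  })
}
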