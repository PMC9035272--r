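#' Specify a base learner
#'
#' A uniform contract over the three pluggable algorithm families used for
#' both the one-stage regressions and the two-stage components:
#' `"penalized_linear"` (LASSO via glmnet), `"tree_ensemble"` (random forest
#' via ranger) and `"feedforward_net"` (single-hidden-layer perceptron via
#' nnet). Hyperparameters left unspecified are tuned by internal k-fold
#' cross-validation over a small default grid; any hyperparameter supplied
#' explicitly is pinned and excluded from tuning.
#'
#' Default grids: penalty strength for the LASSO follows glmnet's internal
#' log-spaced lambda path; the forest tunes `mtry` over `{floor(sqrt(p)),
#' floor(p/3)}` with `num.trees = 300` and `min.node.size = 5`; the network
#' tunes hidden-layer `size` over `{3, 8}` and weight `decay` over
#' `{0.01, 0.1}` with `maxit = 200` on standardized numeric inputs.
#'
#' @param family Algorithm family.
#' @param task `"regression"` or `"classification"` (binary).
#' @param hyperparameters Named list of pinned hyperparameter values.
#' @param cv_folds Folds for internal hyperparameter tuning (>= 2).
#' @param seed Integer seed controlling fold assignment and any stochastic
#'   fitting (forest bootstrap, network initialization).
#' @return An object of class `los_learner_spec`.
#' @examples
#' learner_spec("tree_ensemble", "regression", list(num.trees = 100), seed = 7)
#' @export
learner_spec <- function(family = c(
                           "penalized_linear", "tree_ensemble",
                           "feedforward_net"
                         ),
                         task = c("regression", "classification"),
                         hyperparameters = list(), cv_folds = 5, seed = 1) {
  family <- match.arg(family)
  task <- match.arg(task)
  stopifnot(is.list(hyperparameters))
  check_number(cv_folds, "cv_folds", min = 2)
  check_number(seed, "seed", min = 0)
  structure(
    list(
      family = family, task = task, hyperparameters = hyperparameters,
      cv_folds = as.integer(cv_folds), seed = seed
    ),
    class = "los_learner_spec"
  )
}

#' @export
print.los_learner_spec <- function(x, ...) {
  cat(
    "<los_learner_spec>", x$family, "/", x$task,
    "| cv_folds:", x$cv_folds, "| seed:", x$seed, "\n"
  )
  if (length(x$hyperparameters)) {
    cat(
      "  pinned:",
      paste(names(x$hyperparameters), unlist(x$hyperparameters),
        sep = "=", collapse = ", "
      ), "\n"
    )
  }
  invisible(x)
}

# ---- feature encoding -------------------------------------------------------
# One-hot encoding with an explicit reference level; numeric NAs imputed by
# the training median with a missing-indicator column; standardization stats
# recorded for learners that need them (the network).

build_encoder <- function(data, feature_cols) {
  stopifnot(length(feature_cols) >= 1L)
  cols <- purrr::map(rlang::set_names(feature_cols), function(col) {
    x <- data[[col]]
    if (is.numeric(x)) {
      med <- stats::median(x, na.rm = TRUE)
      if (is.na(med)) abort(sprintf("column `%s` is entirely missing.", col))
      filled <- ifelse(is.na(x), med, x)
      list(
        type = "numeric", median = med, has_missing = anyNA(x),
        center = mean(filled), scale = max(stats::sd(filled), 1e-8)
      )
    } else {
      x <- as.character(x)
      x[is.na(x)] <- "(missing)"
      lev <- sort(unique(x))
      if (length(lev) < 1L) abort(sprintf("column `%s` is empty.", col))
      list(type = "categorical", levels = lev) # lev[1] is the reference
    }
  })
  structure(list(columns = cols), class = "los_encoder")
}

encode_features <- function(encoder, data, standardize = FALSE) {
  missing_cols <- setdiff(names(encoder$columns), names(data))
  if (length(missing_cols)) {
    abort(paste0(
      "new data is missing training column(s): ",
      paste(missing_cols, collapse = ", ")
    ))
  }
  blocks <- purrr::imap(encoder$columns, function(info, col) {
    x <- data[[col]]
    if (info$type == "numeric") {
      if (!is.numeric(x)) abort(sprintf("column `%s` must be numeric.", col))
      na <- is.na(x)
      filled <- ifelse(na, info$median, x)
      if (standardize) filled <- (filled - info$center) / info$scale
      out <- matrix(filled, ncol = 1, dimnames = list(NULL, col))
      if (info$has_missing) {
        out <- cbind(out, matrix(as.numeric(na),
          ncol = 1,
          dimnames = list(NULL, paste0(col, "_missing"))
        ))
      }
      out
    } else {
      x <- as.character(x)
      x[is.na(x)] <- "(missing)"
      unseen <- setdiff(unique(x), info$levels)
      if (length(unseen)) {
        abort(sprintf(
          "column `%s` has level(s) unseen in training: %s",
          col, paste(unseen, collapse = ", ")
        ))
      }
      keep <- info$levels[-1L]
      if (!length(keep)) {
        return(matrix(numeric(length(x)), ncol = 0))
      }
      out <- vapply(keep, function(l) as.numeric(x == l), numeric(length(x)))
      out <- matrix(out,
        ncol = length(keep),
        dimnames = list(NULL, paste0(col, "=", keep))
      )
      out
    }
  })
  do.call(cbind, unname(blocks))
}

# ---- fitting ----------------------------------------------------------------

positive_class <- function(y) levels(y)[2L]

check_target <- function(y, task) {
  if (task == "regression") {
    if (!is.numeric(y)) abort("regression target must be numeric.")
    if (anyNA(y)) abort("target contains missing values.")
  } else {
    if (!is.factor(y)) y <- factor(y)
    if (anyNA(y)) abort("target contains missing values.")
    if (nlevels(y) != 2L || length(unique(y)) != 2L) {
      abort(paste0(
        "classification needs exactly two observed classes; got {",
        paste(unique(as.character(y)), collapse = ", "), "}."
      ))
    }
  }
  y
}

hp <- function(spec, name, default) spec$hyperparameters[[name]] %||% default

# Candidate grid for hyperparameters that are not pinned in the spec.
default_grid <- function(spec, p) {
  switch(spec$family,
    tree_ensemble = {
      mtry <- hp(spec, "mtry", unique(pmax(
        1L, c(floor(sqrt(p)), floor(p / 3))
      )))
      expand.grid(
        mtry = mtry,
        min.node.size = hp(spec, "min.node.size", 5L),
        num.trees = hp(spec, "num.trees", 300L)
      )
    },
    feedforward_net = expand.grid(
      size = hp(spec, "size", c(3L, 8L)),
      decay = hp(spec, "decay", c(0.01, 0.1)),
      maxit = hp(spec, "maxit", 200L)
    ),
    penalized_linear = NULL # glmnet tunes lambda on its own path
  )
}

fit_engine <- function(x, y, spec, params, seed) {
  switch(spec$family,
    tree_ensemble = ranger::ranger(
      x = x, y = y,
      num.trees = params$num.trees, mtry = min(params$mtry, ncol(x)),
      min.node.size = params$min.node.size,
      importance = "impurity",
      probability = spec$task == "classification",
      seed = as.integer(seed %% 2147483647), num.threads = 1
    ),
    feedforward_net = with_seed(seed, {
      if (spec$task == "regression") {
        nnet::nnet(x, y,
          size = params$size, decay = params$decay, maxit = params$maxit,
          linout = TRUE, trace = FALSE, MaxNWts = 5000
        )
      } else {
        nnet::nnet(x, stats::model.matrix(~ y - 1)[, 2L],
          size = params$size, decay = params$decay, maxit = params$maxit,
          entropy = TRUE, trace = FALSE, MaxNWts = 5000
        )
      }
    })
  )
}

predict_engine <- function(fit, x, spec) {
  switch(spec$family,
    tree_ensemble = {
      pr <- predict(fit, data = x, num.threads = 1)$predictions
      if (spec$task == "classification") pr[, 2L] else pr
    },
    feedforward_net = as.numeric(predict(fit, x)),
    penalized_linear = as.numeric(predict(fit,
      newx = x,
      s = fit$lambda.min, type = "response"
    ))
  )
}

# Tuning loss on held-out rows: MSE for regression, Brier score for
# classification probabilities.
tuning_loss <- function(y, pred, task) {
  if (task == "regression") {
    mean((pred - y)^2)
  } else {
    mean((pred - as.numeric(y == positive_class(y)))^2)
  }
}

#' Fit a base learner
#'
#' Fits one of the three algorithm families on an encoded feature table.
#' Categorical predictors are one-hot encoded against an explicit reference
#' level; missing numeric values are imputed by the training-set median with
#' a missing-indicator column; the feed-forward network additionally
#' standardizes numeric inputs. Unpinned hyperparameters are selected by
#' internal k-fold cross-validation (see [learner_spec()]).
#'
#' @param data A data frame containing the outcome and feature columns.
#' @param outcome Bare name of the outcome column. Numeric for regression; a
#'   two-level factor (second level = positive class) for classification.
#' @param spec A [learner_spec()].
#' @param features Optional character vector of feature columns; defaults to
#'   every column except the outcome.
#' @return An object of class `los_fitted_learner` with a [predict()] method
#'   returning a numeric vector: day-scale predictions for regression,
#'   positive-class probabilities for classification.
#' @examples
#' d <- tibble::tibble(x = 1:20, y = 2 * (1:20) + rnorm(20, sd = .01))
#' fit <- fit_learner(d, y, learner_spec("penalized_linear", "regression"))
#' head(predict(fit, d))
#' @export
fit_learner <- function(data, outcome, spec, features = NULL) {
  stopifnot(is.data.frame(data), inherits(spec, "los_learner_spec"))
  outcome_name <- rlang::as_name(rlang::enquo(outcome))
  y <- check_target(data[[outcome_name]], spec$task)
  if (spec$task == "classification" && !is.factor(data[[outcome_name]])) {
    y <- factor(data[[outcome_name]])
  }
  features <- features %||% setdiff(names(data), outcome_name)
  encoder <- build_encoder(data, features)
  standardize <- spec$family == "feedforward_net"
  x <- encode_features(encoder, data, standardize = standardize)

  if (spec$family == "penalized_linear") {
    if (ncol(x) < 2) { # glmnet requires >= 2 columns; pad with a constant
      x <- cbind(x, `.zero` = 0)
    }
    fam <- if (spec$task == "regression") "gaussian" else "binomial"
    foldid <- make_folds(nrow(x), spec$cv_folds, spec$seed)
    lam <- hp(spec, "lambda", NULL)
    fit <- if (is.null(lam)) {
      glmnet::cv.glmnet(x, y,
        family = fam, alpha = hp(spec, "alpha", 1),
        foldid = foldid
      )
    } else {
      g <- glmnet::glmnet(x, y,
        family = fam, alpha = hp(spec, "alpha", 1),
        lambda = lam
      )
      g$lambda.min <- lam
      g
    }
    chosen <- list(lambda = unname(fit$lambda.min %||% lam))
  } else {
    grid <- default_grid(spec, ncol(x))
    if (nrow(grid) > 1L) {
      folds <- make_folds(nrow(x), spec$cv_folds, spec$seed)
      cv_loss <- vapply(seq_len(nrow(grid)), function(g) {
        params <- as.list(grid[g, , drop = FALSE])
        mean(vapply(seq_len(max(folds)), function(k) {
          fit_k <- fit_engine(
            x[folds != k, , drop = FALSE], y[folds != k],
            spec, params, derive_seed(spec$seed, 100L + g * 13L + k)
          )
          tuning_loss(
            y[folds == k],
            predict_engine(fit_k, x[folds == k, , drop = FALSE], spec),
            spec$task
          )
        }, numeric(1)))
      }, numeric(1))
      best <- which.min(cv_loss)
    } else {
      best <- 1L
      cv_loss <- NA_real_
    }
    chosen <- as.list(grid[best, , drop = FALSE])
    fit <- fit_engine(x, y, spec, chosen, spec$seed)
  }

  structure(
    list(
      spec = spec, encoder = encoder, fit = fit, chosen = chosen,
      outcome = outcome_name, features = features,
      encoded_names = colnames(x),
      standardize = standardize,
      y_range = if (spec$task == "regression") range(y) else NULL,
      classes = if (spec$task == "classification") levels(y) else NULL
    ),
    class = "los_fitted_learner"
  )
}

#' @export
print.los_fitted_learner <- function(x, ...) {
  cat(
    "<los_fitted_learner>", x$spec$family, "/", x$spec$task, "on",
    length(x$features), "features\n"
  )
  cat(
    "  chosen:",
    paste(names(x$chosen), vapply(x$chosen, format, ""),
      sep = "=", collapse = ", "
    ), "\n"
  )
  invisible(x)
}

#' Predict from a fitted base learner
#'
#' @param object A `los_fitted_learner`.
#' @param new_data Data frame with the training feature columns.
#' @param ... Unused.
#' @return Numeric vector: predictions (regression) or positive-class
#'   probabilities (classification).
#' @export
predict.los_fitted_learner <- function(object, new_data, ...) {
  x <- encode_features(object$encoder, new_data,
    standardize = object$standardize
  )
  if (object$spec$family == "penalized_linear" && ncol(x) < 2) {
    x <- cbind(x, `.zero` = 0)
  }
  predict_engine(object$fit, x, object$spec)
}

#' Fit a one-stage model with an outcome transform
#'
#' Trains a single regressor on transformed training outcomes and returns
#' predictions on the original day scale: log-model predictions are
#' exponentiated; truncated-model predictions are reported as-is (the cap is
#' not invertible — a forest trained on outcomes truncated at 7 days can
#' never predict beyond 7).
#'
#' @inheritParams fit_learner
#' @param transform A [outcome_transform()] (or its kind as a string).
#' @return An object of class `los_one_stage` with a [predict()] method
#'   returning day-scale predictions (floored at 0).
#' @examples
#' d <- tibble::tibble(x = rnorm(50), y = exp(1 + 0.5 * rnorm(50)))
#' m <- fit_one_stage(d, y, learner_spec("penalized_linear", "regression"),
#'   transform = "log"
#' )
#' @export
fit_one_stage <- function(data, outcome, spec,
                          transform = outcome_transform("identity"),
                          features = NULL) {
  transform <- as_transform(transform)
  outcome_name <- rlang::as_name(rlang::enquo(outcome))
  if (spec$task != "regression") {
    abort("one-stage models require a regression learner spec.")
  }
  y <- data[[outcome_name]]
  if (is.null(y)) abort(sprintf("outcome column `%s` not found.", outcome_name))
  train <- data
  train[[outcome_name]] <- apply_transform(y, transform)
  learner <- fit_learner(train, !!rlang::sym(outcome_name), spec,
    features = features
  )
  structure(
    list(learner = learner, transform = transform, outcome = outcome_name),
    class = "los_one_stage"
  )
}

#' @export
print.los_one_stage <- function(x, ...) {
  cat("<los_one_stage>", x$learner$spec$family, "with", x$transform$kind,
    "outcome\n",
    sep = " "
  )
  invisible(x)
}

#' @rdname fit_one_stage
#' @param object A `los_one_stage`.
#' @param new_data Feature table to predict on.
#' @param ... Unused.
#' @export
predict.los_one_stage <- function(object, new_data, ...) {
  z <- predict(object$learner, new_data)
  out <- if (object$transform$kind == "log") {
    invert_transform(z, object$transform)
  } else {
    z # identity, or truncate reported as-is
  }
  pmax(out, 0)
}
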