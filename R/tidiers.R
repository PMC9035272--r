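#' @importFrom generics tidy glance
#' @export
generics::tidy

#' @export
generics::glance

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot

#' Tidy a fitted two-stage model
#'
#' @param x A `los_two_stage`.
#' @param ... Unused.
#' @return `tidy()`: one row per model component/parameter (`component`,
#'   `term`, `value`). `glance()`: a one-row model summary.
#' @method tidy los_two_stage
#' @export
tidy.los_two_stage <- function(x, ...) {
  tibble::tibble(
    component = c(
      "config", "config", "config", "stage1", "stage1", "stage1",
      "stage2", "stage2"
    ),
    term = c(
      "tau_c", "tau_r", "target_short_sensitivity",
      "cutoff", "oof_short_sensitivity", "oof_prolonged_sensitivity",
      "transform", "n_stage2"
    ),
    value = c(
      x$config$tau_c, x$config$tau_r, x$config$target_short_sensitivity,
      x$cutoff$cutoff, x$cutoff$short_sensitivity,
      x$cutoff$prolonged_sensitivity,
      NA_real_, x$n_stage2
    ),
    label = c(
      rep(NA_character_, 6), x$config$stage2_transform$kind, NA_character_
    )
  )
}

#' @rdname tidy.los_two_stage
#' @method glance los_two_stage
#' @export
glance.los_two_stage <- function(x, ...) {
  tibble::tibble(
    n_train = x$n_train,
    n_stage2 = x$n_stage2,
    tau_c = x$config$tau_c,
    tau_r = x$config$tau_r,
    cutoff = x$cutoff$cutoff,
    oof_short_sensitivity = x$cutoff$short_sensitivity,
    oof_prolonged_sensitivity = x$cutoff$prolonged_sensitivity,
    classifier = x$classifier$spec$family,
    regressor = x$regressor$learner$spec$family,
    stage2_transform = x$config$stage2_transform$kind
  )
}

#' Tidy a fitted base learner
#'
#' For the penalized linear model, the nonzero coefficients at the selected
#' penalty; for the tree ensemble, impurity variable importance; for the
#' network, the input-layer weight magnitudes summed per feature.
#'
#' @param x A `los_fitted_learner`.
#' @param ... Unused.
#' @return `tidy()`: a tibble with `term` and `estimate`. `glance()`: a
#'   one-row summary with the selected hyperparameters.
#' @method tidy los_fitted_learner
#' @export
tidy.los_fitted_learner <- function(x, ...) {
  out <- switch(x$spec$family,
    penalized_linear = {
      cf <- as.matrix(coef(x$fit, s = x$fit$lambda.min))
      tibble::tibble(term = rownames(cf), estimate = cf[, 1])[cf[, 1] != 0, ]
    },
    tree_ensemble = {
      imp <- tryCatch(ranger::importance(x$fit), error = function(e) NULL)
      if (is.null(imp) || !length(imp)) {
        tibble::tibble(term = character(), estimate = numeric())
      } else {
        tibble::tibble(term = names(imp), estimate = unname(imp))
      }
    },
    feedforward_net = {
      w <- x$fit$wts
      nin <- x$fit$n[1]
      nh <- x$fit$n[2]
      m <- matrix(w[seq_len((nin + 1) * nh)], nrow = nin + 1)
      s <- rowSums(abs(m))[-1] # drop the bias row
      tibble::tibble(
        term = x$encoded_names %||% paste0("input", seq_len(nin)),
        estimate = s
      )
    }
  )
  dplyr::arrange(out, dplyr::desc(abs(.data$estimate)))
}

#' @rdname tidy.los_fitted_learner
#' @method glance los_fitted_learner
#' @export
glance.los_fitted_learner <- function(x, ...) {
  dplyr::bind_cols(
    tibble::tibble(family = x$spec$family, task = x$spec$task),
    tibble::as_tibble(x$chosen)
  )
}
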