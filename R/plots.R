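#' Plot a stratified loss report
#'
#' Bar chart of each loss per outcome bin (the overall row is drawn as a
#' dashed reference line), showing where on the outcome scale each metric
#' concentrates its loss.
#'
#' @param object A `los_loss_report` from [stratified_loss()].
#' @param ... Unused.
#' @return A ggplot object.
#' @method autoplot los_loss_report
#' @export
autoplot.los_loss_report <- function(object, ...) {
  df <- tibble::as_tibble(object)
  if (!all(c("metric", "bin", "value") %in% names(df))) {
    abort("expected a stratified loss report with metric/bin/value columns.")
  }
  value_col <- if ("value" %in% names(df)) "value" else "estimate"
  per_bin <- dplyr::filter(df, .data$bin != "overall")
  overall <- dplyr::filter(df, .data$bin == "overall")
  per_bin$bin <- factor(per_bin$bin, levels = unique(per_bin$bin))
  ggplot2::ggplot(
    per_bin,
    ggplot2::aes(x = .data$bin, y = .data[[value_col]])
  ) +
    ggplot2::geom_col(fill = "steelblue") +
    ggplot2::geom_hline(
      data = overall,
      ggplot2::aes(yintercept = .data[[value_col]]),
      linetype = "dashed"
    ) +
    ggplot2::facet_wrap(~metric, scales = "free_y") +
    ggplot2::labs(
      x = "observed LOS bin (days)", y = "loss",
      title = "Stratified evaluation losses",
      subtitle = "dashed line: overall loss"
    ) +
    ggplot2::theme_minimal()
}

#' Plot PR and ROC curves for the stage-1 classifier
#'
#' @param object A `los_curves` object from [pr_and_roc()].
#' @param ... Unused.
#' @return A ggplot object with precision-recall and ROC panels.
#' @method autoplot los_curves
#' @export
autoplot.los_curves <- function(object, ...) {
  pr <- dplyr::mutate(object$pr,
    panel = sprintf("Precision-recall (AP = %.3f)", object$average_precision),
    x = .data$recall, y = .data$precision
  )
  roc <- dplyr::mutate(object$roc,
    panel = sprintf("ROC (AUC = %.3f)", object$auc),
    x = .data$fpr, y = .data$tpr
  )
  df <- dplyr::bind_rows(
    pr[, c("panel", "x", "y")], roc[, c("panel", "x", "y")]
  )
  ggplot2::ggplot(df, ggplot2::aes(x = .data$x, y = .data$y)) +
    ggplot2::geom_step() +
    ggplot2::facet_wrap(~panel) +
    ggplot2::labs(x = NULL, y = NULL, title = "Stage-1 classifier") +
    ggplot2::coord_cartesian(xlim = c(0, 1), ylim = c(0, 1)) +
    ggplot2::theme_minimal()
}

#' Plot the LOS distribution of a cohort
#'
#' Histogram of length of stay; a log x scale makes the two-part mixture
#' (log-normal short stays, heavy prolonged tail) visible.
#'
#' @param object A `los_cohort` (or any data frame with a `los` column).
#' @param log_x Use a logarithmic day axis (default `FALSE`).
#' @param tau_c Reference threshold to mark (days).
#' @param ... Unused.
#' @return A ggplot object.
#' @method autoplot los_cohort
#' @export
autoplot.los_cohort <- function(object, log_x = FALSE, tau_c = 7, ...) {
  p <- ggplot2::ggplot(object, ggplot2::aes(x = .data$los)) +
    ggplot2::geom_histogram(bins = 60, fill = "grey40") +
    ggplot2::geom_vline(xintercept = tau_c, linetype = "dashed") +
    ggplot2::labs(
      x = "length of stay (days)", y = "encounters",
      title = "Cohort LOS distribution"
    ) +
    ggplot2::theme_minimal()
  if (log_x) p <- p + ggplot2::scale_x_log10()
  p
}

#' Predicted-versus-observed scatter for gated predictions
#'
#' Encounters gated as prolonged (no numeric estimate) are drawn as a rug
#' on the observed axis at the classifier threshold.
#'
#' @param predictions Output of [predict.los_two_stage()] joined with the
#'   observed outcome, i.e. a data frame with columns `los_estimate`,
#'   `is_prolonged` and the observed column named by `truth`.
#' @param truth Bare name of the observed-outcome column.
#' @param tau_c Classifier threshold (days).
#' @return A ggplot object.
#' @export
plot_predictions <- function(predictions, truth = observed, tau_c = 7) {
  truth_name <- rlang::as_name(rlang::enquo(truth))
  stopifnot(truth_name %in% names(predictions))
  numeric_rows <- dplyr::filter(predictions, !.data$is_prolonged)
  gated_rows <- dplyr::filter(predictions, .data$is_prolonged)
  ggplot2::ggplot(
    numeric_rows,
    ggplot2::aes(x = .data[[truth_name]], y = .data$los_estimate)
  ) +
    ggplot2::geom_point(alpha = 0.3, size = 0.8) +
    ggplot2::geom_abline(slope = 1, intercept = 0, linetype = "dashed") +
    ggplot2::geom_rug(
      data = gated_rows,
      ggplot2::aes(x = .data[[truth_name]], y = NULL),
      sides = "b", colour = "firebrick", alpha = 0.5
    ) +
    ggplot2::geom_vline(xintercept = tau_c, linetype = "dotted") +
    ggplot2::labs(
      x = "observed LOS (days)", y = "predicted LOS (days)",
      title = "Predicted versus observed",
      subtitle = "red rug: encounters gated as prolonged (no numeric estimate)"
    ) +
    ggplot2::theme_minimal()
}
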