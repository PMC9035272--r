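#' Scalar losses for length-of-stay predictions
#'
#' Evaluation losses for continuous, non-negative outcomes such as hospital
#' length of stay (LOS): mean squared error, mean absolute error, mean
#' relative error, and a truncated hinge ("customized") loss designed for
#' hurdle-style models that only attempt numeric predictions below a
#' prolonged-stay threshold.
#'
#' The customized loss scores each observation as
#' \itemize{
#'   \item 0 when both the true and the predicted LOS are at or above
#'     `tau_c` (both "prolonged": no penalty for not resolving the tail);
#'   \item `|y_pred - tau_c|` when the truth is prolonged but the prediction
#'     is short (the miss is measured only up to the threshold);
#'   \item `|y_pred - y_true|` otherwise (ordinary absolute error).
#' }
#' It is bounded above by the MAE and converges to the MAE as
#' `tau_c` grows beyond the data.
#'
#' @param y_true Numeric vector of observed outcomes (days, `>= 0`).
#' @param y_pred Numeric vector of predictions (days), same length.
#' @param tau_c Prolonged-stay threshold in days (default 7).
#'
#' @return A single numeric value: days^2 for `loss_mse()`, days for
#'   `loss_mae()` and `loss_customized()`, dimensionless for `loss_mre()`.
#'
#' @examples
#' loss_mae(c(0, 4), c(2, 2)) # 2
#' loss_customized(c(10, 10, 3), c(8, 5, 5), tau_c = 7) # mean of 0, 2, 2
#' @export
loss_mse <- function(y_true, y_pred) {
  check_pair(y_true, y_pred)
  mean((y_pred - y_true)^2)
}

#' @rdname loss_mse
#' @export
loss_mae <- function(y_true, y_pred) {
  check_pair(y_true, y_pred)
  mean(abs(y_pred - y_true))
}

#' @rdname loss_mse
#' @export
loss_mre <- function(y_true, y_pred) {
  check_pair(y_true, y_pred, require_positive_truth = TRUE)
  mean(abs(y_pred - y_true) / y_true)
}

#' @rdname loss_mse
#' @export
loss_customized <- function(y_true, y_pred, tau_c = 7) {
  check_pair(y_true, y_pred)
  check_number(tau_c, "tau_c", min = 0, strict_min = TRUE)
  both_prolonged <- y_true >= tau_c & y_pred >= tau_c
  missed_prolonged <- y_true >= tau_c & y_pred < tau_c
  term <- abs(y_pred - y_true)
  term[both_prolonged] <- 0
  term[missed_prolonged] <- abs(y_pred[missed_prolonged] - tau_c)
  mean(term)
}

loss_names <- c("mse", "mae", "mre", "customized")

# Resolve a case-insensitive loss identifier to its kernel.
loss_fn <- function(name, tau_c = 7) {
  key <- match.arg(tolower(name), loss_names)
  switch(key,
    mse = loss_mse,
    mae = loss_mae,
    mre = loss_mre,
    customized = function(y_true, y_pred) loss_customized(y_true, y_pred, tau_c)
  )
}

#' Bin specification for stratified LOS evaluation
#'
#' Half-open day bins used to stratify losses by the observed outcome.
#' The defaults reproduce the clinically motivated grouping 0-2, 2-4, 4-7
#' and >= 7 days; each observation falls in exactly one bin.
#'
#' @param edges Strictly increasing numeric vector of bin boundaries starting
#'   at 0 and ending at `Inf`.
#' @return An object of class `los_bins`: the edges plus bin labels.
#' @examples
#' los_bins()
#' los_bins(c(0, 4, Inf))
#' @export
los_bins <- function(edges = c(0, 2, 4, 7, Inf)) {
  if (!is.numeric(edges) || length(edges) < 2L || anyNA(edges)) {
    abort("`edges` must be a numeric vector with at least two boundaries.")
  }
  if (any(diff(edges) <= 0)) {
    abort("`edges` must be strictly increasing.")
  }
  if (edges[1L] != 0 || !is.infinite(edges[length(edges)])) {
    abort("`edges` must start at 0 and end at Inf to cover [0, Inf).")
  }
  lab <- character(length(edges) - 1L)
  for (i in seq_along(lab)) {
    lab[i] <- if (is.infinite(edges[i + 1L])) {
      paste0(">=", format(edges[i]))
    } else {
      paste0(format(edges[i]), "-", format(edges[i + 1L]))
    }
  }
  structure(list(edges = edges, labels = lab), class = "los_bins")
}

#' @export
print.los_bins <- function(x, ...) {
  cat("<los_bins>", paste(x$labels, collapse = ", "), "days\n")
  invisible(x)
}

bin_index <- function(y, bins) {
  findInterval(y, bins$edges, rightmost.closed = FALSE, left.open = FALSE)
}

#' Overall and per-bin losses from a prediction table
#'
#' Computes one or more losses on a table of observed and predicted outcomes,
#' overall and stratified by the observed LOS bin. The stratified view shows
#' where on the outcome scale a model earns its loss: squared error
#' concentrates in the tail, relative error among the shortest stays.
#'
#' @param data A data frame with one row per encounter.
#' @param truth,estimate Columns of `data` (bare names) holding observed and
#'   predicted LOS in days.
#' @param losses Character vector of loss identifiers (case-insensitive)
#'   among `"mse"`, `"mae"`, `"mre"`, `"customized"`.
#' @param bins A [los_bins()] specification.
#' @param tau_c Prolonged-stay threshold for the customized loss (days).
#'
#' @return A tibble of class `los_loss_report` with columns `metric`, `bin`
#'   (`"overall"` plus each bin label), `n` and `value`. Empty bins keep
#'   their row with `n = 0` and `value = NA`.
#' @examples
#' d <- tibble::tibble(los = c(1, 10), pred = c(2, 10))
#' stratified_loss(d, los, pred, losses = "mae")
#' @export
stratified_loss <- function(data, truth, estimate,
                            losses = c("mse", "mae", "customized"),
                            bins = los_bins(), tau_c = 7) {
  stopifnot(is.data.frame(data))
  y <- dplyr::pull(data, {{ truth }})
  p <- dplyr::pull(data, {{ estimate }})
  check_pair(y, p)
  if (!inherits(bins, "los_bins")) abort("`bins` must come from los_bins().")
  losses <- vapply(
    losses, function(l) match.arg(tolower(l), loss_names), character(1)
  )
  idx <- bin_index(y, bins)
  rows <- purrr::map_dfr(unname(losses), function(name) {
    fn <- loss_fn(name, tau_c)
    per_bin <- purrr::map_dfr(seq_along(bins$labels), function(b) {
      sel <- idx == b
      tibble::tibble(
        metric = name, bin = bins$labels[b], n = sum(sel),
        value = if (any(sel)) fn(y[sel], p[sel]) else NA_real_
      )
    })
    dplyr::bind_rows(
      tibble::tibble(
        metric = name, bin = "overall", n = length(y), value = fn(y, p)
      ),
      per_bin
    )
  })
  structure(rows, class = c("los_loss_report", class(rows)))
}

#' @rdname stratified_loss
#' @details `measure_losses()` returns only the overall (unstratified) values.
#' @export
measure_losses <- function(data, truth, estimate,
                           losses = c("mse", "mae", "customized"),
                           tau_c = 7) {
  stopifnot(is.data.frame(data))
  y <- dplyr::pull(data, {{ truth }})
  p <- dplyr::pull(data, {{ estimate }})
  check_pair(y, p)
  losses <- vapply(
    losses, function(l) match.arg(tolower(l), loss_names), character(1)
  )
  purrr::map_dfr(unname(losses), function(name) {
    tibble::tibble(
      metric = name, n = length(y), value = loss_fn(name, tau_c)(y, p)
    )
  })
}

#' Numeric estimates from gated predictions
#'
#' Two-stage models withhold a numeric estimate for encounters gated as
#' prolonged. To score such predictions with a day-scale loss, gated rows are
#' imputed at the classifier threshold `tau_c`: a truly prolonged encounter
#' then contributes zero customized loss, a truly short one contributes
#' `|tau_c - y|`. This is the only convention under which the truncated hinge
#' loss is computable for gated rows, and it is stated wherever results are
#' reported.
#'
#' @param predictions A data frame with logical column `is_prolonged` and
#'   numeric column `los_estimate` (`NA` on gated rows), as returned by
#'   [predict.los_two_stage()].
#' @param tau_c Classifier threshold in days.
#' @return The input with an additional numeric column `scored_estimate`.
#' @export
impute_gated <- function(predictions, tau_c = 7) {
  stopifnot(is.data.frame(predictions))
  if (!all(c("is_prolonged", "los_estimate") %in% names(predictions))) {
    abort("`predictions` needs columns `is_prolonged` and `los_estimate`.")
  }
  dplyr::mutate(
    tibble::as_tibble(predictions),
    scored_estimate = dplyr::if_else(
      .data$is_prolonged, tau_c, .data$los_estimate
    )
  )
}
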