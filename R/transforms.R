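#' Outcome transformations for skewed training targets
#'
#' Transformations applied to the *training* outcome only; held-out outcomes
#' are always evaluated on the original day scale. `"log"` (natural log,
#' optionally offset for data containing zeros) symmetrizes a right-skewed
#' outcome; `"truncate"` caps training outcomes at a level (e.g. 7 days) to
#' blunt the influence of the long tail; `"identity"` leaves the outcome
#' unchanged.
#'
#' @param kind One of `"identity"`, `"log"`, `"truncate"`.
#' @param level Truncation level in days (required for `"truncate"`).
#' @param offset Days added before taking logs (default 0; the natural-log
#'   transform requires `y + offset > 0`).
#' @return An object of class `los_transform`.
#' @examples
#' apply_transform(c(1, 5, 20), outcome_transform("truncate", level = 7))
#' invert_transform(c(0, 1), outcome_transform("log"))
#' @export
outcome_transform <- function(kind = c("identity", "log", "truncate"),
                              level = NULL, offset = 0) {
  kind <- match.arg(kind)
  if (kind == "truncate") {
    if (is.null(level)) abort("`truncate` requires a `level` in days.")
    check_number(level, "level", min = 0, strict_min = TRUE)
  }
  check_number(offset, "offset", min = 0)
  structure(
    list(kind = kind, level = level, offset = offset),
    class = "los_transform"
  )
}

#' @export
print.los_transform <- function(x, ...) {
  cat("<los_transform>", x$kind)
  if (x$kind == "truncate") cat(" at", x$level, "days")
  if (x$kind == "log" && x$offset > 0) cat(" (offset", x$offset, "days)")
  cat("\n")
  invisible(x)
}

as_transform <- function(x) {
  if (inherits(x, "los_transform")) return(x)
  if (is.character(x) && length(x) == 1L) return(outcome_transform(x))
  abort("expected a `los_transform` or a transform kind string.")
}

#' @rdname outcome_transform
#' @param y Numeric outcome vector on the day scale.
#' @param transform A `los_transform`.
#' @export
apply_transform <- function(y, transform) {
  transform <- as_transform(transform)
  switch(transform$kind,
    identity = y,
    truncate = pmin(y, transform$level),
    log = {
      shifted <- y + transform$offset
      if (any(shifted <= 0)) {
        abort(sprintf(
          "log transform needs positive values; %d value(s) are <= 0 after offset %g.",
          sum(shifted <= 0), transform$offset
        ))
      }
      log(shifted)
    }
  )
}

#' @rdname outcome_transform
#' @param z Numeric vector on the transformed scale.
#' @details Truncation is not invertible: a capped value cannot be restored.
#'   Predictions from a truncated-outcome model are reported as-is.
#' @export
invert_transform <- function(z, transform) {
  transform <- as_transform(transform)
  switch(transform$kind,
    identity = z,
    log = exp(z) - transform$offset,
    truncate = abort("the truncation transform is not invertible.")
  )
}
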