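#' @importFrom rlang abort warn inform %||% .data
#' @importFrom stats median predict quantile runif rnorm rbinom rnbinom
#'   plogis qlnorm plnorm uniroot var coef setNames complete.cases
#' @importFrom utils head modifyList
NULL

# Validate an aligned truth/estimate pair; returns n invisibly.
check_pair <- function(y_true, y_pred, require_positive_truth = FALSE,
                       call = rlang::caller_env()) {
  if (length(y_true) == 0L || length(y_pred) == 0L) {
    abort("`y_true` and `y_pred` must be non-empty.", call = call)
  }
  if (length(y_true) != length(y_pred)) {
    abort(
      sprintf(
        "`y_true` (%d) and `y_pred` (%d) must have equal lengths.",
        length(y_true), length(y_pred)
      ),
      call = call
    )
  }
  if (!is.numeric(y_true) || !is.numeric(y_pred)) {
    abort("`y_true` and `y_pred` must be numeric vectors.", call = call)
  }
  if (anyNA(y_true) || anyNA(y_pred)) {
    abort("`y_true` and `y_pred` must not contain missing values.", call = call)
  }
  if (any(y_true < 0)) {
    abort("`y_true` must be non-negative (a length of stay in days).",
      call = call
    )
  }
  if (require_positive_truth && any(y_true == 0)) {
    abort(
      sprintf(
        "relative error is undefined at `y_true` == 0 (first offending index: %d).",
        which(y_true == 0)[1L]
      ),
      call = call
    )
  }
  invisible(length(y_true))
}

check_number <- function(x, name, min = -Inf, max = Inf,
                         strict_min = FALSE, call = rlang::caller_env()) {
  ok <- is.numeric(x) && length(x) == 1L && !is.na(x) &&
    (if (strict_min) x > min else x >= min) && x <= max
  if (!ok) {
    abort(
      sprintf(
        "`%s` must be a single number in %s%s, %s].",
        name, if (strict_min) "(" else "[", format(min), format(max)
      ),
      call = call
    )
  }
  invisible(x)
}

# Deterministic child seed: keeps derived streams reproducible and < 2^31.
derive_seed <- function(seed, stream) {
  (as.double(seed %% 2147483647L) * 48271 + stream * 7919) %% 2147483629
}

# Fold assignment: balanced, reproducible, independent of the global RNG.
make_folds <- function(n, k, seed) {
  if (k < 2L || k > n) {
    abort(sprintf("cannot make %d folds for %d rows.", k, n))
  }
  old <- get0(".Random.seed", envir = globalenv())
  on.exit(
    if (!is.null(old)) assign(".Random.seed", old, envir = globalenv()),
    add = TRUE
  )
  set.seed(as.integer(derive_seed(seed, 1L) %% 2147483647))
  sample(rep_len(seq_len(k), n))
}

# Evaluate fn under a temporary seed, restoring the caller's RNG state.
with_seed <- function(seed, code) {
  old <- get0(".Random.seed", envir = globalenv())
  on.exit(
    if (!is.null(old)) assign(".Random.seed", old, envir = globalenv()),
    add = TRUE
  )
  set.seed(as.integer(seed %% 2147483647))
  force(code)
}
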