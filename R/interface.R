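#' Load and validate a run configuration
#'
#' A single YAML file drives the pipeline: where the data come from (a CSV
#' path or a synthetic cohort block), the outcome column, the split, the
#' two-stage settings, the comparison grid and the sweep. Values omitted
#' from the file take the package defaults shown in [run_config_defaults()].
#'
#' @param file Path to a YAML configuration file, or `NULL` for the
#'   defaults.
#' @param overrides Named list merged over the file values (used by the
#'   command line for flag overrides such as the seed).
#' @return A validated configuration list of class `los_run_config`.
#' @export
run_config <- function(file = NULL, overrides = list()) {
  cfg <- run_config_defaults()
  user <- list()
  if (!is.null(file)) {
    if (!file.exists(file)) abort(sprintf("config file not found: %s", file))
    user <- yaml::read_yaml(file)
    cfg <- utils::modifyList(cfg, user)
  }
  if (length(overrides)) cfg <- utils::modifyList(cfg, overrides)
  # the data block is a choice, not a set of defaults to merge into
  provided_data <- overrides$data %||% user$data
  if (!is.null(provided_data)) cfg$data <- provided_data
  has_csv <- !is.null(cfg$data$csv)
  has_syn <- !is.null(cfg$data$synthetic)
  if (has_csv == has_syn) {
    abort("config must name exactly one data source: data.csv or data.synthetic.")
  }
  check_number(cfg$seed, "seed", min = 0)
  structure(cfg, class = "los_run_config")
}

#' @rdname run_config
#' @export
run_config_defaults <- function() {
  list(
    seed = 1,
    outcome = "los",
    data = list(csv = NULL, synthetic = list(n = 5000)),
    split = list(train_fraction = 2 / 3, cv_folds = 5),
    two_stage = list(
      tau_c = 7, tau_r = 35, target_short_sensitivity = 0.99,
      stage2_transform = "log",
      classifier = list(family = "tree_ensemble", hyperparameters = list()),
      regressor = list(family = "tree_ensemble", hyperparameters = list())
    ),
    compare = list(
      algorithms = c("penalized_linear", "tree_ensemble", "feedforward_net"),
      transforms = list("identity"),
      losses = c("mse", "mae", "customized"),
      approaches = "one_stage",
      hyperparameters = list()
    ),
    sweep = list(taus = c(7, 21, 35)),
    evaluate = list(
      losses = c("mse", "mae", "customized"), bootstrap = 1000, level = 0.95
    ),
    output_dir = "loshurdle-output",
    verbosity = 1
  )
}

config_cohort_spec <- function(cfg) {
  args <- cfg$data$synthetic
  # YAML 1.1 reads a bare `n:` key as the boolean FALSE; map it back
  names(args)[names(args) == "FALSE"] <- "n"
  args$seed <- args$seed %||% cfg$seed
  if (!is.null(args$risk_coefs)) args$risk_coefs <- unlist(args$risk_coefs)
  if (!is.null(args$shortstay_coefs)) {
    args$shortstay_coefs <- unlist(args$shortstay_coefs)
  }
  do.call(cohort_spec, args)
}

config_two_stage <- function(cfg) {
  ts <- cfg$two_stage
  mk <- function(block, task, stream) {
    learner_spec(
      family = block$family %||% "tree_ensemble", task = task,
      hyperparameters = block$hyperparameters %||% list(),
      cv_folds = cfg$split$cv_folds,
      seed = derive_seed(cfg$seed, stream)
    )
  }
  two_stage_config(
    tau_c = ts$tau_c, tau_r = ts$tau_r,
    target_short_sensitivity = ts$target_short_sensitivity,
    stage2_transform = outcome_transform(ts$stage2_transform),
    classifier_spec = mk(ts$classifier, "classification", 41L),
    regressor_spec = mk(ts$regressor, "regression", 42L)
  )
}

say <- function(cfg, ..., level = 1) {
  msg <- paste0(...)
  if ((cfg$verbosity %||% 1) >= level) inform(msg)
  log_file <- file.path(cfg$output_dir, "run.log")
  if (dir.exists(cfg$output_dir)) {
    cat(msg, "\n", file = log_file, append = TRUE, sep = "")
  }
  invisible(msg)
}

write_manifest <- function(cfg, step, extra = list()) {
  info <- c(
    list(
      package = "loshurdle",
      version = as.character(utils::packageVersion("loshurdle")),
      step = step, seed = cfg$seed,
      config = unclass(cfg), config_hash = rlang::hash(unclass(cfg))
    ),
    extra
  )
  path <- file.path(cfg$output_dir, paste0(step, ".manifest.json"))
  jsonlite::write_json(info, path, auto_unbox = TRUE, pretty = TRUE, digits = NA)
  invisible(path)
}

ensure_outdir <- function(cfg) {
  if (!dir.exists(cfg$output_dir)) {
    dir.create(cfg$output_dir, recursive = TRUE)
  }
  invisible(cfg$output_dir)
}

load_run_data <- function(cfg) {
  if (!is.null(cfg$data$csv)) {
    if (!file.exists(cfg$data$csv)) {
      abort(sprintf("data CSV not found: %s", cfg$data$csv))
    }
    read_cohort(cfg$data$csv)
  } else {
    generate_cohort(config_cohort_spec(cfg))
  }
}

check_outcome_column <- function(data, cfg) {
  if (!cfg$outcome %in% names(data)) {
    abort(sprintf(
      "outcome column `%s` not found; available columns: %s",
      cfg$outcome, paste(names(data), collapse = ", ")
    ))
  }
}

#' Pipeline steps
#'
#' Programmatic equivalents of the command-line subcommands. Each step
#' reads its inputs per the configuration, writes its outputs (CSV/JSON
#' plus a manifest recording the configuration hash and seed) under
#' `output_dir`, and returns its main result invisibly.
#'
#' \describe{
#'   \item{`run_simulate()`}{generate a synthetic cohort; writes
#'     `cohort.csv` + manifest.}
#'   \item{`run_fit()`}{split the data, fit the two-stage model on the
#'     training part; writes `model.rds`, `split.csv` (row assignment) and a
#'     fit log.}
#'   \item{`run_evaluate()`}{evaluate the saved model on the test part;
#'     writes `metrics.csv`, `predictions.csv`, `pr_curve.csv`,
#'     `roc_curve.csv` and `summary.json`.}
#'   \item{`run_compare()`}{cross-validated comparison grid on the training
#'     part; writes `comparison.csv`.}
#'   \item{`run_sweep()`}{stage-2 threshold sweep; writes `sweep.csv`.}
#' }
#'
#' @param cfg A [run_config()].
#' @return See each step; paths of written files are attached as the
#'   `"paths"` attribute.
#' @export
run_simulate <- function(cfg) {
  stopifnot(inherits(cfg, "los_run_config"))
  if (is.null(cfg$data$synthetic)) {
    abort("run_simulate() needs a data.synthetic block in the config.")
  }
  ensure_outdir(cfg)
  cohort <- generate_cohort(config_cohort_spec(cfg))
  path <- file.path(cfg$output_dir, "cohort.csv")
  write_cohort(cohort, path)
  write_manifest(cfg, "simulate", list(n = nrow(cohort), cohort_csv = path))
  say(cfg, "simulate: wrote ", nrow(cohort), " encounters to ", path)
  invisible(structure(cohort, paths = path))
}

#' @rdname run_simulate
#' @export
run_fit <- function(cfg) {
  stopifnot(inherits(cfg, "los_run_config"))
  ensure_outdir(cfg)
  data <- load_run_data(cfg)
  check_outcome_column(data, cfg)
  sp <- split_spec(cfg$split$train_fraction, cfg$split$cv_folds,
    seed = cfg$seed
  )
  parts <- split_data(data, sp)
  model <- fit_two_stage(
    parts$train, !!rlang::sym(cfg$outcome), config_two_stage(cfg)
  )

  model_path <- file.path(cfg$output_dir, "model.rds")
  saveRDS(list(model = model, split_spec = sp), model_path)
  split_path <- file.path(cfg$output_dir, "split.csv")
  readr::write_csv(
    tibble::tibble(
      row_id = seq_len(nrow(data)),
      set = ifelse(seq_len(nrow(data)) %in% parts$train_idx, "train", "test")
    ),
    split_path,
    progress = FALSE
  )
  fitlog <- list(
    n_train = model$n_train, n_stage2 = model$n_stage2,
    cutoff = model$cutoff$cutoff,
    oof_short_sensitivity = model$cutoff$short_sensitivity,
    oof_prolonged_sensitivity = model$cutoff$prolonged_sensitivity,
    target_short_sensitivity = cfg$two_stage$target_short_sensitivity
  )
  jsonlite::write_json(fitlog, file.path(cfg$output_dir, "fit_log.json"),
    auto_unbox = TRUE, pretty = TRUE, digits = NA
  )
  write_manifest(cfg, "fit", fitlog)
  say(
    cfg, "fit: cutoff ", format(model$cutoff$cutoff, digits = 4),
    ", out-of-fold short sensitivity ",
    format(model$cutoff$short_sensitivity, digits = 4)
  )
  invisible(structure(model, paths = model_path))
}

#' @rdname run_simulate
#' @export
run_evaluate <- function(cfg) {
  stopifnot(inherits(cfg, "los_run_config"))
  ensure_outdir(cfg)
  model_path <- file.path(cfg$output_dir, "model.rds")
  if (!file.exists(model_path)) {
    abort("no fitted model found; run run_fit() first.")
  }
  saved <- readRDS(model_path)
  data <- load_run_data(cfg)
  check_outcome_column(data, cfg)
  parts <- split_data(data, saved$split_spec)

  report <- evaluate_model(
    saved$model, parts$test, !!rlang::sym(cfg$outcome),
    losses = cfg$evaluate$losses,
    B = cfg$evaluate$bootstrap, level = cfg$evaluate$level,
    seed = cfg$seed
  )
  paths <- c(
    metrics = file.path(cfg$output_dir, "metrics.csv"),
    predictions = file.path(cfg$output_dir, "predictions.csv"),
    pr = file.path(cfg$output_dir, "pr_curve.csv"),
    roc = file.path(cfg$output_dir, "roc_curve.csv"),
    summary = file.path(cfg$output_dir, "summary.json")
  )
  readr::write_csv(as.data.frame(report), paths["metrics"], progress = FALSE)
  pred <- attr(report, "predictions")
  out_pred <- tibble::tibble(
    row_id = seq_len(nrow(pred)),
    observed = pred$y,
    is_prolonged = pred$gated,
    los_estimate = ifelse(pred$gated, NA_real_, pred$pred)
  )
  readr::write_csv(out_pred, paths["predictions"], na = "", progress = FALSE)
  curves <- attr(report, "curves")
  if (!is.null(curves)) {
    readr::write_csv(curves$pr, paths["pr"], progress = FALSE)
    readr::write_csv(curves$roc, paths["roc"], progress = FALSE)
  }
  overall <- dplyr::filter(report, .data$bin == "overall")
  jsonlite::write_json(
    rlang::set_names(as.list(overall$estimate), overall$metric),
    paths["summary"],
    auto_unbox = TRUE, pretty = TRUE, digits = NA
  )
  write_manifest(cfg, "evaluate", list(n_test = nrow(parts$test)))
  say(
    cfg, "evaluate: ",
    paste(overall$metric, format(overall$estimate, digits = 4),
      sep = " = ", collapse = ", "
    )
  )
  invisible(structure(report, paths = paths))
}

#' @rdname run_simulate
#' @export
run_compare <- function(cfg) {
  stopifnot(inherits(cfg, "los_run_config"))
  ensure_outdir(cfg)
  data <- load_run_data(cfg)
  check_outcome_column(data, cfg)
  sp <- split_spec(cfg$split$train_fraction, cfg$split$cv_folds,
    seed = cfg$seed
  )
  parts <- split_data(data, sp)
  grid <- comparison_grid(
    algorithms = cfg$compare$algorithms,
    transforms = cfg$compare$transforms,
    losses = cfg$compare$losses,
    approaches = cfg$compare$approaches
  )
  report <- crossval_compare(
    parts$train, !!rlang::sym(cfg$outcome),
    grid = grid, spec = sp, config = config_two_stage(cfg),
    hyperparameters = cfg$compare$hyperparameters %||% list()
  )
  path <- file.path(cfg$output_dir, "comparison.csv")
  readr::write_csv(as.data.frame(report), path, progress = FALSE)
  write_manifest(cfg, "compare", list(n_train = nrow(parts$train)))
  say(cfg, "compare: wrote ", path)
  invisible(structure(report, paths = path))
}

#' @rdname run_simulate
#' @export
run_sweep <- function(cfg) {
  stopifnot(inherits(cfg, "los_run_config"))
  ensure_outdir(cfg)
  data <- load_run_data(cfg)
  check_outcome_column(data, cfg)
  sp <- split_spec(cfg$split$train_fraction, cfg$split$cv_folds,
    seed = cfg$seed
  )
  parts <- split_data(data, sp)
  report <- sweep_regressor_threshold(
    parts$train, parts$test, !!rlang::sym(cfg$outcome),
    config = config_two_stage(cfg), taus = unlist(cfg$sweep$taus)
  )
  path <- file.path(cfg$output_dir, "sweep.csv")
  readr::write_csv(report, path, progress = FALSE)
  write_manifest(cfg, "sweep", list(taus = unlist(cfg$sweep$taus)))
  say(cfg, "sweep: wrote ", path)
  invisible(structure(report, paths = path))
}
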