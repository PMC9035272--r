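small_cfg <- function(dir, n = 600, seed = 3) {
  cfg <- run_config(overrides = list(
    seed = seed,
    data = list(synthetic = list(n = n)),
    two_stage = list(
      classifier = list(
        family = "tree_ensemble",
        hyperparameters = list(num.trees = 60, mtry = 3)
      ),
      regressor = list(
        family = "tree_ensemble",
        hyperparameters = list(num.trees = 60, mtry = 3)
      )
    ),
    evaluate = list(bootstrap = 150),
    output_dir = dir,
    verbosity = 0
  ))
  cfg
}

test_that("configurations validate their data source and seed", {
  expect_error(
    run_config(overrides = list(data = list(
      csv = "x.csv", synthetic = list(n = 10)
    ))),
    "exactly one data source"
  )
  cfg <- run_config(overrides = list(data = list(csv = "nope.csv")))
  expect_error(loshurdle:::load_run_data(cfg), "not found")
  withr::with_tempdir({
    writeLines(c("seed: 9", "outcome: stay"), "cfg.yml")
    cfg <- run_config("cfg.yml")
    expect_equal(cfg$seed, 9)
    expect_equal(cfg$outcome, "stay")
  })
})

test_that("simulate writes a cohort, a manifest, and is byte-stable", {
  withr::with_tempdir({
    cfg <- small_cfg("out")
    run_simulate(cfg)
    expect_true(file.exists("out/cohort.csv"))
    expect_true(file.exists("out/cohort.csv.manifest.json"))
    bytes1 <- readBin("out/cohort.csv", "raw", file.size("out/cohort.csv"))
    unlink("out", recursive = TRUE)
    run_simulate(cfg)
    bytes2 <- readBin("out/cohort.csv", "raw", file.size("out/cohort.csv"))
    expect_identical(bytes1, bytes2)
    bad <- run_config(overrides = list(
      data = list(synthetic = list(n = 100, prolonged_prevalence = 1.5)),
      output_dir = "out2", verbosity = 0
    ))
    expect_error(run_simulate(bad), "prolonged_prevalence")
  })
})

test_that("fit/evaluate produce consistent, schema-checked outputs", {
  withr::with_tempdir({
    cfg <- small_cfg("out")
    model <- run_fit(cfg)
    expect_true(file.exists("out/model.rds"))
    expect_true(file.exists("out/fit_log.json"))
    log <- jsonlite::read_json("out/fit_log.json")
    expect_gte(log$oof_short_sensitivity, log$target_short_sensitivity)
    reloaded <- readRDS("out/model.rds")$model
    co <- generate_cohort(loshurdle:::config_cohort_spec(cfg))
    expect_equal(predict(reloaded, co), predict(model, co))

    rep <- run_evaluate(cfg)
    for (f in c(
      "metrics.csv", "predictions.csv", "pr_curve.csv",
      "roc_curve.csv", "summary.json"
    )) {
      expect_true(file.exists(file.path("out", f)))
    }
    metrics <- readr::read_csv("out/metrics.csv", show_col_types = FALSE)
    expect_true(all(
      c("mse", "mae", "customized", "calibration", "auc") %in% metrics$metric
    ))
    preds <- readr::read_csv("out/predictions.csv", show_col_types = FALSE)
    # prolonged rows carry an empty estimate, never a sentinel number
    expect_true(all(is.na(preds$los_estimate[preds$is_prolonged])))

    # a missing outcome column is reported by name
    cfg_bad <- cfg
    cfg_bad$outcome <- "stay_days"
    expect_error(run_fit(cfg_bad), "stay_days")
  })
})

test_that("the full pipeline is byte-identical under one seed", {
  withr::with_tempdir({
    run_once <- function(dir) {
      cfg <- small_cfg(dir, n = 500, seed = 7)
      run_simulate(cfg)
      run_fit(cfg)
      run_evaluate(cfg)
      readBin(
        file.path(dir, "metrics.csv"), "raw",
        file.size(file.path(dir, "metrics.csv"))
      )
    }
    expect_identical(run_once("a"), run_once("b"))
  })
})

test_that("compare and sweep steps write their reports", {
  withr::with_tempdir({
    cfg <- small_cfg("out", n = 400)
    cfg$compare <- utils::modifyList(cfg$compare, list(
      algorithms = "tree_ensemble",
      losses = c("mae", "customized"),
      hyperparameters = list(tree_ensemble = list(num.trees = 40, mtry = 3))
    ))
    cfg$split$cv_folds <- 3
    cfg$sweep$taus <- c(7, 35)
    run_compare(cfg)
    comparison <- readr::read_csv("out/comparison.csv", show_col_types = FALSE)
    expect_true(all(c("approach", "metric", "bin", "value") %in% names(comparison)))
    run_sweep(cfg)
    sweep <- readr::read_csv("out/sweep.csv", show_col_types = FALSE)
    expect_equal(sweep$tau_r, c(7, 35))
    expect_true(all(c("customized", "mae", "short_sensitivity") %in% names(sweep)))
  })
})

test_that("the command-line wrapper runs a simulate step", {
  cli <- system.file("cli", "loshurdle", package = "loshurdle")
  skip_if(cli == "", "CLI script not installed")
  withr::with_tempdir({
    writeLines(
      c(
        "seed: 5",
        "data:",
        "  synthetic:",
        "    n: 120",
        "output_dir: cliout",
        "verbosity: 0"
      ),
      "cfg.yml"
    )
    res <- system2(
      file.path(R.home("bin"), "Rscript"),
      c(cli, "simulate", "--config", "cfg.yml"),
      stdout = TRUE, stderr = TRUE,
      env = paste0("R_LIBS=", paste(.libPaths(), collapse = ":"))
    )
    expect_equal(attr(res, "status") %||% 0L, 0L)
    expect_true(file.exists("cliout/cohort.csv"))
  })
})
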