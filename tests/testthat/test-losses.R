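test_that("loss kernels match their closed forms on worked examples", {
  # zero-error identities
  expect_equal(loss_mse(c(1, 2, 3), c(1, 2, 3)), 0)
  expect_equal(loss_mae(c(1, 2, 3), c(1, 2, 3)), 0)
  expect_equal(loss_mre(c(1, 2), c(1, 2)), 0)
  # hand evaluations
  expect_equal(loss_mse(c(0, 4), c(2, 2)), 4)
  expect_equal(loss_mse(10, 7), 9)
  expect_equal(loss_mae(c(0, 4), c(2, 2)), 2)
  expect_equal(loss_mae(10, 7), 3)
  expect_equal(loss_mre(2, 1), 0.5)
  expect_equal(loss_mre(1, 3), 2)
})

test_that("the truncated hinge loss follows its three branches", {
  # both prolonged: no loss
  expect_equal(loss_customized(10, 8, tau_c = 7), 0)
  # truth prolonged, prediction short: distance to the threshold only
  expect_equal(loss_customized(10, 5, tau_c = 7), 2)
  # truth short: plain absolute error
  expect_equal(loss_customized(3, 5, tau_c = 7), 2)
  # perfect predictions across both regimes
  expect_equal(loss_customized(c(3, 10), c(3, 10), tau_c = 7), 0)
  # boundary values sit in the prolonged branch (>= convention)
  expect_equal(loss_customized(7, 7, tau_c = 7), 0)
  expect_equal(loss_customized(7, 6, tau_c = 7), 1)
})

test_that("losses equal an independent element-wise loop oracle", {
  for (s in 1:50) {
    pr <- random_pair(n = sample(1:50, 1), seed = s)
    y <- pmax(pr$y, 0.01) # mre needs positive truth
    p <- pr$p
    for (name in c("mse", "mae", "mre", "customized")) {
      got <- loss_fn(name, tau_c = 7)(y, p)
      expect_equal(got, oracle_loss(name, y, p, tau = 7), tolerance = 1e-12)
    }
  }
})

test_that("customized loss is bounded by MAE and converges to it", {
  for (s in 1:25) {
    pr <- random_pair(n = 30, seed = 100 + s)
    expect_lte(loss_customized(pr$y, pr$p, tau_c = 7), loss_mae(pr$y, pr$p))
    # per-sample bound, not just on average
    per <- vapply(seq_along(pr$y), function(i) {
      loss_customized(pr$y[i], pr$p[i], tau_c = 7)
    }, numeric(1))
    expect_true(all(per <= abs(pr$p - pr$y) + 1e-12))
    # tau beyond all data: no sample reaches the prolonged branches
    big <- max(pr$y, pr$p) + 1
    expect_equal(loss_customized(pr$y, pr$p, tau_c = big), loss_mae(pr$y, pr$p))
  }
})

test_that("customized loss is zero exactly when every sample is forgiven", {
  for (s in 1:25) {
    pr <- random_pair(n = 20, seed = 200 + s)
    got <- loss_customized(pr$y, pr$p, tau_c = 7)
    forgiven <- (pr$y >= 7 & pr$p >= 7) | pr$p == pr$y
    expect_equal(got == 0, all(forgiven))
  }
})

test_that("losses are permutation invariant and obey Jensen's inequality", {
  for (s in 1:10) {
    pr <- random_pair(n = 25, seed = 300 + s)
    y <- pmax(pr$y, 0.01)
    perm <- sample(length(y))
    for (name in c("mse", "mae", "mre", "customized")) {
      fn <- loss_fn(name)
      expect_equal(fn(y, pr$p), fn(y[perm], pr$p[perm]))
    }
    expect_gte(loss_mse(y, pr$p), loss_mae(y, pr$p)^2)
  }
})

test_that("invalid pairs are rejected with informative errors", {
  expect_error(loss_mae(numeric(0), numeric(0)), "non-empty")
  expect_error(loss_mae(1:3, 1:2), "equal lengths")
  expect_error(loss_mae(c(-1, 2), c(1, 2)), "non-negative")
  expect_error(loss_mre(c(1, 0, 2), c(1, 1, 2)), "index: 2")
  expect_error(loss_customized(3, 5, tau_c = 0), "tau_c")
})

test_that("loss identifiers are case-insensitive", {
  d <- tibble::tibble(y = c(1, 10), p = c(2, 10))
  up <- measure_losses(d, y, p, losses = c("MAE", "Mse"))
  lo <- measure_losses(d, y, p, losses = c("mae", "mse"))
  expect_equal(up$value, lo$value)
  expect_equal(up$metric, c("mae", "mse"))
})

test_that("stratified losses partition by observed bin", {
  d <- tibble::tibble(y = c(1, 3, 5, 10), p = c(1, 3, 5, 10))
  rep <- stratified_loss(d, y, p, losses = "mae")
  expect_true(all(rep$value == 0))
  expect_equal(sum(rep$n[rep$bin != "overall"]), 4)

  d2 <- tibble::tibble(y = c(1, 10), p = c(2, 10))
  rep2 <- stratified_loss(d2, y, p, losses = "mae")
  get <- function(b) rep2$value[rep2$bin == b]
  expect_equal(get("0-2"), 1)
  expect_equal(get(">=7"), 0)
  expect_equal(get("overall"), 0.5)
  # empty bins are reported absent (NA), never zero
  expect_true(is.na(get("2-4")))
  expect_equal(rep2$n[rep2$bin == "2-4"], 0)

  d3 <- tibble::tibble(y = 5, p = 6)
  rep3 <- stratified_loss(d3, y, p, losses = "mse")
  expect_equal(rep3$value[rep3$bin == "4-7"], 1)
  expect_true(all(is.na(rep3$value[!rep3$bin %in% c("4-7", "overall")])))
})

test_that("overall loss is the count-weighted mean of per-bin losses", {
  for (s in 1:10) {
    pr <- random_pair(n = 40, seed = 400 + s)
    d <- tibble::tibble(y = pr$y, p = pr$p)
    for (name in c("mse", "mae", "customized")) {
      rep <- stratified_loss(d, y, p, losses = name)
      per_bin <- rep[rep$bin != "overall" & !is.na(rep$value), ]
      expect_equal(
        sum(per_bin$value * per_bin$n) / sum(per_bin$n),
        rep$value[rep$bin == "overall"]
      )
    }
  }
})

test_that("custom bin edges are validated", {
  expect_error(los_bins(c(0, 2, 2, Inf)), "strictly increasing")
  expect_error(los_bins(c(1, 2, Inf)), "start at 0")
  expect_error(los_bins(c(0, 2, 4)), "end at Inf")
  expect_equal(los_bins(c(0, 4, Inf))$labels, c("0-4", ">=4"))
})

test_that("gated predictions are imputed at the classifier threshold", {
  gp <- tibble::tibble(
    is_prolonged = c(TRUE, FALSE),
    los_estimate = c(NA_real_, 2.5)
  )
  out <- impute_gated(gp, tau_c = 7)
  expect_equal(out$scored_estimate, c(7, 2.5))
  expect_error(impute_gated(tibble::tibble(a = 1)), "is_prolonged")
})
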