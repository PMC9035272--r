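# Shared fixtures: small pinned learner specs keep the forest fits fast and
# deterministic; all expected loss values are recomputed by loop oracles.

quick_rf <- function(task, seed = 1, num.trees = 100, mtry = 3) {
  learner_spec("tree_ensemble", task,
    hyperparameters = list(num.trees = num.trees, mtry = mtry),
    seed = seed
  )
}

quick_two_stage_config <- function(seed = 1, tau_r = 35, num.trees = 100,
                                   mtry = 3,
                                   stage2_transform = outcome_transform("log")) {
  two_stage_config(
    tau_r = tau_r,
    stage2_transform = stage2_transform,
    classifier_spec = quick_rf("classification",
      seed = seed,
      num.trees = num.trees, mtry = mtry
    ),
    regressor_spec = quick_rf("regression",
      seed = seed,
      num.trees = num.trees, mtry = mtry
    )
  )
}

# Element-wise loop oracles, written independently of the vectorized kernels.
oracle_loss <- function(name, y, p, tau = 7) {
  n <- length(y)
  total <- 0
  for (i in seq_len(n)) {
    total <- total + switch(name,
      mse = (p[i] - y[i])^2,
      mae = abs(p[i] - y[i]),
      mre = abs(p[i] - y[i]) / y[i],
      customized = {
        if (y[i] >= tau && p[i] >= tau) {
          0
        } else if (y[i] >= tau && p[i] < tau) {
          abs(p[i] - tau)
        } else {
          abs(p[i] - y[i])
        }
      }
    )
  }
  total / n
}

# Exhaustive cutoff search over all distinct score values plus an
# everyone-short rule, mirroring the documented decision rule directly.
oracle_best_cutoff <- function(scores, labels, target) {
  is_p <- labels == "prolonged"
  cands <- c(sort(unique(scores)), if (max(scores) < 1) (max(scores) + 1) / 2)
  best <- NULL
  for (c in cands) {
    ss <- mean(scores[!is_p] < c)
    ps <- mean(scores[is_p] >= c)
    if (ss >= target && (is.null(best) || ps > best$ps)) {
      best <- list(cutoff = c, ss = ss, ps = ps)
    }
  }
  best
}

random_pair <- function(n, seed) {
  set.seed(seed)
  list(
    y = round(stats::rexp(n, 1 / 3), 3),
    p = round(pmax(stats::rexp(n, 1 / 3) + stats::rnorm(n), 0), 3)
  )
}
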