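test_that("the value function has the stated piecewise-power form", {
  # identity in the linear limit
  x <- seq(-20, 20, by = 0.5)
  expect_equal(value_fn(x, alpha = 1, lambda = 1), x)
  # direct evaluation with published parameters
  expect_equal(value_fn(10, alpha = 0.69), 4.89778819368446)
  expect_equal(value_fn(-10, alpha = 0.69, lambda = 2.57), -12.5873156577691)
  # gain/loss magnitude oracle: |v(-x)| = lambda * v(x) for x > 0
  xs <- c(0.5, 1, 7, 42)
  expect_equal(abs(value_fn(-xs, 0.69, 2.57)), 2.57 * value_fn(xs, 0.69))
  # strictly increasing and continuous, kink only at 0
  g <- seq(-5, 5, by = 0.01)
  v <- value_fn(g, 0.69, 2.57)
  expect_true(all(diff(v) > 0))
  expect_lt(abs(value_fn(1e-12, 0.69, 2.57) - value_fn(-1e-12, 0.69, 2.57)),
            1e-7)
})

test_that("probability weighting is the one-parameter inverse-S form", {
  p <- seq(0, 1, by = 0.05)
  expect_equal(weight_fn(p, gamma = 1), p)
  expect_equal(weight_fn(0.1, gamma = 0.61), 0.186302566377174)
  for (g in c(0.3, 0.61, 1, 1.5, 2)) {
    expect_equal(weight_fn(0, g), 0)
    expect_equal(weight_fn(1, g), 1)
    expect_true(all(diff(weight_fn(p, g)) > 0))
  }
  expect_error(weight_fn(1.2, 0.9), "invalid probability")
})

test_that("gamble expected value matches hand-computed cases", {
  # certainty case: single state
  expect_equal(gamble_ev(1, 60, 50), 10)
  # two-state hand evaluation with loss aversion
  expect_equal(gamble_ev(c(0.5, 0.5), c(40, 60), 50, alpha = 1, lambda = 2),
               -5)
  # all payoffs equal to the price
  expect_equal(gamble_ev(rep(0.25, 4), rep(50, 4), 50, alpha = 0.7,
                         lambda = 2.5), 0)
  # reduces to plain expected value at alpha = lambda = gamma = 1
  set.seed(31)
  for (i in 1:20) {
    K <- sample(2:10, 1)
    p <- as.numeric(stats::rmultinom(1, 60, stats::runif(K)) / 60)
    x <- stats::runif(K, 10, 99); P <- stats::runif(1, 10, 99)
    expect_equal(gamble_ev(p, x, P), sum(p * (x - P)), tolerance = 1e-12)
  }
  expect_error(gamble_ev(c(0.5, 0.5), c(1, 2, 3), 1), "same length")
})

test_that("softmax buy probability is the clipped logistic", {
  expect_equal(buy_probability(0, 0, 1), 0.5)
  expect_equal(buy_probability(2, 0, 1), 0.880797077977882)
  ev <- seq(-10, 10, by = 0.5)
  expect_true(all(diff(buy_probability(ev, 0.3, 0.8)) > 0))
  expect_equal(buy_probability(1e6, 0, 1), 1 - 1e-9)
  expect_equal(buy_probability(-1e6, 0, 1), 1e-9)
})

test_that("dataset log-likelihood is additive and matches closed forms", {
  des <- tiny_design(bins = 1L, ks = 2L)
  ses <- simulate_cohort(des, 1L, seed = 32)
  ses$choices$decision <- 1L
  # slope 0, intercept 0: every trial contributes log(0.5)
  n_active <- sum(ses$choices$condition == "active")
  expect_equal(dataset_loglik(ses, "M2", c(intercept = 0, slope = 0)),
               n_active * log(0.5))
  ses_na <- ses
  ses_na$choices$decision <- NA_integer_
  expect_error(dataset_loglik(ses_na, "M2", c(intercept = 0, slope = 0)),
               "incomplete data")
})

test_that("the vectorized likelihood equals a straight-line recomputation", {
  ses <- simulate_cohort(tiny_design(), 2L, seed = 33, spec = "M4",
                         params = default_choice_params("M4"))
  cases <- list(
    M2 = c(intercept = -0.49, slope = 0.38),
    M3 = c(intercept = -0.39, slope = 0.31, eta = 0.17),
    M4 = default_choice_params("M4"),
    M4a = default_choice_params("M4a"),
    M4b = default_choice_params("M4b"),
    M5 = default_choice_params("M5"))
  for (tag in names(cases)) {
    expect_equal(dataset_loglik(ses, tag, cases[[tag]]),
                 oracle_loglik(ses, tag, cases[[tag]]), tolerance = 1e-10)
  }
})

test_that("no-learning expected values ignore the draw history", {
  ses <- simulate_cohort(tiny_design(), 2L, seed = 34, spec = "M4b",
                         params = default_choice_params("M4b"))
  ll1 <- dataset_loglik(ses, "M4b", default_choice_params("M4b"))
  shuffled <- ses
  set.seed(35)
  # permute the draw stream within each stage; M4b must not notice
  d <- shuffled$draws
  for (key in unique(paste(d$subject, d$bin, d$stage))) {
    idx <- which(paste(d$subject, d$bin, d$stage) == key)
    d[idx, c("state", "payoff")] <- d[sample(idx), c("state", "payoff")]
  }
  shuffled$draws <- d
  expect_equal(dataset_loglik(shuffled, "M4b", default_choice_params("M4b")),
               ll1)
})

test_that("the likelihood is invariant to trial order", {
  ses <- simulate_cohort(tiny_design(), 2L, seed = 36, spec = "M4",
                         params = default_choice_params("M4"))
  ll1 <- dataset_loglik(ses, "M4", default_choice_params("M4"))
  perm <- ses
  set.seed(37)
  perm$choices <- perm$choices[sample(nrow(perm$choices)), ]
  expect_equal(dataset_loglik(perm, "M4", default_choice_params("M4")), ll1)
})

test_that("per-trial outputs carry consistent likelihood terms", {
  ses <- simulate_cohort(tiny_design(), 2L, seed = 38, spec = "M4",
                         params = default_choice_params("M4"))
  out <- trial_outputs(ses, "M4", default_choice_params("M4"))
  expect_equal(sum(out$loglik_term),
               dataset_loglik(ses, "M4", default_choice_params("M4")))
  expect_true(all(out$q > 0 & out$q < 1))
})
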