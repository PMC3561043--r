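test_that("initial beliefs are the equiprobable prior for any K", {
  for (K in c(2L, 5L, 10L)) {
    b <- init_beliefs(K)
    expect_equal(point_estimates(b), rep(1 / K, K))
    expect_equal(sum(b$counts), 0L)
  }
  expect_error(init_beliefs(1L), "invalid state count")
  expect_error(init_beliefs(5L, alpha0 = 0), "alpha0")
})

test_that("hidden states are inferred by inverting the stage legend", {
  map <- c(57, 68)
  expect_equal(infer_state(57, map), 1L)
  expect_equal(infer_state(68, map), 2L)
  expect_error(infer_state(999, map), "unknown payoff")
  # legend then inverse recovers every state
  bin <- fixture_bin2()
  for (stage in 1:2) {
    m <- payoff_map(bin, stage)
    expect_equal(vapply(seq_along(m), function(k) infer_state(m[k], m),
                        integer(1)), seq_along(m))
  }
})

test_that("observation bookkeeping increments counts and respects the variant", {
  b <- init_beliefs(2L)
  b <- observe(b, 1L)
  expect_equal(b$counts, c(1L, 0L))
  expect_error(observe(b, 3L), "invalid state")
  # no-learning variant never moves off the prior
  b0 <- init_beliefs(2L, variant = "none")
  for (k in c(1L, 2L, 1L, 1L)) b0 <- observe(b0, k)
  expect_equal(b0$counts, c(0L, 0L))
  # conservation: counts sum to the number of observations
  set.seed(21)
  b <- init_beliefs(5L)
  for (k in sample.int(5L, 12L, replace = TRUE)) b <- observe(b, k)
  expect_equal(sum(b$counts), 12L)
})

test_that("stage boundaries preserve hidden-state counts and reset observation counts", {
  mk <- function(variant) {
    b <- init_beliefs(2L, variant = variant)
    for (k in c(rep(1L, 7), rep(2L, 3))) b <- observe(b, k)
    b
  }
  expect_equal(stage_transition(mk("hidden_state"))$counts, c(7L, 3L))
  expect_equal(stage_transition(mk("observation"))$counts, c(0L, 0L))
  for (v in c("hidden_state", "observation", "none"))
    expect_equal(stage_transition(mk(v), new_bin = TRUE)$counts, c(0L, 0L))
})

test_that("point estimates follow the conjugate posterior mean", {
  b <- init_beliefs(2L)
  b$counts <- c(2L, 1L)
  expect_equal(point_estimates(b), c(0.6, 0.4))
  b$counts <- c(10L, 0L)
  expect_equal(point_estimates(b), c(11 / 12, 1 / 12))
  # invariants on random reachable states: strictly positive, sums to 1
  set.seed(22)
  for (i in 1:50) {
    K <- sample(c(2L, 5L, 10L), 1L)
    b <- init_beliefs(K, alpha0 = stats::runif(1, 0.2, 3))
    for (k in sample.int(K, stats::rpois(1, 8), replace = TRUE))
      b <- observe(b, k)
    p <- point_estimates(b)
    expect_lt(abs(sum(p) - 1), 1e-12)
    expect_true(all(p > 0))
  }
})

test_that("point estimates are invariant to observation order", {
  set.seed(23)
  for (i in 1:20) {
    K <- sample(2:10, 1L)
    seq1 <- sample.int(K, 15L, replace = TRUE)
    run <- function(s) {
      b <- init_beliefs(K)
      for (k in s) b <- observe(b, k)
      point_estimates(b)
    }
    expect_equal(run(seq1), run(sample(seq1)))
  }
})

test_that("point estimates converge to theta with accumulating draws", {
  theta <- default_theta(5L)
  bin <- bin_config(5L, theta, 11:15, 21:25)
  hits <- vapply(1:40, function(s) {
    set.seed(700 + s)
    d <- sample_draws(bin, 1L, 1000L)
    p <- (tabulate(d$state, 5L) + 1) / (1000 + 5)
    max(abs(p - theta)) < 0.05
  }, logical(1))
  expect_gte(mean(hits), 0.95)
})

test_that("hidden-state and observation learners diverge exactly at the resampling boundary", {
  b4 <- init_beliefs(2L, variant = "hidden_state")
  b4a <- init_beliefs(2L, variant = "observation")
  for (k in c(rep(1L, 7), rep(2L, 3))) { b4 <- observe(b4, k); b4a <- observe(b4a, k) }
  b4 <- stage_transition(b4); b4a <- stage_transition(b4a)
  expect_identical(point_estimates(b4), c(8 / 12, 4 / 12))
  expect_identical(point_estimates(b4a), c(0.5, 0.5))
})

test_that("delta-rule forecasting initializes on the first payoff and tracks limits", {
  s <- init_rl(0.5)
  s <- rl_update(s, 57)
  expect_equal(s$V, 57)
  # no-learning limit
  s0 <- init_rl(0)
  for (x in c(57, 68, 46)) s0 <- rl_update(s0, x)
  expect_equal(s0$V, 57)
  # full-update limit equals the last payoff
  s1 <- init_rl(1)
  for (x in c(57, 68, 46)) s1 <- rl_update(s1, x)
  expect_equal(s1$V, 46)
  # forecast stays within the payoff range seen so far
  set.seed(24)
  s <- init_rl(0.3)
  xs <- stats::runif(30, 10, 99)
  for (x in xs) s <- rl_update(s, x)
  expect_gte(s$V, min(xs)); expect_lte(s$V, max(xs))
  expect_true(is.na(rl_reset(s)$V))
  expect_error(init_rl(1.2), "eta")
})

test_that("belief trajectories replay matches the vectorized likelihood beliefs", {
  ses <- simulate_cohort(tiny_design(), 2L, seed = 25, spec = "M4",
                         params = default_choice_params("M4"))
  traj <- belief_trajectories(ses, "hidden_state")
  prep <- problearn:::prepare_model_data(ses, model_spec("M4"))
  ch <- ses$choices[prep$choice_rows, ]
  # end-of-stage estimates in the prep matrix equal the last trajectory row
  for (i in sample(nrow(ch), 10L)) {
    last <- traj[traj$subject == ch$subject[i] & traj$bin == ch$bin[i] &
                   traj$stage == ch$stage[i], ]
    last <- last[which.max(last$t), ]
    K <- session_bin(ses, ch$subject[i], ch$bin[i])$K
    got <- prep$PHAT[i, seq_len(K)]
    want <- if (ch$stage[i] == 2L) {
      # stage 2 carries stage-1 counts forward; trajectory row already does
      as.numeric(last[paste0("p_hat_", seq_len(K))])
    } else as.numeric(last[paste0("p_hat_", seq_len(K))])
    expect_equal(got, want)
  }
})
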