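test_that("make_bin draws distinct payoffs, permutes theta, and validates input", {
  set.seed(11)
  for (K in c(2L, 5L, 10L)) {
    bin <- make_bin(K, payoff_pool = c(10L, 99L))
    expect_s3_class(bin, "bin_config")
    expect_equal(sort(bin$theta), sort(default_theta(K)))
    expect_equal(anyDuplicated(bin$payoff_stage1), 0L)
    expect_equal(anyDuplicated(bin$payoff_stage2), 0L)
    expect_true(all(bin$payoff_stage1 >= 10 & bin$payoff_stage1 <= 99))
    expect_true(all(bin$payoff_stage2 >= 10 & bin$payoff_stage2 <= 99))
    expect_false(identical(bin$payoff_stage1, bin$payoff_stage2))
  }
  expect_error(make_bin(5L, theta = c(0.5, 0.2, 0.1, 0.1, 0.2) * 1.2),
               "invalid distribution")
  expect_error(make_bin(10L, payoff_pool = c(1L, 5L)), "insufficient payoffs")
})

test_that("draws are i.i.d. from theta and payoffs follow the stage legend", {
  # degenerate distribution: all mass on state 1
  bin1 <- bin_config(2L, c(1 - 1e-12, 1e-12), c(57, 68), c(67, 46))
  set.seed(4)
  d <- sample_draws(bin1, 1L, 12L)
  expect_equal(d$state, rep(1L, 12))
  expect_equal(d$payoff, rep(57, 12))
  expect_equal(d$t, 1:12)
  # binomial oracle on the empirical frequency
  bin <- fixture_bin2()
  set.seed(5)
  d <- sample_draws(bin, 2L, 10000L)
  se <- sqrt(0.7 * 0.3 / 10000)
  expect_lt(abs(mean(d$state == 1L) - 0.7), 3 * se)
  expect_true(all(d$payoff == c(67, 46)[d$state]))
})

test_that("draw counts per stage are uniform on 10..14", {
  set.seed(6)
  ses <- simulate_cohort(task_design(), n_subjects = 12L, seed = 60)
  nd <- aggregate(t ~ subject + bin + stage, ses$draws, max)$t
  expect_true(all(nd %in% 10:14))
  tab <- tabulate(nd - 9L, 5L)
  expect_gt(stats::chisq.test(tab, p = rep(0.2, 5))$p.value, 0.001)
})

test_that("prices are continuous uniform between the stage's payoff extremes", {
  bin_flat <- bin_config(2L, c(0.5, 0.5), c(50, 50 + 1e-9), c(10, 90))
  set.seed(7)
  expect_equal(make_prices(bin_flat, 1L, 5L), rep(50, 5), tolerance = 1e-6)
  p <- make_prices(bin_flat, 2L, 20000L)
  expect_true(all(p >= 10 & p <= 90))
  se <- sqrt((90 - 10)^2 / 12 / 20000)
  expect_lt(abs(mean(p) - 50), 3 * se)
})

test_that("a default session has the full trial layout", {
  set.seed(8)
  ses <- simulate_session(task_design(), subject = 1L)
  expect_equal(nrow(ses$choices), 9L * 2L * 6L)
  expect_equal(sum(ses$choices$condition == "active"), 9L * 2L * 4L)
  # 4 active + 2 control in every stage
  per_stage <- aggregate(condition ~ bin + stage, ses$choices,
                         function(x) sum(x == "active"))
  expect_true(all(per_stage$condition == 4L))
  # stage legends always differ; theta persists across stages by construction
  for (b in 1:9) {
    bin <- session_bin(ses, 1L, b)
    expect_false(identical(bin$payoff_stage1, bin$payoff_stage2))
  }
  # three bins per state count
  expect_equal(sort(unique(ses$bin_table$K)), c(2L, 5L, 10L))
  expect_equal(unname(table(ses$bin_table$K[!duplicated(
    paste(ses$bin_table$subject, ses$bin_table$bin))])), rep(3L, 3),
    ignore_attr = TRUE)
})

test_that("a 23-subject cohort matches the study's active-trial count", {
  ses <- simulate_cohort(task_design(), 23L, seed = 9)
  expect_equal(sum(ses$choices$condition == "active"), 1656L)
})

test_that("empirical state frequencies converge to theta across seeds", {
  theta <- default_theta(5L)
  bin <- bin_config(5L, theta, 11:15, 21:25)
  pvals <- vapply(1:100, function(s) {
    set.seed(400 + s)
    d <- sample_draws(bin, 1L, 2000L)
    stats::chisq.test(tabulate(d$state, 5L), p = theta)$p.value
  }, numeric(1))
  expect_gte(mean(pvals > 0.01), 0.95)
})

test_that("simulated choices follow the softmax generator", {
  des <- tiny_design(bins = 3L, ks = c(2L, 5L, 10L))
  ses <- simulate_cohort(des, 10L, seed = 10)
  # flat logistic: buy rate ~ 0.5
  s1 <- simulate_choices(ses, "M2", c(intercept = 0, slope = 0))
  expect_lt(abs(mean(s1$choices$decision) - 0.5), 3 * sqrt(0.25 / nrow(s1$choices)))
  # saturated logistic: always buy
  s2 <- simulate_choices(ses, "M2", c(intercept = 10, slope = 0))
  expect_equal(mean(s2$choices$decision), 1)
  # incomplete parameters are refused
  expect_error(simulate_choices(ses, "M4", c(intercept = 0, slope = 1)),
               "missing parameter")
})

test_that("buy rate under study-default parameters increases with payoff minus price", {
  ses <- simulate_cohort(task_design(), 23L, seed = 12, spec = "M4",
                         params = default_choice_params("M4"))
  ch <- ses$choices[ses$choices$condition == "active", ]
  rate <- mean(ch$decision)
  expect_gt(rate, 0); expect_lt(rate, 1)
  # trials split by the sign of (realized payoff - price): monotone buy rate
  margin <- ch$outcome_payoff - ch$price
  expect_gt(mean(ch$decision[margin > stats::median(margin)]),
            mean(ch$decision[margin <= stats::median(margin)]))
})

test_that("session serialization round-trips exactly", {
  ses <- simulate_cohort(tiny_design(), 3L, seed = 13, spec = "M4",
                         params = default_choice_params("M4"))
  dir <- tempfile()
  write_session(ses, dir)
  back <- read_session(dir, design = ses$design)
  expect_identical(ses$draws, back$draws)
  expect_identical(ses$choices, back$choices)
  expect_identical(ses$bin_table, back$bin_table)
  # second write from the re-read session is byte-identical
  dir2 <- tempfile()
  write_session(back, dir2)
  for (f in c("draws.tsv", "choices.tsv", "bins.tsv"))
    expect_identical(readLines(file.path(dir, f)),
                     readLines(file.path(dir2, f)))
})
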