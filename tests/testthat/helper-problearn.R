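# Shared fixtures and independent oracles, all built in code.

# small fixed two-state bin with known legends
fixture_bin2 <- function() {
  bin_config(2L, c(0.7, 0.3), payoff_stage1 = c(57, 68),
             payoff_stage2 = c(67, 46))
}

# one-subject design with deterministic stage length
tiny_design <- function(bins = 2L, ks = c(2L, 5L), n_draws = 12L) {
  task_design(bins_per_session = bins, state_counts = ks,
              draws_per_stage_range = c(n_draws, n_draws))
}

# Straight-line recomputation of the active-choice log-likelihood, written
# independently of the package's vectorized path: scalar loops, base R only.
oracle_loglik <- function(session, tag, params, alpha0 = 1) {
  ch <- session$choices
  d <- session$draws
  total <- 0
  for (i in which(ch$condition == "active")) {
    subj <- ch$subject[i]; b <- ch$bin[i]; stage <- ch$stage[i]
    bin <- session_bin(session, subj, b)
    K <- bin$K
    map <- if (stage == 1L) bin$payoff_stage1 else bin$payoff_stage2
    pick <- function(st) d$state[d$subject == subj & d$bin == b & d$stage == st]
    if (tag == "M3") {
      xs <- d$payoff[d$subject == subj & d$bin == b & d$stage == stage]
      V <- xs[1]
      for (x in xs[-1]) V <- V + params[["eta"]] * (x - V)
      ev <- V - ch$price[i]
    } else {
      counts <- switch(tag,
        M2 = , M4 = , M5 = if (stage == 1L) tabulate(pick(1L), K) else
          tabulate(pick(1L), K) + tabulate(pick(2L), K),
        M4a = tabulate(pick(stage), K),
        M4b = rep(0, K))
      p <- (counts + alpha0) / (sum(counts) + K * alpha0)
      if (tag == "M5") {
        g <- params[["gamma"]]
        p <- p^g / (p^g + (1 - p)^g)^(1 / g)
      }
      x <- map - ch$price[i]
      v <- if (tag == "M2") x else
        ifelse(x >= 0, abs(x)^params[["alpha"]],
               -params[["lambda"]] * abs(x)^params[["alpha"]])
      ev <- sum(p * v)
    }
    q <- 1 / (1 + exp(-(params[["intercept"]] + params[["slope"]] * ev)))
    q <- min(max(q, 1e-9), 1 - 1e-9)
    total <- total + if (ch$decision[i] == 1L) log(q) else log(1 - q)
  }
  total
}

# Monte-Carlo mean of a Dirichlet(alpha) via normalized gammas
dirichlet_mc_mean <- function(alpha, n = 1e6) {
  K <- length(alpha)
  g <- matrix(stats::rgamma(n * K, shape = rep(alpha, each = n)), n, K)
  colMeans(g / rowSums(g))
}
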