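#' Task design for the bin-sampling gamble experiment
#'
#' Describes one experimental session: a sequence of bins (urns) whose hidden
#' state (ball color) probabilities must be learned from sequential draws.
#' Each bin is played in two stages (sampling, then resampling). Within a
#' stage, 10--14 balls are drawn with replacement and only the payoff written
#' on each ball is displayed; the state behind it is identifiable through the
#' stage's state-to-payoff legend. Each stage ends with six priced buy/pass
#' choices, four of which are made without knowing the outcome in advance
#' (active) and two with the outcome known (control).
#'
#' Two payoff pools of different widths are cycled across bins so that the
#' spread (standard deviation) of payoffs varies independently of the number
#' of states.
#'
#' @param bins_per_session Number of bins played per subject (default 9).
#' @param state_counts Integer vector of length `bins_per_session` giving the
#'   number of states K for each bin; the default uses three bins each of
#'   K = 2, 5 and 10, shuffled per subject at simulation time.
#' @param draws_per_stage_range Length-2 integer vector; the number of draws
#'   per stage is uniform on this range (default `c(10, 14)`).
#' @param choices_per_stage Priced choices per stage (default 6).
#' @param active_choices How many of those are active, i.e. decided without
#'   knowing the outcome (default 4).
#' @param payoff_pools List of length-2 integer ranges; distinct integer
#'   payoffs are sampled from these pools, cycled across bins (a wide and a
#'   narrow pool by default, manipulating payoff spread).
#' @return An object of class `task_design`.
#' @export
task_design <- function(bins_per_session = 9L,
                        state_counts = rep(c(2L, 5L, 10L), length.out = 9L),
                        draws_per_stage_range = c(10L, 14L),
                        choices_per_stage = 6L,
                        active_choices = 4L,
                        payoff_pools = list(c(10L, 99L), c(40L, 69L))) {
  bins_per_session <- as.integer(bins_per_session)
  state_counts <- as.integer(state_counts)
  draws_per_stage_range <- as.integer(draws_per_stage_range)
  if (bins_per_session < 1L)
    stop("bins_per_session must be >= 1")
  if (length(state_counts) != bins_per_session)
    stop("state_counts must have one entry per bin")
  if (any(state_counts < 2L))
    stop("every bin needs at least 2 states")
  if (length(draws_per_stage_range) != 2L ||
      draws_per_stage_range[1] > draws_per_stage_range[2] ||
      draws_per_stage_range[1] < 1L || draws_per_stage_range[2] > 100L)
    stop("draws_per_stage_range must be an increasing interval within [1, 100]")
  choices_per_stage <- as.integer(choices_per_stage)
  active_choices <- as.integer(active_choices)
  if (active_choices > choices_per_stage)
    stop("active_choices cannot exceed choices_per_stage")
  if (!is.list(payoff_pools)) payoff_pools <- list(payoff_pools)
  for (pool in payoff_pools) {
    if (length(pool) != 2L || pool[1] > pool[2])
      stop("each payoff pool must be an increasing integer range")
    if (pool[2] - pool[1] + 1L < max(state_counts))
      stop("payoff pool too small for the largest state count")
  }
  structure(
    list(bins_per_session = bins_per_session,
         state_counts = state_counts,
         draws_per_stage_range = draws_per_stage_range,
         choices_per_stage = choices_per_stage,
         active_choices = active_choices,
         payoff_pools = lapply(payoff_pools, as.integer)),
    class = "task_design")
}

#' Default true state probabilities for a bin with K states
#'
#' Skewed distributions spanning low and high probabilities: K = 2 uses
#' (0.7, 0.3), K = 5 a fixed decreasing vector, and any other K a normalized
#' geometric decay with ratio 0.75.
#'
#' @param K Number of states (>= 2).
#' @return Probability vector of length `K` summing to 1.
#' @export
default_theta <- function(K) {
  K <- as.integer(K)
  if (K < 2L) stop("K must be >= 2")
  if (K == 2L) return(c(0.7, 0.3))
  if (K == 5L) return(c(0.40, 0.25, 0.15, 0.12, 0.08))
  w <- 0.75^(0:(K - 1L))
  w / sum(w)
}

#' Construct a bin configuration directly
#'
#' Low-level constructor used by [make_bin()] and by tests that need full
#' control over the true probabilities and payoff legends.
#'
#' @param K Number of states.
#' @param theta True state probabilities (length `K`, sums to 1).
#' @param payoff_stage1,payoff_stage2 Numeric vectors of length `K`; the
#'   state-to-payoff bijections of the two stages (payoffs distinct within a
#'   stage).
#' @return An object of class `bin_config`.
#' @export
bin_config <- function(K, theta, payoff_stage1, payoff_stage2) {
  K <- as.integer(K)
  if (length(theta) != K || length(payoff_stage1) != K ||
      length(payoff_stage2) != K)
    stop("theta and payoff maps must have length K")
  if (abs(sum(theta) - 1) > 1e-9)
    stop("invalid distribution: theta must sum to 1")
  if (any(theta <= 0) || any(theta >= 1))
    stop("invalid distribution: theta entries must lie in (0, 1)")
  if (anyDuplicated(payoff_stage1) || anyDuplicated(payoff_stage2))
    stop("payoffs must be distinct within a stage")
  structure(list(K = K, theta = as.numeric(theta),
                 payoff_stage1 = as.numeric(payoff_stage1),
                 payoff_stage2 = as.numeric(payoff_stage2)),
            class = "bin_config")
}

#' Randomly generate a bin
#'
#' Assigns probabilities to states uniformly at random (a random permutation
#' of `theta`) and draws two independent state-to-payoff bijections, one per
#' stage, each using `K` distinct integer payoffs from `payoff_pool`. The two
#' stages' legends always differ, so the state probabilities persist across
#' the resampling boundary while the payoffs do not. Because probabilities
#' and payoffs are assigned independently, payoff probability is orthogonal
#' to payoff magnitude by construction.
#'
#' @param K Number of states (any K >= 2; the task uses 2, 5 or 10).
#' @param theta Optional probability vector of length `K`; defaults to
#'   [default_theta()].
#' @param payoff_pool Length-2 integer range from which payoffs are sampled.
#' @return A [bin_config()].
#' @export
make_bin <- function(K, theta = NULL, payoff_pool = c(10L, 99L)) {
  K <- as.integer(K)
  if (K < 2L) stop("K must be >= 2")
  if (is.null(theta)) theta <- default_theta(K)
  if (length(theta) != K) stop("theta must have length K")
  if (abs(sum(theta) - 1) > 1e-9)
    stop("invalid distribution: theta must sum to 1")
  pool <- payoff_pool[1]:payoff_pool[2]
  if (length(pool) < K)
    stop("insufficient payoffs: pool smaller than K")
  theta <- theta[sample.int(K)]
  p1 <- sample(pool, K)
  repeat {
    p2 <- sample(pool, K)
    if (!identical(p1, p2)) break
  }
  bin_config(K, theta, p1, p2)
}

#' Payoff legend of a stage
#' @param bin A [bin_config()].
#' @param stage 1 or 2.
#' @return Numeric vector mapping state index to payoff.
#' @export
payoff_map <- function(bin, stage) {
  stage <- as.integer(stage)
  if (!stage %in% c(1L, 2L)) stop("stage must be 1 or 2")
  if (stage == 1L) bin$payoff_stage1 else bin$payoff_stage2
}

#' Draw balls with replacement from a bin
#'
#' States are i.i.d. from the bin's true probabilities; the displayed payoff
#' is the stage legend applied to the state.
#'
#' @param bin A [bin_config()].
#' @param stage 1 or 2.
#' @param n_draws Number of draws.
#' @return Data frame with columns `stage`, `t` (1-based draw index),
#'   `state`, `payoff`.
#' @export
sample_draws <- function(bin, stage, n_draws) {
  map <- payoff_map(bin, stage)
  states <- sample.int(bin$K, n_draws, replace = TRUE, prob = bin$theta)
  data.frame(stage = as.integer(stage), t = seq_len(n_draws),
             state = states, payoff = map[states])
}

#' Draw gamble prices for a stage
#'
#' Prices are continuous uniform between the minimum and maximum payoff of
#' the stage's legend.
#'
#' @param bin A [bin_config()].
#' @param stage 1 or 2.
#' @param n Number of prices.
#' @return Numeric vector of length `n`.
#' @export
make_prices <- function(bin, stage, n) {
  map <- payoff_map(bin, stage)
  stats::runif(n, min(map), max(map))
}

#' Simulate one subject's session (no decisions yet)
#'
#' Generates the bins (state counts shuffled, payoff pools cycled), the draw
#' streams of both stages, and the priced choice trials. Each stage has
#' `choices_per_stage` trials in randomized active/control order; every trial
#' is resolved by one extra draw from the bin whose payoff becomes the
#' trial's outcome. Decisions are left `NA` and can be filled in by
#' [simulate_choices()] or supplied from real data.
#'
#' Uses the current RNG state; seed management belongs to the caller (see
#' [simulate_cohort()]).
#'
#' @param design A [task_design()].
#' @param subject Subject identifier recorded in the tables.
#' @return An object of class `gamble_session`: a list with elements
#'   `design`, `bins` (one `bin_config` per subject/bin, plus a long-format
#'   `bin_table`), `draws` and `choices` data frames.
#' @export
simulate_session <- function(design = task_design(), subject = 1L) {
  subject <- as.integer(subject)
  ks <- if (length(design$state_counts) > 1L)
    sample(design$state_counts) else design$state_counts
  n_pools <- length(design$payoff_pools)
  draws_list <- list()
  choice_list <- list()
  bins <- list()
  for (b in seq_len(design$bins_per_session)) {
    pool <- design$payoff_pools[[(b - 1L) %% n_pools + 1L]]
    bin <- make_bin(ks[b], payoff_pool = pool)
    bins[[b]] <- bin
    for (stage in 1:2) {
      nds <- design$draws_per_stage_range[1]:design$draws_per_stage_range[2]
      nd <- nds[sample.int(length(nds), 1L)]
      d <- sample_draws(bin, stage, nd)
      d$subject <- subject; d$bin <- b
      draws_list[[length(draws_list) + 1L]] <- d
      nc <- design$choices_per_stage
      cond <- rep("active", nc)
      cond[sample.int(nc, nc - design$active_choices)] <- "control"
      prices <- make_prices(bin, stage, nc)
      outcome <- sample_draws(bin, stage, nc)
      choice_list[[length(choice_list) + 1L]] <- data.frame(
        subject = subject, bin = b, stage = as.integer(stage),
        choice_idx = seq_len(nc), price = prices, condition = cond,
        decision = NA_integer_, outcome_payoff = outcome$payoff)
    }
  }
  draws <- do.call(rbind, draws_list)
  draws <- draws[, c("subject", "bin", "stage", "t", "state", "payoff")]
  choices <- do.call(rbind, choice_list)
  rownames(draws) <- rownames(choices) <- NULL
  new_session(design, stats::setNames(list(bins), as.character(subject)),
              draws, choices)
}

new_session <- function(design, bins, draws, choices) {
  bt <- bin_table(bins)
  structure(list(design = design, bins = bins, bin_table = bt,
                 draws = draws, choices = choices),
            class = "gamble_session")
}

bin_table <- function(bins) {
  rows <- list()
  for (subj in names(bins)) {
    for (b in seq_along(bins[[subj]])) {
      bin <- bins[[subj]][[b]]
      rows[[length(rows) + 1L]] <- data.frame(
        subject = as.integer(subj), bin = b, K = bin$K,
        state = seq_len(bin$K), theta = bin$theta,
        payoff_stage1 = bin$payoff_stage1,
        payoff_stage2 = bin$payoff_stage2)
    }
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Look up one bin of a session
#' @param session A `gamble_session`.
#' @param subject,bin Identifiers.
#' @return The [bin_config()].
#' @export
session_bin <- function(session, subject, bin) {
  session$bins[[as.character(subject)]][[bin]]
}

#' @export
print.gamble_session <- function(x, ...) {
  cat("<gamble_session> ", length(x$bins), " subject(s), ",
      nrow(x$draws), " draws, ", nrow(x$choices), " choice trials (",
      sum(x$choices$condition == "active"), " active)\n", sep = "")
  invisible(x)
}

#' Simulate a cohort of subjects
#'
#' Runs [simulate_session()] once per subject, each on a deterministic
#' per-subject RNG substream derived from `seed`, and optionally fills in
#' decisions by simulating choices from a model.
#'
#' @param design A [task_design()].
#' @param n_subjects Number of subjects (default 23).
#' @param seed Integer seed; per-subject seeds are derived from it.
#' @param spec Optional model tag or [model_spec()] used to generate
#'   decisions.
#' @param params Named parameter vector for `spec` (see
#'   [default_choice_params()]).
#' @param alpha0 Prior concentration for the generating model's beliefs.
#' @return A `gamble_session` pooling all subjects.
#' @export
simulate_cohort <- function(design = task_design(), n_subjects = 23L,
                            seed = NULL, spec = NULL, params = NULL,
                            alpha0 = 1) {
  sessions <- vector("list", n_subjects)
  for (s in seq_len(n_subjects)) {
    if (!is.null(seed)) set.seed(subject_seed(seed, s))
    sessions[[s]] <- simulate_session(design, subject = s)
  }
  bins <- do.call(c, lapply(sessions, function(x) x$bins))
  draws <- do.call(rbind, lapply(sessions, function(x) x$draws))
  choices <- do.call(rbind, lapply(sessions, function(x) x$choices))
  rownames(draws) <- rownames(choices) <- NULL
  session <- new_session(design, bins, draws, choices)
  if (!is.null(spec)) {
    if (!is.null(seed)) set.seed(subject_seed(seed, n_subjects + 1L))
    session <- simulate_choices(session, spec, params, alpha0 = alpha0)
  }
  session
}

subject_seed <- function(seed, subject) {
  (as.integer(seed) + 7919L * (as.integer(subject) - 1L)) %% 2147483647L
}

#' Simulate buy/pass decisions from a choice model
#'
#' For active trials the gamble's expected value is computed from the model's
#' end-of-stage beliefs and valuation; for control trials (outcome known in
#' advance) it is the subjective value of the known net payoff. Decisions are
#' Bernoulli draws from the softmax buy probability.
#'
#' @param session A `gamble_session` (decisions may be `NA`).
#' @param spec Model tag (`"M2"`, `"M3"`, `"M4"`, `"M4a"`, `"M4b"`, `"M5"`)
#'   or a [model_spec()].
#' @param params Named parameter vector; must be complete for the model.
#' @param alpha0 Prior concentration for belief updating (default 1).
#' @return The session with the `decision` column filled in (1 = buy,
#'   0 = pass).
#' @export
simulate_choices <- function(session, spec, params, alpha0 = 1) {
  spec <- as_model_spec(spec)
  check_params(spec, params)
  ch <- session$choices
  ev <- rep(NA_real_, nrow(ch))
  active <- ch$condition == "active"
  prep <- prepare_model_data(session, spec, alpha0 = alpha0)
  ev[prep$choice_rows] <- ev_from_prep(prep, params)
  vp <- value_params_of(spec, params)
  ev[!active] <- value_fn(ch$outcome_payoff[!active] - ch$price[!active],
                          alpha = vp["alpha"], lambda = vp["lambda"])
  q <- buy_probability(ev, params["intercept"], params["slope"])
  session$choices$decision <- stats::rbinom(nrow(ch), 1L, q)
  session
}

#' Published group-level parameter estimates used as generator defaults
#'
#' Plausible generating values for each model of the family, taken from a
#' pooled fit of this task class (intercept and slope in logit units,
#' loss aversion `lambda`, diminishing sensitivity `alpha`, probability
#' weighting `gamma`, learning rate `eta`).
#'
#' @param tag Model tag.
#' @return Named numeric vector of generating parameters.
#' @export
default_choice_params <- function(tag = "M4") {
  switch(tag,
    M2  = c(intercept = -0.49, slope = 0.38),
    M3  = c(intercept = -0.39, slope = 0.31, eta = 0.17),
    M4  = c(intercept = 0.95, slope = 0.54, lambda = 2.57, alpha = 0.69),
    M4a = c(intercept = 1.00, slope = 0.53, lambda = 2.66, alpha = 0.68),
    M4b = c(intercept = 0.51, slope = 1.31, lambda = 1.69, alpha = 0.44),
    M5  = c(intercept = 1.00, slope = 0.59, lambda = 2.55, alpha = 0.63,
            gamma = 0.89),
    stop("unknown model tag: ", tag))
}
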