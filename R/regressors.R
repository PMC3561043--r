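#' Outcome entropy of a probability distribution
#'
#' Shannon entropy in nats, `-sum(p * log(p))` with the `0 * log(0) = 0`
#' convention; 0 for a degenerate distribution, `log(K)` for the uniform.
#' Measures the expected uncertainty about the next draw.
#'
#' @param p Probability vector (non-negative, sums to 1).
#' @return Entropy in nats.
#' @export
outcome_entropy <- function(p) {
  if (any(p < 0) || abs(sum(p) - 1) > 1e-9)
    stop("invalid distribution: entries must be >= 0 and sum to 1")
  nz <- p > 0
  -sum(p[nz] * log(p[nz]))
}

#' Choice entropy of a buy probability
#'
#' Binary entropy of (q, 1 - q) in nats: maximal (`log 2`) when buying and
#' passing are equally likely (hardest choice), 0 when the choice is
#' certain.
#'
#' @param q Buy probability/ies in \[0, 1\].
#' @return Entropy value(s) in nats.
#' @export
choice_entropy <- function(q) {
  if (any(q < 0 | q > 1)) stop("q must lie in [0, 1]")
  h <- numeric(length(q))
  ok <- q > 0 & q < 1
  h[ok] <- -(q[ok] * log(q[ok]) + (1 - q[ok]) * log(1 - q[ok]))
  h
}

#' Value prediction error of one draw
#'
#' The change in the gamble's subjective expected value caused by
#' incorporating one new draw: `EV(after) - EV(before)`, with EV computed on
#' the raw payoffs (no price exists during sampling). The sign labels the
#' draw as good or bad news about the gamble.
#'
#' @param beliefs_before,beliefs_after `belief_state`s differing by exactly
#'   one observation.
#' @param payoff_map Stage legend (state-to-payoff vector).
#' @param alpha,lambda,gamma Valuation parameters (defaults: linear value,
#'   identity weights).
#' @return Signed scalar value change.
#' @export
prediction_error <- function(beliefs_before, beliefs_after, payoff_map,
                             alpha = 1, lambda = 1, gamma = 1) {
  if (beliefs_before$K != beliefs_after$K ||
      beliefs_before$variant != beliefs_after$variant)
    stop("inconsistent states: belief structures differ")
  diff <- beliefs_after$counts - beliefs_before$counts
  if (beliefs_before$variant != "none" &&
      !(sum(diff) == 1L && all(diff %in% c(0L, 1L))))
    stop("inconsistent states: beliefs must differ by exactly one observation")
  ev <- function(b) sum(weight_fn(point_estimates(b), gamma) *
                          value_fn(payoff_map, alpha, lambda))
  ev(beliefs_after) - ev(beliefs_before)
}

#' Build a per-subject event table with parametric modulators
#'
#' Lays the session out on a synthetic timeline and attaches the trial-wise
#' covariates a neuroimaging analysis would regress on: every draw becomes a
#' 1-second stimulus event carrying the pre-update probability of the
#' observed stimulus and its value prediction error; every priced choice
#' becomes a decision event carrying the gamble's expected value, the
#' outcome entropy of the end-of-stage beliefs and the choice entropy of the
#' model's buy probability; each stage ends with one feedback event carrying
#' the stage's total net payoff. All modulators are mean-centered within
#' subject.
#'
#' For control trials (outcome known in advance) the expected value is the
#' subjective value of the known net payoff and the outcome entropy is 0.
#'
#' @param session A `gamble_session` with decisions.
#' @param fit A `fit_result` from a probability-based model (its learning
#'   rule and valuation parameters define the modulators).
#' @param stim_on,stim_off Stimulus presentation / gap duration in seconds.
#' @param decision_dur,feedback_dur,iti Decision and feedback durations and
#'   inter-trial interval in seconds.
#' @return Data frame of class `event_table`: `subject`, `bin`, `stage`,
#'   `trial_type` (stimulus/decision/feedback), `onset`, `duration`, and
#'   modulator columns (`NA` where a modulator does not apply).
#' @export
build_event_table <- function(session, fit, stim_on = 1, stim_off = 1,
                              decision_dur = 2, feedback_dur = 2, iti = 1) {
  spec <- fit$spec
  if (spec$inference == "reinforcement")
    stop("event tables require a probability-based model")
  params <- fit$estimates
  vp <- value_params_of(spec, params)
  gam <- if (spec$weight_form == "curved") params[["gamma"]] else 1
  alpha0 <- if (is.null(fit$alpha0)) 1 else fit$alpha0
  ch <- session$choices
  d <- session$draws
  d <- d[order(d$subject, d$bin, d$stage, d$t), ]
  rows <- list()
  for (subj in sort(unique(ch$subject))) {
    clock <- 0
    for (b in sort(unique(ch$bin[ch$subject == subj]))) {
      bin <- session_bin(session, subj, b)
      beliefs <- init_beliefs(bin$K, alpha0, spec$inference)
      for (stage in 1:2) {
        if (stage == 2L) beliefs <- stage_transition(beliefs)
        map <- payoff_map(bin, stage)
        ds <- d[d$subject == subj & d$bin == b & d$stage == stage, ]
        for (j in seq_len(nrow(ds))) {
          k <- ds$state[j]
          stim_p <- predictive_probability(beliefs, k)
          after <- observe(beliefs, k)
          pe <- prediction_error(beliefs, after, map, alpha = vp["alpha"],
                                 lambda = vp["lambda"], gamma = gam)
          rows[[length(rows) + 1L]] <- data.frame(
            subject = subj, bin = b, stage = stage, trial_type = "stimulus",
            onset = clock, duration = stim_on, stim_probability = stim_p,
            prediction_error = pe, ev = NA_real_,
            outcome_entropy = NA_real_, choice_entropy = NA_real_,
            net_payoff = NA_real_)
          clock <- clock + stim_on + stim_off
          beliefs <- after
        }
        phat <- point_estimates(beliefs)
        h_out <- outcome_entropy(phat)
        cs <- ch[ch$subject == subj & ch$bin == b & ch$stage == stage, ]
        cs <- cs[order(cs$choice_idx), ]
        net <- 0
        for (j in seq_len(nrow(cs))) {
          if (cs$condition[j] == "active") {
            ev <- gamble_ev(phat, map, cs$price[j], alpha = vp["alpha"],
                            lambda = vp["lambda"], gamma = gam)
            h <- h_out
          } else {
            ev <- value_fn(cs$outcome_payoff[j] - cs$price[j],
                           alpha = vp["alpha"], lambda = vp["lambda"])
            h <- 0
          }
          q <- buy_probability(ev, params[["intercept"]], params[["slope"]])
          rows[[length(rows) + 1L]] <- data.frame(
            subject = subj, bin = b, stage = stage, trial_type = "decision",
            onset = clock, duration = decision_dur,
            stim_probability = NA_real_, prediction_error = NA_real_,
            ev = ev, outcome_entropy = h, choice_entropy = choice_entropy(q),
            net_payoff = NA_real_)
          clock <- clock + decision_dur + iti
          if (!is.na(cs$decision[j]) && cs$decision[j] == 1L)
            net <- net + cs$outcome_payoff[j] - cs$price[j]
        }
        rows[[length(rows) + 1L]] <- data.frame(
          subject = subj, bin = b, stage = stage, trial_type = "feedback",
          onset = clock, duration = feedback_dur,
          stim_probability = NA_real_, prediction_error = NA_real_,
          ev = NA_real_, outcome_entropy = NA_real_,
          choice_entropy = NA_real_, net_payoff = net)
        clock <- clock + feedback_dur + iti
      }
    }
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  mods <- c("stim_probability", "prediction_error", "ev", "outcome_entropy",
            "choice_entropy", "net_payoff")
  for (subj in unique(out$subject)) {
    idx <- out$subject == subj
    for (m in mods) {
      v <- out[[m]][idx]
      out[[m]][idx] <- v - mean(v, na.rm = TRUE)
    }
  }
  class(out) <- c("event_table", "data.frame")
  out
}
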