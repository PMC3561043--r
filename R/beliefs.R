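#' Initialize a belief state
#'
#' Beliefs over the K states of a bin are a symmetric Dirichlet with
#' concentration `alpha0` per state plus integer observation counts; the
#' posterior over state probabilities after `t` draws is
#' Dirichlet(counts + alpha0). At a fresh bin all counts are zero, so every
#' point estimate equals the equiprobable prior 1/K.
#'
#' Three variants differ only in their bookkeeping across stages:
#' `"hidden_state"` keeps counts across the resampling boundary (states are
#' identified through the stage legend, so stage-1 evidence remains valid);
#' `"observation"` resets counts at every stage start (learning over payoffs
#' directly, which become worthless when the legend changes); `"none"` never
#' updates, leaving probabilities at the prior.
#'
#' @param K Number of states (>= 2).
#' @param alpha0 Prior concentration per state (> 0, default 1, the uniform
#'   Dirichlet).
#' @param variant One of `"hidden_state"`, `"observation"`, `"none"`.
#' @return An object of class `belief_state`.
#' @export
init_beliefs <- function(K, alpha0 = 1,
                         variant = c("hidden_state", "observation", "none")) {
  K <- as.integer(K)
  if (K < 2L) stop("invalid state count: K must be >= 2")
  if (alpha0 <= 0) stop("alpha0 must be > 0")
  variant <- match.arg(variant)
  structure(list(K = K, counts = integer(K), alpha0 = alpha0,
                 variant = variant),
            class = "belief_state")
}

#' @export
print.belief_state <- function(x, ...) {
  cat("<belief_state ", x$variant, "> counts:", x$counts,
      " alpha0:", x$alpha0, "\n")
  invisible(x)
}

#' Infer the hidden state behind a displayed payoff
#'
#' Only the payoff is shown during sampling; the generating state is
#' recovered through the inverse of the stage's state-to-payoff legend.
#'
#' @param payoff Observed payoff.
#' @param payoff_map Numeric vector mapping state index to payoff (a
#'   bijection within the stage).
#' @return Integer state index.
#' @export
infer_state <- function(payoff, payoff_map) {
  k <- match(payoff, payoff_map)
  if (is.na(k)) stop("unknown payoff: ", payoff, " not in the stage legend")
  k
}

#' Record one observed state
#'
#' Increments the state's count. For the `"none"` variant the beliefs are
#' returned unchanged: probabilities are never updated and remain at the
#' prior.
#'
#' @param beliefs A `belief_state`.
#' @param state Integer state index in `1:K`.
#' @return Updated `belief_state`.
#' @export
observe <- function(beliefs, state) {
  if (state < 1L || state > beliefs$K) stop("invalid state index")
  if (beliefs$variant == "none") return(beliefs)
  beliefs$counts[state] <- beliefs$counts[state] + 1L
  beliefs
}

#' Apply a stage or bin boundary to beliefs
#'
#' At a resampling boundary, hidden-state beliefs keep their counts while
#' observation beliefs are reset to the prior. A new bin resets every
#' variant.
#'
#' @param beliefs A `belief_state`.
#' @param new_bin Logical; `TRUE` at a new-bin boundary.
#' @return Updated `belief_state`.
#' @export
stage_transition <- function(beliefs, new_bin = FALSE) {
  if (new_bin || beliefs$variant == "observation")
    beliefs$counts <- integer(beliefs$K)
  beliefs
}

#' Posterior-mean point estimates of the state probabilities
#'
#' The conjugate posterior mean `(n_k + alpha0) / (t + K * alpha0)` with
#' `t = sum(n_k)`; always a strictly positive vector summing to 1, equal to
#' the uniform prior before any observation.
#'
#' @param beliefs A `belief_state`.
#' @return Probability vector of length K.
#' @export
point_estimates <- function(beliefs) {
  (beliefs$counts + beliefs$alpha0) /
    (sum(beliefs$counts) + beliefs$K * beliefs$alpha0)
}

#' Predictive probability of a stimulus
#'
#' The point estimate of the drawn state computed from the beliefs held
#' *before* the draw is incorporated (the probability of seeing the
#' evidence). Callers therefore pass the pre-update belief state.
#'
#' @param beliefs A `belief_state` (pre-update).
#' @param state Integer state index.
#' @return Scalar probability.
#' @export
predictive_probability <- function(beliefs, state) {
  if (state < 1L || state > beliefs$K) stop("invalid state index")
  point_estimates(beliefs)[state]
}

#' Initialize a delta-rule payoff forecaster
#'
#' The reinforcement baseline tracks the expected payoff directly, without
#' probabilities: the first payoff of a stage defines the initial forecast
#' and each later payoff moves the forecast by `eta` times the prediction
#' error. The forecast is re-initialized at the start of each sampling and
#' resampling stage because payoffs change with the legend.
#'
#' @param eta Learning rate in \[0, 1\].
#' @return An object of class `rl_state` with fields `V` (forecast, `NA`
#'   until the first payoff) and `eta`.
#' @export
init_rl <- function(eta) {
  if (eta < 0 || eta > 1) stop("eta must lie in [0, 1]")
  structure(list(V = NA_real_, eta = eta), class = "rl_state")
}

#' Delta-rule forecast update
#'
#' @param state An `rl_state`.
#' @param payoff Observed payoff.
#' @return Updated `rl_state`.
#' @export
rl_update <- function(state, payoff) {
  if (is.na(state$V)) state$V <- payoff
  else state$V <- state$V + state$eta * (payoff - state$V)
  state
}

#' Reset the forecast at a stage boundary
#' @param state An `rl_state`.
#' @return `rl_state` with the forecast unset.
#' @export
rl_reset <- function(state) {
  state$V <- NA_real_
  state
}

#' Belief trajectories of a session
#'
#' Replays every bin's draw stream through the chosen belief variant and
#' returns one row per draw with the full point-estimate vector held *after*
#' the draw and the pre-update predictive probability of the drawn state.
#'
#' @param session A `gamble_session`.
#' @param variant Belief variant (see [init_beliefs()]).
#' @param alpha0 Prior concentration.
#' @return Data frame with columns `subject`, `bin`, `stage`, `t`,
#'   `state_observed`, `p_hat_1` .. `p_hat_K` (NA beyond the bin's K) and
#'   `predictive_prob`.
#' @export
belief_trajectories <- function(session, variant = "hidden_state",
                                alpha0 = 1) {
  d <- session$draws
  kmax <- max(session$bin_table$K)
  ord <- order(d$subject, d$bin, d$stage, d$t)
  d <- d[ord, ]
  keys <- unique(d[, c("subject", "bin")])
  rows <- list()
  for (i in seq_len(nrow(keys))) {
    subj <- keys$subject[i]; b <- keys$bin[i]
    bin <- session_bin(session, subj, b)
    beliefs <- init_beliefs(bin$K, alpha0, variant)
    dd <- d[d$subject == subj & d$bin == b, ]
    for (stage in 1:2) {
      if (stage == 2L) beliefs <- stage_transition(beliefs)
      ds <- dd[dd$stage == stage, ]
      for (j in seq_len(nrow(ds))) {
        k <- ds$state[j]
        pp <- predictive_probability(beliefs, k)
        beliefs <- observe(beliefs, k)
        ph <- rep(NA_real_, kmax)
        ph[seq_len(bin$K)] <- point_estimates(beliefs)
        rows[[length(rows) + 1L]] <- c(
          subject = subj, bin = b, stage = stage, t = ds$t[j],
          state_observed = k, stats::setNames(ph, paste0("p_hat_", seq_len(kmax))),
          predictive_prob = pp)
      }
    }
  }
  out <- as.data.frame(do.call(rbind, rows))
  out
}
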