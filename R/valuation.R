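#' Model specifications of the choice-model family
#'
#' Six models, indexed by their number of free parameters, factorially
#' combine a value function (linear or prospect-theory), a probability
#' transform (identity or one-parameter weighting) and a learning rule
#' (hidden-state counts, per-stage observation counts, no learning, or
#' delta-rule payoff forecasting):
#'
#' * `M2` — linear value, hidden-state learning; parameters intercept, slope.
#' * `M3` — delta-rule reinforcement forecaster, linear value; + `eta`.
#' * `M4` — prospect value, hidden-state learning; + `lambda`, `alpha`.
#' * `M4a` — as M4 with per-stage observation learning.
#' * `M4b` — as M4 with no learning (probabilities stay at the prior).
#' * `M5` — as M4 plus probability weighting; + `gamma`.
#'
#' @param tag One of `"M2"`, `"M3"`, `"M4"`, `"M4a"`, `"M4b"`, `"M5"`.
#' @return An object of class `model_spec` with fields `tag`, `value_form`,
#'   `weight_form`, `inference`, `n_params`, `param_names`.
#' @export
model_spec <- function(tag) {
  info <- switch(tag,
    M2  = list(value_form = "linear", weight_form = "identity",
               inference = "hidden_state",
               param_names = c("intercept", "slope")),
    M3  = list(value_form = "linear", weight_form = "identity",
               inference = "reinforcement",
               param_names = c("intercept", "slope", "eta")),
    M4  = list(value_form = "prospect", weight_form = "identity",
               inference = "hidden_state",
               param_names = c("intercept", "slope", "lambda", "alpha")),
    M4a = list(value_form = "prospect", weight_form = "identity",
               inference = "observation",
               param_names = c("intercept", "slope", "lambda", "alpha")),
    M4b = list(value_form = "prospect", weight_form = "identity",
               inference = "none",
               param_names = c("intercept", "slope", "lambda", "alpha")),
    M5  = list(value_form = "prospect", weight_form = "curved",
               inference = "hidden_state",
               param_names = c("intercept", "slope", "lambda", "alpha",
                               "gamma")),
    stop("unknown model tag: ", tag))
  structure(c(list(tag = tag), info,
              list(n_params = length(info$param_names))),
            class = "model_spec")
}

as_model_spec <- function(spec) {
  if (inherits(spec, "model_spec")) spec else model_spec(spec)
}

#' @export
print.model_spec <- function(x, ...) {
  cat("<model_spec ", x$tag, "> value: ", x$value_form, ", weights: ",
      x$weight_form, ", inference: ", x$inference, ", params: ",
      paste(x$param_names, collapse = ", "), "\n", sep = "")
  invisible(x)
}

check_params <- function(spec, params) {
  missing <- setdiff(spec$param_names, names(params))
  if (length(missing))
    stop("missing parameter(s) for ", spec$tag, ": ",
         paste(missing, collapse = ", "))
  invisible(TRUE)
}

value_params_of <- function(spec, params) {
  if (spec$value_form == "linear") c(alpha = 1, lambda = 1)
  else c(alpha = unname(params["alpha"]), lambda = unname(params["lambda"]))
}

#' Prospect-theory value function
#'
#' Piecewise power value with a shared diminishing-sensitivity exponent for
#' gains and losses and a loss-aversion multiplier:
#' `v(x) = x^alpha` for `x >= 0` and `v(x) = -lambda * (-x)^alpha` for
#' `x < 0`. Continuous and strictly increasing, with its only kink at 0.
#' `alpha = lambda = 1` gives the identity (the linear value used by M2 and
#' M3).
#'
#' @param x Net payoff(s).
#' @param alpha Diminishing-sensitivity exponent (> 0).
#' @param lambda Loss-aversion multiplier (> 0).
#' @return Subjective value(s), same shape as `x`.
#' @export
value_fn <- function(x, alpha = 1, lambda = 1) {
  v <- abs(x)^alpha
  neg <- x < 0
  v[neg] <- -lambda * v[neg]
  v
}

#' One-parameter probability weighting function
#'
#' `w(p) = p^gamma / (p^gamma + (1 - p)^gamma)^(1/gamma)`, the inverse-S
#' weighting of prospect theory; `gamma` controls the S shape and
#' `gamma = 1` is the identity. Endpoints are preserved exactly
#' (`w(0) = 0`, `w(1) = 1`). Kept monotone by restricting `gamma` to about
#' \[0.3, 2\] during fitting.
#'
#' @param p Probability/ies in \[0, 1\].
#' @param gamma Curvature parameter (> 0).
#' @return Decision weight(s).
#' @export
weight_fn <- function(p, gamma = 1) {
  if (any(p < 0 | p > 1, na.rm = TRUE))
    stop("invalid probability: p must lie in [0, 1]")
  pg <- p^gamma
  pg / (pg + (1 - p)^gamma)^(1 / gamma)
}

#' Expected value of a priced gamble
#'
#' Subjective values of the state payoffs net of the price, weighted by the
#' (optionally transformed) state probability estimates and summed:
#' `EV = sum_k w(p_k) * v(x_k - P)`. With `alpha = lambda = gamma = 1` this
#' is the ordinary expected net payoff.
#'
#' @param p_hat Probability vector over states (sums to 1).
#' @param payoffs Payoff per state (same length).
#' @param price Posted gamble price.
#' @param alpha,lambda Value-function parameters.
#' @param gamma Probability-weighting parameter (1 = identity).
#' @return Scalar expected value.
#' @export
gamble_ev <- function(p_hat, payoffs, price, alpha = 1, lambda = 1,
                      gamma = 1) {
  if (length(p_hat) != length(payoffs))
    stop("p_hat and payoffs must have the same length")
  if (abs(sum(p_hat) - 1) > 1e-6)
    stop("p_hat must sum to 1")
  sum(weight_fn(p_hat, gamma) * value_fn(payoffs - price, alpha, lambda))
}

#' Softmax probability of buying
#'
#' Logistic choice rule `q = plogis(intercept + slope * ev)`, clipped to
#' `[1e-9, 1 - 1e-9]` so that log-likelihoods stay finite.
#'
#' @param ev Expected value(s) of the gamble.
#' @param intercept,slope Logistic coefficients.
#' @return Buy probability/ies.
#' @export
buy_probability <- function(ev, intercept, slope) {
  q <- stats::plogis(intercept + slope * ev)
  pmin(pmax(q, 1e-9), 1 - 1e-9)
}

#' Log-likelihood of a session's active choices under a model
#'
#' Replays each bin's draw stream through the model's learning rule,
#' computes the end-of-stage expected value of every active trial, converts
#' it to a buy probability, and sums `log q` over buys and `log(1 - q)` over
#' passes. Control trials (outcome known in advance) are excluded.
#'
#' @param session A `gamble_session` with decisions.
#' @param spec Model tag or [model_spec()].
#' @param params Complete named parameter vector for the model.
#' @param alpha0 Prior concentration for belief updating.
#' @return Scalar log-likelihood.
#' @export
dataset_loglik <- function(session, spec, params, alpha0 = 1) {
  spec <- as_model_spec(spec)
  check_params(spec, params)
  prep <- prepare_model_data(session, spec, alpha0 = alpha0)
  loglik_from_prep(prep, params)
}

#' Per-trial model outputs
#'
#' Expected value, buy probability and log-likelihood contribution of every
#' active trial under a model, e.g. for export or diagnostics.
#'
#' @inheritParams dataset_loglik
#' @return Data frame with columns `subject`, `bin`, `stage`, `choice_idx`,
#'   `ev`, `q`, `decision`, `loglik_term`.
#' @export
trial_outputs <- function(session, spec, params, alpha0 = 1) {
  spec <- as_model_spec(spec)
  check_params(spec, params)
  prep <- prepare_model_data(session, spec, alpha0 = alpha0)
  ev <- ev_from_prep(prep, params)
  q <- buy_probability(ev, params["intercept"], params["slope"])
  ch <- session$choices[prep$choice_rows, ]
  ll <- ifelse(ch$decision == 1L, log(q), log(1 - q))
  data.frame(subject = ch$subject, bin = ch$bin, stage = ch$stage,
             choice_idx = ch$choice_idx, ev = ev, q = q,
             decision = ch$decision, loglik_term = ll)
}

# ---- internal vectorized likelihood machinery ------------------------------

# Precomputes, once per (session, spec), everything the likelihood needs:
# for probability models a trial x state matrix of end-of-stage point
# estimates (zero-padded beyond each bin's K; padded entries get weight 0)
# and log|net payoff| matrices; for the reinforcement model the per-stage
# payoff sequences grouped by length so the delta-rule forecast is a single
# matrix product per group.
prepare_model_data <- function(session, spec, alpha0 = 1) {
  spec <- as_model_spec(spec)
  ch <- session$choices
  active <- which(ch$condition == "active")
  cha <- ch[active, ]
  n <- nrow(cha)
  price <- cha$price
  dec <- cha$decision
  out <- list(spec = spec, alpha0 = alpha0, n = n, price = price,
              dec = dec, choice_rows = active)

  d <- session$draws
  d <- d[order(d$subject, d$bin, d$stage, d$t), ]
  keys <- unique(cha[, c("subject", "bin")])
  keys <- keys[order(keys$subject, keys$bin), ]
  trial_key <- paste(cha$subject, cha$bin, cha$stage)

  if (spec$inference == "reinforcement") {
    seqs <- list(); stage_of_trial <- integer(n)
    for (i in seq_len(nrow(keys))) {
      subj <- keys$subject[i]; b <- keys$bin[i]
      dd <- d[d$subject == subj & d$bin == b, ]
      for (stage in 1:2) {
        seqs[[length(seqs) + 1L]] <- dd$payoff[dd$stage == stage]
        stage_of_trial[trial_key == paste(subj, b, stage)] <-
          length(seqs)
      }
    }
    lens <- lengths(seqs)
    groups <- lapply(sort(unique(lens)), function(L) {
      idx <- which(lens == L)
      list(L = L, idx = idx,
           X = do.call(rbind, seqs[idx]))
    })
    out$rl <- list(n_stages = length(seqs), groups = groups,
                   stage_of_trial = stage_of_trial)
    return(out)
  }

  kmax <- max(session$bin_table$K)
  PHAT <- matrix(0, n, kmax)
  PAY <- matrix(0, n, kmax)
  for (i in seq_len(nrow(keys))) {
    subj <- keys$subject[i]; b <- keys$bin[i]
    bin <- session_bin(session, subj, b)
    K <- bin$K
    dd <- d[d$subject == subj & d$bin == b, ]
    c1 <- tabulate(dd$state[dd$stage == 1L], K)
    c2s <- tabulate(dd$state[dd$stage == 2L], K)
    counts <- switch(spec$inference,
      hidden_state = list(c1, c1 + c2s),
      observation  = list(c1, c2s),
      none         = list(integer(K), integer(K)))
    for (stage in 1:2) {
      rows <- which(trial_key == paste(subj, b, stage))
      if (!length(rows)) next
      ph <- (counts[[stage]] + alpha0) / (sum(counts[[stage]]) + K * alpha0)
      PHAT[rows, seq_len(K)] <- matrix(ph, length(rows), K, byrow = TRUE)
      PAY[rows, seq_len(K)] <- matrix(payoff_map(bin, stage),
                                      length(rows), K, byrow = TRUE)
    }
  }
  XP <- PAY - price           # net payoff per trial x state (pads: -price)
  pad <- PHAT == 0            # padded or impossible states get weight 0
  XP[pad] <- 0
  out$PHAT <- PHAT
  out$LAX <- log(abs(XP))     # -Inf at exact zeros; exp(alpha * -Inf) = 0
  out$NEG <- which(XP < 0)
  if (spec$weight_form == "curved") {
    out$LP <- log(PHAT)       # -Inf at pads -> weight exactly 0
    out$LQ <- log1p(-PHAT)
  }
  out
}

ev_from_prep <- function(prep, params) {
  spec <- prep$spec
  if (spec$inference == "reinforcement") {
    eta <- params[["eta"]]
    V <- numeric(prep$rl$n_stages)
    for (g in prep$rl$groups) {
      L <- g$L
      w <- if (L == 1L) 1 else
        c((1 - eta)^(L - 1L), eta * (1 - eta)^((L - 2L):0))
      V[g$idx] <- as.numeric(g$X %*% w)
    }
    return(V[prep$rl$stage_of_trial] - prep$price)
  }
  if (spec$value_form == "linear") {
    V <- exp(prep$LAX)
    V[prep$NEG] <- -V[prep$NEG]
  } else {
    V <- exp(params[["alpha"]] * prep$LAX)
    V[prep$NEG] <- -params[["lambda"]] * V[prep$NEG]
  }
  W <- if (spec$weight_form == "identity") prep$PHAT else {
    g <- params[["gamma"]]
    pg <- exp(g * prep$LP)
    pg / (pg + exp(g * prep$LQ))^(1 / g)
  }
  rowSums(W * V)
}

loglik_from_prep <- function(prep, params) {
  if (any(is.na(prep$dec)))
    stop("incomplete data: active trials without decisions")
  ev <- ev_from_prep(prep, params)
  q <- buy_probability(ev, params[["intercept"]], params[["slope"]])
  sum(log(q[prep$dec == 1L])) + sum(log(1 - q[prep$dec == 0L]))
}
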