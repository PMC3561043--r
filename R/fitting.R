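#' Bayesian Information Criterion
#'
#' `BIC = -2 * mll + n_params * log(n_data)`; lower is better.
#'
#' @param mll Maximized log-likelihood.
#' @param n_params Number of free parameters.
#' @param n_data Number of data points (active choices).
#' @return Scalar BIC.
#' @export
bic <- function(mll, n_params, n_data) {
  if (any(n_data < 1)) stop("n_data must be >= 1")
  -2 * mll + n_params * log(n_data)
}

# ---- parameter transforms ---------------------------------------------------
# Optimization runs in an unconstrained space: identity for the logistic
# coefficients, log for lambda and alpha (positivity), scaled logit onto
# [0.3, 2] for gamma (keeps the weighting function monotone), logit for eta.

GAMMA_LO <- 0.3
GAMMA_HI <- 2

to_free <- function(params, names) {
  vapply(names, function(nm) {
    x <- params[[nm]]
    switch(nm,
      lambda = , alpha = log(x),
      gamma = stats::qlogis((x - GAMMA_LO) / (GAMMA_HI - GAMMA_LO)),
      eta = stats::qlogis(x),
      x)
  }, numeric(1))
}

from_free <- function(free, names) {
  stats::setNames(vapply(seq_along(names), function(i) {
    nm <- names[i]; x <- free[i]
    switch(nm,
      lambda = , alpha = exp(x),
      gamma = GAMMA_LO + (GAMMA_HI - GAMMA_LO) * stats::plogis(x),
      eta = stats::plogis(x),
      x)
  }, numeric(1)), names)
}

# Restart starting values, drawn on the natural scale.
draw_start <- function(names) {
  stats::setNames(vapply(names, function(nm) switch(nm,
    intercept = stats::rnorm(1, 0, 1),
    slope = stats::runif(1, 0.1, 2),
    lambda = stats::runif(1, 0.5, 3),
    alpha = stats::runif(1, 0.3, 1.2),
    gamma = stats::runif(1, 0.5, 1.5),
    eta = stats::runif(1, 0.1, 0.9),
    stop("no start rule for ", nm)), numeric(1)), names)
}

#' Fit a choice model by maximum likelihood
#'
#' Nelder-Mead maximization of [dataset_loglik()] in an unconstrained
#' parameter space, repeated from `n_restarts` random starting points; the
#' best restart is retained and then polished by re-running the simplex from
#' its solution until the improvement is negligible. On well-sized data the
#' restarts end very close together (their spread is reported).
#'
#' @param session A `gamble_session` with decisions.
#' @param spec Model tag or [model_spec()].
#' @param n_restarts Number of random restarts (default 5).
#' @param seed Optional integer seed for the restart draws.
#' @param alpha0 Prior concentration for belief updating.
#' @param fixed Optional named vector of parameters held fixed (profiled
#'   out), e.g. `c(lambda = 1.69, alpha = 0.44)`.
#' @param reltol Relative convergence tolerance of the simplex.
#' @param maxit Maximum simplex iterations per (re)start.
#' @return An object of class `fit_result`: `tag`, `estimates`, `mll`,
#'   `bic`, `n_data`, `restart_mll`, `converged`.
#' @export
fit_model <- function(session, spec, n_restarts = 5L, seed = NULL,
                      alpha0 = 1, fixed = NULL, reltol = 1e-10,
                      maxit = 5000L) {
  spec <- as_model_spec(spec)
  prep <- prepare_model_data(session, spec, alpha0 = alpha0)
  if (any(is.na(prep$dec)))
    stop("incomplete data: active trials without decisions")
  if (prep$n < 10L * spec$n_params)
    stop("too few active choices (", prep$n, ") to identify ",
         spec$n_params, " parameters")
  free_names <- setdiff(spec$param_names, names(fixed))
  if (!length(free_names)) stop("no free parameters left to fit")
  negll <- function(free) {
    params <- c(from_free(free, free_names), fixed)
    ll <- loglik_from_prep(prep, params)
    if (!is.finite(ll)) return(1e10)
    -ll
  }
  if (!is.null(seed)) set.seed(seed)
  ctrl <- list(maxit = maxit, reltol = reltol)
  fits <- vector("list", n_restarts)
  for (r in seq_len(n_restarts)) {
    start <- to_free(as.list(draw_start(free_names)), free_names)
    fits[[r]] <- stats::optim(start, negll, method = "Nelder-Mead",
                              control = ctrl)
  }
  vals <- vapply(fits, `[[`, numeric(1), "value")
  if (all(vals >= 1e10)) stop("fit failure: likelihood non-finite at all starts")
  best <- fits[[which.min(vals)]]
  # polish: restart the simplex at its own solution (fresh simplex, tighter
  # localization) until no meaningful improvement remains
  ctrl_polish <- list(maxit = maxit, reltol = 1e-13)
  for (p in 1:6) {
    again <- stats::optim(best$par, negll, method = "Nelder-Mead",
                          control = ctrl_polish)
    improved <- best$value - again$value
    if (again$value <= best$value) best <- again
    if (improved < 1e-11) break
  }
  est <- c(from_free(best$par, free_names), fixed)[spec$param_names]
  mll <- -best$value
  structure(list(tag = spec$tag, spec = spec, estimates = est, mll = mll,
                 bic = bic(mll, spec$n_params, prep$n), n_data = prep$n,
                 restart_mll = -vals,
                 converged = best$convergence == 0L,
                 alpha0 = alpha0, seed = seed),
            class = "fit_result")
}

#' @export
print.fit_result <- function(x, ...) {
  cat("<fit_result ", x$tag, ">  n = ", x$n_data,
      "  logLik = ", formatC(x$mll, digits = 2, format = "f"),
      "  BIC = ", formatC(x$bic, digits = 1, format = "f"), "\n", sep = "")
  print(round(x$estimates, 4))
  cat("restart spread:",
      formatC(max(x$restart_mll) - min(x$restart_mll), digits = 3,
              format = "g"), "\n")
  invisible(x)
}

#' Fit and compare several models by BIC
#'
#' Fits each model to the same session and tabulates estimates, maximized
#' log-likelihood and BIC. The minimum-BIC model is flagged; exact ties are
#' broken toward fewer parameters.
#'
#' @param session A `gamble_session` with decisions.
#' @param specs Character vector of model tags.
#' @param n_restarts Restarts per fit.
#' @param seed Integer seed; each model gets a seed derived from it and its
#'   tag, so identical tags produce identical rows.
#' @param alpha0 Prior concentration.
#' @return Data frame of class `model_comparison`, one row per spec, with
#'   the fits attached as an attribute.
#' @export
compare_models <- function(session,
                           specs = c("M2", "M3", "M4", "M4a", "M4b", "M5"),
                           n_restarts = 5L, seed = 1L, alpha0 = 1) {
  if (length(specs) < 2L) stop("need at least two models to compare")
  all_tags <- c("M2", "M3", "M4", "M4a", "M4b", "M5")
  fits <- lapply(specs, function(tag) {
    fit_model(session, tag, n_restarts = n_restarts,
              seed = seed + 1000L * match(tag, all_tags), alpha0 = alpha0)
  })
  par_cols <- c("intercept", "slope", "lambda", "alpha", "gamma", "eta")
  tab <- do.call(rbind, lapply(fits, function(f) {
    row <- stats::setNames(rep(NA_real_, length(par_cols)), par_cols)
    row[names(f$estimates)] <- f$estimates
    data.frame(model = f$tag, n_params = f$spec$n_params, t(row),
               mll = f$mll, bic = f$bic, n_data = f$n_data)
  }))
  tab$best <- seq_len(nrow(tab)) == select_best(tab$bic, tab$n_params)
  rownames(tab) <- NULL
  attr(tab, "fits") <- fits
  class(tab) <- c("model_comparison", "data.frame")
  tab
}

# strict minimum BIC; ties (to within 1e-9) broken toward fewer parameters
select_best <- function(bics, n_params) {
  tied <- which(bics <= min(bics) + 1e-9)
  tied[which.min(n_params[tied])]
}

#' @export
print.model_comparison <- function(x, ...) {
  y <- as.data.frame(x)
  num <- vapply(y, is.numeric, logical(1))
  y[num] <- lapply(y[num], function(v) round(v, 3))
  print(y, row.names = FALSE)
  invisible(x)
}

#' Serialize a fit to JSON
#' @param fit A `fit_result`.
#' @param path Output file.
#' @return `path`, invisibly.
#' @export
write_fit_json <- function(fit, path) {
  jsonlite::write_json(
    list(tag = fit$tag, estimates = as.list(fit$estimates), mll = fit$mll,
         bic = fit$bic, n_data = fit$n_data,
         restart_mll = fit$restart_mll, converged = fit$converged,
         alpha0 = fit$alpha0, seed = fit$seed),
    path, auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(path)
}
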