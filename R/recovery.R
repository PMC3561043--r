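#' Parameter-recovery study
#'
#' Repeatedly simulates a cohort from a generating model with known
#' parameters, refits the same model, and summarizes how well the
#' parameters are recovered (bias, RMSE, medians across replicates).
#'
#' @param spec Model tag or [model_spec()] used both to generate and to fit.
#' @param generating_params Named parameter vector of the generator.
#' @param n_subjects Subjects per simulated cohort (default 23).
#' @param replicates Number of simulate-and-fit replicates.
#' @param design A [task_design()].
#' @param seed Integer seed; each replicate derives its own seed from it.
#' @param n_restarts Restarts per fit.
#' @param alpha0 Prior concentration.
#' @return An object of class `recovery_report` with the per-replicate
#'   estimates and per-parameter `bias`, `rmse` and `median`.
#' @export
parameter_recovery <- function(spec, generating_params, n_subjects = 23L,
                               replicates = 50L, design = task_design(),
                               seed = 1L, n_restarts = 5L, alpha0 = 1) {
  if (replicates < 1L) stop("replicates must be >= 1")
  spec <- as_model_spec(spec)
  check_params(spec, generating_params)
  est <- matrix(NA_real_, replicates, spec$n_params,
                dimnames = list(NULL, spec$param_names))
  for (r in seq_len(replicates)) {
    rs <- replicate_seed(seed, r)
    ses <- simulate_cohort(design, n_subjects, seed = rs, spec = spec,
                           params = generating_params, alpha0 = alpha0)
    fit <- fit_model(ses, spec, n_restarts = n_restarts, seed = rs + 1L,
                     alpha0 = alpha0)
    est[r, ] <- fit$estimates[spec$param_names]
  }
  gen <- generating_params[spec$param_names]
  structure(list(kind = "parameter", tag = spec$tag,
                 generating_params = gen, n_subjects = n_subjects,
                 replicates = replicates, estimates = est,
                 bias = colMeans(est) - gen,
                 rmse = sqrt(colMeans(sweep(est, 2, gen)^2)),
                 median = apply(est, 2, stats::median), seed = seed),
            class = "recovery_report")
}

replicate_seed <- function(seed, r) {
  (as.integer(seed) + 104729L * as.integer(r)) %% 2147483647L
}

#' Model-recovery study
#'
#' For each generating model, repeatedly simulates a cohort, fits all
#' candidate models, and records which one the BIC selects. Reports the
#' confusion matrix (generating x selected; rows sum to the replicate
#' count) and the full per-replicate BIC tables.
#'
#' @param fit_specs Character vector of candidate model tags to fit.
#' @param generating Named list mapping a generating tag to its parameter
#'   vector, e.g. `list(M4 = default_choice_params("M4"))`.
#' @param replicates Replicates per generating model (>= 10 recommended).
#' @inheritParams parameter_recovery
#' @return An object of class `recovery_report` with elements `confusion`
#'   (matrix) and `bics` (list of replicate x model BIC matrices, one per
#'   generating model).
#' @export
model_recovery <- function(fit_specs, generating, replicates = 50L,
                           n_subjects = 23L, design = task_design(),
                           seed = 1L, n_restarts = 5L, alpha0 = 1) {
  if (replicates < 1L) stop("replicates must be >= 1")
  gen_tags <- names(generating)
  confusion <- matrix(0L, length(gen_tags), length(fit_specs),
                      dimnames = list(generating = gen_tags,
                                      selected = fit_specs))
  bics <- list()
  n_params <- vapply(fit_specs, function(t) model_spec(t)$n_params,
                     integer(1))
  for (g in seq_along(gen_tags)) {
    gtag <- gen_tags[g]
    B <- matrix(NA_real_, replicates, length(fit_specs),
                dimnames = list(NULL, fit_specs))
    for (r in seq_len(replicates)) {
      rs <- replicate_seed(seed + 31L * g, r)
      ses <- simulate_cohort(design, n_subjects, seed = rs, spec = gtag,
                             params = generating[[gtag]], alpha0 = alpha0)
      for (m in seq_along(fit_specs)) {
        fit <- fit_model(ses, fit_specs[m], n_restarts = n_restarts,
                         seed = rs + 7L * m, alpha0 = alpha0)
        B[r, m] <- fit$bic
      }
      sel <- select_best(B[r, ], n_params)
      confusion[g, sel] <- confusion[g, sel] + 1L
    }
    bics[[gtag]] <- B
  }
  structure(list(kind = "model", fit_specs = fit_specs,
                 generating = generating, replicates = replicates,
                 n_subjects = n_subjects, confusion = confusion,
                 bics = bics, seed = seed),
            class = "recovery_report")
}

#' @export
print.recovery_report <- function(x, ...) {
  if (x$kind == "parameter") {
    cat("<recovery_report parameter> ", x$tag, ", ", x$replicates,
        " replicates x ", x$n_subjects, " subjects\n", sep = "")
    print(round(rbind(generating = x$generating_params,
                      median = x$median, bias = x$bias, rmse = x$rmse), 4))
  } else {
    cat("<recovery_report model> ", x$replicates,
        " replicates per generating model\n", sep = "")
    print(x$confusion)
  }
  invisible(x)
}
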