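#' Build and validate a run configuration
#'
#' Bundles everything a reproducible study run needs: the task design, the
#' generating model and its parameters, the candidate models to fit, fitting
#' and replication settings, the seed and the output directory.
#'
#' @param seed Integer seed (mandatory).
#' @param out_dir Output directory.
#' @param design A [task_design()].
#' @param generating_spec Tag of the generating model.
#' @param generating_params Named parameters for it (defaults to
#'   [default_choice_params()] of the tag).
#' @param models Character vector of model tags to fit.
#' @param n_subjects Cohort size.
#' @param n_restarts Restarts per fit.
#' @param replicates Replicates for recovery studies (>= 1).
#' @param alpha0 Prior concentration.
#' @return A validated list of class `run_config`.
#' @export
run_config <- function(seed, out_dir = ".", design = task_design(),
                       generating_spec = "M4",
                       generating_params = default_choice_params(generating_spec),
                       models = c("M2", "M3", "M4", "M4a", "M4b", "M5"),
                       n_subjects = 23L, n_restarts = 5L, replicates = 50L,
                       alpha0 = 1) {
  cfg <- list(seed = seed, out_dir = out_dir, design = design,
              generating_spec = generating_spec,
              generating_params = generating_params, models = models,
              n_subjects = as.integer(n_subjects),
              n_restarts = as.integer(n_restarts),
              replicates = as.integer(replicates), alpha0 = alpha0)
  validate_run_config(cfg)
  class(cfg) <- "run_config"
  cfg
}

validate_run_config <- function(cfg) {
  if (is.null(cfg$seed) || !is.finite(cfg$seed))
    stop("config field 'seed' is mandatory and must be a finite integer")
  tags <- c("M2", "M3", "M4", "M4a", "M4b", "M5")
  bad <- setdiff(c(cfg$models, cfg$generating_spec), tags)
  if (length(bad))
    stop("config field 'models'/'generating_spec': unknown tag(s) ",
         paste(bad, collapse = ", "))
  if (cfg$replicates < 1L)
    stop("config field 'replicates' must be >= 1")
  if (cfg$n_subjects < 1L)
    stop("config field 'n_subjects' must be >= 1")
  check_params(model_spec(cfg$generating_spec), cfg$generating_params)
  invisible(TRUE)
}

#' Read a run configuration from a YAML file
#'
#' Top-level keys mirror the arguments of [run_config()]; `design` may be a
#' mapping of [task_design()] arguments and `generating_params` a mapping of
#' parameter values.
#'
#' @param path YAML file.
#' @return A `run_config`.
#' @export
read_run_config <- function(path) {
  y <- yaml::read_yaml(path)
  design <- if (is.null(y$design)) task_design() else {
    if (!is.null(y$design$payoff_pools))
      y$design$payoff_pools <- lapply(y$design$payoff_pools, unlist)
    do.call(task_design, y$design)
  }
  run_config(
    seed = y$seed, out_dir = if (is.null(y$out_dir)) "." else y$out_dir,
    design = design,
    generating_spec = if (is.null(y$generating_spec)) "M4" else y$generating_spec,
    generating_params = if (is.null(y$generating_params))
      default_choice_params(if (is.null(y$generating_spec)) "M4" else y$generating_spec)
      else unlist(y$generating_params),
    models = if (is.null(y$models)) c("M2", "M3", "M4", "M4a", "M4b", "M5")
      else unlist(y$models),
    n_subjects = if (is.null(y$n_subjects)) 23L else y$n_subjects,
    n_restarts = if (is.null(y$n_restarts)) 5L else y$n_restarts,
    replicates = if (is.null(y$replicates)) 50L else y$replicates,
    alpha0 = if (is.null(y$alpha0)) 1 else y$alpha0)
}

config_hash <- function(cfg) {
  tmp <- tempfile(fileext = ".json")
  on.exit(unlink(tmp))
  plain <- cfg
  plain$out_dir <- NULL           # hash the science, not the file layout
  class(plain) <- NULL
  plain$design <- unclass(plain$design)
  jsonlite::write_json(plain, tmp, auto_unbox = TRUE, digits = NA)
  unname(tools::md5sum(tmp))
}

log_msg <- function(...) {
  message(format(Sys.time(), "%H:%M:%S"), " [problearn] ", ...)
}

#' Run the full model-comparison study
#'
#' Simulates the configured cohort from the generating model, writes the
#' session tables, fits every configured model, and writes one JSON per fit
#' plus a `comparison.tsv` mirroring a model-comparison table (the BIC
#' ranking is logged). All outputs embed the seed and a hash of the
#' configuration; re-running the same configuration reproduces them
#' byte-for-byte.
#'
#' @param cfg A [run_config()].
#' @return The comparison table, invisibly.
#' @export
run_table1_study <- function(cfg) {
  validate_run_config(cfg)
  hash <- config_hash(cfg)
  dir.create(cfg$out_dir, showWarnings = FALSE, recursive = TRUE)
  log_msg("simulating ", cfg$n_subjects, " subjects from ",
          cfg$generating_spec, " (seed ", cfg$seed, ")")
  ses <- simulate_cohort(cfg$design, cfg$n_subjects, seed = cfg$seed,
                         spec = cfg$generating_spec,
                         params = cfg$generating_params, alpha0 = cfg$alpha0)
  write_session(ses, cfg$out_dir)
  log_msg("fitting ", length(cfg$models), " models on ",
          sum(ses$choices$condition == "active"), " active choices")
  tab <- compare_models(ses, cfg$models, n_restarts = cfg$n_restarts,
                        seed = cfg$seed, alpha0 = cfg$alpha0)
  fit_dir <- file.path(cfg$out_dir, "fits")
  dir.create(fit_dir, showWarnings = FALSE)
  for (fit in attr(tab, "fits")) {
    fit$config_md5 <- hash
    write_fit_json(fit, file.path(fit_dir, paste0(fit$tag, ".json")))
  }
  write_tsv(as.data.frame(tab), file.path(cfg$out_dir, "comparison.tsv"),
            header_comment = paste0("seed=", cfg$seed, " config_md5=", hash))
  ord <- order(tab$bic)
  log_msg("BIC ranking: ", paste(tab$model[ord], collapse = " < "))
  invisible(tab)
}

#' Run parameter- and model-recovery studies
#'
#' Parameter recovery refits the generating model to its own simulated data
#' across replicates; model recovery fits every configured model and records
#' the BIC selection. Results are written as `recovery_params.tsv`,
#' `confusion.tsv` and `recovery.json` (with seeds and the configuration
#' hash embedded).
#'
#' @param cfg A [run_config()].
#' @return List with both `recovery_report`s, invisibly.
#' @export
run_recovery_study <- function(cfg) {
  validate_run_config(cfg)
  hash <- config_hash(cfg)
  dir.create(cfg$out_dir, showWarnings = FALSE, recursive = TRUE)
  log_msg("parameter recovery: ", cfg$replicates, " replicates of ",
          cfg$generating_spec)
  pr <- parameter_recovery(cfg$generating_spec, cfg$generating_params,
                           n_subjects = cfg$n_subjects,
                           replicates = cfg$replicates, design = cfg$design,
                           seed = cfg$seed, n_restarts = cfg$n_restarts,
                           alpha0 = cfg$alpha0)
  est <- as.data.frame(pr$estimates)
  est$replicate <- seq_len(nrow(est))
  write_tsv(est, file.path(cfg$out_dir, "recovery_params.tsv"),
            header_comment = paste0("seed=", cfg$seed, " config_md5=", hash))
  log_msg("model recovery: ", cfg$replicates, " replicates, fitting ",
          paste(cfg$models, collapse = ", "))
  mr <- model_recovery(cfg$models,
                       stats::setNames(list(cfg$generating_params),
                                       cfg$generating_spec),
                       replicates = cfg$replicates,
                       n_subjects = cfg$n_subjects, design = cfg$design,
                       seed = cfg$seed, n_restarts = cfg$n_restarts,
                       alpha0 = cfg$alpha0)
  conf <- as.data.frame(mr$confusion)
  conf <- cbind(generating = rownames(mr$confusion), conf)
  write_tsv(conf, file.path(cfg$out_dir, "confusion.tsv"),
            header_comment = paste0("seed=", cfg$seed, " config_md5=", hash))
  jsonlite::write_json(
    list(seed = cfg$seed, config_md5 = hash,
         parameter_recovery = list(
           tag = pr$tag, generating = as.list(pr$generating_params),
           median = as.list(pr$median), bias = as.list(pr$bias),
           rmse = as.list(pr$rmse)),
         model_recovery = list(
           confusion = mr$confusion, replicates = mr$replicates)),
    file.path(cfg$out_dir, "recovery.json"),
    auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(list(parameter = pr, model = mr))
}
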