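# Tab-separated serialization of sessions and event tables. Numeric columns
# are written with 17 significant digits so that write -> read round-trips
# doubles exactly; decimal separator is always ".".

write_tsv <- function(df, path, header_comment = NULL) {
  out <- df
  for (j in seq_along(out)) {
    if (is.double(out[[j]])) out[[j]] <- sprintf("%.17g", out[[j]])
  }
  con <- file(path, "w", encoding = "UTF-8")
  on.exit(close(con))
  if (!is.null(header_comment)) writeLines(paste0("# ", header_comment), con)
  utils::write.table(out, con, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

read_tsv <- function(path, colClasses = NA) {
  utils::read.table(path, header = TRUE, sep = "\t", comment.char = "#",
                    colClasses = colClasses, stringsAsFactors = FALSE)
}

#' Write a session to a directory of TSV tables
#'
#' Produces `draws.tsv` (subject, bin, stage, t, state, payoff),
#' `choices.tsv` (subject, bin, stage, choice_idx, price, condition,
#' decision, outcome_payoff) and `bins.tsv` (the true probabilities and both
#' stage legends, needed to replay beliefs). [read_session()] reconstructs
#' an identical session.
#'
#' @param session A `gamble_session`.
#' @param dir Output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_session <- function(session, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  write_tsv(session$draws, file.path(dir, "draws.tsv"))
  write_tsv(session$choices, file.path(dir, "choices.tsv"))
  write_tsv(session$bin_table, file.path(dir, "bins.tsv"))
  invisible(dir)
}

#' Read a session written by [write_session()]
#'
#' @param dir Directory containing `draws.tsv`, `choices.tsv`, `bins.tsv`.
#' @param design Optional [task_design()] to attach (defaults to the
#'   standard design).
#' @return A `gamble_session`.
#' @export
read_session <- function(dir, design = task_design()) {
  draws <- read_tsv(file.path(dir, "draws.tsv"),
                    colClasses = c("integer", "integer", "integer",
                                   "integer", "integer", "numeric"))
  choices <- read_tsv(file.path(dir, "choices.tsv"),
                      colClasses = c("integer", "integer", "integer",
                                     "integer", "numeric", "character",
                                     "integer", "numeric"))
  bt <- read_tsv(file.path(dir, "bins.tsv"),
                 colClasses = c("integer", "integer", "integer", "integer",
                                "numeric", "numeric", "numeric"))
  bins <- list()
  for (subj in unique(bt$subject)) {
    sb <- bt[bt$subject == subj, ]
    bins[[as.character(subj)]] <- lapply(sort(unique(sb$bin)), function(b) {
      bb <- sb[sb$bin == b, ]
      bb <- bb[order(bb$state), ]
      bin_config(bb$K[1], bb$theta, bb$payoff_stage1, bb$payoff_stage2)
    })
  }
  new_session(design, bins, draws, choices)
}

#' Write an event table as per-subject events TSVs
#'
#' One `sub-<id>_events.tsv` per subject with columns `onset`, `duration`,
#' `trial_type` and one column per parametric modulator, following the
#' layout of BIDS events files.
#'
#' @param events An `event_table` from [build_event_table()].
#' @param dir Output directory.
#' @return Character vector of written paths, invisibly.
#' @export
write_events_tsv <- function(events, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  cols <- c("onset", "duration", "trial_type", "stim_probability",
            "prediction_error", "ev", "outcome_entropy", "choice_entropy",
            "net_payoff")
  paths <- character(0)
  for (subj in sort(unique(events$subject))) {
    path <- file.path(dir, sprintf("sub-%02d_events.tsv", subj))
    write_tsv(events[events$subject == subj, cols], path)
    paths <- c(paths, path)
  }
  invisible(paths)
}
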