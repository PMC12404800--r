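trial_columns <- c("participant_id", "condition", "test_index", "item_id",
                   "item_status", "recognition", "recollection", "belief",
                   "feedback")
feedback_levels <- c("none", "true_old", "true_new", "false_old", "false_new")

#' Validate participant and trial tables against the package schema
#'
#' Fail-fast structural validation run before any analysis stage: required
#' columns, scale ranges (recognition 0/1, recollection and belief 1..8,
#' state distrust 1..10), recognized factor codes, and uniqueness of the
#' (participant, test, item) trial key. Errors name the offending column and
#' row.
#'
#' @param participants,trials The two tables.
#' @return Invisibly `TRUE`; errors otherwise.
#' @export
validate_tables <- function(participants, trials) {
  need_p <- c("participant_id", "condition")
  miss <- setdiff(need_p, names(participants))
  if (length(miss) > 0L) {
    stop(sprintf("participants table missing column(s): %s",
                 paste(miss, collapse = ", ")))
  }
  miss <- setdiff(trial_columns, names(trials))
  if (length(miss) > 0L) {
    stop(sprintf("trials table missing column(s): %s",
                 paste(miss, collapse = ", ")))
  }
  if (anyDuplicated(participants$participant_id)) {
    stop("duplicate participant_id in participants table")
  }
  bad_cond <- !participants$condition %in% c("commission", "omission", "control")
  if (any(bad_cond)) {
    stop(sprintf("unknown condition %s in participants row %d",
                 dQuote(participants$condition[which(bad_cond)[1]]),
                 which(bad_cond)[1]))
  }
  check_range <- function(x, lo, hi, col, tab) {
    bad <- which(!is.na(x) & (x < lo | x > hi | x != round(x)))
    if (length(bad) > 0L) {
      stop(sprintf("%s out of range [%d, %d] in %s row %d (value %s)",
                   col, lo, hi, tab, bad[1], format(x[bad[1]])))
    }
  }
  for (col in c("state_distrust_commission", "state_distrust_omission")) {
    if (col %in% names(participants)) {
      check_range(participants[[col]], 1L, 10L, col, "participants")
    }
  }
  check_range(trials$recognition, 0L, 1L, "recognition", "trials")
  check_range(trials$recollection, 1L, 8L, "recollection", "trials")
  check_range(trials$belief, 1L, 8L, "belief", "trials")
  bad_status <- which(!trials$item_status %in% c("old", "new"))
  if (length(bad_status) > 0L) {
    stop(sprintf("unknown item_status in trials row %d", bad_status[1]))
  }
  bad_fb <- which(!trials$feedback %in% feedback_levels)
  if (length(bad_fb) > 0L) {
    stop(sprintf("unknown feedback label in trials row %d", bad_fb[1]))
  }
  key <- paste(trials$participant_id, trials$test_index, trials$item_id)
  dup <- anyDuplicated(key)
  if (dup) stop(sprintf("duplicate (participant, test, item) key in trials row %d", dup))
  orphan <- which(!trials$participant_id %in% participants$participant_id)
  if (length(orphan) > 0L) {
    stop(sprintf("trials row %d references unknown participant_id %s",
                 orphan[1], format(trials$participant_id[orphan[1]])))
  }
  invisible(TRUE)
}

#' Read the participant and trial CSV tables
#'
#' Reads the two delimited tables in the package schema, types them and runs
#' [validate_tables()]. Missing ratings are empty fields in the CSV and
#' become `NA`.
#'
#' @param participants_path,trials_path File paths.
#' @return List with `participants` and `trials` data.frames.
#' @export
read_tables <- function(participants_path, trials_path) {
  for (p in c(participants_path, trials_path)) {
    if (!file.exists(p)) stop(sprintf("file not found: %s", p))
  }
  participants <- utils::read.csv(participants_path, stringsAsFactors = FALSE)
  trials <- utils::read.csv(trials_path, stringsAsFactors = FALSE)
  validate_tables(participants, trials)
  list(participants = participants, trials = trials)
}

#' Write a simulated experiment to CSV tables
#'
#' @param experiment A [simulate_experiment()] result.
#' @param dir Output directory (created if needed).
#' @return Invisibly, the two file paths written.
#' @export
write_tables <- function(experiment, dir) {
  stopifnot(inherits(experiment, "sim_experiment"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  pp <- file.path(dir, "participants.csv")
  tp <- file.path(dir, "trials.csv")
  utils::write.csv(experiment$participants, pp, row.names = FALSE, na = "")
  utils::write.csv(experiment$trials, tp, row.names = FALSE, na = "")
  invisible(c(participants = pp, trials = tp))
}

# Recursively strip non-serializable members (model fits, closures) and
# convert result objects to plain lists for the JSON report.
report_to_list <- function(x) {
  if (inherits(x, "data.frame")) return(x)
  if (is.list(x)) {
    x <- unclass(x)
    x$fit <- NULL
    return(lapply(x, report_to_list))
  }
  x
}

#' Serialize a pipeline report to JSON
#'
#' @param report A `pipeline_report` (or any result list).
#' @param path Output file.
#' @return Invisibly, `path`.
#' @export
write_report_json <- function(report, path) {
  out <- report_to_list(report)
  out$sdt <- NULL  # per-participant table stays in R; keep the report compact
  jsonlite::write_json(out, path, auto_unbox = TRUE, digits = NA,
                       force = TRUE, pretty = TRUE)
  invisible(path)
}
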