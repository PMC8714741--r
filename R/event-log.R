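#' @title Interaction event logs
#' @description An `event_log` is the raw record of one participant's
#'   interaction with one task: an ordered stream of timestamped events plus
#'   the seed that generated the matching task battery, so scoring is fully
#'   self-contained. Timestamps are integer milliseconds from task onset.
#' @name event_log
NULL

.legal_kinds <- list(
  d2 = c("page_start", "nav_left", "nav_right", "mark", "page_end"),
  dmts = c("trial_start", "choices_on", "select"),
  swm = c("trial_start", "sequence_start", "open", "token_found")
)

.event_payload_cols <- c("page", "trial", "choice_index", "box_id")

#' Construct an event log
#'
#' @param participant_id Character scalar identifying the participant.
#' @param task_id One of `"d2"`, `"dmts"`, `"swm"`.
#' @param seed Integer seed used to generate the matching task battery.
#' @param events A data frame with columns `t` (integer ms, non-decreasing),
#'   `kind` (task-legal event tag), and any payload columns among
#'   `page`, `trial`, `choice_index`, `box_id`.
#' @return An object of class `event_log`.
#' @export
event_log <- function(participant_id, task_id, seed, events) {
  task_id <- match.arg(task_id, names(.legal_kinds))
  events <- as_tibble(events)
  log <- structure(
    list(
      participant_id = as.character(participant_id),
      task_id = task_id,
      seed = as.integer(seed),
      events = events
    ),
    class = "event_log"
  )
  validate_event_log(log)
  log
}

#' @export
print.event_log <- function(x, ...) {
  cat(sprintf(
    "<event_log> task %s, participant %s, seed %d, %d events\n",
    x$task_id, x$participant_id, x$seed, nrow(x$events)
  ))
  invisible(x)
}

validate_event_log <- function(log, where = NULL) {
  ctx <- if (is.null(where)) "" else paste0(where, ": ")
  ev <- log$events
  if (!all(c("t", "kind") %in% names(ev))) {
    abort(paste0(ctx, "events must have columns 't' and 'kind'"))
  }
  if (nrow(ev)) {
    if (anyNA(ev$t) || any(ev$t < 0)) {
      abort(paste0(ctx, "field 't': timestamps must be non-negative"))
    }
    if (is.unsorted(ev$t)) {
      i <- which(diff(ev$t) < 0)[1] + 1L
      abort(paste0(
        ctx, "field 't': timestamps must be non-decreasing (event ", i,
        " at t=", ev$t[i], " follows t=", ev$t[i - 1L], ")"
      ))
    }
    bad <- setdiff(unique(ev$kind), .legal_kinds[[log$task_id]])
    if (length(bad)) {
      abort(paste0(
        ctx, "field 'kind': illegal event kind(s) for task ", log$task_id,
        ": ", paste(bad, collapse = ", ")
      ))
    }
  }
  invisible(log)
}

#' Read event logs from a JSON-Lines file
#'
#' One JSON object per line with fields `participant_id`, `task_id`, `seed`
#' and `events` (an array of objects with `t`, `kind`, and payload fields).
#' Malformed lines are rejected with line-numbered errors.
#'
#' @param path Path to a `.jsonl` file.
#' @return A list of [event_log] objects, in file order.
#' @export
read_event_logs <- function(path) {
  lines <- readLines(path, warn = FALSE)
  lines <- lines[nzchar(trimws(lines))]
  map(seq_along(lines), function(i) {
    where <- paste0("line ", i)
    rec <- tryCatch(
      jsonlite::fromJSON(lines[i], simplifyVector = TRUE),
      error = function(e) abort(paste0(where, ": invalid JSON: ", conditionMessage(e)))
    )
    for (fld in c("participant_id", "task_id", "seed", "events")) {
      if (is.null(rec[[fld]])) {
        abort(paste0(where, ": missing required field '", fld, "'"))
      }
    }
    if (!rec$task_id %in% names(.legal_kinds)) {
      abort(paste0(where, ": field 'task_id': unknown task_id '", rec$task_id, "'"))
    }
    ev <- as_tibble(rec$events)
    if (nrow(ev) && !all(c("t", "kind") %in% names(ev))) {
      abort(paste0(where, ": field 'events': every event needs 't' and 'kind'"))
    }
    if (!nrow(ev)) ev <- tibble(t = integer(), kind = character())
    ev$t <- as.integer(ev$t)
    log <- structure(
      list(
        participant_id = as.character(rec$participant_id),
        task_id = rec$task_id,
        seed = as.integer(rec$seed),
        events = ev
      ),
      class = "event_log"
    )
    validate_event_log(log, where = where)
    log
  })
}

#' Write event logs to a JSON-Lines file
#'
#' @param logs A list of [event_log] objects.
#' @param path Output path.
#' @return Invisibly, the number of records written.
#' @export
write_event_logs <- function(logs, path) {
  if (inherits(logs, "event_log")) logs <- list(logs)
  con <- file(path, open = "wt")
  on.exit(close(con))
  for (log in logs) {
    ev <- log$events
    keep <- names(ev)[colSums(!is.na(ev)) > 0]
    events <- map(seq_len(nrow(ev)), function(r) {
      row <- as.list(ev[r, intersect(keep, names(ev))])
      row[!is.na(unlist(row, use.names = FALSE))]
    })
    rec <- list(
      participant_id = log$participant_id,
      task_id = log$task_id,
      seed = log$seed,
      events = events
    )
    writeLines(
      jsonlite::toJSON(rec, auto_unbox = TRUE, digits = NA),
      con
    )
  }
  invisible(length(logs))
}

#' Write a cohort metrics table
#'
#' One row per participant: identifier, demographics, PHQ-9 total, then the
#' fourteen behavioral measures in a stable, documented column order (see
#' [metric_columns()]). Missing metrics are written as empty cells.
#'
#' @param records A data frame with columns `participant_id`, `age`,
#'   `gender` and `phq9` (one row per participant, ids unique).
#' @param metrics A data frame of behavioral measures keyed by
#'   `participant_id`, as produced by [score_cohort()].
#' @param path Output CSV path.
#' @return Invisibly, the number of participant rows written.
#' @export
write_metrics_table <- function(records, metrics, path) {
  records <- as_tibble(records)
  if (anyDuplicated(records$participant_id)) {
    dup <- records$participant_id[duplicated(records$participant_id)][1]
    abort(paste0("duplicate participant_id: ", dup))
  }
  out <- records %>%
    select(any_of(c("participant_id", "age", "gender", "phq9"))) %>%
    left_join(
      as_tibble(metrics) %>% select(any_of(c("participant_id", metric_columns()))),
      by = "participant_id"
    )
  for (col in metric_columns()) {
    if (!col %in% names(out)) out[[col]] <- NA_real_
  }
  out <- out[, c("participant_id", "age", "gender", "phq9", metric_columns())]
  readr::write_csv(out, path, na = "")
  invisible(nrow(out))
}

#' Read a cohort metrics table written by [write_metrics_table()]
#'
#' @param path CSV path.
#' @return A tibble with one row per participant.
#' @export
read_metrics_table <- function(path) {
  readr::read_csv(path, show_col_types = FALSE, progress = FALSE)
}

#' Canonical metric column order
#'
#' The fourteen behavioral measures of the battery, in the order they appear
#' in serialized metrics tables: six d2 measures, five DMTS measures, three
#' SWM measures.
#'
#' @return A character vector of column names.
#' @export
metric_columns <- function() {
  c(
    "d2_n_items", "d2_n_correct", "d2_n_omission", "d2_n_commission",
    "d2_n_errors", "d2_error_rate",
    "dmts_n_correct", "dmts_avg_latency_ms", "dmts_n_color_errors",
    "dmts_n_shape_errors", "dmts_n_both_errors",
    "swm_n_between_errors", "swm_n_within_errors", "swm_strategy_score"
  )
}
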