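#' Score a cohort's event logs into the fourteen behavioral measures
#'
#' For every participant, the matching batteries are regenerated from the
#' seed stored in each event log (scoring is self-contained), the three
#' scorers are applied, and the results are joined with demographics and the
#' PHQ-9 total. Participants missing a task's log get `NA` for that task's
#' measures.
#'
#' @param cohort A `cohort` object from [simulate_cohort()], or a logs
#'   tibble (`participant_id`, `task_id`, `log`).
#' @param config Configuration list used to regenerate batteries; must match
#'   the one the logs were produced under.
#' @return A tibble with one row per participant: `participant_id`, then
#'   (when available from the cohort) `age`, `gender`, `phq9`, then the
#'   fourteen measures named as in [metric_columns()].
#' @export
score_cohort <- function(cohort, config = default_config()) {
  logs <- if (inherits(cohort, "cohort")) cohort$logs else as_tibble(cohort)
  # batteries are deterministic in the log seed: regenerate once per seed
  battery_cache <- new.env(parent = emptyenv())
  get_batteries <- function(seed) {
    key <- as.character(seed)
    if (is.null(battery_cache[[key]])) {
      battery_cache[[key]] <- list(
        d2 = generate_d2_battery(seed, config),
        dmts = generate_dmts_battery(seed, config = config),
        swm = generate_swm_battery(seed, config)
      )
    }
    battery_cache[[key]]
  }

  score_one <- function(log) {
    bats <- get_batteries(log$seed)
    switch(log$task_id,
      d2 = score_d2(log, bats$d2) %>%
        rename_with(~ paste0("d2_", .x)),
      dmts = score_dmts(log, bats$dmts) %>%
        select(-"n_trials") %>%
        rename_with(~ paste0("dmts_", .x)),
      swm = score_swm(log, bats$swm) %>%
        rename_with(~ paste0("swm_", .x))
    )
  }

  scored <- logs %>%
    mutate(metrics = map(.data$log, score_one)) %>%
    select("participant_id", "metrics")
  metrics <- scored %>%
    group_by(.data$participant_id) %>%
    summarise(metrics = list(bind_cols(.data$metrics)), .groups = "drop") %>%
    unnest("metrics")

  if (inherits(cohort, "cohort")) {
    cohort$participants %>%
      select(any_of(c("participant_id", "age", "gender", "phq9"))) %>%
      left_join(metrics, by = "participant_id")
  } else {
    metrics
  }
}

#' Mapping from behavioral measure to task
#'
#' Used by [select_combined_metrics()] to attribute rotated components to
#' tasks.
#'
#' @param measures Character vector of measure names (default: all fourteen
#'   from [metric_columns()]).
#' @return A named character vector, measure -> task id.
#' @export
task_of_measure <- function(measures = metric_columns()) {
  task <- dplyr::case_when(
    startsWith(measures, "d2_") ~ "d2",
    startsWith(measures, "dmts_") ~ "dmts",
    startsWith(measures, "swm_") ~ "swm"
  )
  if (anyNA(task)) {
    abort(paste0(
      "cannot infer task for measure(s): ",
      paste(measures[is.na(task)], collapse = ", ")
    ))
  }
  setNames(task, measures)
}

#' Write a simulated cohort to plain-text files
#'
#' Emits `participants.csv`, `scales.csv` (long format, one row per
#' participant x scale x item), `logs.jsonl` and `truth.csv` under `dir`.
#'
#' @param cohort A `cohort` object.
#' @param dir Output directory (created if missing).
#' @return Invisibly, the directory.
#' @export
write_cohort <- function(cohort, dir) {
  stopifnot(inherits(cohort, "cohort"))
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  readr::write_csv(cohort$participants, file.path(dir, "participants.csv"), na = "")
  scales_long <- cohort$scales %>%
    mutate(item_index = map(.data$responses, seq_along)) %>%
    unnest(c("responses", "item_index")) %>%
    select("participant_id", "scale_id", "item_index",
           response = "responses", "completion_time_s")
  readr::write_csv(scales_long, file.path(dir, "scales.csv"))
  write_event_logs(cohort$logs$log, file.path(dir, "logs.jsonl"))
  if (!is.null(cohort$truth)) {
    readr::write_csv(cohort$truth, file.path(dir, "truth.csv"))
  }
  invisible(dir)
}

#' Read a long-format scales table written by [write_cohort()]
#'
#' @param path Path to `scales.csv`.
#' @return A nested scales table as used by the quality filters.
#' @export
read_scales <- function(path) {
  readr::read_csv(path, show_col_types = FALSE, progress = FALSE) %>%
    arrange(.data$participant_id, .data$scale_id, .data$item_index) %>%
    group_by(.data$participant_id, .data$scale_id) %>%
    summarise(
      responses = list(as.integer(.data$response)),
      completion_time_s = first(.data$completion_time_s),
      .groups = "drop"
    )
}
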