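#' @title Careless-responding filters
#' @description Online cohorts contain participants who click through
#'   questionnaires without engaging (or are bots). Three per-scale filters
#'   flag them: completing a scale faster than 1 s per item, answering every
#'   item of a scale identically (zero variance), and having a response
#'   variance more than three standard deviations above the cohort's mean
#'   variance on that scale (random clicking). A participant is removed when
#'   any single filter flags more than two of their scales.
#'
#'   All three operate on a long *scales table*: one row per participant x
#'   scale with columns `participant_id`, `scale_id`, `responses` (list
#'   column of integer item vectors) and `completion_time_s`.
#' @name quality_filters
NULL

#' Speed filter: flag scales completed in under 1 s per item
#'
#' @param scales A scales table (see [quality_filters]).
#' @param min_seconds_per_item Threshold; a scale is flagged iff
#'   `completion_time_s / n_items` is strictly below it.
#' @return A tibble with `participant_id` and `speed_flags`, the number of
#'   flagged scales per participant.
#' @export
speed_filter <- function(scales, min_seconds_per_item = 1) {
  scales <- as_tibble(scales)
  n_items <- map_int(scales$responses, length)
  if (any(n_items == 0)) abort("scale with zero items")
  if (any(scales$completion_time_s <= 0)) abort("completion_time_s must be positive")
  scales %>%
    mutate(flag = .data$completion_time_s / n_items < min_seconds_per_item) %>%
    group_by(.data$participant_id) %>%
    summarise(speed_flags = sum(.data$flag), .groups = "drop")
}

#' Zero-variance filter: flag scales answered with a single repeated response
#'
#' A one-item scale is degenerate and counts as zero-variance; cohort
#' configurations should exclude singleton scales from filtering.
#'
#' @param scales A scales table (see [quality_filters]).
#' @return A tibble with `participant_id` and `zero_variance_flags`.
#' @export
zero_variance_filter <- function(scales) {
  scales <- as_tibble(scales)
  if (any(map_int(scales$responses, length) == 0)) abort("scale with zero items")
  scales %>%
    mutate(flag = map_lgl(.data$responses, ~ length(unique(.x)) == 1L)) %>%
    group_by(.data$participant_id) %>%
    summarise(zero_variance_flags = sum(.data$flag), .groups = "drop")
}

#' Outlier-variance filter: flag scales with extreme response variance
#'
#' For each scale, every participant's response variance (sample, n-1) is
#' compared with the cohort's distribution of variances on that scale; a
#' participant is flagged on the scale iff their variance is strictly greater
#' than mean + `outlier_sd` standard deviations. Thresholds are computed once
#' on the cohort passed in (no iterative re-filtering).
#'
#' @param scales A scales table for the whole cohort (at least 3
#'   participants per scale).
#' @param outlier_sd Number of standard deviations above the mean variance
#'   (default 3).
#' @return A tibble with `participant_id` and `outlier_variance_flags`.
#' @export
outlier_variance_filter <- function(scales, outlier_sd = 3) {
  scales <- as_tibble(scales)
  scales <- scales %>% mutate(v = map_dbl(.data$responses, var))
  counts <- scales %>% count(.data$scale_id)
  if (any(counts$n < 3)) {
    abort("outlier-variance filter needs at least 3 participants per scale")
  }
  scales %>%
    group_by(.data$scale_id) %>%
    mutate(flag = .data$v > mean(.data$v) + outlier_sd * sd(.data$v)) %>%
    ungroup() %>%
    group_by(.data$participant_id) %>%
    summarise(outlier_variance_flags = sum(.data$flag), .groups = "drop")
}

#' Apply the three careless-responding filters to a cohort
#'
#' Flag counts are computed per filter on the full original cohort; a
#' participant is removed iff any one filter flags strictly more than
#' `max_flagged_scales` of their scales. Thresholds are not re-estimated
#' after removals, so filtering is idempotent on the kept cohort.
#'
#' @param cohort A `cohort` object (see [simulate_cohort()]) or a bare
#'   scales table.
#' @param config Configuration list; `config$filters` carries the
#'   thresholds.
#' @return A list with `cohort` (the kept cohort, same class as the input)
#'   and `report`, a tibble with one row per original participant: the three
#'   flag counts, `removed`, and a comma-separated `reason` string.
#' @export
apply_filters <- function(cohort, config = default_config()) {
  fc <- config$filters
  scales <- if (inherits(cohort, "cohort")) cohort$scales else as_tibble(cohort)
  ids <- unique(scales$participant_id)

  report <- tibble(participant_id = ids) %>%
    left_join(speed_filter(scales, fc$min_seconds_per_item), by = "participant_id") %>%
    left_join(zero_variance_filter(scales), by = "participant_id") %>%
    left_join(outlier_variance_filter(scales, fc$outlier_sd), by = "participant_id") %>%
    mutate(across(ends_with("_flags"), ~ coalesce(.x, 0L)))

  k <- fc$max_flagged_scales
  report <- report %>%
    mutate(
      removed = .data$speed_flags > k | .data$zero_variance_flags > k |
        .data$outlier_variance_flags > k,
      reason = pmap_chr(
        list(.data$speed_flags > k, .data$zero_variance_flags > k,
             .data$outlier_variance_flags > k),
        function(s, z, o) {
          paste(c("speed", "zero_variance", "outlier_variance")[c(s, z, o)],
                collapse = ",")
        }
      )
    )

  kept_ids <- report$participant_id[!report$removed]
  kept <- if (inherits(cohort, "cohort")) {
    cohort$participants <- cohort$participants %>%
      filter(.data$participant_id %in% kept_ids)
    cohort$scales <- cohort$scales %>%
      filter(.data$participant_id %in% kept_ids)
    cohort$logs <- cohort$logs %>%
      filter(.data$participant_id %in% kept_ids)
    if (!is.null(cohort$truth)) {
      cohort$truth <- cohort$truth %>%
        filter(.data$participant_id %in% kept_ids)
    }
    cohort
  } else {
    scales %>% filter(.data$participant_id %in% kept_ids)
  }
  list(cohort = kept, report = report)
}
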