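#' Generate a spatial working memory (SWM) battery
#'
#' Six trials of the box-search task, one at each difficulty level (4, 6, 8,
#' 10, 12 and 14 boxes, ascending). A trial consists of as many search
#' sequences as boxes; in each sequence one box hides a token, drawn
#' uniformly among the boxes not yet emptied, so over a trial every box
#' hides the token exactly once and a token never reappears in an emptied
#' box. Box positions are cosmetic, re-randomized each trial to discourage
#' stereotyped search, and excluded from scoring.
#'
#' @param seed Integer seed.
#' @param config Configuration list; `config$swm$box_levels` gives the
#'   difficulty levels.
#' @return An `swm_battery` tibble with one row per trial: `trial` (0-based),
#'   `n_boxes`, `positions` (list of n_boxes x 2 coordinate matrices) and
#'   `token_schedule` (list; element s is the 0-based box holding the token
#'   in sequence s).
#' @export
generate_swm_battery <- function(seed, config = default_config()) {
  levels <- sort(config$swm$box_levels)
  with_seed(derive_seed(seed, "swm_battery"), {
    rows <- map(seq_along(levels), function(i) {
      n <- levels[i]
      positions <- cbind(x = runif(n), y = runif(n))
      emptied <- integer(0)
      schedule <- integer(n)
      for (s in seq_len(n)) {
        schedule[s] <- place_token(n, emptied)
        emptied <- c(emptied, schedule[s])
      }
      tibble(
        trial = i - 1L, n_boxes = n,
        positions = list(positions), token_schedule = list(schedule)
      )
    })
    battery <- bind_rows(rows)
    structure(battery,
      class = c("swm_battery", class(battery)),
      seed = as.integer(seed)
    )
  })
}

#' Place the next SWM token
#'
#' Draws the token's box uniformly among the boxes not yet emptied, using the
#' current RNG state. A token is never placed in an emptied box.
#'
#' @param n_boxes Number of boxes in the trial.
#' @param emptied Integer vector of 0-based box ids already emptied.
#' @return A 0-based box id.
#' @export
place_token <- function(n_boxes, emptied = integer(0)) {
  candidates <- setdiff(seq_len(n_boxes) - 1L, emptied)
  if (!length(candidates)) abort("no non-emptied boxes remain")
  candidates[sample.int(length(candidates), 1L)]
}

#' Score an SWM event log
#'
#' Replays each trial's search sequences. A **within error** is any re-open
#' of a box already opened earlier in the same sequence; a **between error**
#' is any open of a box already emptied (token found) earlier in the same
#' trial. A single open can count as both. The **strategy score** of a trial
#' is the number of distinct boxes used to start its sequences (lower =
#' more systematic); the battery score sums it over all six trials.
#'
#' @param log An [event_log] with `task_id == "swm"` and matching seed.
#' @param battery An `swm_battery` from [generate_swm_battery()].
#' @param double_count If `TRUE` (default), an open that violates both
#'   definitions at once -- re-opening an emptied box already opened this
#'   sequence -- increments both counters; if `FALSE` it counts only as a
#'   between error.
#' @return A one-row tibble: `n_between_errors`, `n_within_errors`,
#'   `strategy_score`.
#' @export
score_swm <- function(log, battery, double_count = TRUE) {
  stopifnot(inherits(log, "event_log"), inherits(battery, "swm_battery"))
  if (log$task_id != "swm") abort("score_swm needs an swm event log")
  if (log$seed != attr(battery, "seed")) {
    abort("log seed does not match battery seed")
  }
  ev <- log$events
  n_between <- 0L; n_within <- 0L; strategy <- 0L
  if (!nrow(ev)) {
    return(tibble(
      n_between_errors = 0L, n_within_errors = 0L, strategy_score = 0L
    ))
  }
  kind <- ev$kind
  box_id <- ev$box_id
  starts <- kind == "trial_start"
  if (!starts[1]) abort("swm log must begin with trial_start")
  trial_of <- ev$trial[starts][cumsum(starts)]

  for (tr in unique(trial_of)) {
    in_tr <- trial_of == tr
    b <- which(battery$trial == tr)
    if (!length(b)) abort(paste0("trial index out of range: ", tr))
    n_boxes <- battery$n_boxes[b]
    schedule <- battery$token_schedule[[b]]

    kind_tr <- kind[in_tr]
    box_tr <- box_id[in_tr]
    seq_id <- cumsum(kind_tr == "sequence_start")
    emptied <- integer(0)
    start_boxes <- integer(0)
    for (s in seq_len(max(seq_id, 0L))) {
      in_s <- seq_id == s
      opens <- box_tr[in_s & kind_tr == "open"]
      if (anyNA(opens)) abort("open event without box_id")
      if (any(opens < 0 | opens >= n_boxes)) {
        abort(paste0("open of unknown box_id in trial ", tr))
      }
      if (!any(kind_tr[in_s] == "token_found")) {
        abort(paste0("trial ", tr, " sequence ", s, ": no token_found"))
      }
      if (tail(opens, 1) != schedule[s]) {
        abort(paste0(
          "trial ", tr, " sequence ", s, ": token_found at box ",
          tail(opens, 1), " but scheduled at box ", schedule[s]
        ))
      }
      within_hits <- duplicated(opens)
      between_hits <- opens %in% emptied
      if (!double_count) within_hits <- within_hits & !between_hits
      n_within <- n_within + sum(within_hits)
      n_between <- n_between + sum(between_hits)
      start_boxes <- c(start_boxes, opens[1])
      emptied <- c(emptied, schedule[s])
    }
    strategy <- strategy + length(unique(start_boxes))
  }
  tibble(
    n_between_errors = n_between, n_within_errors = n_within,
    strategy_score = strategy
  )
}
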