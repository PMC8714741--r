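#' Generate a d2 attention-test battery
#'
#' Produces the 20 pages of the digital d2 test of attention. Each page is a
#' 7-column by 6-row grid of 42 items; an item carries 1-4 dots and a notch
#' on its left or right side, and is a target exactly when it has 2 dots and
#' a left notch. Non-targets fall into three distractor classes: correct
#' notch with wrong dot count, wrong notch with the correct dot count, or
#' wrong notch and wrong dots. Per page, the number of targets is
#' `round(42 * target_prop)`; the remaining items are split evenly across the
#' three distractor classes with any remainder assigned by a seeded draw.
#' Item positions are shuffled per page. Generation is deterministic in
#' `seed`.
#'
#' @param seed Integer seed.
#' @param config Configuration list, see [default_config()]; `config$d2`
#'   supplies the page count, grid shape, target proportion and distractor
#'   mix.
#' @return A `d2_battery`: a tibble with one row per item and columns
#'   `page` (0-based), `index` (0-based, row-major), `dots`, `notch`
#'   (`"left"`/`"right"`), `class` (`"target"` or a distractor class) and
#'   `is_target`.
#' @export
#' @examples
#' b <- generate_d2_battery(seed = 1)
#' nrow(b) # 20 pages x 42 items
generate_d2_battery <- function(seed, config = default_config()) {
  cfg <- config$d2
  n_items <- cfg$n_rows * cfg$n_cols
  mix <- cfg$distractor_mix
  if (abs(sum(mix) - 1) > 1e-8) {
    abort("d2 distractor_mix proportions must sum to 1")
  }
  if (cfg$target_prop < 0 || cfg$target_prop > 1) {
    abort("d2 target_prop must lie in [0, 1]")
  }
  n_targets <- as.integer(round(n_items * cfg$target_prop))
  n_dis <- n_items - n_targets
  wrong_dots <- c(1L, 3L, 4L)

  with_seed(derive_seed(seed, "d2_battery"), {
    total <- cfg$n_pages * n_items
    cls_all <- character(total)
    for (pg in seq_len(cfg$n_pages)) {
      base <- floor(n_dis * mix)
      rem <- n_dis - sum(base)
      counts <- base
      if (rem > 0) {
        extra <- sample.int(3L, rem)
        counts[extra] <- counts[extra] + 1L
      }
      cls_all[(pg - 1L) * n_items + seq_len(n_items)] <- sample(rep.int(
        c("target", "notch_ok_dots_wrong", "notch_wrong_dots_ok", "both_wrong"),
        c(n_targets, counts)
      ))
    }
    dots <- integer(total)
    notch <- character(total)
    tgt <- cls_all == "target"
    dots[tgt] <- 2L
    notch[tgt] <- "left"
    i1 <- cls_all == "notch_ok_dots_wrong"
    dots[i1] <- sample(wrong_dots, sum(i1), replace = TRUE)
    notch[i1] <- "left"
    i2 <- cls_all == "notch_wrong_dots_ok"
    dots[i2] <- 2L
    notch[i2] <- "right"
    i3 <- cls_all == "both_wrong"
    dots[i3] <- sample(wrong_dots, sum(i3), replace = TRUE)
    notch[i3] <- "right"
    battery <- tibble(
      page = rep(seq_len(cfg$n_pages) - 1L, each = n_items),
      index = rep(seq_len(n_items) - 1L, cfg$n_pages),
      dots = dots, notch = notch, class = cls_all, is_target = tgt
    )
    structure(battery,
      class = c("d2_battery", class(battery)),
      seed = as.integer(seed),
      n_pages = cfg$n_pages, n_items_per_page = n_items,
      page_duration_ms = cfg$page_duration_ms
    )
  })
}

#' Score a d2 event log
#'
#' Replays navigation and marking events against the generated battery.
#' The cursor starts at item 0 on each `page_start`; `nav_right`/`nav_left`
#' move it within the 42-item page (clamped at the edges); `mark` marks the
#' item under the cursor. Per page, the number of items processed is one plus
#' the maximum item index the cursor reached (backtracking never reduces it),
#' and omissions are counted only among processed items. Counts are summed
#' across pages.
#'
#' @param log An [event_log] with `task_id == "d2"` whose seed matches the
#'   battery.
#' @param battery A `d2_battery` from [generate_d2_battery()].
#' @return A one-row tibble: `n_items`, `n_correct`, `n_omission`,
#'   `n_commission`, `n_errors` (= omissions + commissions) and
#'   `error_rate` (percent, errors per 100 processed items).
#' @export
score_d2 <- function(log, battery) {
  stopifnot(inherits(log, "event_log"), inherits(battery, "d2_battery"))
  if (log$task_id != "d2") abort("score_d2 needs a d2 event log")
  if (log$seed != attr(battery, "seed")) {
    abort("log seed does not match battery seed")
  }
  n_pages <- attr(battery, "n_pages")
  npp <- attr(battery, "n_items_per_page")
  # page -> logical target vector, in item-index order
  tgt_by_page <- split(battery$is_target[order(battery$page, battery$index)],
                       battery$page[order(battery$page, battery$index)])

  ev <- log$events
  n_items <- 0L; n_correct <- 0L; n_omission <- 0L; n_commission <- 0L

  cur_page <- NA_integer_
  cursor <- 0L; max_idx <- 0L; marked <- integer(0)

  finalize <- function() {
    tgt <- tgt_by_page[[as.character(cur_page)]]
    if (is.null(tgt)) abort(paste0("page index out of range: ", cur_page))
    processed <- max_idx + 1L
    seen <- tgt[seq_len(processed)]
    mk <- unique(marked) + 1L
    hit <- seen[mk]
    n_items <<- n_items + processed
    n_correct <<- n_correct + sum(hit)
    n_commission <<- n_commission + sum(!hit)
    n_omission <<- n_omission + (sum(seen) - sum(hit))
  }

  kinds <- ev$kind
  pages <- if ("page" %in% names(ev)) ev$page else rep(NA_integer_, nrow(ev))
  for (r in seq_along(kinds)) {
    k <- kinds[r]
    if (k == "page_start") {
      if (!is.na(cur_page)) finalize()
      pg <- pages[r]
      if (is.na(pg)) abort(paste0("event ", r, ": page_start without page index"))
      cur_page <- as.integer(pg)
      cursor <- 0L; max_idx <- 0L; marked <- integer(0)
    } else if (k == "nav_right") {
      if (is.na(cur_page)) abort(paste0("event ", r, ": navigation before page_start"))
      cursor <- min(cursor + 1L, npp - 1L)
      if (cursor > max_idx) max_idx <- cursor
    } else if (k == "nav_left") {
      if (is.na(cur_page)) abort(paste0("event ", r, ": navigation before page_start"))
      cursor <- max(cursor - 1L, 0L)
    } else if (k == "mark") {
      if (is.na(cur_page)) abort(paste0("event ", r, ": mark with no cursor position"))
      marked <- c(marked, cursor)
    } else if (k == "page_end") {
      if (!is.na(cur_page)) finalize()
      cur_page <- NA_integer_
    }
  }
  if (!is.na(cur_page)) finalize()

  n_errors <- n_omission + n_commission
  tibble(
    n_items = n_items, n_correct = n_correct,
    n_omission = n_omission, n_commission = n_commission,
    n_errors = n_errors,
    error_rate = d2_error_rate(n_errors, n_items)
  )
}

#' d2 error rate
#'
#' Errors per 100 processed items: `100 * n_errors / n_items`, defined as 0
#' when no items were processed. This per-items definition reproduces the
#' magnitude of published cohort means (on the order of 10), which an
#' errors-per-second reading cannot.
#'
#' @param n_errors Total errors (omissions + commissions).
#' @param n_items Items processed.
#' @return The error rate in percent, vectorized over inputs.
#' @export
#' @examples
#' d2_error_rate(42, 420) # 10
d2_error_rate <- function(n_errors, n_items) {
  stopifnot(all(n_items >= 0), all(n_errors >= 0))
  ifelse(n_items == 0, 0, 100 * n_errors / n_items)
}
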