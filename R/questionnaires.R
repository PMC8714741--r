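#' Score the PHQ-9 depression module
#'
#' Sums the nine 0-3 frequency items into a 0-27 total and attaches the
#' conventional severity band. The optional tenth "difficulty" item is
#' collected by the instrument but never scored.
#'
#' @param items Integer vector of exactly 9 responses, each in 0-3.
#' @param difficulty_item Optional integer, stored but unscored.
#' @return A one-row tibble with `total` (0-27) and `level` (ordered factor:
#'   minimal < mild < moderate < moderately severe < severe).
#' @export
#' @examples
#' score_phq9(c(1, 1, 1, 1, 1, 1, 1, 0, 0)) # total 7, mild
score_phq9 <- function(items, difficulty_item = NULL) {
  if (length(items) != 9) {
    abort(paste0("PHQ-9 needs exactly 9 items, got ", length(items)))
  }
  items <- as.integer(items)
  if (anyNA(items) || any(items < 0 | items > 3)) {
    abort("PHQ-9 item responses must be integers in 0-3")
  }
  total <- sum(items)
  tibble(total = total, level = phq9_level(total))
}

#' PHQ-9 severity level
#'
#' Maps totals to the standard severity bands: 0-4 minimal, 5-9 mild, 10-14
#' moderate, 15-19 moderately severe, 20-27 severe.
#'
#' @param total Integer vector of PHQ-9 totals in 0-27.
#' @return An ordered factor of severity levels.
#' @export
phq9_level <- function(total) {
  if (anyNA(total) || any(total < 0 | total > 27)) {
    abort("PHQ-9 total must lie in 0-27")
  }
  lv <- c("minimal", "mild", "moderate", "moderately severe", "severe")
  cut(total,
    breaks = c(-1, 4, 9, 14, 19, 27), labels = lv,
    ordered_result = TRUE
  )
}
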