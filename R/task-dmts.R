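#' Generate a delayed matching-to-sample (DMTS) battery
#'
#' Produces 40 trials: 10 at each retention delay (0, 1, 4 and 12 s by
#' default), interleaved in seeded random order (or blocked by delay via
#' `config$dmts$order`). Each trial shows a prompt -- a 4-quadrant abstract
#' pattern, one color and one form per quadrant -- for 4,500 ms, then after
#' the delay four choice patterns:
#'
#' * the **match**, identical to the prompt;
#' * a **novel distractor**, differing from the prompt in both color and
#'   form in every non-shared quadrant;
#' * a **color distractor** with the prompt's forms but the novel
#'   distractor's colors (selecting it is a *color error*: correct form,
#'   incorrect color);
#' * a **shape distractor** with the prompt's colors but the novel
#'   distractor's forms.
#'
#' All four choices agree with the prompt (color and form) in one seeded
#' shared quadrant, which discourages single-quadrant mnemonics. Novel colors
#' and forms are drawn without replacement from palette entries unused by the
#' prompt; display positions of the four roles are a seeded permutation per
#' trial.
#'
#' @param seed Integer seed.
#' @param assigned_shape Optional `(color_id, form_id)` pair cosmetically
#'   assigned to the participant (used as task background; not scored).
#' @param config Configuration list; `config$palettes` sizes must permit
#'   three novel colors and forms beyond the prompt's.
#' @return A `dmts_battery` tibble, one row per trial, with columns `trial`
#'   (0-based), `delay_ms`, `shared_quadrant` (0-3), `prompt` (list of 4x2
#'   integer matrices, columns color/form, 0-based palette ids), `choices`
#'   (list of 4 such matrices in display order) and `roles` (list of the
#'   role label of each display position).
#' @export
generate_dmts_battery <- function(seed, assigned_shape = NULL,
                                  config = default_config()) {
  cfg <- config$dmts
  pal <- config$palettes
  if (pal$n_colors < 7 || pal$n_forms < 7) {
    abort("palette exhaustion: need at least 7 colors and 7 forms for novel draws")
  }
  delays <- rep(cfg$delays_ms, each = cfg$n_per_delay)
  n_trials <- length(delays)
  roles_all <- c("match", "color_distractor", "shape_distractor", "novel_distractor")

  with_seed(derive_seed(seed, "dmts_battery"), {
    delays <- if (identical(cfg$order, "interleaved")) sample(delays) else delays
    shared_v <- integer(n_trials)
    prompt_l <- vector("list", n_trials)
    choices_l <- vector("list", n_trials)
    roles_l <- vector("list", n_trials)
    for (i in seq_len(n_trials)) {
      prompt_col <- sample.int(pal$n_colors, 4, replace = TRUE) - 1L
      prompt_form <- sample.int(pal$n_forms, 4, replace = TRUE) - 1L
      shared <- sample.int(4L, 1L)
      other <- setdiff(1:4, shared)
      free_col <- setdiff(seq_len(pal$n_colors) - 1L, unique(prompt_col))
      free_form <- setdiff(seq_len(pal$n_forms) - 1L, unique(prompt_form))
      if (length(free_col) < 3 || length(free_form) < 3) {
        abort("palette exhaustion while drawing novel colors/forms")
      }
      novel_col <- free_col[sample.int(length(free_col), 3)]
      novel_form <- free_form[sample.int(length(free_form), 3)]

      pat <- function(col, form) {
        m <- cbind(color = col, form = form)
        rownames(m) <- NULL
        m
      }
      prompt <- pat(prompt_col, prompt_form)
      novel <- prompt
      novel[other, "color"] <- novel_col
      novel[other, "form"] <- novel_form
      color_d <- prompt # prompt forms ...
      color_d[other, "color"] <- novel_col # ... novel colors
      shape_d <- prompt # prompt colors ...
      shape_d[other, "form"] <- novel_form # ... novel forms

      by_role <- list(
        match = prompt, color_distractor = color_d,
        shape_distractor = shape_d, novel_distractor = novel
      )
      order_roles <- roles_all[sample.int(4L)]
      shared_v[i] <- shared - 1L
      prompt_l[[i]] <- prompt
      choices_l[[i]] <- unname(by_role[order_roles])
      roles_l[[i]] <- order_roles
    }
    battery <- tibble(
      trial = seq_len(n_trials) - 1L, delay_ms = delays,
      shared_quadrant = shared_v, prompt = prompt_l,
      choices = choices_l, roles = roles_l
    )
    structure(battery,
      class = c("dmts_battery", class(battery)),
      seed = as.integer(seed),
      prompt_duration_ms = cfg$prompt_duration_ms,
      assigned_shape = assigned_shape
    )
  })
}

#' Classify a DMTS selection by the role of the chosen pattern
#'
#' @param choice_role Character vector of role labels (`match`,
#'   `color_distractor`, `shape_distractor`, `novel_distractor`).
#' @return The matching outcome labels: `correct`, `color_error`,
#'   `shape_error`, `both_error`.
#' @export
#' @examples
#' classify_selection(c("match", "novel_distractor"))
classify_selection <- function(choice_role) {
  mapping <- c(
    match = "correct",
    color_distractor = "color_error",
    shape_distractor = "shape_error",
    novel_distractor = "both_error"
  )
  bad <- setdiff(unique(choice_role), names(mapping))
  if (length(bad)) {
    abort(paste0("invalid choice role(s): ", paste(bad, collapse = ", ")))
  }
  unname(mapping[choice_role])
}

#' Score a DMTS event log
#'
#' Only the first selection of each trial is scored (the task forces
#' continued selection until the match, which is logged but unscored); its
#' outcome is the classification of the selected pattern's role, and its
#' latency is the time from choice onset to that first selection. The
#' average latency is taken over all scored trials, correct and error alike.
#'
#' @param log An [event_log] with `task_id == "dmts"` and matching seed.
#' @param battery A `dmts_battery` from [generate_dmts_battery()].
#' @return A one-row tibble: `n_trials`, `n_correct`, `avg_latency_ms`,
#'   `n_color_errors`, `n_shape_errors`, `n_both_errors`. The four outcome
#'   counts partition the scored trials.
#' @export
score_dmts <- function(log, battery) {
  stopifnot(inherits(log, "event_log"), inherits(battery, "dmts_battery"))
  if (log$task_id != "dmts") abort("score_dmts needs a dmts event log")
  if (log$seed != attr(battery, "seed")) {
    abort("log seed does not match battery seed")
  }
  ev <- log$events
  if (!nrow(ev)) {
    return(tibble(
      n_trials = 0L, n_correct = 0L, avg_latency_ms = NA_real_,
      n_color_errors = 0L, n_shape_errors = 0L, n_both_errors = 0L
    ))
  }
  # carry the current trial index forward from each trial_start
  kind <- ev$kind
  tms <- ev$t
  starts <- kind == "trial_start"
  if (!starts[1]) abort("dmts log must begin with trial_start")
  trial_of <- ev$trial[starts][cumsum(starts)]
  choice_idx <- ev$choice_index

  trials <- unique(trial_of)
  outcomes <- character(length(trials))
  latencies <- numeric(length(trials))
  for (j in seq_along(trials)) {
    tr <- trials[j]
    in_tr <- trial_of == tr
    t_on <- tms[in_tr & kind == "choices_on"]
    if (!length(t_on)) abort(paste0("trial ", tr, ": no choices_on event"))
    sel <- which(in_tr & kind == "select")
    if (!length(sel)) abort(paste0("trial ", tr, ": trial with no selections"))
    b <- which(battery$trial == tr)
    if (!length(b)) abort(paste0("trial index out of range: ", tr))
    roles <- battery$roles[[b]]
    sel_roles <- roles[choice_idx[sel] + 1L]
    if (anyNA(sel_roles)) abort(paste0("trial ", tr, ": choice_index out of range"))
    hit <- which(sel_roles == "match")
    if (!length(hit)) abort(paste0("trial ", tr, ": sequence does not end with the match"))
    if (hit[1] < length(sel)) {
      abort(paste0("trial ", tr, ": selection after match already chosen"))
    }
    outcomes[j] <- classify_selection(sel_roles[1])
    latencies[j] <- tms[sel[1]] - t_on[1]
  }
  tibble(
    n_trials = length(outcomes),
    n_correct = sum(outcomes == "correct"),
    avg_latency_ms = mean(latencies),
    n_color_errors = sum(outcomes == "color_error"),
    n_shape_errors = sum(outcomes == "shape_error"),
    n_both_errors = sum(outcomes == "both_error")
  )
}
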