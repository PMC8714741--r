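#' @title Generative participant model
#' @description The simulator is the package's test harness: a latent
#'   depression severity (standardized) drives both PHQ-9 item responses
#'   (through a graded ordinal response model) and task-error propensities
#'   (through monotone links configured in `default_config()$simulate`).
#'   Agents then play the three task batteries by the task rules, emitting
#'   event logs that satisfy every scorer precondition, so the full
#'   simulate -> score -> filter -> fit loop can be checked for parameter
#'   recovery. The behavioral model is a harness, not a scientific claim;
#'   its calibration constants are chosen so cohort-level metric means and
#'   spreads land near the validation study's descriptive statistics.
#' @name simulate
NULL

# Draw one participant's latent profile: severity plus all behavioral
# parameters, each a monotone function of severity with individual noise.
participant_profile <- function(severity, config = default_config()) {
  sc <- config$simulate
  d2 <- sc$d2
  dm <- sc$dmts
  sw <- sc$swm
  het_d2 <- rnorm(1, 0, d2$heterogeneity)
  list(
    severity = severity,
    d2_p_omission = plogis(d2$omission_base + d2$severity_slope * severity + het_d2),
    d2_p_commission = plogis(d2$commission_base + d2$severity_slope * severity + het_d2),
    d2_items_per_page = pmin(pmax(round(rnorm(
      config$d2$n_pages, d2$items_per_page_mean, d2$items_per_page_sd
    )), 1L), config$d2$n_rows * config$d2$n_cols),
    dmts_fidelity_base = dm$fidelity_base - dm$severity_slope * severity +
      rnorm(1, 0, dm$heterogeneity),
    dmts_delay_slope = dm$delay_slope,
    dmts_latency_meanlog = dm$latency_meanlog +
      dm$latency_severity_slope * severity + rnorm(1, 0, 0.15),
    dmts_latency_sdlog = dm$latency_sdlog,
    swm_p_error = plogis(sw$error_base + sw$severity_slope * severity +
      rnorm(1, 0, sw$heterogeneity)),
    swm_within_share = sw$within_share,
    swm_start_discipline = sw$start_discipline,
    swm_start_explore = sw$start_explore
  )
}

# Memory fidelity at a given delay: probability the agent's first DMTS
# selection is the match. Non-increasing in delay and in severity.
dmts_fidelity <- function(profile, delay_ms) {
  plogis(profile$dmts_fidelity_base -
    profile$dmts_delay_slope * sqrt(delay_ms / 1000))
}

#' Simulate PHQ-9 item responses for a given severity
#'
#' Each item follows an ordered 4-category graded model: the probability of
#' endorsing at least category k is `plogis(a * (severity - t_k - d_i))`,
#' with common discrimination `a`, category thresholds `t_k`, and an item
#' shift `d_i` spreading item difficulty. The expected total is strictly
#' increasing in severity and covers 0-27 in the limits.
#'
#' @param severity Latent severity (standardized scale).
#' @param config Configuration list; `config$simulate$phq9` holds the item
#'   parameters.
#' @return Integer vector of 9 responses in 0-3 (uses the current RNG
#'   state).
#' @export
simulate_phq9 <- function(severity, config = default_config()) {
  simulate_phq9_vec(severity, config)
}

# One item draw: a single uniform compared against the decreasing exceedance
# probabilities P(X >= k) yields a draw with exactly those margins.
simulate_phq9_item <- function(severity, thresholds, discrimination, shift = 0) {
  p_ge <- plogis(discrimination * (severity - thresholds - shift))
  u <- runif(1)
  as.integer(sum(u < p_ge))
}

#' Play the three tasks with a behavioral agent
#'
#' Generates event logs for a participant profile against the three task
#' batteries. The agent obeys all task rules: it marks items as the cursor
#' sweeps each d2 page (15 s per page), keeps selecting DMTS choices until
#' the match is found, and searches SWM boxes until each token is found.
#' Error propensities come from the profile.
#'
#' @param profile A profile from the internal severity model (see
#'   [simulate_cohort()]), or constructed by hand for tests.
#' @param batteries A named list with elements `d2`, `dmts`, `swm`.
#' @param participant_id Identifier stamped on the logs.
#' @param seed The battery seed stamped on the logs.
#' @param config Configuration list.
#' @return A named list of three [event_log] objects.
#' @export
run_agents <- function(profile, batteries, participant_id = "p1",
                       seed = 1L, config = default_config()) {
  list(
    d2 = agent_d2(profile, batteries$d2, participant_id, seed, config),
    dmts = agent_dmts(profile, batteries$dmts, participant_id, seed, config),
    swm = agent_swm(profile, batteries$swm, participant_id, seed, config)
  )
}

agent_d2 <- function(profile, battery, participant_id, seed, config) {
  page_ms <- config$d2$page_duration_ms
  npp <- attr(battery, "n_items_per_page")
  is_target <- battery$is_target[order(battery$page, battery$index)]
  n_pages <- attr(battery, "n_pages")
  kpp <- rep_len(profile$d2_items_per_page, n_pages)

  t_all <- integer(0); kind_all <- character(0); page_all <- integer(0)
  for (pg in seq_len(n_pages) - 1L) {
    t0 <- pg * (page_ms + 1000L)
    k <- kpp[pg + 1]
    tgt <- is_target[pg * npp + seq_len(k)]
    mark <- ifelse(tgt,
      runif(k) > profile$d2_p_omission,
      runif(k) < profile$d2_p_commission
    )
    step <- page_ms %/% max(k, 1L)
    # item i is under the cursor from t0 + i*step; marks land mid-dwell
    nav_t <- t0 + step * seq_len(max(k - 1L, 0L))
    mark_t <- t0 + step * (seq_len(k) - 1L) + step %/% 2L
    t_page <- c(t0, nav_t, mark_t[mark], t0 + page_ms)
    k_page <- c("page_start", rep("nav_right", length(nav_t)),
                rep("mark", sum(mark)), "page_end")
    o <- order(t_page, match(k_page, c("page_start", "nav_right", "mark", "page_end")))
    t_all <- c(t_all, t_page[o])
    kind_all <- c(kind_all, k_page[o])
    page_all <- c(page_all, ifelse(k_page[o] %in% c("page_start", "page_end"),
                                   pg, NA_integer_))
  }
  event_log(participant_id, "d2", seed, tibble(
    t = as.integer(t_all), kind = kind_all, page = as.integer(page_all)
  ))
}

agent_dmts <- function(profile, battery, participant_id, seed, config) {
  prompt_ms <- attr(battery, "prompt_duration_ms")
  t <- 0L
  t_v <- integer(0); kind_v <- character(0)
  trial_v <- integer(0); choice_v <- integer(0)
  push <- function(tm, kind, trial = NA_integer_, choice = NA_integer_) {
    t_v <<- c(t_v, as.integer(tm)); kind_v <<- c(kind_v, kind)
    trial_v <<- c(trial_v, trial); choice_v <<- c(choice_v, choice)
  }
  for (i in seq_len(nrow(battery))) {
    tr <- battery$trial[i]
    roles <- battery$roles[[i]]
    push(t, "trial_start", trial = tr)
    t_on <- t + prompt_ms + battery$delay_ms[i]
    push(t_on, "choices_on")
    latency <- round(rlnorm(1, profile$dmts_latency_meanlog,
                            profile$dmts_latency_sdlog))
    p_ok <- dmts_fidelity(profile, battery$delay_ms[i])
    w <- config$simulate$dmts$error_weights
    first <- if (runif(1) < p_ok) {
      "match"
    } else {
      c("color_distractor", "shape_distractor", "novel_distractor")[
        sample.int(3L, 1L, prob = w)
      ]
    }
    tsel <- t_on + latency
    push(tsel, "select", choice = which(roles == first) - 1L)
    # forced continuation until the match (logged, unscored)
    if (first != "match") {
      remaining <- setdiff(roles, first)
      remaining <- sample(remaining)
      hit <- which(remaining == "match")
      for (rr in remaining[seq_len(hit)]) {
        tsel <- tsel + round(rlnorm(1, profile$dmts_latency_meanlog - 0.7,
                                    profile$dmts_latency_sdlog))
        push(tsel, "select", choice = which(roles == rr) - 1L)
      }
    }
    t <- tsel + 1500L
  }
  event_log(participant_id, "dmts", seed, tibble(
    t = t_v, kind = kind_v, trial = trial_v, choice_index = choice_v
  ))
}

agent_swm <- function(profile, battery, participant_id, seed, config) {
  t <- 0L
  t_v <- integer(0); kind_v <- character(0)
  trial_v <- integer(0); box_v <- integer(0)
  push <- function(kind, trial = NA_integer_, box = NA_integer_) {
    t <<- t + 299L + sample.int(601L, 1L)
    t_v <<- c(t_v, t); kind_v <<- c(kind_v, kind)
    trial_v <<- c(trial_v, trial); box_v <<- c(box_v, box)
  }
  for (i in seq_len(nrow(battery))) {
    n <- battery$n_boxes[i]
    schedule <- battery$token_schedule[[i]]
    push("trial_start", trial = battery$trial[i])
    boxes <- seq_len(n) - 1L
    emptied_b <- logical(n) # indexed by box id + 1
    started_b <- logical(n)
    prev_start <- NA_integer_
    for (s in seq_len(n)) {
      push("sequence_start")
      token <- schedule[s]
      opened_b <- logical(n)
      first <- TRUE
      repeat {
        # a lapse revisits an emptied box (between error) or, less often, a
        # box already opened this sequence (within error); if the targeted
        # pool is empty the search proceeds correctly instead
        pool <- if (runif(1) < profile$swm_p_error) {
          if (runif(1) < profile$swm_within_share) {
            boxes[opened_b]
          } else {
            boxes[emptied_b & !opened_b]
          }
        } else {
          integer(0)
        }
        box <- if (first && !is.na(prev_start) &&
                     runif(1) < profile$swm_start_discipline &&
                     !emptied_b[prev_start + 1L]) {
          prev_start
        } else if (first && any(!started_b & !emptied_b) &&
                     runif(1) < profile$swm_start_explore) {
          # start at a non-emptied box not yet used to begin a sequence
          fresh <- boxes[!started_b & !emptied_b]
          fresh[sample.int(length(fresh), 1L)]
        } else if (length(pool)) {
          pool[sample.int(length(pool), 1L)]
        } else {
          good <- boxes[!emptied_b & !opened_b]
          good[sample.int(length(good), 1L)]
        }
        if (first) {
          prev_start <- box
          started_b[box + 1L] <- TRUE
        }
        first <- FALSE
        push("open", box = box)
        opened_b[box + 1L] <- TRUE
        if (box == token) {
          push("token_found")
          break
        }
      }
      emptied_b[token + 1L] <- TRUE
    }
  }
  event_log(participant_id, "swm", seed, tibble(
    t = t_v, kind = kind_v, trial = trial_v, box_id = box_v
  ))
}

#' Simulate a full cohort
#'
#' Draws `n` participants (severity standard normal; age truncated normal;
#' gender Bernoulli), simulates their PHQ-9 and auxiliary scale responses
#' with per-scale completion times, generates per-participant task batteries
#' from derived seeds, and plays them with behavioral agents. Optionally
#' plants careless responders -- speeders, straight-liners and random
#' clickers -- that violate at least three scales of the corresponding
#' quality filter. A truth table of latent severities and behavioral
#' parameters accompanies the cohort for recovery tests.
#'
#' @param n Number of participants.
#' @param seed Master seed; every stream derives from it, so cohorts are
#'   exactly reproducible.
#' @param config Configuration list; `config$simulate` carries the cohort
#'   model, including `careless_fraction`.
#' @return A `cohort` object: list with `participants` (tibble:
#'   participant_id, age, gender, phq9, careless, careless_type), `scales`
#'   (long scales table, see [quality_filters]), `logs` (tibble:
#'   participant_id, task_id, log list-column) and `truth` (latent
#'   severities and agent parameters).
#' @export
simulate_cohort <- function(n = 90, seed = 1L, config = default_config()) {
  stopifnot(n >= 1)
  sc <- config$simulate
  with_seed(derive_seed(seed, "cohort"), {
    ids <- sprintf("p%04d", seq_len(n))
    severity <- rnorm(n)
    age <- round(rnorm(n, sc$age_mean, sc$age_sd))
    age <- pmin(pmax(age, sc$age_range[1]), sc$age_range[2])
    gender <- ifelse(runif(n) < sc$p_male, "male", "female")
    n_careless <- floor(n * sc$careless_fraction)
    careless <- c(rep(TRUE, n_careless), rep(FALSE, n - n_careless))
    careless <- sample(careless)
    types <- c("speeder", "straightliner", "clicker")
    careless_type <- ifelse(careless,
      types[(cumsum(careless) - 1L) %% 3L + 1L], NA_character_
    )

    participants <- vector("list", n)
    scales <- vector("list", n)
    logs <- vector("list", n)
    truth <- vector("list", n)
    for (i in seq_len(n)) {
      profile <- participant_profile(severity[i], config)
      phq9_items <- simulate_phq9_vec(severity[i], config)
      sc_tab <- simulate_scales(ids[i], phq9_items, careless_type[i], config)
      pseed <- derive_seed(seed, paste0("participant_", i))
      batteries <- list(
        d2 = generate_d2_battery(pseed, config),
        dmts = generate_dmts_battery(pseed, config = config),
        swm = generate_swm_battery(pseed, config)
      )
      ag <- run_agents(profile, batteries, ids[i], pseed, config)
      logs[[i]] <- tibble(
        participant_id = ids[i], task_id = c("d2", "dmts", "swm"),
        log = list(ag$d2, ag$dmts, ag$swm)
      )
      participants[[i]] <- tibble(
        participant_id = ids[i], age = age[i], gender = gender[i],
        phq9 = sum(phq9_items), careless = careless[i],
        careless_type = careless_type[i]
      )
      scales[[i]] <- sc_tab
      truth[[i]] <- tibble(
        participant_id = ids[i], severity = severity[i],
        d2_p_omission = profile$d2_p_omission,
        d2_p_commission = profile$d2_p_commission,
        dmts_fidelity_0s = dmts_fidelity(profile, 0),
        dmts_fidelity_12s = dmts_fidelity(profile, 12000),
        swm_p_error = profile$swm_p_error
      )
    }
    structure(
      list(
        participants = bind_rows(participants),
        scales = bind_rows(scales),
        logs = bind_rows(logs),
        truth = bind_rows(truth),
        seed = as.integer(seed)
      ),
      class = "cohort"
    )
  })
}

#' @export
print.cohort <- function(x, ...) {
  cat(sprintf(
    "<cohort> %d participants (seed %d), %d scale responses, %d event logs\n",
    nrow(x$participants), x$seed, nrow(x$scales), nrow(x$logs)
  ))
  invisible(x)
}

# One draw of all 9 PHQ-9 items for a severity (one uniform per item and
# category boundary handled inside simulate_phq9_item).
simulate_phq9_vec <- function(severity, config) {
  pp <- config$simulate$phq9
  shift <- seq(-pp$item_spread, pp$item_spread, length.out = 9)
  vapply(shift, function(d) {
    simulate_phq9_item(severity, pp$thresholds, pp$discrimination, d)
  }, integer(1))
}

# Scale responses (PHQ-9 + auxiliary inventories) for one participant,
# overridden for planted careless responders so that >= 3 scales violate
# the matching filter.
simulate_scales <- function(id, phq9_items, careless_type, config) {
  ss <- config$simulate$scales
  spi <- ss$seconds_per_item_range
  honest_time <- function(k) k * runif(1, spi[1], spi[2])
  aux_resp <- function(k, maxv) {
    center <- runif(1, 1, maxv - 1)
    r <- pmin(pmax(round(center + rnorm(k)), 0L), maxv)
    as.integer(r)
  }
  scale_ids <- c("phq9", ss$aux_ids)
  n_items <- c(phq9 = 9L, ss$aux_items)
  maxv <- c(phq9 = 3L, setNames(rep(ss$aux_max, length(ss$aux_ids)), ss$aux_ids))

  resp <- list(phq9 = as.integer(phq9_items))
  for (a in ss$aux_ids) resp[[a]] <- aux_resp(n_items[[a]], maxv[[a]])
  times <- vapply(scale_ids, function(s) honest_time(n_items[[s]]), numeric(1))

  if (!is.na(careless_type)) {
    if (careless_type == "speeder") {
      times <- n_items[scale_ids] * 0.3 # well under 1 s/item everywhere
    } else if (careless_type == "straightliner") {
      resp <- lapply(scale_ids, function(s) {
        rep(sample(0:maxv[[s]], 1L), n_items[[s]])
      })
      names(resp) <- scale_ids
    } else { # clicker: alternate scale extremes -> huge response variance
      resp <- lapply(scale_ids, function(s) {
        as.integer(rep_len(c(0L, maxv[[s]]), n_items[[s]]))
      })
      names(resp) <- scale_ids
    }
  }
  tibble(
    participant_id = id, scale_id = scale_ids,
    responses = unname(resp[scale_ids]),
    completion_time_s = unname(times[scale_ids])
  )
}

#' Simulate a tabular cohort from fitted regression coefficients
#'
#' Generative twin of a fitted linear model: predictors are drawn
#' independently (normal with the given moments; Bernoulli for binary
#' variables) and the outcome is their linear combination plus Gaussian
#' noise. Used for coefficient-recovery checks against published model fits.
#'
#' @param coefficients Named numeric vector including `(Intercept)`; other
#'   names must match rows of `predictor_moments`.
#' @param predictor_moments A data frame with columns `variable`, `dist`
#'   (`"normal"` or `"bernoulli"`), `mean` and `sd` (`sd` ignored for
#'   Bernoulli, where `mean` is the success probability).
#' @param residual_sd Positive residual standard deviation.
#' @param n Number of rows to draw.
#' @param outcome Name of the generated outcome column.
#' @return A tibble with one column per predictor plus the outcome.
#' @export
#' @examples
#' mom <- data.frame(
#'   variable = "x", dist = "normal", mean = 0, sd = 1
#' )
#' d <- simulate_from_fitted_model(
#'   c(`(Intercept)` = 1, x = 2), mom,
#'   residual_sd = 0.5, n = 100
#' )
simulate_from_fitted_model <- function(coefficients, predictor_moments,
                                       residual_sd, n, outcome = "phq9") {
  if (residual_sd <= 0) abort("residual_sd must be positive")
  stopifnot(all(is.finite(coefficients)), n >= 1)
  mom <- as_tibble(predictor_moments)
  vars <- setdiff(names(coefficients), "(Intercept)")
  missing <- setdiff(vars, mom$variable)
  if (length(missing)) {
    abort(paste0("no moments for predictor(s): ", paste(missing, collapse = ", ")))
  }
  out <- tibble(.rows = n)
  for (v in vars) {
    row <- mom[mom$variable == v, ]
    out[[v]] <- if (row$dist == "bernoulli") {
      rbinom(n, 1, row$mean)
    } else {
      rnorm(n, row$mean, row$sd)
    }
  }
  eta <- coefficients[["(Intercept)"]] +
    as.matrix(out[vars]) %*% coefficients[vars]
  out[[outcome]] <- as.numeric(eta) + rnorm(n, 0, residual_sd)
  out
}
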