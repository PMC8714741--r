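# Shared fixtures: hand-built event logs and agent profiles.

# A profile that never lapses: marks all and only targets, always picks the
# DMTS match, never revisits boxes. Used for perfect-agent invariants.
perfect_profile <- function(items_per_page = 21L) {
  list(
    severity = -99,
    d2_p_omission = 0, d2_p_commission = 0,
    d2_items_per_page = rep(items_per_page, 20),
    dmts_fidelity_base = 1e6, dmts_delay_slope = 0,
    dmts_latency_meanlog = 7.5, dmts_latency_sdlog = 0.2,
    swm_p_error = 0, swm_within_share = 0,
    swm_start_discipline = 0, swm_start_explore = 0.5
  )
}

# Profile with given d2 lapse probabilities, otherwise perfect.
lapse_profile <- function(p_om = 0, p_com = 0, fidelity_base = 1e6,
                          delay_slope = 0, swm_p_error = 0) {
  p <- perfect_profile()
  p$d2_p_omission <- p_om
  p$d2_p_commission <- p_com
  p$dmts_fidelity_base <- fidelity_base
  p$dmts_delay_slope <- delay_slope
  p$swm_p_error <- swm_p_error
  p$swm_within_share <- 0.2
  p
}

# Single-task agent plays (the exported surface runs all three at once).
agent_logs_dmts <- function(profile, battery, seed = attr(battery, "seed")) {
  cogmarker:::agent_dmts(profile, battery, "p", seed, default_config())
}

agent_logs_swm <- function(profile, battery, seed = attr(battery, "seed")) {
  cogmarker:::agent_swm(profile, battery, "p", seed, default_config())
}

# d2 log visiting items 0..(k-1) of page 0 and marking `mark_idx` (0-based).
d2_page_log <- function(seed, k, mark_idx, page = 0L) {
  nav_t <- 100L * seq_len(k - 1L)
  mark_t <- 100L * mark_idx + 50L
  ev <- rbind(
    data.frame(t = 0L, kind = "page_start", page = page),
    data.frame(t = nav_t, kind = rep("nav_right", length(nav_t)),
               page = rep(NA_integer_, length(nav_t))),
    data.frame(t = mark_t, kind = rep("mark", length(mark_t)),
               page = rep(NA_integer_, length(mark_t))),
    data.frame(t = 15000L, kind = "page_end", page = page)
  )
  ev <- ev[order(ev$t), ]
  event_log("px", "d2", seed, ev)
}

# DMTS log whose first selections follow `first_roles` (per trial, a role
# label); continues to the match when the first selection is wrong.
dmts_fixture_log <- function(battery, first_roles, latency_ms = 700L) {
  seed <- attr(battery, "seed")
  prompt_ms <- attr(battery, "prompt_duration_ms")
  rows <- list()
  t <- 0L
  for (i in seq_len(nrow(battery))) {
    roles <- battery$roles[[i]]
    tr <- battery$trial[i]
    t_on <- t + prompt_ms + battery$delay_ms[i]
    rows[[length(rows) + 1]] <- data.frame(
      t = c(t, t_on), kind = c("trial_start", "choices_on"),
      trial = c(tr, NA), choice_index = NA_integer_
    )
    first <- first_roles[i]
    sel_roles <- if (first == "match") "match" else c(first, "match")
    sel_t <- t_on + latency_ms + 500L * (seq_along(sel_roles) - 1L)
    rows[[length(rows) + 1]] <- data.frame(
      t = sel_t, kind = "select", trial = NA_integer_,
      choice_index = match(sel_roles, roles) - 1L
    )
    t <- max(sel_t) + 1000L
  }
  event_log("px", "dmts", seed, do.call(rbind, rows))
}

# SWM log from explicit per-sequence open lists (0-based box ids); each
# sequence must end at the scheduled token box.
swm_fixture_log <- function(battery, opens_by_trial) {
  seed <- attr(battery, "seed")
  rows <- list()
  t <- 0L
  tick <- function() {
    t <<- t + 500L
    t
  }
  for (i in seq_along(opens_by_trial)) {
    tr <- battery$trial[i]
    rows[[length(rows) + 1]] <- data.frame(
      t = tick(), kind = "trial_start", trial = tr, box_id = NA_integer_
    )
    for (opens in opens_by_trial[[i]]) {
      rows[[length(rows) + 1]] <- data.frame(
        t = tick(), kind = "sequence_start", trial = NA_integer_,
        box_id = NA_integer_
      )
      for (b in opens) {
        rows[[length(rows) + 1]] <- data.frame(
          t = tick(), kind = "open", trial = NA_integer_, box_id = b
        )
      }
      rows[[length(rows) + 1]] <- data.frame(
        t = tick(), kind = "token_found", trial = NA_integer_,
        box_id = NA_integer_
      )
    }
  }
  event_log("px", "swm", seed, do.call(rbind, rows))
}

# Plays along a schedule with no errors: each sequence opens fresh
# non-emptied boxes and finds the token last.
perfect_swm_opens <- function(battery) {
  lapply(seq_len(nrow(battery)), function(i) {
    schedule <- battery$token_schedule[[i]]
    n <- battery$n_boxes[i]
    emptied <- integer(0)
    lapply(seq_len(n), function(s) {
      token <- schedule[s]
      pool <- setdiff(setdiff(seq_len(n) - 1L, emptied), token)
      k <- sample.int(length(pool) + 1L, 1L) - 1L
      opens <- c(if (k > 0) pool[sample.int(length(pool), k)], token)
      emptied <<- c(emptied, token)
      opens
    })
  })
}

# Synthetic measure matrix with a planted 3-block correlation structure:
# each block is driven by its own latent factor; within a block, the first
# measure is a clearly separated strongest marker (principal components
# compress within-block loading gaps, so identifiability needs separation).
# Blocks mimic the d2/dmts/swm split.
planted_measures <- function(n = 400, loadings = list(
                               d2 = c(0.92, 0.6, 0.55, 0.5),
                               dmts = c(0.92, 0.6, 0.55, 0.5),
                               swm = c(0.92, 0.6, 0.55)
                             ), factor_cor = 0.2) {
  k <- length(loadings)
  sigma <- matrix(factor_cor, k, k)
  diag(sigma) <- 1
  f <- matrix(rnorm(n * k), n, k) %*% chol(sigma)
  out <- list()
  for (b in seq_len(k)) {
    task <- names(loadings)[b]
    lam <- loadings[[b]]
    for (j in seq_along(lam)) {
      out[[paste0(task, "_m", j)]] <-
        lam[j] * f[, b] + sqrt(1 - lam[j]^2) * rnorm(n)
    }
  }
  tibble::as_tibble(out)
}

planted_tasks <- function(d) {
  task_of_measure(names(d))
}


# Independent normal-equations oracle for least squares.
ols_oracle <- function(x, y) {
  xm <- cbind(1, as.matrix(x))
  xtx <- crossprod(xm)
  b <- solve(xtx, crossprod(xm, y))
  res <- y - xm %*% b
  df <- nrow(xm) - ncol(xm)
  sigma2 <- sum(res^2) / df
  se <- sqrt(diag(solve(xtx)) * sigma2)
  list(b = drop(b), se = se, r2 = 1 - sum(res^2) / sum((y - mean(y))^2))
}

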