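test_that("swm batteries cover the six difficulty levels with valid schedules", {
  b <- generate_swm_battery(seed = 1)
  expect_equal(b$n_boxes, c(4, 6, 8, 10, 12, 14))
  expect_identical(
    as.data.frame(generate_swm_battery(4))[c("trial", "n_boxes", "token_schedule")],
    as.data.frame(generate_swm_battery(4))[c("trial", "n_boxes", "token_schedule")]
  )
  # positions are re-randomized across trials
  expect_false(identical(b$positions[[1]], b$positions[[2]][1:4, ]))
})

test_that("every token schedule is a permutation: no token in an emptied box", {
  # brute-force over 1,000 seeds
  for (seed in 1:1000) {
    b <- generate_swm_battery(seed)
    for (i in seq_len(nrow(b))) {
      expect_setequal(b$token_schedule[[i]], 0:(b$n_boxes[i] - 1))
    }
  }
})

test_that("token placement is uniform among non-emptied boxes", {
  withr::local_seed(8)
  # forced: a single candidate remains
  expect_equal(place_token(4, emptied = c(0L, 1L, 3L)), 2L)
  expect_error(place_token(2, emptied = 0:1), "no non-emptied boxes")

  draws <- replicate(10000, place_token(4, emptied = 1L))
  expect_false(any(draws == 1L)) # never an emptied box
  tab <- table(factor(draws, levels = c(0, 2, 3)))
  p <- stats::chisq.test(tab)$p.value
  expect_gt(p, 1e-4) # uniformity within sampling noise
})

test_that("hand-traced fixtures score the published error definitions", {
  b <- generate_swm_battery(seed = 2)
  sched4 <- b$token_schedule[[1]] # 4-box trial

  # perfect play on the 4-box trial: no within, no between
  withr::local_seed(1)
  opens <- perfect_swm_opens(b[1, ])
  m <- score_swm(swm_fixture_log(b, opens), b)
  expect_equal(m$n_between_errors, 0)
  expect_equal(m$n_within_errors, 0)

  # sequence starts at boxes [x, x, y, z] -> trial strategy 3
  starts <- c(sched4[1], sched4[1], sched4[2], sched4[3])
  opens2 <- lapply(1:4, function(s) {
    token <- sched4[s]
    if (starts[s] == token) token else c(starts[s], token)
  })
  # guard: constructed opens must end at the token and start as intended
  stopifnot(
    vapply(opens2, function(o) o[length(o)], integer(1)) == sched4,
    vapply(opens2, function(o) o[1], integer(1)) == starts
  )
  m2 <- score_swm(swm_fixture_log(b, list(opens2)), b)
  expect_equal(m2$strategy_score, 3)

  # sequence 2 opens the box emptied in sequence 1 twice -> between 2, within 1
  a <- sched4[1]
  opens3 <- list(
    c(setdiff(0:3, sched4[1])[1], sched4[1]), # seq 1 finds token in a
    c(a, a, sched4[2]), # seq 2 revisits emptied a twice
    c(sched4[3]),
    c(sched4[4])
  )
  m3 <- score_swm(swm_fixture_log(b, list(opens3)), b)
  expect_equal(m3$n_between_errors, 2)
  expect_equal(m3$n_within_errors, 1)
  # without double counting, the overlapping open counts only as between
  m3b <- score_swm(swm_fixture_log(b, list(opens3)), b, double_count = FALSE)
  expect_equal(m3b$n_between_errors, 2)
  expect_equal(m3b$n_within_errors, 0)
})

test_that("scoring rejects unknown boxes and misplaced tokens", {
  b <- generate_swm_battery(seed = 2)
  sched <- b$token_schedule[[1]]
  bad_box <- list(list(c(9L, sched[1]), sched[2], sched[3], sched[4]))
  expect_error(score_swm(swm_fixture_log(b, bad_box), b), "unknown box_id")

  wrong_token <- list(list(
    setdiff(0:3, sched[1])[1], sched[2], sched[3], sched[4]
  ))
  expect_error(
    score_swm(swm_fixture_log(b, wrong_token), b),
    "scheduled at box"
  )
})

test_that("a perfect agent is exhaustively clean at every difficulty", {
  for (seed in c(3, 14, 77)) {
    b <- generate_swm_battery(seed)
    log <- agent_logs_swm(perfect_profile(), b)
    m <- score_swm(log, b)
    expect_equal(m$n_between_errors, 0)
    expect_equal(m$n_within_errors, 0)
    expect_gte(m$strategy_score, 6)
    expect_lte(m$strategy_score, 54)
  }
})

test_that("scorer matches a brute-force replay oracle on error-prone logs", {
  # oracle: flat replay over the raw event stream with explicit state
  oracle <- function(log, battery) {
    ev <- log$events
    within <- 0L
    between <- 0L
    strat <- 0L
    tr <- NA_integer_
    emptied <- NULL
    seq_opens <- NULL
    starts <- NULL
    flush_trial <- function() {
      if (!is.null(starts)) strat <<- strat + length(unique(starts))
    }
    for (r in seq_len(nrow(ev))) {
      k <- ev$kind[r]
      if (k == "trial_start") {
        flush_trial()
        tr <- ev$trial[r]
        emptied <- integer(0)
        starts <- integer(0)
        seq_opens <- NULL
      } else if (k == "sequence_start") {
        seq_opens <- integer(0)
      } else if (k == "open") {
        bx <- ev$box_id[r]
        if (bx %in% seq_opens) within <- within + 1L
        if (bx %in% emptied) between <- between + 1L
        if (!length(seq_opens)) starts <- c(starts, bx)
        seq_opens <- c(seq_opens, bx)
      } else if (k == "token_found") {
        emptied <- c(emptied, seq_opens[length(seq_opens)])
      }
    }
    flush_trial()
    c(between = between, within = within, strategy = strat)
  }

  withr::local_seed(5)
  for (seed in c(9, 23)) {
    b <- generate_swm_battery(seed)
    log <- agent_logs_swm(lapse_profile(swm_p_error = 0.35), b)
    m <- score_swm(log, b)
    o <- oracle(log, b)
    expect_equal(m$n_between_errors, unname(o["between"]))
    expect_equal(m$n_within_errors, unname(o["within"]))
    expect_equal(m$strategy_score, unname(o["strategy"]))
    expect_gt(m$n_between_errors + m$n_within_errors, 0) # fixture not vacuous
  }
})
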