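test_that("d2 batteries have 20 pages of 42 items with the configured mix", {
  b <- generate_d2_battery(seed = 1)
  expect_equal(length(unique(b$page)), 20)
  expect_equal(nrow(b), 20 * 42)
  per_page <- table(b$page)
  expect_true(all(per_page == 42))

  # per-page target count = round(42 * 0.45) = 19; distractors only from the
  # three admissible classes, split 23 = 8 + 8 + 7 in some order
  counts <- table(b$page, b$class)
  expect_true(all(counts[, "target"] == 19))
  dis <- counts[, c("notch_ok_dots_wrong", "notch_wrong_dots_ok", "both_wrong")]
  expect_true(all(rowSums(dis) == 23))
  expect_true(all(dis >= 7 & dis <= 8))

  # the target definition is structural: 2 dots and a left notch
  expect_equal(b$is_target, b$dots == 2 & b$notch == "left")
  expect_false(any(b$class == "notch_ok_dots_wrong" & b$dots == 2))
  expect_true(all(b$notch[b$class == "notch_ok_dots_wrong"] == "left"))
  expect_true(all(b$dots[b$class == "notch_wrong_dots_ok"] == 2))

  expect_identical(
    as.data.frame(generate_d2_battery(99)),
    as.data.frame(generate_d2_battery(99))
  )
  expect_false(identical(
    as.data.frame(generate_d2_battery(99)), as.data.frame(b)
  ))

  cfg <- default_config()
  cfg$d2$distractor_mix <- c(0.5, 0.2, 0.2)
  expect_error(generate_d2_battery(1, cfg), "sum to 1")
})

test_that("hand-traced page scoring matches the processed-range definition", {
  b <- generate_d2_battery(seed = 5)
  page0 <- b[b$page == 0, ]
  targets <- page0$index[page0$is_target][1:3]
  nontarget <- page0$index[!page0$is_target][1]

  # visit items 0..9 and mark exactly the targets among them
  k <- 10L
  hit <- targets[targets < k]
  m <- score_d2(d2_page_log(5, k, hit), b)
  expect_equal(m$n_items, 10)
  expect_equal(m$n_correct, length(hit))
  expect_equal(m$n_omission, sum(page0$is_target[1:10]) - length(hit))
  expect_equal(m$n_commission, 0)

  # mark one non-target and skip one target instead
  stopifnot(nontarget < k, length(hit) >= 1)
  marks <- c(hit[-1], nontarget)
  m2 <- score_d2(d2_page_log(5, k, marks), b)
  expect_equal(m2$n_omission, m$n_omission + 1)
  expect_equal(m2$n_commission, 1)
  expect_equal(m2$n_errors, m2$n_omission + m2$n_commission)
  expect_equal(m2$error_rate, 100 * m2$n_errors / 10)
})

test_that("an empty log scores zero and backtracking never shrinks the range", {
  b <- generate_d2_battery(seed = 5)
  empty <- event_log("p", "d2", 5L, data.frame(t = integer(), kind = character()))
  m <- score_d2(empty, b)
  expect_true(all(m == 0))

  # forward to item 4, back to 1, forward to 2: processed = 5
  ev <- data.frame(
    t = 0:8 * 100L,
    kind = c("page_start", rep("nav_right", 4), rep("nav_left", 3), "nav_right"),
    page = c(0L, rep(NA_integer_, 8))
  )
  m <- score_d2(event_log("p", "d2", 5L, ev), b)
  expect_equal(m$n_items, 5)

  # a mark before any page_start is an error
  expect_error(
    score_d2(event_log("p", "d2", 5L, data.frame(t = 0L, kind = "mark")), b),
    "no cursor position"
  )
  # page index beyond the battery is an error
  ev_bad <- data.frame(t = 0L, kind = "page_start", page = 20L)
  expect_error(score_d2(event_log("p", "d2", 5L, ev_bad), b), "out of range")
})

test_that("error rate is errors per 100 items, zero-safe, bounded and monotone", {
  expect_equal(d2_error_rate(42, 420), 10)
  expect_equal(d2_error_rate(0, 100), 0)
  expect_equal(d2_error_rate(0, 0), 0)
  # published cohort scale: ~42.8 errors over ~419.2 items sits near 10.2
  expect_equal(d2_error_rate(42.8, 419.2), 10.21, tolerance = 1e-3)

  e <- 0:50
  r <- d2_error_rate(e, 50)
  expect_true(all(r >= 0 & r <= 100))
  expect_true(all(diff(r) > 0))
})

test_that("a perfect agent never errs and scored marks match the battery", {
  for (seed in c(2, 17)) {
    b <- generate_d2_battery(seed)
    log <- run_agents(perfect_profile(), list(
      d2 = b, dmts = generate_dmts_battery(seed), swm = generate_swm_battery(seed)
    ), seed = seed)$d2
    m <- score_d2(log, b)
    expect_equal(m$n_omission, 0)
    expect_equal(m$n_commission, 0)
    expect_equal(m$n_correct + m$n_omission, m$n_correct)
    expect_gt(m$n_items, 0)
  }
})

test_that("scoring agrees with an independent set-arithmetic oracle", {
  # oracle: recompute counts from the battery and the raw mark positions,
  # independent of the scorer's replay loop
  withr::local_seed(31)
  b <- generate_d2_battery(13)
  for (rep in 1:20) {
    k <- sample(5:42, 1)
    marks <- sort(sample(0:(k - 1), sample(0:6, 1)))
    log <- d2_page_log(13, k, marks)
    m <- score_d2(log, b)

    page0 <- b[b$page == 0, ]
    tgt_set <- page0$index[page0$is_target & page0$index < k]
    non_set <- setdiff(0:(k - 1), tgt_set)
    expect_equal(m$n_items, k)
    expect_equal(m$n_correct, length(intersect(marks, tgt_set)))
    expect_equal(m$n_commission, length(intersect(marks, non_set)))
    expect_equal(m$n_omission, length(setdiff(tgt_set, marks)))
    expect_equal(m$n_errors, m$n_omission + m$n_commission)
  }
})
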