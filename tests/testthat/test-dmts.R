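test_that("dmts batteries have 40 trials, 10 per delay, reproducibly", {
  b <- generate_dmts_battery(seed = 1)
  expect_equal(nrow(b), 40)
  expect_equal(as.vector(table(b$delay_ms)), rep(10, 4))
  expect_setequal(unique(b$delay_ms), c(0, 1000, 4000, 12000))
  expect_equal(attr(b, "prompt_duration_ms"), 4500)
  expect_identical(
    as.data.frame(generate_dmts_battery(8)),
    as.data.frame(generate_dmts_battery(8))
  )

  cfg <- default_config()
  cfg$palettes$n_colors <- 5
  expect_error(generate_dmts_battery(1, config = cfg), "palette exhaustion")
})

test_that("distractor construction obeys the role taxonomy and shared quadrant", {
  # brute-force structural check over 1,000 generated trials
  for (seed in 1:25) {
    b <- generate_dmts_battery(seed)
    for (i in seq_len(nrow(b))) {
      prompt <- b$prompt[[i]]
      roles <- b$roles[[i]]
      ch <- b$choices[[i]]
      sq <- b$shared_quadrant[i] + 1L
      other <- setdiff(1:4, sq)
      by_role <- setNames(ch, roles)

      expect_identical(by_role$match, prompt)
      for (r in roles) {
        # every choice agrees with the prompt at the shared quadrant
        expect_equal(by_role[[r]][sq, ], prompt[sq, ])
      }
      nv <- by_role$novel_distractor
      expect_true(all(nv[other, "color"] != prompt[other, "color"]))
      expect_true(all(nv[other, "form"] != prompt[other, "form"]))
      # novel colors/forms are drawn outside the prompt's palette use
      expect_length(intersect(nv[other, "color"], prompt[, "color"]), 0)
      expect_length(intersect(nv[other, "form"], prompt[, "form"]), 0)

      cd <- by_role$color_distractor
      expect_equal(cd[, "form"], prompt[, "form"]) # prompt forms
      expect_equal(cd[other, "color"], nv[other, "color"]) # novel colors

      sd_ <- by_role$shape_distractor
      expect_equal(sd_[, "color"], prompt[, "color"]) # prompt colors
      expect_equal(sd_[other, "form"], nv[other, "form"]) # novel forms
    }
  }
})

test_that("selections classify by role", {
  expect_equal(classify_selection("match"), "correct")
  expect_equal(classify_selection("color_distractor"), "color_error")
  expect_equal(classify_selection("shape_distractor"), "shape_error")
  expect_equal(classify_selection("novel_distractor"), "both_error")
  expect_error(classify_selection("prompt"), "invalid choice role")
})

test_that("only the first selection is scored; outcomes partition the trials", {
  b <- generate_dmts_battery(seed = 3)
  first_roles <- rep("match", 40)
  first_roles[2] <- "color_distractor"
  first_roles[5] <- "novel_distractor"
  log <- dmts_fixture_log(b, first_roles)
  m <- score_dmts(log, b)
  expect_equal(m$n_trials, 40)
  expect_equal(m$n_correct, 38)
  expect_equal(m$n_color_errors, 1)
  expect_equal(m$n_shape_errors, 0)
  expect_equal(m$n_both_errors, 1)
  expect_equal(
    m$n_correct + m$n_color_errors + m$n_shape_errors + m$n_both_errors,
    m$n_trials
  )
  # latency is first-selection time minus choice onset, averaged over all
  expect_equal(m$avg_latency_ms, 700)
})

test_that("scoring rejects rule-breaking logs", {
  b <- generate_dmts_battery(seed = 3)
  log <- dmts_fixture_log(b, rep("match", 40))

  # truncate the first trial's selection away -> no selections
  ev <- log$events
  drop <- which(ev$kind == "select")[1]
  bad <- event_log("p", "dmts", 3L, ev[-drop, ])
  expect_error(score_dmts(bad, b), "no selections|does not end with the match")

  # selecting again after the match was found
  sel1 <- which(ev$kind == "select")[1]
  extra <- ev[sel1, ]
  extra$t <- extra$t + 1L
  bad2 <- event_log("p", "dmts", 3L, dplyr::bind_rows(
    ev[seq_len(sel1), ], extra, ev[-seq_len(sel1), ]
  ))
  expect_error(score_dmts(bad2, b), "after match")

  expect_error(score_dmts(log, generate_dmts_battery(seed = 4)), "seed")
})

test_that("agents obey the continue-until-match rule and delays drive errors", {
  withr::local_seed(17)
  b <- generate_dmts_battery(seed = 6)
  prof <- lapse_profile(fidelity_base = 1.2, delay_slope = 0.5)
  errors_by_delay <- c(`0` = 0, `1000` = 0, `4000` = 0, `12000` = 0)
  trials_by_delay <- errors_by_delay
  for (rep in 1:15) {
    log <- agent_logs_dmts(prof, b)
    # independent mini-replay: first selection per trial from the raw events
    ev <- log$events
    starts <- ev$kind == "trial_start"
    trial_of <- ev$trial[starts][cumsum(starts)]
    for (tr in unique(trial_of)) {
      sel <- ev$choice_index[trial_of == tr & ev$kind == "select"]
      roles <- b$roles[[which(b$trial == tr)]]
      expect_equal(roles[sel[length(sel)] + 1L], "match") # forced continuation
      d <- as.character(b$delay_ms[b$trial == tr])
      trials_by_delay[d] <- trials_by_delay[d] + 1
      if (roles[sel[1] + 1L] != "match") {
        errors_by_delay[d] <- errors_by_delay[d] + 1
      }
    }
  }
  rate <- errors_by_delay / trials_by_delay
  expect_gt(rate[["12000"]], rate[["0"]])
  m <- score_dmts(agent_logs_dmts(lapse_profile(), b), b)
  expect_equal(m$n_correct, 40) # perfect memory
})
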