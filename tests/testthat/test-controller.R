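cfg <- lwl_config()

excl_off_of <- function(spec, cfg) {
  cfg$preview_ms + cfg$exclamation_durations_ms[spec$exclamation_id]
}

test_that("trigger detection needs one continuous fixation of the threshold length", {
  ws <- 3000
  # continuous 120 ms look starting at window start
  s <- data.frame(onset = c(0, ws), offset = c(ws, ws + 120), aoi = c("off", "left"))
  trig <- detect_trigger_fixation(s, ws, cfg)
  expect_equal(trig$aoi, "left")
  expect_equal(trig$time, ws + 100)

  # two 80 ms looks separated by an off-screen gap never trigger
  s2 <- data.frame(
    onset = c(ws, ws + 80, ws + 200),
    offset = c(ws + 80, ws + 200, ws + 280),
    aoi = c("left", "off", "left")
  )
  expect_null(detect_trigger_fixation(s2, ws, cfg))

  # contiguous same-AOI fixations count as one continuous look
  s3 <- data.frame(onset = c(ws, ws + 60), offset = c(ws + 60, ws + 150),
                   aoi = c("right", "right"))
  expect_equal(detect_trigger_fixation(s3, ws, cfg)$time, ws + 100)

  # empty stream is a timeout, not an error
  expect_null(detect_trigger_fixation(s2[0, ], ws, cfg))

  # a look qualifying only after the window closes does not trigger
  w_end <- ws + cfg$trigger_window_ms
  s4 <- data.frame(onset = w_end - 50, offset = w_end + 500, aoi = "left")
  expect_null(detect_trigger_fixation(s4, ws, cfg))
})

test_that("gaze rule names the other item; third-in-a-row flips with bias flag", {
  h0 <- list(fixated_sequence = character(0), label_counts = c(apple = 0L, jacket = 0L))
  sel <- select_target_gaze(h0, "apple", 1)
  expect_equal(sel$target, "jacket")
  expect_false(sel$bias_corrected)

  h2 <- list(fixated_sequence = c("apple", "apple"),
             label_counts = c(apple = 0L, jacket = 2L))
  sel <- select_target_gaze(h2, "apple", 3)
  expect_equal(sel$target, "apple")
  expect_true(sel$bias_corrected)

  expect_error(select_target_gaze(h0, "dog", 1), class = "lwl_domain_error")
})

test_that("all 16 length-4 fixation sequences end with a 2/2 label split", {
  items <- c("A", "B")
  for (bits in 0:15) {
    fix_seq <- items[(bitwAnd(bits, 2^(0:3)) > 0) + 1]
    h <- list(fixated_sequence = character(0), label_counts = c(A = 0L, B = 0L))
    n_bias <- 0
    for (k in 1:4) {
      sel <- select_target_gaze(h, fix_seq[k], k)
      h$fixated_sequence <- c(h$fixated_sequence, fix_seq[k])
      h$label_counts[sel$target] <- h$label_counts[sel$target] + 1L
      n_bias <- n_bias + sel$bias_corrected
    }
    expect_equal(unname(h$label_counts), c(2L, 2L),
                 label = paste("sequence", paste(fix_seq, collapse = "")))
    expect_lte(n_bias, 2)
  }
})

test_that("run_trial honours the trial timeline in both conditions", {
  sch <- build_schedule(cfg, 0, 21)
  state <- new_session_state(cfg)

  orig <- sch$trials[sch$trials$trial_type == "original", ][1, ]
  excl_off <- cfg$preview_ms + cfg$exclamation_durations_ms[orig$exclamation_id]
  stream <- data.frame(onset = 0, offset = 12000, aoi = "left")
  res <- run_trial(orig, stream, state, cfg)
  expect_equal(res$record$label_onset_ms, excl_off + 100)
  expect_equal(res$record$target_item, orig$predetermined_target)
  expect_true(res$record$completed)

  gaze <- sch$trials[sch$trials$trial_type == "gaze_triggered", ][1, ]
  excl_off <- cfg$preview_ms + cfg$exclamation_durations_ms[gaze$exclamation_id]
  res2 <- run_trial(gaze, stream, res$state, cfg)
  expect_equal(res2$record$label_onset_ms, excl_off + 100)
  expect_equal(res2$record$target_item, gaze$right_item) # left was fixated
  expect_false(res2$record$bias_corrected)

  # never on screen: manual trigger still yields a record, trial fails
  off_stream <- data.frame(onset = 0, offset = 12000, aoi = "off")
  gaze2 <- sch$trials[sch$trials$trial_type == "gaze_triggered", ][2, ]
  res3 <- run_trial(gaze2, off_stream, res2$state, cfg)
  expect_true(res3$record$manual_trigger)
  expect_equal(res3$record$label_onset_ms, excl_off_of(gaze2, cfg) + cfg$trigger_window_ms)
  expect_false(res3$record$completed)
  expect_equal(res3$state$consecutive_failed, 1L)

  # determinism given stream + spec + state
  res3b <- run_trial(gaze2, off_stream, res2$state, cfg)
  expect_identical(res3$record, res3b$record)
})

test_that("stop rule fires at five consecutive failures and resets on completion", {
  state <- new_session_state(cfg)
  state$consecutive_failed <- 4L
  expect_equal(session_stop_rule(state, cfg), "continue")
  state$consecutive_failed <- 5L
  expect_equal(session_stop_rule(state, cfg), "stop")
  state$consecutive_failed <- 0L
  expect_equal(session_stop_rule(state, cfg), "continue")

  # a completed trial resets the counter
  sch <- build_schedule(cfg, 0, 22)
  st <- new_session_state(cfg)
  st$consecutive_failed <- 4L
  stream <- data.frame(onset = 0, offset = 12000, aoi = "right")
  res <- run_trial(sch$trials[1, ], stream, st, cfg)
  expect_equal(res$state$consecutive_failed, 0L)
})

test_that("a session replayed on off-screen gaze stops after five trials", {
  sch <- build_schedule(cfg, 0, 23)
  gaze <- policy_gaze(sch, function(row) "off")
  ev <- run_session(sch, gaze, cfg)
  expect_equal(nrow(ev), 5)
  expect_true(all(!ev$completed))
})
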