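test_that("default schedule has the 80-trial structure with balanced pairs and targets", {
  cfg <- lwl_config()
  sch <- build_schedule(cfg, participant_index = 0, seed = 11)
  tr <- sch$trials

  expect_equal(nrow(tr), 80)
  expect_equal(sum(tr$trial_type == "gaze_triggered"), 32)
  expect_equal(sum(tr$trial_type == "original"), 32)
  expect_equal(sum(tr$trial_type == "filler"), 16)

  exp <- tr[tr$trial_type != "filler", ]
  expect_true(all(table(exp$pair_id) == 8))

  # each item is predetermined target exactly twice in the original condition
  orig <- tr[tr$trial_type == "original", ]
  items <- c(cfg$pairs$item_a, cfg$pairs$item_b)
  expect_equal(unname(table(factor(orig$predetermined_target, levels = items))),
               rep(2L, 16), ignore_attr = TRUE)

  # left/right balance: each item left for half its appearances per condition
  for (cond in c("gaze_triggered", "original")) {
    cexp <- exp[exp$trial_type == cond, ]
    for (p in seq_len(nrow(cfg$pairs))) {
      pp <- cexp[cexp$pair_id == cfg$pairs$pair_id[p], ]
      expect_equal(sum(pp$left_item == cfg$pairs$item_a[p]), nrow(pp) / 2)
    }
  }

  # gaze-triggered trials carry no predetermined target, but a backup
  expect_true(all(is.na(tr$predetermined_target[tr$trial_type == "gaze_triggered"])))
  expect_true(all(!is.na(tr$backup_target[tr$trial_type == "gaze_triggered"])))
})

test_that("blocks alternate conditions and hold 8 experimental + 2 legally placed fillers", {
  for (seed in c(3, 17)) {
    sch <- build_schedule(lwl_config(), participant_index = 1, seed = seed)
    tr <- sch$trials
    conds <- vapply(split(tr, tr$block_index), function(b) {
      unique(b$trial_type[b$trial_type != "filler"])
    }, character(1))
    expect_true(all(conds[-1] != conds[-length(conds)]))
    expect_equal(unname(conds[1]), condition_order(1))
    for (b in split(tr, tr$block_index)) {
      expect_equal(sum(b$trial_type == "filler"), 2)
      fpos <- sort(b$position_in_block[b$trial_type == "filler"])
      expect_false(any(fpos %in% c(0, 9)))
      expect_true(diff(fpos) >= 2)
    }
  }
})

test_that("condition order alternates by parity and balances even cohorts", {
  expect_equal(condition_order(0), "gaze_triggered")
  expect_equal(condition_order(1), "original")
  orders <- vapply(0:9, condition_order, character(1))
  expect_equal(sum(orders == "gaze_triggered"), 5)
  expect_error(condition_order(-1), class = "lwl_domain_error")
})

test_that("schedules are deterministic in (config, participant, seed)", {
  a <- build_schedule(lwl_config(), 2, 99)
  b <- build_schedule(lwl_config(), 2, 99)
  expect_identical(a$trials, b$trials)
  c <- build_schedule(lwl_config(), 2, 100)
  expect_false(identical(a$trials, c$trials))
})

test_that("validate_schedule reports violations without raising", {
  sch <- build_schedule(lwl_config(), 0, 5)
  expect_length(validate_schedule(sch), 0)

  # force two adjacent fillers in block 0
  bad <- sch
  blk <- bad$trials$block_index == 0
  fidx <- which(blk & bad$trials$trial_type == "filler")
  nidx <- which(blk & bad$trials$position_in_block ==
                  bad$trials$position_in_block[fidx[1]] + 1)
  bad$trials$trial_type[nidx] <- "filler"
  rep <- validate_schedule(bad)
  expect_true(any(grepl("consecutive filler", rep)))

  # drop a trial
  short <- sch
  short$trials <- short$trials[-1, ]
  expect_true(any(grepl("trial count", validate_schedule(short))))
})

test_that("config validation names the violated constraint", {
  expect_error(lwl_config(n_gaze_trials = 30, n_original_trials = 30),
               "divisible", class = "lwl_config_error")
  expect_error(lwl_config(n_gaze_trials = 30), "equal",
               class = "lwl_config_error")
  expect_error(lwl_config(n_filler_trials = 10), "fillers_per_block",
               class = "lwl_config_error")
  expect_error(lwl_config(rt_window = c(300, 2500)), "attention",
               class = "lwl_config_error")
  expect_error(lwl_config(preview_ms = 0), class = "lwl_config_error")
})

test_that("schedule JSON round-trips", {
  sch <- build_schedule(lwl_config(), 0, 8)
  path <- withr::local_tempfile(fileext = ".json")
  write_schedule_json(sch, path)
  tr <- read_schedule_json(path)
  expect_equal(as.data.frame(tr), as.data.frame(sch$trials), ignore_attr = TRUE)
  expect_equal(attr(tr, "participant_index"), 0)
})
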