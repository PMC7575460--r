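test_that("fixation CSV reading enforces the schema and round-trips", {
  df <- data.frame(
    participant_id = "p001", trial_index = c(0L, 0L, 1L),
    fix_onset_ms = c(0, 150, 10), fix_offset_ms = c(120, 400, 200),
    aoi = c("left", "right", "off")
  )
  path <- withr::local_tempfile(fileext = ".csv")
  write.csv(df, path, row.names = FALSE)
  fx <- read_fixation_csv(path)
  expect_equal(nrow(fx), 3)
  expect_equal(as.data.frame(fx), df)

  bad <- df
  bad$fix_offset_ms[2] <- 100 # offset < onset
  write.csv(bad, path, row.names = FALSE)
  expect_error(read_fixation_csv(path), "lines: 2", class = "lwl_io_error")

  write.csv(df[, -5], path, row.names = FALSE)
  expect_error(read_fixation_csv(path), "missing columns", class = "lwl_io_error")
})

test_that("EyeLink ASC parsing re-bases, truncates, and warns as specified", {
  asc <- c(
    "** header junk",
    "EFIX R 500 700 200 100.0 450.0 900.0", # before any trial: dropped
    "MSG 1000 TRIAL_START 0",
    "MSG 3100 EXCL_ONSET",
    "MSG 4000 LABEL_ONSET",
    "EFIX R 1200 1450 250 300.0 450.0 900.0",
    "EFIX R 5500 7200 1700 1200.0 450.0 900.0", # straddles TRIAL_END
    "MSG 7000 TRIAL_END",
    "SSACC R 1450 junk ignored"
  )
  expect_warning(res <- parse_asc_efix(asc), "TRIAL_START")
  fx <- res$fixations
  expect_equal(nrow(fx), 2)
  expect_equal(fx$fix_onset_ms[1], 200)
  expect_equal(fx$fix_offset_ms[1], 450)
  expect_false(fx$truncated[1])
  expect_equal(fx$fix_offset_ms[2], 6000) # truncated at trial end
  expect_true(fx$truncated[2])
  expect_equal(res$events$excl_onset_ms, 2100)
  expect_equal(res$events$label_onset_ms, 3000)

  expect_warning(empty <- parse_asc_efix("EFIX R 1 2 1 0 0 0"), "MSG")
  expect_equal(nrow(empty$fixations), 0)
})

test_that("ASC parsing prefers the right eye in binocular records", {
  asc <- c(
    "MSG 100 TRIAL_START 0",
    "EFIX L 200 400 200 100.0 450.0 900.0",
    "EFIX R 210 420 210 1200.0 450.0 900.0",
    "MSG 5000 TRIAL_END"
  )
  fx <- parse_asc_efix(asc)$fixations
  expect_equal(nrow(fx), 1)
  expect_equal(fx$fix_onset_ms, 110)
})

test_that("short fixations are dropped with a closed threshold", {
  fx <- tibble::tibble(fix_onset_ms = c(0, 200, 600),
                       fix_offset_ms = c(99, 300, 850))
  kept <- filter_short_fixations(fx)
  expect_equal(kept$fix_offset_ms - kept$fix_onset_ms, c(100, 250))
  expect_equal(nrow(filter_short_fixations(fx[0, ])), 0)

  withr::with_seed(12, {
    dur <- sample(50:200, 1000, replace = TRUE)
    rnd <- tibble::tibble(fix_onset_ms = cumsum(dur) - dur,
                          fix_offset_ms = cumsum(dur))
    expect_equal(nrow(filter_short_fixations(rnd)), sum(dur >= 100))
  })
})

test_that("AOI assignment is half-open and matches brute-force containment", {
  lay <- aoi_layout()
  expect_equal(assign_aoi(350, 450, lay), "left")
  expect_equal(assign_aoi(1200, 450, lay), "right")
  expect_equal(assign_aoi(700, 450, lay), "off") # exactly on x1: outside
  expect_equal(assign_aoi(800, 450, lay), "off") # central gutter
  expect_error(aoi_layout(left_region = c(0, 1000, 0, 900),
                          right_region = c(900, 1600, 0, 900)),
               class = "lwl_config_error")

  withr::with_seed(5, {
    x <- runif(10000, -100, 1700)
    y <- runif(10000, -100, 1000)
    got <- assign_aoi(x, y, lay)
    manual <- ifelse(
      x >= 0 & x < 700 & y >= 0 & y < 900, "left",
      ifelse(x >= 900 & x < 1600 & y >= 0 & y < 900, "right", "off")
    )
    expect_identical(got, manual)
  })
})

test_that("segmentation removes fillers and commutes with the fixation filter", {
  coh <- simulate_cohort(2, lwl_config(), seed = 77)
  seg <- segment_trials(coh$gaze, coh$events)
  expect_false(any(seg$trial_type == "filler"))
  expect_true(all(c("label_onset_ms", "t_label") %in% names(seg)))

  a <- filter_short_fixations(segment_trials(coh$gaze, coh$events))
  b <- segment_trials(filter_short_fixations(coh$gaze), coh$events)
  expect_equal(as.data.frame(a), as.data.frame(b))

  orphan <- coh$gaze
  orphan$trial_index[1] <- 999L
  expect_error(segment_trials(orphan, coh$events), "999",
               class = "lwl_input_error")
})
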