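test_that("paired t follows the textbook formula and tail convention", {
  x <- c(5, 6, 7)
  res <- paired_t_one_sided(x, x, "greater")
  expect_equal(res$t, 0)
  expect_equal(res$p, 0.5)

  # d = (1, 2, 3): t = mean/ (sd/sqrt(3)) = 2 * sqrt(3)
  res <- paired_t_one_sided(c(2, 4, 6), c(1, 2, 3), "greater")
  expect_equal(res$t, 2 * sqrt(3), tolerance = 1e-12)
  expect_equal(res$df, 2)

  # hand-computed formula as independent oracle on random paired samples
  withr::with_seed(10, {
    for (i in 1:25) {
      a <- rnorm(8)
      b <- rnorm(8)
      d <- a - b
      t_hand <- mean(d) / (sd(d) / sqrt(length(d)))
      p_hand <- 1 - pt(t_hand, df = length(d) - 1)
      got <- paired_t_one_sided(a, b, "greater")
      expect_equal(got$t, t_hand, tolerance = 1e-10)
      expect_equal(got$p, p_hand, tolerance = 1e-10)
    }
  })

  res <- paired_t_one_sided(c(1, 1, 1), c(0, 0, 0), "greater")
  expect_true(res$degenerate)
  expect_equal(res$p, 0)
})

test_that("Spearman rho matches rank-then-Pearson to 1e-12, including ties", {
  expect_equal(spearman_rho(1:10, (1:10)^2)$rho, 1)
  expect_equal(spearman_rho(1:10, -(1:10))$rho, -1)

  withr::with_seed(11, {
    for (i in 1:30) {
      x <- sample(1:6, 15, replace = TRUE) # heavy ties
      y <- sample(1:6, 15, replace = TRUE)
      if (sd(x) == 0 || sd(y) == 0) next
      oracle <- cor(rank(x), rank(y))
      expect_equal(spearman_rho(x, y)$rho, oracle, tolerance = 1e-12)
      expect_equal(spearman_rho(x, y)$rho,
                   cor(x, y, method = "spearman"), tolerance = 1e-12)
    }
  })

  res <- spearman_rho(rep(1, 5), 1:5)
  expect_true(res$degenerate)
  expect_true(is.na(res$rho))
  expect_error(spearman_rho(1:2, 1:2), class = "lwl_domain_error")
})

test_that("statistics are permutation-sane", {
  withr::with_seed(13, {
    x <- rnorm(20)
    y <- x + rnorm(20)
    base_rho <- spearman_rho(x, y)$rho
    base_t <- paired_t_one_sided(x, y, "two.sided")$t
    perm <- sample(20)
    expect_equal(spearman_rho(x[perm], y[perm])$rho, base_rho, tolerance = 1e-12)
    expect_equal(paired_t_one_sided(x[perm], y[perm], "two.sided")$t, base_t,
                 tolerance = 1e-12)
    # shuffling y alone destroys the association on average
    rhos <- replicate(200, spearman_rho(x, sample(y))$rho)
    expect_lt(abs(mean(rhos)), 0.1)
  })
})

make_outcomes <- function(rts_by_participant, condition = "gaze_triggered") {
  dplyr::bind_rows(lapply(names(rts_by_participant), function(p) {
    v <- rts_by_participant[[p]]
    tibble::tibble(
      participant_id = p, trial_index = seq_along(v) * 2L, condition = condition,
      pair_id = "P1", target_item = rep(c("apple", "jacket"), length.out = length(v)),
      attended = TRUE, initial_aoi_at_onset = "distractor", rt_ms = v,
      rt_valid = TRUE, invalid_reason = "valid", bias_corrected = FALSE,
      manual_trigger = FALSE, completed = TRUE
    )
  }))
}

test_that("split-half reliability drops sparse participants and is seed-stable", {
  out <- make_outcomes(list(
    a = c(700, 700, 700, 700), b = c(900, 900, 900, 900),
    c = c(1100, 1100, 1100, 1100), d = c(650) # only one RT: dropped
  ))
  res <- split_half_reliability(out, "gaze_triggered", seed = 3)
  expect_equal(res$n, 3)
  expect_equal(res$n_dropped, 1)
  # constant RTs per participant: halves are identical, ranks agree perfectly
  expect_equal(res$rho, 1)

  res2 <- split_half_reliability(out, "gaze_triggered", seed = 3)
  expect_identical(res, res2)

  expect_error(
    split_half_reliability(make_outcomes(list(a = c(1, 2))), "gaze_triggered"),
    class = "lwl_domain_error"
  )
})

test_that("trial-order effect: flat RTs give a zero slope; injected trends are found", {
  out <- make_outcomes(list(a = rep(900, 4), b = rep(800, 4), c = rep(1000, 4)))
  res <- trial_order_effect(out, "gaze_triggered")
  expect_equal(res$estimate, 0)

  withr::with_seed(14, {
    rts <- lapply(1:20, function(i) 800 + 10 * (1:12) + rnorm(12, 0, 30))
    names(rts) <- paste0("p", 1:20)
    out2 <- make_outcomes(rts)
    out2$trial_index <- rep(1:12 * 2L, 20)
    res2 <- trial_order_effect(out2, "gaze_triggered")
    expect_gt(res2$estimate, 0)
    expect_lt(res2$p, 0.05)
  })
})

test_that("mixed-model pass-through agrees in sign with the two-stage estimate", {
  skip_if_not_installed("lmerTest")
  withr::with_seed(15, {
    rts <- lapply(1:15, function(i) 800 + 8 * (1:10) + rnorm(10, 0, 40))
    names(rts) <- paste0("p", 1:15)
    out <- make_outcomes(rts)
    out$trial_index <- rep(1:10 * 2L, 15)
    two <- trial_order_effect(out, "gaze_triggered")
    mix <- trial_order_effect(out, "gaze_triggered", method = "mixed")
    expect_equal(sign(mix$estimate), sign(two$estimate))
    expect_equal(mix$estimate, two$estimate, tolerance = 0.5)
  })
})

test_that("word-knowledge filter is a no-op when all words are known", {
  coh <- simulate_cohort(3, lwl_config(), seed = 55)
  out <- extract_outcomes(coh$gaze, coh$events)
  vocab_all <- coh$vocab
  vocab_all$known_items <- paste(
    c(lwl_item_pairs()$item_a, lwl_item_pairs()$item_b), collapse = ";"
  )
  res <- word_known_filter_and_effect(out, vocab_all)
  expect_equal(res$n_unknown_trials, 0)
  expect_equal(as.data.frame(res$filtered_summaries),
               as.data.frame(summarize_participants(out)))

  vocab_none <- coh$vocab
  vocab_none$known_items <- ""
  res2 <- word_known_filter_and_effect(out, vocab_none)
  expect_equal(res2$n_unknown_trials, nrow(out))
  expect_null(res2$filtered_summaries)

  vocab_bad <- coh$vocab
  vocab_bad$known_items <- "unicorn"
  expect_error(word_known_filter_and_effect(out, vocab_bad), "unicorn",
               class = "lwl_input_error")
})

test_that("vocabulary correlation delegates to the Spearman routine", {
  coh <- simulate_cohort(6, lwl_config(), seed = 56)
  out <- extract_outcomes(coh$gaze, coh$events)
  s <- summarize_participants(out)
  res <- vocab_correlation(s, coh$vocab)
  means <- tapply(s$mean_rt_ms, s$participant_id, mean, na.rm = TRUE)
  direct <- spearman_rho(as.numeric(means),
                         coh$vocab$cdi_produced[match(names(means),
                                                      coh$vocab$participant_id)])
  expect_equal(res$rho, direct$rho, tolerance = 1e-12)
})

test_that("inclusion rule excludes participants without valid RTs in both conditions", {
  g <- make_outcomes(list(a = c(700, 800), b = c(900, 850)), "gaze_triggered")
  o <- make_outcomes(list(a = c(750, 820)), "original")
  o_b <- make_outcomes(list(b = 900), "original")
  o_b$rt_valid <- FALSE
  o_b$rt_ms <- NA_real_
  o_b$invalid_reason <- "target_initial"
  s <- summarize_participants(dplyr::bind_rows(g, o, o_b))
  res <- apply_inclusion(s)
  expect_equal(res$excluded$participant_id, "b")
  expect_true(all(res$included$participant_id == "a"))

  # min_rt_trials = 2 equals a brute-force filter
  s2 <- summarize_participants(dplyr::bind_rows(g, o, make_outcomes(list(b = 880), "original")))
  res2 <- apply_inclusion(s2, min_rt_trials = 2)
  brute <- tapply(s2$rt_valid_trials, s2$participant_id, min)
  expect_setequal(unique(res2$included$participant_id), names(brute)[brute >= 2])
})
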