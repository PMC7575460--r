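# The paradigm's reliability and validity statistics: paired t tests,
# Spearman rank correlations with Fisher-z intervals, split-half
# reliability, and two-stage (summary-statistics) estimates of trial-order
# and word-knowledge effects, with an optional mixed-model pass-through.

#' One-sided paired t test
#'
#' Paired t on per-participant values: `t = mean(d) / (sd(d) / sqrt(n))`,
#' `df = n - 1`, with the p value taken from the stated tail. With zero
#' variance of the differences the p value degenerates to 0 or 1 by the sign
#' of the mean difference and is flagged.
#'
#' @param x,y Paired numeric vectors (same participants, same order).
#' @param direction `"greater"` tests `mean(x - y) > 0`; `"less"` the
#'   reverse; `"two.sided"` gives the ordinary paired t test.
#' @return List: `t`, `df`, `p`, `mean_diff`, `degenerate` flag.
#' @export
#' @examples
#' paired_t_one_sided(c(5, 6, 7), c(4, 4, 5), "greater")
paired_t_one_sided <- function(x, y, direction = c("greater", "less", "two.sided")) {
  direction <- match.arg(direction)
  if (length(x) != length(y) || length(x) < 2) {
    abort("x and y must be paired vectors of equal length >= 2",
          class = "lwl_domain_error")
  }
  d <- x - y
  if (sd(d) == 0) {
    p <- switch(direction,
      greater = if (mean(d) > 0) 0 else if (mean(d) < 0) 1 else 0.5,
      less = if (mean(d) < 0) 0 else if (mean(d) > 0) 1 else 0.5,
      two.sided = if (mean(d) == 0) 1 else 0
    )
    return(list(t = if (mean(d) == 0) 0 else sign(mean(d)) * Inf,
                df = length(d) - 1, p = p, mean_diff = mean(d), degenerate = TRUE))
  }
  tt <- t.test(x, y, paired = TRUE, alternative = direction)
  list(t = unname(tt$statistic), df = unname(tt$parameter), p = tt$p.value,
       mean_diff = unname(tt$estimate), degenerate = FALSE)
}

#' Spearman rank correlation with t-approximation p and Fisher-z CI
#'
#' Ranks use average ranks for ties; rho is the Pearson correlation of the
#' ranks; the p value uses the t approximation
#' `t = rho * sqrt((n - 2) / (1 - rho^2))` on `n - 2` df; the confidence
#' interval applies the Fisher z transform with standard error
#' `1 / sqrt(n - 3)` to rho (a pragmatic choice, reported as such).
#'
#' @param x,y Numeric vectors of equal length >= 3.
#' @param conf_level Confidence level for the interval.
#' @return List: `rho`, `p`, `ci` (length 2), `n`, `degenerate` flag
#'   (constant input).
#' @export
#' @examples
#' spearman_rho(1:10, c(2, 1, 4, 3, 6, 5, 8, 7, 10, 9))
spearman_rho <- function(x, y, conf_level = 0.95) {
  ok <- is.finite(x) & is.finite(y)
  x <- x[ok]
  y <- y[ok]
  n <- length(x)
  if (n < 3) abort("need at least 3 complete pairs", class = "lwl_domain_error")
  if (sd(x) == 0 || sd(y) == 0) {
    return(list(rho = NA_real_, p = NA_real_, ci = c(NA_real_, NA_real_),
                n = n, degenerate = TRUE))
  }
  rx <- rank(x)
  ry <- rank(y)
  rho <- sum((rx - mean(rx)) * (ry - mean(ry))) /
    sqrt(sum((rx - mean(rx))^2) * sum((ry - mean(ry))^2))
  if (abs(rho) >= 1) {
    p <- 0
  } else {
    tstat <- rho * sqrt((n - 2) / (1 - rho^2))
    p <- 2 * pt(-abs(tstat), df = n - 2)
  }
  if (n > 3 && abs(rho) < 1) {
    z <- atanh(rho)
    se <- 1 / sqrt(n - 3)
    q <- qnorm(1 - (1 - conf_level) / 2)
    ci <- tanh(c(z - q * se, z + q * se))
  } else {
    ci <- c(NA_real_, NA_real_)
  }
  list(rho = rho, p = p, ci = ci, n = n, degenerate = FALSE)
}

#' Split-half reliability of mean reaction time
#'
#' Per participant, the valid RTs of one condition are split at random into
#' two halves (an odd trial goes to a random half); the mean RT of each half
#' is computed, and the halves are rank-correlated across participants.
#' Participants with fewer than `min_trials` valid RTs in the condition are
#' dropped and counted. With `n_splits > 1` the procedure is repeated and
#' the average rho over splits is reported (labelled as an extension of the
#' single-split default).
#'
#' @param outcomes Trial outcomes ([extract_outcomes()]).
#' @param condition `"gaze_triggered"` or `"original"`.
#' @param seed Integer seed controlling the split(s).
#' @param min_trials Minimum valid RTs per participant (default 2).
#' @param n_splits Number of random splits to average over (default 1).
#' @return List: `rho`, `p`, `ci`, `n` (participants used), `n_dropped`,
#'   `seed`, `n_splits`.
#' @export
split_half_reliability <- function(outcomes, condition, seed = 1,
                                   min_trials = 2, n_splits = 1) {
  rts <- outcomes %>%
    filter(.data$condition == !!condition, .data$rt_valid) %>%
    select("participant_id", "rt_ms")
  by_p <- split(rts$rt_ms, rts$participant_id)
  usable <- names(by_p)[vapply(by_p, length, integer(1)) >= min_trials]
  n_dropped <- length(by_p) - length(usable)
  if (length(usable) < 3) {
    abort("fewer than 3 participants with enough valid RTs for a split-half estimate",
          class = "lwl_domain_error")
  }
  one_split <- function(k) {
    halves <- vapply(seq_along(usable), function(i) {
      v <- by_p[[usable[i]]]
      m <- length(v)
      with_seed(mix_seed(seed, k, i, 23), {
        take <- sample.int(m, floor(m / 2) + sample(0:1, 1) * (m %% 2))
        c(mean(v[take]), mean(v[-take]))
      })
    }, numeric(2))
    halves
  }
  rhos <- numeric(n_splits)
  last <- NULL
  for (k in seq_len(n_splits)) {
    h <- one_split(k)
    last <- spearman_rho(h[1, ], h[2, ])
    rhos[k] <- last$rho
  }
  list(rho = mean(rhos), p = last$p, ci = last$ci, n = length(usable),
       n_dropped = n_dropped, seed = seed, n_splits = n_splits)
}

# Two-stage estimate shared by the trial-order and word-knowledge effects:
# stage 1 computes a per-participant statistic (OLS slope or mean
# difference); stage 2 is a one-sample t test of those statistics against 0.
two_stage_t <- function(stats_per_participant) {
  est <- stats_per_participant[is.finite(stats_per_participant)]
  if (length(est) < 3) {
    abort("need per-participant estimates from at least 3 participants",
          class = "lwl_domain_error")
  }
  tt <- t.test(est)
  list(estimate = mean(est), se = sd(est) / sqrt(length(est)),
       t = unname(tt$statistic), df = unname(tt$parameter), p = tt$p.value,
       ci = unname(tt$conf.int), n = length(est))
}

#' Trial-order effect on reaction times
#'
#' Tests whether RTs change over the course of the experiment (a learning
#' signature the gaze-triggered design must not introduce). The primary
#' implementation is a two-stage summary-statistics analysis: an ordinary
#' least-squares slope of RT on trial number per participant, then a
#' one-sample t test of the slopes against zero. `method = "mixed"` instead
#' fits the random-effects model `rt ~ trial + (1 | participant) +
#' (1 | target) + (1 | participant:target)` via lmerTest when available.
#'
#' @param outcomes Trial outcomes; only valid RTs enter.
#' @param condition Condition to analyse (default `"gaze_triggered"`).
#' @param method `"two_stage"` (default) or `"mixed"`.
#' @return For `"two_stage"`: list with `estimate` (ms per trial), `se`,
#'   `t`, `df`, `p`, `ci`, `n`. For `"mixed"`: list with `estimate`, `se`,
#'   `p` from the lmerTest fit.
#' @export
trial_order_effect <- function(outcomes, condition = "gaze_triggered",
                               method = c("two_stage", "mixed")) {
  method <- match.arg(method)
  dat <- outcomes %>%
    filter(.data$condition == !!condition, .data$rt_valid) %>%
    select("participant_id", "trial_index", "rt_ms", "target_item")
  if (method == "mixed") {
    if (!requireNamespace("lmerTest", quietly = TRUE)) {
      abort("method = 'mixed' requires the lmerTest package",
            class = "lwl_dependency_error")
    }
    fit <- suppressMessages(suppressWarnings(lmerTest::lmer(
      rt_ms ~ trial_index + (1 | participant_id) + (1 | target_item) +
        (1 | participant_id:target_item),
      data = dat
    )))
    cf <- coef(summary(fit))
    return(list(estimate = cf["trial_index", "Estimate"],
                se = cf["trial_index", "Std. Error"],
                p = cf["trial_index", "Pr(>|t|)"],
                method = "mixed"))
  }
  slopes <- vapply(split(dat, dat$participant_id), function(d) {
    if (nrow(d) < 2 || sd(d$trial_index) == 0) return(NA_real_)
    unname(coef(lm(rt_ms ~ trial_index, data = d))[2])
  }, numeric(1))
  c(two_stage_t(slopes), list(method = "two_stage"))
}

# Parse vocab.csv's semicolon-joined known_items into a named list.
known_items_list <- function(vocab) {
  setNames(
    lapply(strsplit(vocab$known_items, ";", fixed = TRUE), function(x) x[nzchar(x)]),
    vocab$participant_id
  )
}

#' Word-knowledge filter and effect on reaction times
#'
#' (a) Recomputes the participant summaries after dropping trials whose
#' target word the participant is not reported to understand; (b) estimates
#' the known-vs-unknown RT difference with the same two-stage strategy as
#' [trial_order_effect()] (per-participant mean difference, then a
#' one-sample t test), or with the analogous random-effects model when
#' `method = "mixed"`.
#'
#' @param outcomes Trial outcomes.
#' @param vocab Vocabulary tibble with `participant_id` and `known_items`
#'   (semicolon-joined labels).
#' @param config An [lwl_config()] (for the item inventory).
#' @param method `"two_stage"` or `"mixed"`.
#' @return List: `filtered_summaries` (summaries over known-word trials
#'   only), `effect` (known minus unknown, ms; NULL when no participant has
#'   RTs in both categories), `n_unknown_trials`.
#' @export
word_known_filter_and_effect <- function(outcomes, vocab, config = lwl_config(),
                                         method = c("two_stage", "mixed")) {
  method <- match.arg(method)
  items <- c(config$pairs$item_a, config$pairs$item_b)
  known <- known_items_list(vocab)
  alien <- setdiff(unique(unlist(known)), items)
  if (length(alien) > 0) {
    abort(paste0("vocabulary lists unknown item labels: ",
                 paste(alien, collapse = ", ")),
          class = "lwl_input_error")
  }
  out <- outcomes %>%
    mutate(word_known = purrr::map2_lgl(
      .data$participant_id, .data$target_item,
      function(p, it) it %in% (known[[p]] %||% character(0))
    ))
  n_unknown <- sum(!out$word_known)
  filtered <- out %>% filter(.data$word_known)
  filtered_summaries <- if (nrow(filtered) > 0) summarize_participants(filtered) else NULL

  rts <- out %>% filter(.data$rt_valid)
  effect <- NULL
  if (method == "mixed") {
    if (!requireNamespace("lmerTest", quietly = TRUE)) {
      abort("method = 'mixed' requires the lmerTest package",
            class = "lwl_dependency_error")
    }
    if (length(unique(rts$word_known)) == 2) {
      fit <- suppressMessages(suppressWarnings(lmerTest::lmer(
        rt_ms ~ word_known + (1 | participant_id) + (1 | target_item) +
          (1 | participant_id:target_item),
        data = rts
      )))
      cf <- coef(summary(fit))
      effect <- list(estimate = cf["word_knownTRUE", "Estimate"],
                     se = cf["word_knownTRUE", "Std. Error"],
                     p = cf["word_knownTRUE", "Pr(>|t|)"],
                     method = "mixed")
    }
  } else {
    diffs <- vapply(split(rts, rts$participant_id), function(d) {
      if (length(unique(d$word_known)) < 2) return(NA_real_)
      mean(d$rt_ms[d$word_known]) - mean(d$rt_ms[!d$word_known])
    }, numeric(1))
    if (sum(is.finite(diffs)) >= 3) {
      effect <- c(two_stage_t(diffs), list(method = "two_stage"))
    }
  }
  list(filtered_summaries = filtered_summaries, effect = effect,
       n_unknown_trials = n_unknown)
}

#' Rank correlation between processing speed and expressive vocabulary
#'
#' Spearman correlation between each participant's mean RT across both
#' conditions (so at least two RTs contribute) and their expressive
#' vocabulary score.
#'
#' @param summaries Participant summaries ([summarize_participants()]).
#' @param vocab Vocabulary tibble with `cdi_produced`.
#' @return As [spearman_rho()].
#' @export
vocab_correlation <- function(summaries, vocab) {
  means <- summaries %>%
    group_by(.data$participant_id) %>%
    summarise(mean_rt = mean(.data$mean_rt_ms, na.rm = TRUE), .groups = "drop") %>%
    left_join(vocab, by = "participant_id")
  spearman_rho(means$mean_rt, means$cdi_produced)
}

#' Full comparison report for a cohort
#'
#' Assembles every statistic of the standard analysis: valid-trial yield per
#' condition with the one-sided paired t test, mean RTs with a two-sided
#' paired t test, the between-condition Spearman correlation, within-
#' condition split-half reliabilities, the trial-order effect, the
#' word-knowledge effect, and the RT-vocabulary correlation.
#'
#' @param outcomes Trial outcomes ([extract_outcomes()]).
#' @param vocab Vocabulary tibble (optional; vocabulary analyses are skipped
#'   with an explicit marker when absent).
#' @param config An [lwl_config()].
#' @param seed Seed for the split-half randomisation.
#' @param min_rt_trials Inclusion threshold, see [apply_inclusion()].
#' @return List of class `lwl_report`.
#' @export
comparison_report <- function(outcomes, vocab = NULL, config = lwl_config(),
                              seed = 1, min_rt_trials = 1) {
  summaries <- summarize_participants(outcomes)
  incl <- apply_inclusion(summaries, min_rt_trials)
  s <- incl$included
  wide <- s %>%
    select("participant_id", "condition", "pct_valid", "mean_rt_ms",
           "rt_valid_trials") %>%
    tidyr::pivot_wider(names_from = "condition",
                       values_from = c("pct_valid", "mean_rt_ms", "rt_valid_trials"))
  keep_out <- outcomes %>% filter(.data$participant_id %in% s$participant_id)

  valid_stats <- function(cond) {
    v <- s$rt_valid_trials[s$condition == cond]
    list(mean = mean(v), sd = sd(v), range = range(v))
  }
  pct_t <- paired_t_one_sided(wide$pct_valid_gaze_triggered,
                              wide$pct_valid_original, "greater")
  rt_ok <- is.finite(wide$mean_rt_ms_gaze_triggered) &
    is.finite(wide$mean_rt_ms_original)
  rt_t <- paired_t_one_sided(wide$mean_rt_ms_gaze_triggered[rt_ok],
                             wide$mean_rt_ms_original[rt_ok], "two.sided")
  between <- spearman_rho(wide$mean_rt_ms_gaze_triggered,
                          wide$mean_rt_ms_original)
  sh <- lapply(c(gaze_triggered = "gaze_triggered", original = "original"),
               function(cond) {
                 tryCatch(
                   split_half_reliability(keep_out, cond, seed = mix_seed(seed, 29)),
                   lwl_domain_error = function(e) list(insufficient_n = TRUE)
                 )
               })
  order_eff <- tryCatch(trial_order_effect(keep_out, "gaze_triggered"),
                        lwl_domain_error = function(e) list(insufficient_n = TRUE))
  word_eff <- NULL
  vocab_rho <- NULL
  if (!is.null(vocab)) {
    wk <- word_known_filter_and_effect(keep_out, vocab, config)
    word_eff <- wk$effect %||% list(insufficient_n = TRUE)
    vocab_rho <- tryCatch(vocab_correlation(s, vocab),
                          lwl_domain_error = function(e) list(insufficient_n = TRUE))
  } else {
    word_eff <- list(skipped = "no vocabulary data supplied")
    vocab_rho <- list(skipped = "no vocabulary data supplied")
  }

  structure(list(
    n_participants = length(unique(s$participant_id)),
    n_excluded = nrow(incl$excluded),
    exclusions = incl$excluded,
    valid_trials = list(gaze_triggered = valid_stats("gaze_triggered"),
                        original = valid_stats("original")),
    pct_valid = list(
      mean_gaze_triggered = mean(s$pct_valid[s$condition == "gaze_triggered"], na.rm = TRUE),
      mean_original = mean(s$pct_valid[s$condition == "original"], na.rm = TRUE),
      paired_t_one_sided = pct_t
    ),
    mean_rt = list(
      gaze_triggered = mean(s$mean_rt_ms[s$condition == "gaze_triggered"], na.rm = TRUE),
      original = mean(s$mean_rt_ms[s$condition == "original"], na.rm = TRUE),
      sd_gaze_triggered = sd(s$mean_rt_ms[s$condition == "gaze_triggered"], na.rm = TRUE),
      sd_original = sd(s$mean_rt_ms[s$condition == "original"], na.rm = TRUE),
      paired_t_two_sided = rt_t
    ),
    between_condition_spearman = between,
    split_half = sh,
    trial_order = order_eff,
    word_known = word_eff,
    vocab_correlation = vocab_rho,
    seed = seed
  ), class = "lwl_report")
}

#' @export
print.lwl_report <- function(x, ...) {
  cat("<lwl_report>\n")
  cat(sprintf("  participants included: %d (excluded: %d)\n",
              x$n_participants, x$n_excluded))
  cat(sprintf("  %% valid RT trials: gaze-triggered %.2f vs original %.2f (t(%d) = %.2f, one-sided p = %.3g)\n",
              x$pct_valid$mean_gaze_triggered, x$pct_valid$mean_original,
              x$pct_valid$paired_t_one_sided$df, x$pct_valid$paired_t_one_sided$t,
              x$pct_valid$paired_t_one_sided$p))
  cat(sprintf("  mean RT (ms): gaze-triggered %.1f vs original %.1f (t(%d) = %.2f, p = %.3g)\n",
              x$mean_rt$gaze_triggered, x$mean_rt$original,
              x$mean_rt$paired_t_two_sided$df, x$mean_rt$paired_t_two_sided$t,
              x$mean_rt$paired_t_two_sided$p))
  b <- x$between_condition_spearman
  cat(sprintf("  between-condition Spearman rho = %.3f (n = %d, p = %.3g, 95%% CI [%.2f, %.2f])\n",
              b$rho, b$n, b$p, b$ci[1], b$ci[2]))
  for (cond in names(x$split_half)) {
    shc <- x$split_half[[cond]]
    if (isTRUE(shc$insufficient_n)) {
      cat(sprintf("  split-half (%s): insufficient n\n", cond))
    } else {
      cat(sprintf("  split-half (%s): rho = %.3f (n = %d, dropped %d)\n",
                  cond, shc$rho, shc$n, shc$n_dropped))
    }
  }
  invisible(x)
}

#' Serialise a comparison report to JSON
#'
#' @param report An `lwl_report`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_report_json <- function(report, path) {
  jsonlite::write_json(unclass(report), path, auto_unbox = TRUE, digits = NA,
                       na = "null", force = TRUE)
  invisible(path)
}
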