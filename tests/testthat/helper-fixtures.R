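# Shared fixtures and independent brute-force oracles. All fixtures are
# generated in code under fixed seeds; nothing is read from disk.

# A random fixation stream of sequential bouts with occasional gaps; integer
# millisecond times so the ms-grid oracles are exact.
random_stream <- function(n_bouts = 12, t_max = 10000,
                          aois = c("left", "right", "off")) {
  dur <- sample(30:900, n_bouts, replace = TRUE)
  gap <- sample(0:150, n_bouts, replace = TRUE) * rbinom(n_bouts, 1, 0.3)
  onset <- cumsum(c(0, head(dur + gap, -1)))
  keep <- onset < t_max
  data.frame(
    onset = onset[keep],
    offset = pmin(onset[keep] + dur[keep], t_max),
    aoi = sample(aois, sum(keep), replace = TRUE)
  )
}

# Brute-force trigger oracle: millisecond occupancy grid over the trigger
# window; the first run of >= fix_ms consecutive ms on a single picture AOI
# wins, triggering at run start (clipped to the window) + fix_ms.
bf_trigger <- function(stream, window_start, window_ms = 5000, fix_ms = 100) {
  t0 <- window_start
  grid <- rep(NA_character_, window_ms + fix_ms)
  for (i in seq_len(nrow(stream))) {
    a <- max(stream$onset[i], t0)
    b <- min(stream$offset[i], t0 + length(grid))
    if (b > a) grid[(a - t0 + 1):(b - t0)] <- stream$aoi[i]
  }
  best <- NULL
  for (aoi in c("left", "right")) {
    occ <- !is.na(grid) & grid == aoi
    r <- rle(occ)
    ends <- cumsum(r$lengths)
    starts <- ends - r$lengths + 1
    ok <- which(r$values & r$lengths >= fix_ms)
    for (j in ok) {
      trig_t <- t0 + starts[j] - 1 + fix_ms
      if (trig_t <= t0 + window_ms && (is.null(best) || trig_t < best$time)) {
        best <- list(aoi = aoi, time = trig_t)
      }
    }
  }
  best
}

# Brute-force attention oracle: count on-screen milliseconds in the window.
bf_attention <- function(stream, label_onset, win = c(0, 2000), min_ms = 100) {
  a <- label_onset + win[1]
  b <- label_onset + win[2]
  grid <- rep(FALSE, b - a)
  scr <- stream[stream$aoi %in% c("left", "right"), , drop = FALSE]
  for (i in seq_len(nrow(scr))) {
    lo <- max(scr$onset[i], a)
    hi <- min(scr$offset[i], b)
    if (hi > lo) grid[(lo - a + 1):(hi - a)] <- TRUE
  }
  sum(grid) >= min_ms
}

# Brute-force RT oracle: exhaustive scan over fixations.
bf_rt <- function(stream, label_onset, target_side) {
  initial <- "none"
  for (i in seq_len(nrow(stream))) {
    if (stream$onset[i] <= label_onset && stream$offset[i] > label_onset &&
        stream$aoi[i] %in% c("left", "right")) {
      initial <- if (stream$aoi[i] == target_side) "target" else "distractor"
      break
    }
  }
  rt <- NA_real_
  cand <- Inf
  for (i in seq_len(nrow(stream))) {
    if (stream$aoi[i] == target_side && stream$onset[i] > label_onset) {
      cand <- min(cand, stream$onset[i])
    }
  }
  if (is.finite(cand)) rt <- cand - label_onset
  list(initial = initial, rt = rt)
}

# Gaze table for a whole session under a deterministic policy: one long
# continuous fixation per trial on the requested side.
policy_gaze <- function(schedule, side_for_trial) {
  trials <- schedule$trials
  do.call(rbind, lapply(seq_len(nrow(trials)), function(i) {
    data.frame(
      trial_index = trials$trial_index[i],
      onset = 0,
      offset = 15000,
      aoi = side_for_trial(trials[i, ])
    )
  }))
}

# Side showing item_a on each trial (item_a for fillers: just "left").
side_of_item_a <- function(row) {
  pairs <- lwl_item_pairs()
  ia <- pairs$item_a[match(row$pair_id, pairs$pair_id)]
  if (is.na(ia)) return("left")
  if (row$left_item == ia) "left" else "right"
}

# Replicate cohorts are expensive; simulate them once per test run and share
# across the acceptance blocks that need them.
.rep_cohort_cache <- new.env(parent = emptyenv())

replicate_cohorts <- function(n_reps = 20, n = 43, base_seed = 101) {
  key <- sprintf("r%d_n%d_s%d", n_reps, n, base_seed)
  if (!is.null(.rep_cohort_cache[[key]])) return(.rep_cohort_cache[[key]])
  cfg <- lwl_config()
  out <- lapply(seq_len(n_reps), function(r) {
    coh <- simulate_cohort(n, cfg, seed = base_seed + r - 1)
    outcomes <- extract_outcomes(coh$gaze, coh$events, cfg)
    summaries <- summarize_participants(outcomes)
    mu <- vapply(coh$truth, function(p) p$mu_latency_ms, numeric(1))
    names(mu) <- vapply(coh$truth, function(p) p$participant_id, character(1))
    list(outcomes = outcomes, summaries = summaries, mu_true = mu,
         seed = base_seed + r - 1)
  })
  .rep_cohort_cache[[key]] <- out
  out
}
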