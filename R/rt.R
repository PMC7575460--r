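# Trial-validity and visual reaction-time rules, plus per-participant
# aggregation and cohort inclusion.

#' Attention criterion for one trial
#'
#' A trial counts as attended when total on-screen (left or right AOI)
#' looking inside the critical window (0-2000 ms after label onset) reaches
#' `attention_min_ms`; the looking may be split across several fixations.
#'
#' @param stream Fixation table for the trial (`onset`/`offset` or
#'   `fix_onset_ms`/`fix_offset_ms`, plus `aoi`), trial-relative ms.
#' @param label_onset_ms Label onset, trial-relative ms.
#' @param config An [lwl_config()].
#' @return Logical flag.
#' @export
attention_valid <- function(stream, label_onset_ms, config = lwl_config()) {
  stream <- normalize_stream(stream)
  if (is.null(stream) || nrow(stream) == 0) return(FALSE)
  scr <- stream[stream$aoi %in% c("left", "right"), , drop = FALSE]
  w <- label_onset_ms + config$attention_window
  interval_overlap_total(scr$onset, scr$offset, w[1], w[2]) >= config$attention_min_ms
}

#' Extract the trial outcome and visual reaction time
#'
#' The initial AOI is the AOI of the fixation whose interval covers the
#' label-onset instant (none if the infant is off-screen or between
#' fixations at that moment). The RT is the onset, relative to label onset,
#' of the first target-AOI fixation beginning after label onset. A valid RT
#' requires an attended trial, a distractor-initial start, no bias
#' correction or manual trigger, and a shift inside the validity window
#' (300-1800 ms by default); out-of-window shifts are recorded but flagged
#' with a reason. Bias-corrected and manually triggered trials never yield
#' an RT.
#'
#' @param stream Fixation table for one trial, trial-relative ms (use the
#'   filtered fixations, see [filter_short_fixations()]).
#' @param event One events row for the trial ([run_trial()] record).
#' @param config An [lwl_config()].
#' @return One-row tibble: `trial_index`, `condition`, `attended`,
#'   `initial_aoi_at_onset`, `rt_ms`, `rt_valid`, `invalid_reason`,
#'   `bias_corrected`, `manual_trigger`, `completed`, `target_item`,
#'   `pair_id`.
#' @export
extract_rt <- function(stream, event, config = lwl_config()) {
  as_tibble(extract_rt_core(normalize_stream(stream), event, config))
}

extract_rt_core <- function(stream, event, config) {
  L <- event$label_onset_ms
  attended <- attention_valid(stream, L, config)

  initial <- "none"
  rt <- NA_real_
  if (!is.null(stream) && nrow(stream) > 0) {
    cov <- which(stream$onset <= L & stream$offset > L &
                   stream$aoi %in% c("left", "right"))
    if (length(cov) > 0) {
      side <- stream$aoi[cov[1]]
      initial <- if (side == event$target_side) "target" else "distractor"
    }
    tgt_on <- stream$onset[stream$aoi == event$target_side & stream$onset > L]
    if (length(tgt_on) > 0) rt <- min(tgt_on) - L
  }

  reason <- "valid"
  if (event$bias_corrected) {
    reason <- "bias_corrected"
  } else if (event$manual_trigger) {
    reason <- "manual_trigger"
  } else if (!attended) {
    reason <- "not_attended"
  } else if (initial == "target") {
    reason <- "target_initial"
  } else if (initial == "none") {
    reason <- "no_aoi_at_onset"
  } else if (is.na(rt)) {
    reason <- "no_shift"
  } else if (rt < config$rt_window[1]) {
    reason <- "too_early"
  } else if (rt > config$rt_window[2]) {
    reason <- "too_late"
  }
  if (event$bias_corrected || event$manual_trigger) rt <- NA_real_

  list(
    participant_id = event$participant_id %||% NA_character_,
    trial_index = event$trial_index,
    condition = event$trial_type,
    pair_id = event$pair_id,
    target_item = event$target_item,
    attended = attended,
    initial_aoi_at_onset = initial,
    rt_ms = rt,
    rt_valid = reason == "valid",
    invalid_reason = reason,
    bias_corrected = event$bias_corrected,
    manual_trigger = event$manual_trigger,
    completed = event$completed
  )
}

#' Compute trial outcomes for a whole data set
#'
#' Applies the fixation filter, segments experimental trials, and runs
#' [extract_rt()] on every completed or attempted experimental trial.
#'
#' @param fixations Session or cohort fixation tibble.
#' @param events Matching events tibble.
#' @param config An [lwl_config()].
#' @return Outcomes tibble, one row per experimental trial in `events`.
#' @export
extract_outcomes <- function(fixations, events, config = lwl_config()) {
  fx <- filter_short_fixations(normalize_stream(fixations), config$min_fixation_ms)
  fx <- as.data.frame(fx)
  ev <- as.data.frame(events[events$trial_type != "filler", , drop = FALSE])
  if (nrow(ev) == 0) {
    return(extract_rt(NULL, list(
      participant_id = NA_character_, trial_index = 0L, trial_type = "original",
      pair_id = NA_character_, target_item = NA_character_, target_side = "left",
      label_onset_ms = 0, bias_corrected = FALSE, manual_trigger = FALSE,
      completed = FALSE
    ), config)[0, ])
  }
  key_f <- paste(fx$participant_id, fx$trial_index)
  fx_idx <- split(seq_len(nrow(fx)), key_f)
  out <- vector("list", nrow(ev))
  for (i in seq_len(nrow(ev))) {
    e <- ev[i, ]
    idx <- fx_idx[[paste(e$participant_id, e$trial_index)]]
    stream <- if (is.null(idx)) NULL else fx[idx, , drop = FALSE]
    out[[i]] <- extract_rt_core(stream, e, config)
  }
  cols <- names(out[[1]])
  res <- lapply(cols, function(cn) unlist(lapply(out, `[[`, cn), use.names = FALSE))
  names(res) <- cols
  as_tibble(res)
}

#' Summarise outcomes per participant and condition
#'
#' Per condition: completed experimental trials, attended trials, RT-valid
#' trials, the percentage of completed trials yielding a valid RT, and the
#' mean/SD of valid RTs. A condition with zero completed trials gets an
#' undefined (NA) percentage and is flagged.
#'
#' @param outcomes Tibble from [extract_outcomes()].
#' @return Tibble, one row per participant x condition, plus `included`
#'   (valid RT in both conditions, see [apply_inclusion()]).
#' @export
summarize_participants <- function(outcomes) {
  res <- outcomes %>%
    group_by(.data$participant_id, .data$condition) %>%
    summarise(
      completed_trials = sum(.data$completed),
      attended_trials = sum(.data$attended),
      rt_valid_trials = sum(.data$rt_valid),
      pct_valid = ifelse(sum(.data$completed) > 0,
                         100 * sum(.data$rt_valid) / sum(.data$completed),
                         NA_real_),
      mean_rt_ms = ifelse(sum(.data$rt_valid) > 0,
                          mean(.data$rt_ms[.data$rt_valid]), NA_real_),
      sd_rt_ms = ifelse(sum(.data$rt_valid) > 1,
                        sd(.data$rt_ms[.data$rt_valid]), NA_real_),
      .groups = "drop"
    )
  incl <- res %>%
    group_by(.data$participant_id) %>%
    summarise(included = sum(.data$rt_valid_trials >= 1) == 2 & n() == 2,
              .groups = "drop")
  left_join(res, incl, by = "participant_id")
}

#' Apply the participant inclusion rule
#'
#' Keeps participants with at least `min_rt_trials` valid reaction times in
#' *each* condition (default 1; much of the literature uses 2) and logs each
#' exclusion with its reason.
#'
#' @param summaries Tibble from [summarize_participants()].
#' @param min_rt_trials Minimum valid RT trials per condition.
#' @return List with `included` (filtered summaries) and `excluded`
#'   (tibble `participant_id`, `reason`).
#' @export
apply_inclusion <- function(summaries, min_rt_trials = 1) {
  status <- summaries %>%
    group_by(.data$participant_id) %>%
    summarise(
      n_conditions = n(),
      min_valid = min(.data$rt_valid_trials),
      .groups = "drop"
    )
  bad <- status %>%
    filter(.data$n_conditions < 2 | .data$min_valid < min_rt_trials) %>%
    mutate(reason = ifelse(
      .data$n_conditions < 2,
      "missing a condition entirely",
      sprintf("fewer than %d valid RT trials in at least one condition", min_rt_trials)
    )) %>%
    select("participant_id", "reason")
  list(
    included = summaries %>% filter(!.data$participant_id %in% bad$participant_id),
    excluded = bad
  )
}
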