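# The gaze-contingent trial state machine: trigger detection, target
# selection with bias correction, per-trial event generation, and the
# session-level stop rule.

# Accept either analysis-style (onset/offset/aoi) or file-style
# (fix_onset_ms/fix_offset_ms/aoi) fixation tables.
normalize_stream <- function(stream) {
  if (!is.null(stream) && "fix_onset_ms" %in% names(stream)) {
    stream <- stream %>% rename(onset = "fix_onset_ms", offset = "fix_offset_ms")
  }
  stream
}

# Merge temporally contiguous fixations on the same AOI into runs.
# Returns a data.frame with aoi, onset, offset, one row per run.
merge_aoi_runs <- function(stream) {
  if (is.null(stream) || nrow(stream) == 0) {
    return(data.frame(aoi = character(0), onset = numeric(0), offset = numeric(0)))
  }
  s <- stream[order(stream$onset), , drop = FALSE]
  new_run <- c(TRUE, s$aoi[-1] != s$aoi[-nrow(s)] | s$onset[-1] > s$offset[-nrow(s)])
  run_id <- cumsum(new_run)
  first <- !duplicated(run_id)
  last <- !duplicated(run_id, fromLast = TRUE)
  data.frame(
    aoi = s$aoi[first],
    onset = s$onset[first],
    offset = s$offset[last],
    row.names = NULL
  )
}

#' Detect the gaze trigger within a trial
#'
#' Scans a time-ordered fixation stream for the first continuous fixation of
#' at least `trigger_fix_ms` on one of the two picture AOIs inside the
#' trigger window. A look already in progress at window start counts from
#' window start. Contiguous fixations on the same AOI (no temporal gap) are
#' treated as one continuous look.
#'
#' @param stream Fixation table with columns `onset`, `offset`, `aoi`
#'   (`"left"`, `"right"`, `"off"`, `"attention_getter"`); times in ms.
#' @param window_start Start of the trigger window (normally exclamation
#'   offset), ms.
#' @param config An [lwl_config()].
#' @return A list with `aoi` (`"left"`/`"right"`) and `time` (ms, the end of
#'   the qualifying fixation run's first `trigger_fix_ms`), or `NULL` on
#'   timeout (including an empty stream).
#' @export
detect_trigger_fixation <- function(stream, window_start, config = lwl_config()) {
  stream <- normalize_stream(stream)
  runs <- merge_aoi_runs(stream)
  runs <- runs[runs$aoi %in% c("left", "right"), , drop = FALSE]
  if (nrow(runs) == 0) return(NULL)
  w1 <- window_start + config$trigger_window_ms
  start_in <- pmax(runs$onset, window_start)
  t_trig <- start_in + config$trigger_fix_ms
  ok <- t_trig <= pmin(runs$offset, w1)
  if (!any(ok)) return(NULL)
  i <- which(ok)[which.min(t_trig[ok])]
  list(aoi = runs$aoi[i], time = unname(t_trig[i]))
}

#' Fresh session state for the controller
#'
#' Tracks the consecutive-failure counter and, per pair, the sequence of
#' pre-naming fixated items and the per-item label counts that drive bias
#' correction in the gaze-triggered condition.
#'
#' @param config An [lwl_config()].
#' @return A list with `consecutive_failed`, `trials_run`, `pairs`.
#' @export
new_session_state <- function(config = lwl_config()) {
  pairs <- config$pairs
  ph <- lapply(seq_len(nrow(pairs)), function(p) {
    list(
      fixated_sequence = character(0),
      label_counts = setNames(c(0L, 0L), c(pairs$item_a[p], pairs$item_b[p]))
    )
  })
  names(ph) <- pairs$pair_id
  list(consecutive_failed = 0L, trials_run = 0L, pairs = ph)
}

#' Choose the target on a gaze-triggered trial
#'
#' Implements the gaze-contingent rule with bias correction. By default the
#' fixated item becomes the distractor and its pair mate is named. Two
#' deviations keep each item of a pair labelled equally often: (1) if the
#' infant fixates the same item of a pair for the third time in a row, that
#' item is named instead; (2) on the pair's fourth (final) gaze-triggered
#' trial the target is whichever item has been labelled less often so far,
#' enforcing an exact 2/2 split (`fourth_trial_rule = "balance"`). The
#' alternative reading `"repeat_previous"` deviates on the fourth trial only
#' when the infant fixates the same item as on the pair's previous trial; it
#' does not guarantee exact balance and is provided for sensitivity analysis.
#'
#' @param pair_history List with `fixated_sequence` (items fixated at trigger
#'   time on the pair's prior gaze-triggered trials, `NA` for manual
#'   triggers) and `label_counts` (named counts of labels per item).
#' @param fixated The item fixated at trigger time.
#' @param trial_ordinal This trial's ordinal (1-4) among the pair's
#'   gaze-triggered trials.
#' @param rule Fourth-trial rule, see above.
#' @return List with `target` and `bias_corrected` (TRUE iff the fixated
#'   item itself is named).
#' @export
#' @examples
#' h <- list(fixated_sequence = c("apple", "apple"),
#'           label_counts = c(apple = 0, jacket = 2))
#' select_target_gaze(h, "apple", 3) # third in a row: apple is named
select_target_gaze <- function(pair_history, fixated, trial_ordinal,
                               rule = c("balance", "repeat_previous")) {
  rule <- match.arg(rule)
  items <- names(pair_history$label_counts)
  if (!fixated %in% items) {
    abort(sprintf("fixated item '%s' is not in the pair (%s)",
                  fixated, paste(items, collapse = ", ")),
          class = "lwl_domain_error")
  }
  other <- setdiff(items, fixated)
  seqn <- pair_history$fixated_sequence
  third_in_row <- length(seqn) >= 2 &&
    !is.na(seqn[length(seqn)]) && !is.na(seqn[length(seqn) - 1]) &&
    seqn[length(seqn)] == fixated && seqn[length(seqn) - 1] == fixated

  max_ordinal <- 4L
  if (rule == "balance" && trial_ordinal >= max_ordinal) {
    counts <- pair_history$label_counts
    target <- names(counts)[which.min(counts)]
    return(list(target = target, bias_corrected = identical(target, fixated)))
  }
  if (rule == "repeat_previous" && trial_ordinal >= max_ordinal &&
      length(seqn) >= 1 && !is.na(seqn[length(seqn)]) &&
      seqn[length(seqn)] == fixated) {
    return(list(target = fixated, bias_corrected = TRUE))
  }
  if (third_in_row) {
    return(list(target = fixated, bias_corrected = TRUE))
  }
  list(target = other, bias_corrected = FALSE)
}

# Target choice when the experimenter triggers the label manually (infant
# never met the gaze criterion): the pair's least-labelled item, ties broken
# by the schedule's backup target.
manual_trigger_target <- function(pair_history, backup_target) {
  counts <- pair_history$label_counts
  if (counts[1] == counts[2]) {
    return(backup_target)
  }
  names(counts)[which.min(counts)]
}

#' Run one trial through the controller
#'
#' Replays a fixation stream against the trial timeline: 2 s silent preview,
#' exclamation, then either the fixed 100 ms silence before a predetermined
#' label (original and filler trials) or the gaze trigger (gaze-triggered
#' trials, with manual fallback on timeout). Updates the pair's label
#' bookkeeping and the consecutive-failure counter.
#'
#' @param spec One schedule row (list or one-row tibble).
#' @param stream Fixation table for the trial, trial-relative ms (picture
#'   onset = 0), spanning the whole trial.
#' @param state Session state from [new_session_state()] (or a previous
#'   `run_trial()` call).
#' @param config An [lwl_config()].
#' @return List with `record` (one-row tibble of trial events) and `state`.
#' @export
run_trial <- function(spec, stream, state, config = lwl_config()) {
  stream <- normalize_stream(stream)
  if (!is.null(stream) && "trial_index" %in% names(stream) && nrow(stream) > 0) {
    if (any(stream$trial_index != spec$trial_index)) {
      abort(sprintf("stream trial_index does not match spec trial_index %d",
                    spec$trial_index),
            class = "lwl_input_error")
    }
  }
  excl_onset <- config$preview_ms
  excl_offset <- excl_onset + config$exclamation_durations_ms[spec$exclamation_id]

  bias_corrected <- FALSE
  manual_trigger <- FALSE

  if (spec$trial_type == "gaze_triggered") {
    trig <- detect_trigger_fixation(stream, excl_offset, config)
    hist <- state$pairs[[spec$pair_id]]
    ordinal <- length(hist$fixated_sequence) + 1L
    if (is.null(trig)) {
      manual_trigger <- TRUE
      label_onset <- excl_offset + config$trigger_window_ms
      target <- manual_trigger_target(hist, spec$backup_target)
      fixated <- NA_character_
    } else {
      fixated <- if (trig$aoi == "left") spec$left_item else spec$right_item
      sel <- select_target_gaze(hist, fixated, ordinal, rule = config$fourth_trial_rule)
      target <- sel$target
      bias_corrected <- sel$bias_corrected
      label_onset <- trig$time
    }
    hist$fixated_sequence <- c(hist$fixated_sequence, fixated)
    hist$label_counts[target] <- hist$label_counts[target] + 1L
    state$pairs[[spec$pair_id]] <- hist
  } else {
    label_onset <- excl_offset + config$original_silence_ms
    target <- spec$predetermined_target
  }

  trial_end <- label_onset + config$post_label_ms
  on_screen <- 0
  if (!is.null(stream) && nrow(stream) > 0) {
    scr <- stream[stream$aoi %in% c("left", "right"), , drop = FALSE]
    on_screen <- interval_overlap_total(scr$onset, scr$offset, 0, trial_end)
  }
  completed <- on_screen >= config$attention_min_ms

  state$trials_run <- state$trials_run + 1L
  state$consecutive_failed <- if (completed) 0L else state$consecutive_failed + 1L

  target_side <- if (target == spec$left_item) "left" else "right"
  distractor <- if (target_side == "left") spec$right_item else spec$left_item
  record <- tibble::new_tibble(list(
    trial_index = spec$trial_index,
    block_index = spec$block_index,
    trial_type = spec$trial_type,
    pair_id = spec$pair_id,
    target_item = target,
    distractor_item = distractor,
    target_side = target_side,
    picture_onset_ms = 0,
    exclamation_onset_ms = excl_onset,
    label_onset_ms = label_onset,
    bias_corrected = bias_corrected,
    manual_trigger = manual_trigger,
    completed = completed
  ), nrow = 1L)
  list(record = record, state = state)
}

#' Session stop rule
#'
#' The session is ended once the participant has failed to complete
#' `stop_after_failed` trials in a row.
#'
#' @param state Session state.
#' @param config An [lwl_config()].
#' @return `"stop"` or `"continue"`.
#' @export
session_stop_rule <- function(state, config = lwl_config()) {
  if (state$consecutive_failed >= config$stop_after_failed) "stop" else "continue"
}

#' Replay a whole session offline
#'
#' Runs every scheduled trial against a recorded (or simulated) gaze table,
#' applying the stop rule between trials; trials after a stop are not run.
#'
#' @param schedule An `lwl_schedule`.
#' @param gaze Fixation table for the session with columns `trial_index`,
#'   `fix_onset_ms`/`onset`, `fix_offset_ms`/`offset`, `aoi`.
#' @param config Defaults to the schedule's config.
#' @param participant_id Identifier stamped on the event rows.
#' @return Events tibble, one row per trial run (see [run_trial()]).
#' @export
run_session <- function(schedule, gaze, config = NULL,
                        participant_id = schedule$participant_index) {
  config <- config %||% schedule$config
  gaze <- normalize_stream(gaze)
  state <- new_session_state(config)
  records <- list()
  for (i in seq_len(nrow(schedule$trials))) {
    spec <- schedule$trials[i, ]
    stream <- gaze[gaze$trial_index == spec$trial_index, , drop = FALSE]
    res <- run_trial(spec, stream, state, config)
    state <- res$state
    records[[length(records) + 1]] <- res$record
    if (session_stop_rule(state, config) == "stop") break
  }
  out <- bind_rows(records)
  out$participant_id <- participant_id
  select(out, "participant_id", dplyr::everything())
}
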