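# Reading gaze data, filtering fixations, assigning AOIs, and segmenting
# records into analysis-ready experimental trials.

#' Read a fixation CSV
#'
#' Expects columns `participant_id`, `trial_index`, `fix_onset_ms`,
#' `fix_offset_ms`, `aoi` (times in ms from picture onset). Rows whose
#' offset does not exceed their onset are rejected with their line numbers.
#'
#' @param path CSV file path.
#' @return Tibble of fixations.
#' @export
read_fixation_csv <- function(path) {
  df <- tryCatch(
    read.csv(path, stringsAsFactors = FALSE),
    error = function(e) abort(sprintf("cannot parse '%s': %s", path, conditionMessage(e)),
                              class = "lwl_io_error")
  )
  required <- c("participant_id", "trial_index", "fix_onset_ms", "fix_offset_ms", "aoi")
  missing <- setdiff(required, names(df))
  if (length(missing) > 0) {
    abort(paste0("fixation file is missing columns: ", paste(missing, collapse = ", ")),
          class = "lwl_io_error")
  }
  bad_num <- which(!is.finite(df$fix_onset_ms) | !is.finite(df$fix_offset_ms))
  if (length(bad_num) > 0) {
    abort(paste0("malformed fixation rows (non-numeric times) at data lines: ",
                 paste(bad_num, collapse = ", ")),
          class = "lwl_io_error")
  }
  bad <- which(df$fix_offset_ms <= df$fix_onset_ms)
  if (length(bad) > 0) {
    abort(paste0("fixations with offset <= onset at data lines: ",
                 paste(bad, collapse = ", ")),
          class = "lwl_io_error")
  }
  as_tibble(df)
}

#' Parse a minimal EyeLink ASCII (`.asc`) fixation report
#'
#' Consumes only `EFIX` fixation-end lines and `MSG` lines carrying the trial
#' events `TRIAL_START <i>`, `EXCL_ONSET`, `LABEL_ONSET`, `TRIAL_END`.
#' Fixations are re-based to trial-relative ms (picture onset = 0); a
#' fixation straddling `TRIAL_END` is truncated at trial end and flagged in
#' column `truncated`. When both eyes are recorded, the right eye is kept.
#' `EFIX` lines before any `TRIAL_START` are dropped with a warning, as is a
#' file with no `MSG` tags at all.
#'
#' @param lines Character vector of ASC lines (or a file path).
#' @return List with `fixations` (tibble: `trial_index`, `fix_onset_ms`,
#'   `fix_offset_ms`, `x`, `y`, `truncated`) and `events` (tibble:
#'   `trial_index`, `excl_onset_ms`, `label_onset_ms`, `trial_end_ms`,
#'   trial-relative).
#' @export
parse_asc_efix <- function(lines) {
  if (length(lines) == 1 && file.exists(lines)) lines <- readLines(lines)
  msg_re <- "^MSG\\s+(\\d+)\\s+(.*)$"
  efix_re <- "^EFIX\\s+([LR])\\s+(\\d+)\\s+(\\d+)\\s+(\\d+)\\s+([0-9.]+)\\s+([0-9.]+)\\s+([0-9.]+)"

  msg_lines <- grep(msg_re, lines, value = TRUE)
  if (length(msg_lines) == 0) {
    warn("no MSG lines found; returning empty fixation set")
    return(list(
      fixations = tibble(trial_index = integer(0), fix_onset_ms = numeric(0),
                         fix_offset_ms = numeric(0), x = numeric(0), y = numeric(0),
                         truncated = logical(0)),
      events = tibble(trial_index = integer(0), excl_onset_ms = numeric(0),
                      label_onset_ms = numeric(0), trial_end_ms = numeric(0))
    ))
  }
  msg_time <- as.numeric(sub(msg_re, "\\1", msg_lines))
  msg_tag <- trimws(sub(msg_re, "\\2", msg_lines))

  starts <- grepl("^TRIAL_START\\s+\\d+$", msg_tag)
  trial_ids <- as.integer(sub("^TRIAL_START\\s+", "", msg_tag[starts]))
  trial_t0 <- msg_time[starts]
  find_after <- function(tag, t0, t_next) {
    i <- which(msg_tag == tag & msg_time >= t0 & (is.na(t_next) | msg_time < t_next))
    if (length(i) == 0) NA_real_ else msg_time[i[1]]
  }
  n_tr <- length(trial_ids)
  next_t0 <- c(trial_t0[-1], NA)
  events <- tibble(
    trial_index = trial_ids,
    excl_onset_ms = vapply(seq_len(n_tr), function(i)
      find_after("EXCL_ONSET", trial_t0[i], next_t0[i]), numeric(1)) - trial_t0,
    label_onset_ms = vapply(seq_len(n_tr), function(i)
      find_after("LABEL_ONSET", trial_t0[i], next_t0[i]), numeric(1)) - trial_t0,
    trial_end_ms = vapply(seq_len(n_tr), function(i)
      find_after("TRIAL_END", trial_t0[i], next_t0[i]), numeric(1)) - trial_t0
  )

  efix_lines <- grep(efix_re, lines, value = TRUE)
  if (length(efix_lines) == 0) {
    return(list(
      fixations = tibble(trial_index = integer(0), fix_onset_ms = numeric(0),
                         fix_offset_ms = numeric(0), x = numeric(0), y = numeric(0),
                         truncated = logical(0)),
      events = events
    ))
  }
  m <- regmatches(efix_lines, regexec(efix_re, efix_lines))
  eye <- vapply(m, `[`, character(1), 2)
  f_on <- as.numeric(vapply(m, `[`, character(1), 3))
  f_off <- as.numeric(vapply(m, `[`, character(1), 4))
  fx <- as.numeric(vapply(m, `[`, character(1), 6))
  fy <- as.numeric(vapply(m, `[`, character(1), 7))
  if (any(eye == "R") && any(eye == "L")) {
    keep <- eye == "R"
    f_on <- f_on[keep]; f_off <- f_off[keep]; fx <- fx[keep]; fy <- fy[keep]
  }

  trial_of <- findInterval(f_on, trial_t0)
  orphan <- trial_of == 0
  if (any(orphan)) {
    warn(sprintf("%d EFIX line(s) before any TRIAL_START dropped", sum(orphan)))
  }
  keep <- !orphan
  trial_of <- trial_of[keep]
  t0 <- trial_t0[trial_of]
  t_end_abs <- t0 + events$trial_end_ms[trial_of]
  onset <- f_on[keep] - t0
  offset <- f_off[keep] - t0
  truncated <- !is.na(events$trial_end_ms[trial_of]) &
    f_off[keep] > t_end_abs
  offset[truncated] <- events$trial_end_ms[trial_of][truncated]
  inside <- is.na(events$trial_end_ms[trial_of]) | onset < events$trial_end_ms[trial_of]
  fixations <- tibble(
    trial_index = trial_ids[trial_of],
    fix_onset_ms = onset,
    fix_offset_ms = offset,
    x = fx[keep],
    y = fy[keep],
    truncated = truncated
  )[inside, ]
  list(fixations = fixations, events = events)
}

#' Drop fixations shorter than the minimum duration
#'
#' Fixations lasting less than `min_ms` (default 100 ms, the conventional
#' reliability threshold for infant eye-tracking) are removed; order is
#' preserved and the threshold is closed (a fixation of exactly `min_ms`
#' is kept).
#'
#' @param fixations Tibble with `fix_onset_ms`/`fix_offset_ms` (or
#'   `onset`/`offset`) columns.
#' @param min_ms Minimum duration in ms.
#' @return The filtered tibble.
#' @export
#' @examples
#' fx <- tibble::tibble(fix_onset_ms = c(0, 200), fix_offset_ms = c(99, 350))
#' filter_short_fixations(fx)
filter_short_fixations <- function(fixations, min_ms = 100) {
  nm <- names(fixations)
  on <- if ("fix_onset_ms" %in% nm) fixations$fix_onset_ms else fixations$onset
  off <- if ("fix_offset_ms" %in% nm) fixations$fix_offset_ms else fixations$offset
  fixations[off - on >= min_ms, , drop = FALSE]
}

#' Screen layout of the two picture areas of interest
#'
#' Axis-aligned, half-open rectangles `[x0, x1) x [y0, y1)` in pixels.
#' Defaults carve a 1600 x 900 screen into left and right halves separated
#' by a 200 px central gutter.
#'
#' @param left_region,right_region Numeric `c(x0, x1, y0, y1)`.
#' @param screen_size `c(width, height)` in pixels.
#' @return An `lwl_aoi_layout` list.
#' @export
aoi_layout <- function(left_region = c(0, 700, 0, 900),
                       right_region = c(900, 1600, 0, 900),
                       screen_size = c(1600, 900)) {
  overlap_x <- max(left_region[1], right_region[1]) < min(left_region[2], right_region[2])
  overlap_y <- max(left_region[3], right_region[3]) < min(left_region[4], right_region[4])
  if (overlap_x && overlap_y) {
    abort("AOI regions must be disjoint", class = "lwl_config_error")
  }
  structure(list(left_region = left_region, right_region = right_region,
                 screen_size = screen_size),
            class = "lwl_aoi_layout")
}

#' Assign screen coordinates to an AOI
#'
#' Point-in-half-open-rectangle: a point exactly on an upper boundary (`x1`
#' or `y1`) falls outside. Anything in neither region is `"off"`.
#'
#' @param x,y Numeric vectors of gaze coordinates in pixels.
#' @param layout An [aoi_layout()].
#' @return Character vector of `"left"`, `"right"`, `"off"`.
#' @export
assign_aoi <- function(x, y, layout = aoi_layout()) {
  in_rect <- function(r) {
    x >= r[1] & x < r[2] & y >= r[3] & y < r[4]
  }
  out <- rep("off", length(x))
  out[in_rect(layout$right_region)] <- "right"
  out[in_rect(layout$left_region)] <- "left"
  out
}

#' Segment fixations into analysis-ready experimental trials
#'
#' Joins fixations to the trial events, removes filler trials and
#' attention-getter fixations (calibration never enters the fixation
#' tables), and attaches each trial's label onset so label-relative times
#' can be computed on demand.
#'
#' @param fixations Fixation tibble (`participant_id`, `trial_index`,
#'   `fix_onset_ms`, `fix_offset_ms`, `aoi`).
#' @param events Events tibble as produced by [run_session()] /
#'   [simulate_cohort()].
#' @return Tibble of experimental-trial fixations with `condition`,
#'   `label_onset_ms` and `t_label` (= onset relative to label onset) added.
#' @export
segment_trials <- function(fixations, events) {
  key_f <- paste(fixations$participant_id, fixations$trial_index)
  key_e <- paste(events$participant_id, events$trial_index)
  orphan <- setdiff(unique(key_f), key_e)
  if (length(orphan) > 0) {
    abort(paste0("fixations reference trials absent from events: ",
                 paste(orphan, collapse = ", ")),
          class = "lwl_input_error")
  }
  ev <- events %>%
    select("participant_id", "trial_index", "trial_type", "pair_id",
           "target_item", "distractor_item", "target_side", "label_onset_ms",
           "bias_corrected", "manual_trigger", "completed")
  fixations %>%
    filter(.data$aoi != "attention_getter") %>%
    left_join(ev, by = c("participant_id", "trial_index")) %>%
    filter(.data$trial_type != "filler") %>%
    mutate(
      condition = .data$trial_type,
      t_label = .data$fix_onset_ms - .data$label_onset_ms
    )
}
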