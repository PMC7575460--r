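#' Default stimulus inventory: eight yoked picture pairs
#'
#' The sixteen experimental items used in the gaze-triggered
#' looking-while-listening design, four from each of the categories food,
#' animals, clothes and toys, arranged in eight fixed pairs. Pictures always
#' appear with their pair mate; side of presentation is counterbalanced by
#' [build_schedule()].
#'
#' @return A tibble with columns `pair_id`, `item_a`, `item_b`,
#'   `category_a`, `category_b`.
#' @export
#' @examples
#' lwl_item_pairs()
lwl_item_pairs <- function() {
  tibble(
    pair_id    = paste0("P", 1:8),
    item_a     = c("apple", "banana", "bottle", "bowl", "cat", "cow", "dog", "horse"),
    item_b     = c("jacket", "book", "ball", "shoe", "hat", "sock", "bike", "car"),
    category_a = c("food", "food", "food", "food", "animals", "animals", "animals", "animals"),
    category_b = c("clothes", "toys", "toys", "clothes", "clothes", "clothes", "toys", "toys")
  )
}

#' Design configuration for a looking-while-listening session
#'
#' Collects every timing constant and count the paradigm uses. Defaults
#' reproduce the standard 80-trial within-subject design: 32 gaze-triggered
#' trials, 32 original (predetermined-target) trials and 16 fillers, in
#' alternating blocks of eight experimental trials plus two fillers.
#'
#' @param n_gaze_trials,n_original_trials,n_filler_trials Trial counts per
#'   type (defaults 32, 32, 16).
#' @param block_size_experimental Experimental trials per block (default 8).
#' @param fillers_per_block Filler trials inserted per block (default 2).
#' @param attention_getter_fix_ms Fixation on the attention getter that ends
#'   the inter-trial phase (default 500 ms).
#' @param preview_ms Silent viewing before the exclamation (default 2000 ms).
#' @param original_silence_ms Pause between exclamation offset and label
#'   onset in the original condition (default 100 ms).
#' @param trigger_fix_ms Continuous single-AOI fixation that triggers the
#'   label in the gaze-triggered condition (default 100 ms).
#' @param trigger_window_ms Window after exclamation offset in which the gaze
#'   trigger is armed; on timeout the label is triggered manually
#'   (default 5000 ms).
#' @param post_label_ms Trial continuation after label onset (default 2000 ms).
#' @param min_fixation_ms Shortest fixation retained by the preprocessing
#'   filter (default 100 ms).
#' @param attention_window Analysis window, in ms after label onset, over
#'   which on-screen looking is summed (default `c(0, 2000)`).
#' @param attention_min_ms Minimum total on-screen looking inside
#'   `attention_window` for a trial to count as attended (default 100 ms).
#' @param rt_window Validity window for distractor-to-target shifts, in ms
#'   after label onset (default `c(300, 1800)`).
#' @param stop_after_failed Consecutive failed trials after which the session
#'   is ended (default 5).
#' @param filler_items The four filler picture labels.
#' @param pairs Item-pair inventory, see [lwl_item_pairs()].
#' @param exclamation_durations_ms Durations of the 16 exclamation
#'   recordings (4 exclamations x 4 variants); defaults span 610-1120 ms so
#'   original-condition label onsets fall 710-1220 ms after exclamation onset.
#' @param fourth_trial_rule How the fourth appearance of a pair in the
#'   gaze-triggered condition is resolved: `"balance"` (default) names
#'   whichever item has been labelled less often, guaranteeing an exact 2/2
#'   split; `"repeat_previous"` only deviates from the gaze rule when the
#'   infant fixates the same item as on the previous trial of that pair.
#'
#' @return A validated list of class `lwl_config`.
#' @export
#' @examples
#' cfg <- lwl_config()
#' cfg$rt_window
lwl_config <- function(n_gaze_trials = 32,
                       n_original_trials = 32,
                       n_filler_trials = 16,
                       block_size_experimental = 8,
                       fillers_per_block = 2,
                       attention_getter_fix_ms = 500,
                       preview_ms = 2000,
                       original_silence_ms = 100,
                       trigger_fix_ms = 100,
                       trigger_window_ms = 5000,
                       post_label_ms = 2000,
                       min_fixation_ms = 100,
                       attention_window = c(0, 2000),
                       attention_min_ms = 100,
                       rt_window = c(300, 1800),
                       stop_after_failed = 5,
                       filler_items = c("baby", "cookie", "spoon", "bear"),
                       pairs = lwl_item_pairs(),
                       exclamation_durations_ms = round(seq(610, 1120, length.out = 16)),
                       fourth_trial_rule = c("balance", "repeat_previous")) {
  cfg <- list(
    n_gaze_trials = n_gaze_trials,
    n_original_trials = n_original_trials,
    n_filler_trials = n_filler_trials,
    block_size_experimental = block_size_experimental,
    fillers_per_block = fillers_per_block,
    attention_getter_fix_ms = attention_getter_fix_ms,
    preview_ms = preview_ms,
    original_silence_ms = original_silence_ms,
    trigger_fix_ms = trigger_fix_ms,
    trigger_window_ms = trigger_window_ms,
    post_label_ms = post_label_ms,
    min_fixation_ms = min_fixation_ms,
    attention_window = attention_window,
    attention_min_ms = attention_min_ms,
    rt_window = rt_window,
    stop_after_failed = stop_after_failed,
    filler_items = filler_items,
    pairs = pairs,
    exclamation_durations_ms = exclamation_durations_ms,
    fourth_trial_rule = match.arg(fourth_trial_rule)
  )
  class(cfg) <- "lwl_config"
  validate_config(cfg)
  cfg
}

validate_config <- function(cfg) {
  durs <- c(
    cfg$attention_getter_fix_ms, cfg$preview_ms, cfg$original_silence_ms,
    cfg$trigger_fix_ms, cfg$trigger_window_ms, cfg$post_label_ms,
    cfg$min_fixation_ms, cfg$attention_min_ms
  )
  if (any(durs <= 0)) {
    abort("all durations in the design config must be > 0", class = "lwl_config_error")
  }
  if (cfg$rt_window[1] < cfg$attention_window[1] ||
      cfg$rt_window[2] > cfg$attention_window[2]) {
    abort("rt_window must lie within the attention analysis window", class = "lwl_config_error")
  }
  if (cfg$n_gaze_trials != cfg$n_original_trials) {
    abort("n_gaze_trials must equal n_original_trials", class = "lwl_config_error")
  }
  n_pairs <- nrow(cfg$pairs)
  if (cfg$n_gaze_trials %% n_pairs != 0) {
    abort(
      sprintf("n_gaze_trials (%d) must be divisible by the number of pairs (%d)",
              cfg$n_gaze_trials, n_pairs),
      class = "lwl_config_error"
    )
  }
  n_blocks_per_cond <- cfg$n_gaze_trials / cfg$block_size_experimental
  if (n_blocks_per_cond != floor(n_blocks_per_cond)) {
    abort("experimental trial count must divide into whole blocks", class = "lwl_config_error")
  }
  n_blocks <- 2 * n_blocks_per_cond
  if (cfg$n_filler_trials != n_blocks * cfg$fillers_per_block) {
    abort(
      sprintf("n_filler_trials (%d) must equal blocks (%d) x fillers_per_block (%d)",
              cfg$n_filler_trials, n_blocks, cfg$fillers_per_block),
      class = "lwl_config_error"
    )
  }
  if (any(cfg$pairs$item_a == cfg$pairs$item_b)) {
    abort("a pair cannot show the same item twice", class = "lwl_config_error")
  }
  invisible(cfg)
}

#' Read a design configuration from JSON
#'
#' @param path Path to a JSON file holding any subset of [lwl_config()]'s
#'   arguments; unspecified fields keep their defaults.
#' @return An `lwl_config` object.
#' @export
read_config_json <- function(path) {
  raw <- jsonlite::read_json(path, simplifyVector = TRUE)
  known <- names(formals(lwl_config))
  extra <- setdiff(names(raw), known)
  if (length(extra) > 0) {
    abort(paste0("unknown config fields: ", paste(extra, collapse = ", ")),
          class = "lwl_config_error")
  }
  if (!is.null(raw$pairs)) raw$pairs <- as_tibble(raw$pairs)
  do.call(lwl_config, raw)
}

#' @export
print.lwl_config <- function(x, ...) {
  cat("<lwl_config>\n")
  cat(sprintf("  trials: %d gaze-triggered + %d original + %d filler\n",
              x$n_gaze_trials, x$n_original_trials, x$n_filler_trials))
  cat(sprintf("  blocks: %d experimental + %d filler trials each\n",
              x$block_size_experimental, x$fillers_per_block))
  cat(sprintf("  trigger: %d ms fixation within %d ms window\n",
              x$trigger_fix_ms, x$trigger_window_ms))
  cat(sprintf("  RT window: %d-%d ms after label onset\n",
              x$rt_window[1], x$rt_window[2]))
  invisible(x)
}
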