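#' Condition order for a participant
#'
#' The condition of the first block is counterbalanced across participants by
#' parity: even participant indices start with the gaze-triggered condition,
#' odd indices with the original condition, so any even-sized cohort is
#' exactly balanced.
#'
#' @param participant_index Non-negative integer.
#' @return `"gaze_triggered"` or `"original"`.
#' @export
#' @examples
#' condition_order(0)
#' condition_order(1)
condition_order <- function(participant_index) {
  if (length(participant_index) != 1 || is.na(participant_index) ||
      participant_index < 0 || participant_index != floor(participant_index)) {
    abort("participant_index must be a single non-negative integer",
          class = "lwl_domain_error")
  }
  if (participant_index %% 2 == 0) "gaze_triggered" else "original"
}

# Uniformly sample the positions (0-based, within a block of
# block_size + n_fillers trials) of the filler trials: never first or last,
# never adjacent.
sample_filler_positions <- function(block_len, n_fillers) {
  slots <- 1:(block_len - 2)
  combos <- utils::combn(slots, n_fillers)
  ok <- apply(combos, 2, function(p) all(diff(sort(p)) >= 2))
  legal <- combos[, ok, drop = FALSE]
  sort(legal[, sample.int(ncol(legal), 1)])
}

# Rows of filler trials for the whole session, in presentation order.
# Each of the four filler items is named n_filler/4 times, partners rotate
# through the other three filler items, and each filler item appears on the
# left for half of its target appearances.
make_filler_rows <- function(config) {
  items <- config$filler_items
  n <- config$n_filler_trials
  k <- seq_len(n) - 1
  target <- items[(k %% 4) + 1]
  round_i <- k %/% 4
  partner <- vapply(seq_len(n), function(i) {
    others <- setdiff(items, target[i])
    others[(round_i[i] %% length(others)) + 1]
  }, character(1))
  target_left <- round_i %% 2 == 0
  tibble(
    trial_type = "filler",
    pair_id = "FILLER",
    left_item = ifelse(target_left, target, partner),
    right_item = ifelse(target_left, partner, target),
    predetermined_target = target,
    backup_target = NA_character_
  )
}

#' Build a counterbalanced session schedule
#'
#' Generates the full trial list for one participant: alternating blocks of
#' eight gaze-triggered or eight original trials, two filler trials inserted
#' pseudo-randomly into each block (never first, last, or adjacent), one
#' trial per pair per experimental block, exact 2/2 target balance per item
#' in the original condition, and exact left/right counterbalancing of every
#' item within each condition. Deterministic given
#' `(config, participant_index, seed)`.
#'
#' @param config An [lwl_config()].
#' @param participant_index Non-negative integer; also sets the condition of
#'   the first block via [condition_order()].
#' @param seed Integer RNG seed.
#' @return An object of class `lwl_schedule`: a list with
#'   `participant_index`, `condition_first`, `seed`, `config`, and `trials`
#'   (a tibble, one row per trial in presentation order).
#' @export
#' @examples
#' sch <- build_schedule(lwl_config(), participant_index = 0, seed = 1)
#' dplyr::count(sch$trials, trial_type)
build_schedule <- function(config = lwl_config(), participant_index = 0, seed = 1) {
  validate_config(config)
  first_cond <- condition_order(participant_index)
  pairs <- config$pairs
  n_pairs <- nrow(pairs)
  blocks_per_cond <- config$n_gaze_trials / config$block_size_experimental
  n_blocks <- 2 * blocks_per_cond
  if (config$block_size_experimental != n_pairs) {
    abort(sprintf(
      "block size (%d) must equal the number of pairs (%d) so each pair appears once per block",
      config$block_size_experimental, n_pairs
    ), class = "lwl_config_error")
  }
  appearances <- blocks_per_cond # per pair per condition
  if (appearances %% 2 != 0) {
    abort("pairs must appear an even number of times per condition for exact balance",
          class = "lwl_config_error")
  }

  with_seed(mix_seed(seed, participant_index, 7), {
    conds <- rep(c(first_cond, setdiff(c("gaze_triggered", "original"), first_cond)),
                 length.out = n_blocks)

    # Per pair and condition: which of its appearances have item_a as the
    # (predetermined or backup) target, and which show item_a on the left.
    # Each is an exact half split, sampled independently.
    half_split <- function() sample(rep(c(TRUE, FALSE), appearances / 2))
    plan <- list()
    for (cond in c("gaze_triggered", "original")) {
      plan[[cond]] <- lapply(seq_len(n_pairs), function(p) {
        list(a_target = half_split(), a_left = half_split())
      })
    }

    token_start <- sample.int(4, n_pairs, replace = TRUE)
    excl_ids <- rep(sample.int(16), length.out = n_blocks *
                      (config$block_size_experimental + config$fillers_per_block))

    filler_rows <- make_filler_rows(config)
    filler_cursor <- 1
    cond_block_no <- c(gaze_triggered = 0, original = 0)
    block_len <- config$block_size_experimental + config$fillers_per_block

    out <- vector("list", n_blocks)
    for (b in seq_len(n_blocks)) {
      cond <- conds[b]
      cond_block_no[cond] <- cond_block_no[cond] + 1
      app <- cond_block_no[cond] # this pair-appearance ordinal within condition

      pair_order <- sample.int(n_pairs)
      exp_rows <- lapply(pair_order, function(p) {
        pr <- pairs[p, ]
        a_target <- plan[[cond]][[p]]$a_target[app]
        a_left <- plan[[cond]][[p]]$a_left[app]
        target <- if (a_target) pr$item_a else pr$item_b
        tibble(
          trial_type = cond,
          pair_id = pr$pair_id,
          left_item = if (a_left) pr$item_a else pr$item_b,
          right_item = if (a_left) pr$item_b else pr$item_a,
          predetermined_target = if (cond == "original") target else NA_character_,
          backup_target = if (cond == "gaze_triggered") target else NA_character_,
          label_token_id = ((token_start[p] + app - 2) %% 4) + 1
        )
      })
      exp_rows <- bind_rows(exp_rows)

      fill <- filler_rows[filler_cursor:(filler_cursor + config$fillers_per_block - 1), ]
      fill$label_token_id <- ((filler_cursor - 1 + seq_len(nrow(fill)) - 1) %% 4) + 1
      filler_cursor <- filler_cursor + config$fillers_per_block

      fpos <- sample_filler_positions(block_len, config$fillers_per_block)
      block <- vector("list", block_len)
      ei <- 1
      fi <- 1
      for (pos in 0:(block_len - 1)) {
        if (pos %in% fpos) {
          block[[pos + 1]] <- fill[fi, ]
          fi <- fi + 1
        } else {
          block[[pos + 1]] <- exp_rows[ei, ]
          ei <- ei + 1
        }
      }
      block <- bind_rows(block)
      block$block_index <- b - 1L
      block$position_in_block <- 0:(block_len - 1)
      out[[b]] <- block
    }
    trials <- bind_rows(out)
    trials$trial_index <- seq_len(nrow(trials)) - 1L
    trials$attention_getter_id <- (trials$trial_index %% 6) + 1L
    trials$exclamation_id <- excl_ids[trials$trial_index + 1]
    trials <- trials %>%
      select(
        "trial_index", "block_index", "position_in_block", "trial_type",
        "pair_id", "left_item", "right_item", "predetermined_target",
        "backup_target", "attention_getter_id", "exclamation_id",
        "label_token_id"
      )

    structure(
      list(
        participant_index = as.integer(participant_index),
        condition_first = first_cond,
        seed = as.integer(seed),
        config = config,
        trials = trials
      ),
      class = "lwl_schedule"
    )
  })
}

#' Validate a session schedule against the design invariants
#'
#' Reports (rather than enforces) violations: wrong trial counts, illegal
#' filler placement, unbalanced pair/target/side assignments, or
#' predetermined targets on gaze-triggered trials.
#'
#' @param schedule An `lwl_schedule` (or a bare trials tibble plus `config`).
#' @param config Used when `schedule` is a bare tibble.
#' @return Character vector of violated rules; empty if the schedule is valid.
#' @export
validate_schedule <- function(schedule, config = NULL) {
  if (inherits(schedule, "lwl_schedule")) {
    trials <- schedule$trials
    config <- schedule$config
  } else {
    trials <- schedule
    config <- config %||% lwl_config()
  }
  bad <- character(0)
  note <- function(msg) bad <<- c(bad, msg)

  n_expected <- config$n_gaze_trials + config$n_original_trials + config$n_filler_trials
  if (nrow(trials) != n_expected) {
    note(sprintf("trial count: expected %d trials, found %d", n_expected, nrow(trials)))
  }
  counts <- table(factor(trials$trial_type,
                         levels = c("gaze_triggered", "original", "filler")))
  if (counts[["gaze_triggered"]] != config$n_gaze_trials ||
      counts[["original"]] != config$n_original_trials ||
      counts[["filler"]] != config$n_filler_trials) {
    note(sprintf("per-type counts: expected (%d, %d, %d), found (%d, %d, %d)",
                 config$n_gaze_trials, config$n_original_trials, config$n_filler_trials,
                 counts[["gaze_triggered"]], counts[["original"]], counts[["filler"]]))
  }

  block_len <- config$block_size_experimental + config$fillers_per_block
  for (b in unique(trials$block_index)) {
    blk <- trials[trials$block_index == b, ]
    blk <- blk[order(blk$position_in_block), ]
    exp_types <- unique(blk$trial_type[blk$trial_type != "filler"])
    if (length(exp_types) > 1) {
      note(sprintf("block %d mixes experimental conditions", b))
    }
    nf <- sum(blk$trial_type == "filler")
    if (nf != config$fillers_per_block ||
        sum(blk$trial_type != "filler") != config$block_size_experimental) {
      note(sprintf("block %d composition: expected %d experimental + %d filler",
                   b, config$block_size_experimental, config$fillers_per_block))
    }
    fpos <- blk$position_in_block[blk$trial_type == "filler"]
    if (any(fpos == 0) || any(fpos == block_len - 1)) {
      note(sprintf("block %d places a filler at the first or last position", b))
    }
    if (any(diff(sort(fpos)) == 1)) {
      note(sprintf("block %d has two consecutive filler trials", b))
    }
    exp_pairs <- blk$pair_id[blk$trial_type != "filler"]
    if (anyDuplicated(exp_pairs)) {
      note(sprintf("block %d repeats a pair", b))
    }
  }

  blk_conds <- trials %>%
    filter(.data$trial_type != "filler") %>%
    distinct(.data$block_index, .data$trial_type) %>%
    arrange(.data$block_index)
  if (nrow(blk_conds) >= 2 &&
      any(blk_conds$trial_type[-1] == blk_conds$trial_type[-nrow(blk_conds)])) {
    note("blocks do not alternate between conditions")
  }

  exp <- trials[trials$trial_type != "filler", ]
  pair_counts <- table(exp$pair_id)
  per_pair <- 2 * config$n_gaze_trials / nrow(config$pairs)
  if (any(pair_counts != per_pair)) {
    note(sprintf("pair display counts: each pair must appear %d times", per_pair))
  }

  orig <- exp[exp$trial_type == "original", ]
  items <- c(config$pairs$item_a, config$pairs$item_b)
  tgt_counts <- table(factor(orig$predetermined_target, levels = items))
  per_item <- config$n_original_trials / length(items)
  if (any(tgt_counts != per_item)) {
    note(sprintf("original targets: each item must be predetermined target %d times", per_item))
  }
  if (any(!is.na(trials$predetermined_target[trials$trial_type == "gaze_triggered"]))) {
    note("gaze-triggered trials must not carry a predetermined target")
  }
  pt <- trials$predetermined_target
  has_t <- !is.na(pt)
  if (any(pt[has_t] != trials$left_item[has_t] & pt[has_t] != trials$right_item[has_t])) {
    note("a predetermined target is not one of the displayed items")
  }

  for (cond in c("gaze_triggered", "original")) {
    cexp <- exp[exp$trial_type == cond, ]
    for (p in seq_len(nrow(config$pairs))) {
      pr <- config$pairs[p, ]
      pp <- cexp[cexp$pair_id == pr$pair_id, ]
      if (nrow(pp) == 0) next
      n_left_a <- sum(pp$left_item == pr$item_a)
      if (n_left_a * 2 != nrow(pp)) {
        note(sprintf("side balance: %s shows %s on the left %d/%d times in %s",
                     pr$pair_id, pr$item_a, n_left_a, nrow(pp), cond))
      }
    }
  }
  bad
}

#' @export
print.lwl_schedule <- function(x, ...) {
  cat(sprintf("<lwl_schedule> participant %d, %s first, seed %d\n",
              x$participant_index, x$condition_first, x$seed))
  print(count(x$trials, .data$trial_type))
  invisible(x)
}

#' Write / read a schedule as JSON
#'
#' @param schedule An `lwl_schedule`.
#' @param path Output (input) file path.
#' @return `write_schedule_json()` returns `path` invisibly;
#'   `read_schedule_json()` returns the trials tibble with schedule metadata
#'   in attributes `participant_index`, `condition_first`, `seed`.
#' @export
write_schedule_json <- function(schedule, path) {
  payload <- list(
    participant_index = schedule$participant_index,
    condition_first = schedule$condition_first,
    seed = schedule$seed,
    trials = schedule$trials
  )
  jsonlite::write_json(payload, path, auto_unbox = TRUE, digits = NA, na = "null")
  invisible(path)
}

#' @rdname write_schedule_json
#' @export
read_schedule_json <- function(path) {
  raw <- jsonlite::read_json(path, simplifyVector = TRUE)
  trials <- as_tibble(raw$trials)
  attr(trials, "participant_index") <- raw$participant_index
  attr(trials, "condition_first") <- raw$condition_first
  attr(trials, "seed") <- raw$seed
  trials
}
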