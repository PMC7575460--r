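# Synthetic infant gaze: per-infant generative parameters, per-trial
# fixation streams, and whole-cohort simulation with ground truth. Every
# downstream stage (controller, preprocessing, RT extraction, statistics)
# can be exercised against the known generative process.

#' Draw the generative parameters of one simulated infant
#'
#' Latent shift latency has mean `mu_latency_ms ~ Normal(950, 130)` truncated
#' at 400 ms, matching the 600-1300 ms range of mean visual reaction times
#' reported for 18-month-olds across the looking-while-listening literature.
#' Realised known-word shift latencies are `300 + LogNormal` with the
#' lognormal parameterised so its mean is exactly `mu_latency_ms`. Expressive
#' vocabulary is generated with a weak negative dependence on latency, and
#' per-item word knowledge is Bernoulli with probability increasing in
#' vocabulary (about 2 of the 16 items unknown for an average infant).
#'
#' @param cohort_seed Master seed of the cohort.
#' @param participant_index Non-negative integer.
#' @param config An [lwl_config()] (supplies the item inventory).
#' @return A list of class `lwl_infant` with fields `participant_id`,
#'   `mu_latency_ms`, `sigma_log`, `p_attend_trial`, `dwell_shape`,
#'   `dwell_scale`, `p_off_bout`, `side_bias`, `object_pref` (per pair),
#'   `p_shift_unknown`, `expressive_vocab`, `known_words` (named logical).
#' @export
sample_infant <- function(cohort_seed, participant_index, config = lwl_config()) {
  with_seed(mix_seed(cohort_seed, participant_index, 11), {
    mu <- rnorm(1, 950, 130)
    while (mu < 400) mu <- rnorm(1, 950, 130)
    vocab <- round(max(0, 200 - 0.15 * (mu - 950) + rnorm(1, 0, 40)))
    items <- c(config$pairs$item_a, config$pairs$item_b)
    p_known <- stats::plogis(1.8 + (vocab - 200) / 80)
    known <- setNames(runif(length(items)) < p_known, items)
    params <- list(
      participant_id = sprintf("p%03d", participant_index + 1),
      participant_index = as.integer(participant_index),
      mu_latency_ms = mu,
      sigma_log = 0.3,
      p_attend_trial = rbeta(1, 8, 2),
      dwell_shape = 2,
      dwell_scale = 300,
      p_off_bout = 0.15,
      side_bias = 0.5,
      object_pref = setNames(rbeta(nrow(config$pairs), 2, 2), config$pairs$pair_id),
      p_shift_unknown = 0.3,
      expressive_vocab = vocab,
      known_words = known
    )
    class(params) <- "lwl_infant"
    params
  })
}

# Dwell-duration modifier implementing the per-pair object preference:
# looks at the preferred item last proportionally longer. Neutral (1) for
# fillers and unknown pairs.
dwell_modifier <- function(params, spec, side) {
  pref <- params$object_pref[spec$pair_id]
  if (is.na(pref)) return(1)
  item <- if (side == "left") spec$left_item else spec$right_item
  pr <- config_pair_item_a(spec)
  if (is.na(pr)) return(1)
  if (item == pr) 0.5 + pref else 1.5 - pref
}

config_pair_item_a <- function(spec) {
  # item_a of the pair is recoverable from the schedule row: the pairs table
  # always lists item_a first, so take the lexicographically stable mapping
  # stored on the row itself.
  spec$pair_item_a %||% NA_character_
}

# Alternating pre-naming fixation bouts covering [0, t_max): Gamma dwells on
# the two picture AOIs with occasional off-screen bouts. Inattentive trials
# yield at most a sub-criterion glance.
gen_prenaming <- function(params, spec, t_max) {
  if (runif(1) >= params$p_attend_trial) {
    glance_on <- runif(1, 0, t_max - 100)
    glance <- runif(1, 40, 90)
    side <- if (runif(1) < params$side_bias) "left" else "right"
    return(data.frame(
      onset = c(0, glance_on, glance_on + glance),
      offset = c(glance_on, glance_on + glance, t_max),
      aoi = c("off", side, "off")
    ))
  }
  first <- if (runif(1) < params$side_bias) "left" else "right"
  nb <- max(12L, ceiling(t_max / 120))
  sides <- rep(if (first == "left") c("left", "right") else c("right", "left"),
               length.out = nb)
  mod <- vapply(c("left", "right"), function(s) dwell_modifier(params, spec, s),
                numeric(1))
  dwell <- pmax(40, rgamma(nb, params$dwell_shape, scale = params$dwell_scale) *
                  mod[sides])
  off_flag <- runif(nb) < params$p_off_bout
  off_dur <- rgamma(nb, 1.5, scale = 200)
  aoi <- as.vector(rbind(sides, ifelse(off_flag, "off", NA)))
  dur <- as.vector(rbind(dwell, ifelse(off_flag, off_dur, NA)))
  keep <- !is.na(aoi)
  aoi <- aoi[keep]
  dur <- as.numeric(dur[keep])
  offset <- cumsum(dur)
  onset <- c(0, offset[-length(offset)])
  keep2 <- onset < t_max
  data.frame(onset = onset[keep2], offset = pmin(offset[keep2], t_max), aoi = aoi[keep2])
}

#' Draw known-word shift latencies
#'
#' Latencies are `300 + LogNormal`, shifted so no shift beats the 300 ms
#' physiological floor, with the lognormal's meanlog chosen as
#' `log(mu - 300) - sigma^2 / 2` so the distribution's mean is exactly `mu`.
#'
#' @param mu Mean shift latency in ms (> 300).
#' @param sigma Lognormal shape parameter.
#' @param n Number of draws.
#' @return Numeric vector of latencies in ms.
#' @export
draw_shift_latency <- function(mu, sigma = 0.3, n = 1) {
  300 + rlnorm(n, log(mu - 300) - sigma^2 / 2, sigma)
}

# Post-naming behaviour: if the infant is on the distractor at label onset
# and knows the word, one distractor-to-target shift at the infant's latent
# latency; unknown words shift only with probability p_shift_unknown, at a
# uniform latency; otherwise bout dynamics simply continue. The stream is
# truncated at trial end.
apply_label_behavior <- function(stream, label_onset, target_side, known,
                                 params, trial_end) {
  truncate_stream <- function(s) {
    s <- s[s$onset < trial_end, , drop = FALSE]
    s$offset <- pmin(s$offset, trial_end)
    s
  }
  cov <- which(stream$onset <= label_onset & stream$offset > label_onset &
                 stream$aoi %in% c("left", "right"))
  if (length(cov) == 0) return(truncate_stream(stream))
  cov <- cov[1]
  distractor_side <- setdiff(c("left", "right"), target_side)
  if (stream$aoi[cov] != distractor_side) return(truncate_stream(stream))

  if (known) {
    latency <- draw_shift_latency(params$mu_latency_ms, params$sigma_log)
  } else if (runif(1) < params$p_shift_unknown) {
    latency <- runif(1, 300, 1800)
  } else {
    return(truncate_stream(stream))
  }
  t_shift <- label_onset + latency
  s <- stream[seq_len(cov), , drop = FALSE]
  s$offset[cov] <- min(t_shift, trial_end)
  if (t_shift < trial_end) {
    s <- rbind(s, data.frame(onset = t_shift, offset = trial_end, aoi = target_side))
  }
  truncate_stream(s)
}

#' Simulate the gaze stream of one trial
#'
#' For original and filler trials the label time and target are fixed by the
#' schedule; for gaze-triggered trials the pre-naming stream is generated
#' first, the controller's trigger and target-selection rules are applied to
#' it, and the post-naming behaviour is generated conditional on the
#' resulting label onset and target — mirroring the closed loop of the live
#' experiment.
#'
#' @param params An `lwl_infant` from [sample_infant()].
#' @param spec One schedule row.
#' @param state Session state (consulted, never modified; pass the state the
#'   controller will see so target selection agrees).
#' @param config An [lwl_config()].
#' @param seed Integer seed for this trial.
#' @return Fixation data.frame with columns `onset`, `offset`, `aoi`.
#' @export
simulate_trial_gaze <- function(params, spec, state, config = lwl_config(), seed = 1) {
  with_seed(seed, {
    excl_offset <- config$preview_ms + config$exclamation_durations_ms[spec$exclamation_id]
    t_max <- excl_offset + config$trigger_window_ms + config$post_label_ms + 500
    pre <- gen_prenaming(params, spec, t_max)

    if (spec$trial_type == "gaze_triggered") {
      trig <- detect_trigger_fixation(pre, excl_offset, config)
      hist <- state$pairs[[spec$pair_id]]
      if (is.null(trig)) {
        label_onset <- excl_offset + config$trigger_window_ms
        target <- manual_trigger_target(hist, spec$backup_target)
      } else {
        fixated <- if (trig$aoi == "left") spec$left_item else spec$right_item
        sel <- select_target_gaze(hist, fixated, length(hist$fixated_sequence) + 1L,
                                  rule = config$fourth_trial_rule)
        target <- sel$target
        label_onset <- trig$time
      }
    } else {
      label_onset <- excl_offset + config$original_silence_ms
      target <- spec$predetermined_target
    }
    target_side <- if (target == spec$left_item) "left" else "right"
    known <- if (target %in% names(params$known_words)) {
      params$known_words[[target]]
    } else {
      TRUE # filler items are assumed familiar
    }
    apply_label_behavior(pre, label_onset, target_side, known, params,
                         label_onset + config$post_label_ms)
  })
}

#' Simulate one full session
#'
#' Runs every scheduled trial through [simulate_trial_gaze()] and
#' [run_trial()] in lockstep, honouring the stop rule.
#'
#' @param params An `lwl_infant`.
#' @param schedule An `lwl_schedule`.
#' @param config Defaults to the schedule's config.
#' @param seed Session seed.
#' @return List with `gaze` (fixation tibble) and `events` (trial records).
#' @export
simulate_session <- function(params, schedule, config = NULL, seed = 1) {
  config <- config %||% schedule$config
  state <- new_session_state(config)
  gaze <- list()
  records <- list()
  trials <- schedule$trials
  # stash item_a per row so the object-preference modifier knows pair polarity
  ia <- setNames(config$pairs$item_a, config$pairs$pair_id)
  for (i in seq_len(nrow(trials))) {
    spec <- as.list(trials[i, ])
    spec$pair_item_a <- unname(ia[spec$pair_id])
    stream <- simulate_trial_gaze(params, spec, state, config,
                                  seed = mix_seed(seed, spec$trial_index, 13))
    res <- run_trial(spec, stream, state, config)
    state <- res$state
    records[[length(records) + 1]] <- res$record
    stream$trial_index <- spec$trial_index
    gaze[[length(gaze) + 1]] <- stream
    if (session_stop_rule(state, config) == "stop") break
  }
  gaze <- bind_rows(gaze)
  gaze <- tibble(
    participant_id = params$participant_id,
    trial_index = gaze$trial_index,
    fix_onset_ms = gaze$onset,
    fix_offset_ms = gaze$offset,
    aoi = gaze$aoi
  )
  events <- bind_rows(records)
  events$participant_id <- params$participant_id
  events <- select(events, "participant_id", dplyr::everything())
  list(gaze = gaze, events = events)
}

#' Simulate a cohort with known ground truth
#'
#' Builds each participant's counterbalanced schedule, simulates their
#' session against the gaze-contingent controller, and emits the standard
#' file tables plus the generative truth.
#'
#' @param n Number of infants.
#' @param config An [lwl_config()].
#' @param seed Master seed; everything downstream is reproducible from it.
#' @param out_dir Optional directory: writes `gaze.csv`, `events.csv`,
#'   `vocab.csv`, `truth.json`, `schedule_<id>.json`.
#' @return List of class `lwl_cohort`: `truth` (list of `lwl_infant`),
#'   `gaze`, `events`, `vocab` tibbles, `schedules`, `config`, `seed`.
#' @export
#' @examples
#' coh <- simulate_cohort(2, lwl_config(), seed = 1)
#' head(coh$events)
simulate_cohort <- function(n, config = lwl_config(), seed = 1, out_dir = NULL) {
  stopifnot(n >= 1)
  truth <- vector("list", n)
  gaze <- vector("list", n)
  events <- vector("list", n)
  vocab <- vector("list", n)
  schedules <- vector("list", n)
  for (i in seq_len(n)) {
    idx <- i - 1L
    params <- sample_infant(seed, idx, config)
    schedule <- build_schedule(config, idx, seed)
    ses <- simulate_session(params, schedule, config, seed = mix_seed(seed, idx, 17))
    truth[[i]] <- params
    schedules[[i]] <- schedule
    gaze[[i]] <- ses$gaze
    events[[i]] <- ses$events
    comp <- with_seed(mix_seed(seed, idx, 19), {
      round(min(684, max(params$expressive_vocab * 1.3 + 80 + rnorm(1, 0, 30),
                         params$expressive_vocab)))
    })
    vocab[[i]] <- tibble(
      participant_id = params$participant_id,
      cdi_comprehended = comp,
      cdi_produced = params$expressive_vocab,
      known_items = paste(names(params$known_words)[params$known_words],
                          collapse = ";")
    )
  }
  out <- structure(
    list(
      truth = truth,
      gaze = bind_rows(gaze),
      events = bind_rows(events),
      vocab = bind_rows(vocab),
      schedules = schedules,
      config = config,
      seed = as.integer(seed)
    ),
    class = "lwl_cohort"
  )
  if (!is.null(out_dir)) write_cohort(out, out_dir)
  out
}

#' Write a simulated cohort's tables to disk
#'
#' @param cohort An `lwl_cohort`.
#' @param out_dir Directory (created if missing).
#' @return `out_dir`, invisibly.
#' @export
write_cohort <- function(cohort, out_dir) {
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  write.csv(cohort$gaze, file.path(out_dir, "gaze.csv"), row.names = FALSE)
  write.csv(cohort$events, file.path(out_dir, "events.csv"), row.names = FALSE)
  write.csv(cohort$vocab, file.path(out_dir, "vocab.csv"), row.names = FALSE)
  truth <- lapply(cohort$truth, function(p) {
    p <- unclass(p)
    p$known_words <- as.list(p$known_words)
    p$object_pref <- as.list(p$object_pref)
    p
  })
  jsonlite::write_json(
    list(seed = cohort$seed, participants = truth),
    file.path(out_dir, "truth.json"),
    auto_unbox = TRUE, digits = NA
  )
  for (sch in cohort$schedules) {
    write_schedule_json(
      sch, file.path(out_dir, sprintf("schedule_p%03d.json", sch$participant_index + 1))
    )
  }
  invisible(out_dir)
}
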