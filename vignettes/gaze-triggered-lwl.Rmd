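---
title: "Gaze-triggered looking-while-listening: design, simulation, and analysis"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Gaze-triggered looking-while-listening: design, simulation, and analysis}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(gazetrigger)
```

## The paradigm and its core measurement

In a looking-while-listening (LWL) trial an infant views two pictures while
one is named; the visual reaction time (RT) is the latency from label onset
to the first fixation shift from the unnamed picture (distractor) to the
named one (target). An RT is only defined on distractor-initial trials, so
roughly half of the trials of the classic design are unusable, and per-infant
RT estimates are noisy.

The gaze-triggered variant implemented here makes the paradigm contingent on
the infant's own gaze: after an attention-getting exclamation, the first
picture fixated continuously for `trigger_fix_ms` (100 ms) becomes the
distractor, and its pair mate is named at that instant. Distractor-initial
trials are thereby guaranteed. Because a strongly preferred picture would
otherwise never be named, two bias-correction deviations keep labelling
balanced within each pair (see below). Original-condition trials are left
untouched: a predetermined target is named 100 ms after the exclamation ends.

## Trial timeline

All times are trial-relative milliseconds with picture onset at 0.

1. Attention getter until a 500 ms fixation (or experimenter override); this
   phase precedes picture onset and is abstracted away by the offline
   controller — gaze streams begin at picture onset.
2. Silent preview: `preview_ms` = 2000 ms.
3. Exclamation: one of 16 recorded tokens; durations are fixed per token and
   span 610–1120 ms, so original-condition labels begin 710–1220 ms after
   exclamation onset.
4. Labelling: original trials at exclamation offset + `original_silence_ms`
   (100 ms); gaze-triggered trials at the trigger instant, or — if no trigger
   occurs within `trigger_window_ms` (5000 ms) after exclamation offset — by
   simulated manual trigger at the window's end.
5. The trial continues `post_label_ms` = 2000 ms after label onset.

A trial is *completed* when total on-screen looking during the trial reaches
`attention_min_ms` (100 ms); five consecutive uncompleted trials end the
session (`stop_after_failed`). We chose the completion rule to mirror the
analysis-side attention criterion, which sums on-screen looking in the 0–2000
ms window after label onset.

## Session design

The default design is 80 trials: 32 gaze-triggered + 32 original in
alternating blocks of eight, plus 16 fillers, two per block, placed
pseudo-randomly but never first, last, or adjacent. The eight picture pairs
(four categories, two items each per pair) each appear once per experimental
block — with eight pairs and eight trials per block this is forced, and it
makes the four-appearances-per-condition balance structural. In the original
condition each of the 16 items is the predetermined target exactly twice, and
each item appears on the left for exactly half of its pair's appearances per
condition. Pair order within a block is a uniform random permutation — the
design constrains only filler placement, so we randomise the rest and expose
the seed. Condition order alternates with participant parity, which
counterbalances any even-sized cohort exactly.

Filler trials pair two of the four filler items, rotating partners so each
filler item is named four times; fillers never touch the experimental pairs'
labelling history.

## Bias correction

On gaze-triggered trials the fixated item's pair mate is named, except:

- **Third-in-a-row**: if the infant fixates the same item of a pair at
  trigger time on three consecutive trials of that pair, the fixated item
  itself is named.
- **Fourth trial**: on a pair's final gaze-triggered trial the target is
  whichever item has been named less often, enforcing an exact 2/2 split.

The fourth-trial rule could also be read as "deviate only if the infant
fixates the same item as on the previous trial". We implement balance
enforcement as the default (`fourth_trial_rule = "balance"`) because it is
the only reading that guarantees every item is heard equally often and that
caps bias-corrected trials at two per pair — 16 per session, the maximum the
design admits; the literal-previous-trial reading remains available as
`"repeat_previous"` for sensitivity analysis, without any claim about which
reading other implementations use. Exhaustive enumeration of all 16 length-4
fixation sequences (in the test suite) confirms the 2/2 guarantee.

When the trigger times out, the manually triggered label goes to the pair's
least-named item, with the schedule's pre-assigned backup target breaking
ties — this preserves the equal-labels guarantee without gaze information.
Bias-corrected and manual-trigger trials count as completed but never yield
an RT (on bias-corrected trials the infant is fixating the target at onset;
on manual triggers there is no defined pre-naming fixation).

The trigger fixation is read as **one continuous** fixation of ≥ 100 ms on a
single AOI — eye trackers emit discrete fixation events, and a cumulative
reading would trigger on the sum of glances that never individually indicate
engagement. Contiguous same-AOI fixation events (zero gap) are merged first.
The trigger window is anchored at exclamation **offset**; its 5000 ms default
is a design choice wide enough to represent label delays of several seconds
while keeping trials bounded.

## Analysis rules

- Fixations shorter than `min_fixation_ms` (100 ms) are discarded before any
  analysis; the threshold is closed (exactly 100 ms is kept).
- Calibration, attention-getter, and filler data are removed during
  segmentation.
- **Attention**: a trial enters analysis when on-screen looking within
  0–2000 ms after label onset totals ≥ 100 ms (cumulative).
- **Initial AOI**: the AOI of the fixation whose interval covers the label
  onset instant. If no fixation covers it, the initial AOI is `none` and no
  RT is extracted — the strictest reading; we do not impute gaze across
  gaps.
- **RT**: onset of the first target-AOI fixation after label onset, relative
  to label onset, on distractor-initial trials. Off-AOI excursions between
  distractor and target do not invalidate the shift; the window defines
  validity, not path purity. Valid RTs lie in `rt_window` = [300, 1800] ms:
  earlier shifts cannot be reactions to the word, later shifts probably are
  not. Out-of-window shifts are recorded with a reason
  (`too_early`/`too_late`).
- **Inclusion**: participants need ≥ 1 valid RT in *each* condition
  (`min_rt_trials`; much of the literature uses 2, which is exposed as a
  parameter).
- The percentage of valid trials uses completed experimental trials of the
  condition as its denominator.

## The synthetic cohort

The simulator exists so every downstream stage can be tested against known
ground truth; the generative choices are this package's own, calibrated to
the magnitudes typical of 18-month-old LWL cohorts:

- **Shift latency**: per infant, a mean `mu_latency_ms ~ Normal(950, 130)`
  truncated at 400 ms — published cohort means cluster between roughly 600
  and 1300 ms. Realised known-word latencies are `300 + LogNormal` with
  `meanlog = log(mu - 300) - sigma^2/2` (`sigma_log` = 0.3), so the
  distribution's mean is exactly `mu`: the parameter recovers directly as the
  empirical mean, and no shift beats the 300 ms floor.
- **Pre-naming gaze**: alternating left/right fixation bouts with
  Gamma(2, scale 300 ms) dwells, occasional off-screen bouts (p = 0.15,
  Gamma(1.5, 200 ms)), first-look side from `side_bias` (0.5), and a per-pair
  object preference (Beta(2, 2)) that scales dwell durations. Symmetric
  defaults put the infant on either picture about equally often at label
  onset — the 50% baseline that motivates the paradigm.
- **Attention**: each trial is attended with probability
  `p_attend_trial ~ Beta(8, 2)`; inattentive trials contain at most a
  sub-criterion glance.
- **Word knowledge**: expressive vocabulary is
  `round(max(0, 200 - 0.15 (mu - 950) + Normal(0, 40)))` — a weak negative
  latency link, since the empirical RT–vocabulary association is modest —
  and each item is known with probability `plogis(1.8 + (vocab - 200)/80)`
  (about two unknown items for an average infant). Unknown-word trials shift
  only with probability `p_shift_unknown` = 0.3, at a Uniform(300, 1800)
  latency.

Gaze-triggered trials are generated interactively: the pre-naming stream is
produced first, the controller's own trigger and selection rules are applied
to it, and post-naming behaviour is generated conditional on the resulting
label onset and target — exactly the closed loop of the live experiment. The
recorded stream then replays deterministically through `run_trial()`.

What the simulator does **not** emulate: saccade kinematics, pupil data, raw
1000 Hz samples, drift and calibration error, fatigue or block-order effects,
and real-infant heterogeneity beyond the parameters above. Passing tests
therefore demonstrate that the machinery is correct under a plausible
generative model, not that real infants will produce any particular yield;
empirical anchor values from real cohorts are treated as qualitative
expectations (ordering and rough magnitude), never as fitting targets.

## Statistical choices

- The yield comparison is a one-sided paired *t* test on the percentage of
  completed trials with a valid RT (directional prediction); mean RTs are
  compared two-sided. Zero-variance differences are flagged and given
  degenerate p values by sign.
- Spearman correlations use average ranks for ties, rho as Pearson on ranks,
  a *t* approximation for the p value, and a Fisher-z interval with standard
  error `1/sqrt(n - 3)`. The interval method is a pragmatic choice and is
  labelled in the output; the rank-then-Pearson contract is pinned to 1e-12
  in the tests.
- Split-half reliability splits each participant's valid RTs of a condition
  at random (a surplus trial on odd counts goes to a random half,
  seed-controlled), takes half-means, and rank-correlates the halves across
  participants; participants under `min_trials` (2) are dropped and counted.
  A single seeded split is the default; `n_splits` averages rho over
  repeated splits as a labelled extension.
- Trial-order and word-knowledge effects use a two-stage summary-statistics
  estimate (per-participant OLS slope or mean difference, then a one-sample
  *t* across participants) as the primary, dependency-light path; a
  random-effects pass-through
  (`rt ~ trial + (1|participant) + (1|target) + (1|participant:target)`)
  via lmerTest is available with `method = "mixed"`. The two-stage estimator
  is unbiased under balanced designs and its null calibration is verified by
  simulation in the test suite.

## Problem sizes and numerical conventions

The test suite verifies the extraction primitives (trigger detection,
fixation filtering, AOI assignment, attention validity, RT extraction)
against independent brute-force oracles on 10,000 randomised trials each,
with integer-millisecond fixtures so grid oracles are exact. Cohort-level
properties (yield advantage, ~50%/~0% distractor-initial baselines, parameter
recovery, split-half growth with trial count) use 20 replicate cohorts of 43
infants; calibration checks use 100 null replicates. These sizes give
Monte-Carlo error comfortably below the asserted margins while keeping the
suite quick to run.

Numerical conventions: times are double-precision ms; AOI rectangles are
half-open so boundaries are unambiguous; intervals are half-open
`[onset, offset)`; the trigger merges only exactly contiguous same-AOI
fixations; empty streams are timeouts or inattentive trials, never errors;
degenerate statistical inputs (constant vectors, too few participants) raise
classed conditions or return flagged NA results rather than silently
producing numbers.

## Known limitations

- The offline controller replays recorded or simulated streams; it does not
  interface with eye-tracking hardware, render stimuli, or parse binary EDF
  files (only the EFIX/MSG subset of ASC exports).
- The two-stage estimators ignore shrinkage across participants; with very
  unbalanced trial counts the mixed-model path is preferable.
- The simulator's bout process is memoryless within a trial; real infant
  scan paths show richer temporal dependence, so absolute yield percentages
  from simulation should not be read as forecasts for real cohorts.
- Proportion-of-looking (accuracy) analyses are deliberately out of scope:
  gaze triggering moves the pre-naming baseline from ~50% to ~0% target
  fixation, which changes what accuracy means between conditions.
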