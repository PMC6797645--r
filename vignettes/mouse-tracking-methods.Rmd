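---
title: "Methods: measures, quality control, GEE models, and the simulator"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: measures, quality control, GEE models, and the simulator}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(mousetrackr)
```

This vignette documents the scientific and numerical choices behind
`mousetrackr`: how the raw export dialect is interpreted, how the outcome
measures are defined where their verbal definitions leave room, how the
models are specified, what the synthetic-data generator does and does not
emulate, and where the package's behavior is a design decision rather than
a forced consequence of the problem.

## The raw export and trial segmentation

Online survey platforms export one row per subject. Cursor samples
(`xPos`, `yPos`, `time`) accumulate across the whole session as strings of
values joined by a separator character (default `"a"`, a character that can
never occur inside a decimal number), while per-trial quantities — trial
onset `onReadyTime`, `buttonClickTime`, alerts, latency, window size,
stimulus order — carry one value per trial. Coordinates are pixels relative
to the browser window's upper-left corner; times are milliseconds since the
Unix epoch. Sampling runs at roughly one coordinate triplet every 16–18 ms.

Trials are recovered by assigning every sample to the unique trial whose
closed window `[onReadyTime, buttonClickTime]` contains its timestamp.
Window boundaries belong to the trial: the boundary sample is the trial
onset or the click itself. Samples falling between trials are dropped and
counted, and segmentation conserves samples by construction
(assigned + dropped = parsed).

Numbers are parsed as plain decimals with optional sign and fraction.
Scientific notation is rejected: raw streams are pixel and millisecond
integers in practice, and a stray `e` in a numeric cell indicates a
corrupted export rather than a valid value. An empty cell is an *absent*
stream, distinct from an empty one; absence surfaces as a
`missing_trajectory` flag downstream rather than as a parse failure.

## Quality control

The flagging stage never raises on bad data — surfacing bad data is its
purpose. Four defect codes (`missing_trajectory`, `stream_length_mismatch`,
`nonmonotone_time`, `wrong_trial_count`) feed the exclusion policy. The
default *conservative* policy drops any subject with any defect on any
trial; the *permissive* alternative drops only subjects with no intact
trials. Non-monotone timestamps are flagged rather than re-sorted, because
re-sorting would fabricate dynamics that never happened.

Two further flags are covariates, not exclusion reasons:

- `weird.scaling` — some trial's start-to-end horizontal displacement falls
  outside a tolerance band around the expected half button separation
  (285 px for the default 570 px layout). The band is ±25% by default and
  configurable; the underlying phenomenon (browser zoom, unusual
  pixels-per-inch) has no sharp published threshold, so the default is a
  deliberately generous band that catches common zoom levels (≤ 0.75×,
  ≥ 1.25×) while tolerating motor noise in the endpoint. Only the
  x-dimension enters, matching how the displacement is produced: the cursor
  starts at the horizontal midpoint (the Next button) and ends on a button.
- `wts` — some trial's reported window is smaller than the minimum that can
  display the full interface (default 800 × 600 px, below which the
  570 px button row plus margins cannot fit), or the "window too small"
  alert (code 4) fired.

Both become model covariates because they shift the *level* of the outcome
measures without biasing the randomized ambiguity contrast; adjusting for
them recovers precision rather than removing confounding.

Recorded latencies are cross-checked against latencies recomputed from the
trajectory; discrepancies beyond 50 ms are reported as messages but are not
defects, since browser event timing jitters at that scale.

## Outcome measures

Trajectories are min–max rescaled per axis onto the unit square, which
makes the spatial measures invariant to any uniform zoom and translation of
the display. A degenerate axis (no movement) maps to constant zero and the
trial's spatial measures become missing rather than contrived.

Where the verbal definitions leave freedom, the package resolves them as
follows:

- **Deviation parametrization.** The ideal trajectory is the straight line
  from the trial's first to last cursor position. "Horizontal deviation" is
  evaluated at matched *vertical progress*: at sample *i* the ideal x is
  the line evaluated at ỹᵢ, extended beyond its endpoints when a trajectory
  overshoots vertically. Vertical progress is the natural abscissa for an
  interface whose buttons sit a fixed vertical distance above the start
  point; a time-parametrized variant is available via
  `metric_options(parametrize = "time")` for sensitivity analyses.
- **Unsigned deviations.** Excursions left and right of the ideal line both
  count positively, so opposite-side detours add rather than cancel in the
  area.
- **Riemann rule.** The area integral uses the trapezoidal rule over
  successive samples; a left-endpoint rule is available via
  `metric_options(riemann = "left")` for bit-compatibility comparisons.
  At 16–18 ms sampling the two differ far below any effect of interest.
- **x-flip threshold.** Every strict sign reversal counts
  (`jitter_threshold = 0`); zero differences are skipped, never counted as
  reversals. A positive threshold discards sub-threshold jitter for noisy
  pointing devices.
- **Raw-unit measures.** Peak speed is computed on raw pixel coordinates
  (px/ms) — rescaling would destroy its unit meaning and it is listed
  nowhere among the unitless measures — and reaction time is exactly
  `buttonClickTime − onReadyTime`.
- **Degenerate trials.** Fewer than two samples, zero trial duration, or no
  net vertical progress yield missing measures that propagate as explicit
  `NA` rows in the long table.

## The GEE models

The unit of analysis is the trial; subjects are clusters. For each outcome
the model regresses the (standardized, for continuous outcomes) measure on
the ambiguity indicator plus the two idiosyncrasy covariates and *all*
their interactions — the full factorial expansion
`ambiguous * weird.scaling * wts` (three 2-way terms and one 3-way term).
In cohorts where an interaction cell is empty (e.g. no subject has both
flags), the inestimable columns are dropped with a warning rather than
poisoning the fit.

The working correlation is exchangeable — any two trials of a subject share
a common correlation α, estimated by the moment method — and inference uses
the robust sandwich covariance, so standard errors remain valid when the
working structure is wrong. Continuous outcomes use the identity link with
Gaussian working variance; x-flips uses the Poisson log link. No
overdispersion parameter is needed for the count model: sandwich inference
absorbs over- or under-dispersion. Wald p-values use the normal reference
distribution, the standard large-cluster GEE convention; with few clusters
(tens rather than hundreds) this is mildly anticonservative, which the
calibration study below quantifies.

Standardization is computed across *all* analyzed trials, both ambiguity
groups pooled, so a coefficient reads "pooled standard deviations by which
the outcome is larger for ambiguous trials". Rows with missing values are
dropped listwise per model with the count recorded on the fit; GEE handles
the resulting unbalanced clusters natively. Fitting is Fisher scoring to a
relative step tolerance of 1e-10 (cap 100 iterations; a non-converged fit
says so on its `converged` field); α is clamped to the positive-definite
range of the exchangeable structure.

Moderation models retain exactly two moderator levels (by default the two
most frequent, e.g. Chrome vs. Firefox), exclude other rows, and add the
moderator's main effect and its interaction with ambiguity; the interaction
is the estimand.

## The synthetic-data generator

`simulate_dataset()` generates cohorts from a two-attractor model of cursor
dynamics and serializes them in the exact export dialect, giving every
pipeline stage a ground truth. Within a trial the cursor starts on the Next
button; after a planted latency it moves toward the currently active
category button at constant base speed with Gaussian positional noise per
step. On ambiguous trials the active attractor switches between the two
buttons as a Poisson process until a commit time, then the cursor heads to
the finally chosen button; unambiguous trials are committed from the start.
Cursor speed additionally grows mildly with elapsed movement time
("time pressure"), which is what gives ambiguous trials — whose decisive
movement happens later — their higher peak speeds. The trial ends when the
committed cursor reaches a click radius around the button.

Defaults describe a realistic crowdsourced cohort and are the package's
reference study conditions: 10 recorded trials per subject (plus 6
practice trials that produce no trajectories), half the stimuli ambiguous,
sampling every 17 ± 1 ms, mean first-move latency 442 ms (exponential,
truncated at 2.5 s), base speed 0.8 px/ms, positional noise 3 px, switch
hazard 0.004/ms, commit time 900 ± 300 ms, and the interface geometry of
the default layout (buttons 570 px apart, 472 px above the Next button).
These produce median reaction times near 1.2 s, a realistic alert mix, and
baseline (unambiguous) x-flip counts well above zero, as human cohorts
show. Idiosyncrasies are injected at the rates such cohorts exhibit:
non-standard pixel scaling for 40% of subjects (zoom factors 0.6–1.6
applied to all coordinates), too-small windows for 10%, wholesale
coordinate-stream loss for 10%, and spurious "started too early" alerts on
10% of trials. Alert codes are assigned by applying the interface's rules
to the generated timings — code 2 when latency exceeds 700 ms, code 3 when
the trial exceeds 5000 ms, code 4 for too-small windows — so alert fidelity
is checkable end to end. A seed fully determines the cohort, including the
serialized bytes.

What the generator does *not* emulate: human-likeness of kinematics (no
Fitts'-law speed–accuracy coupling, no minimum-jerk profiles), practice
effects, inter-trial cursor drift (alert code 1 is therefore injected as an
independent Bernoulli event), scrolling artifacts, or bot behavior. Tests
passing on simulated cohorts therefore certify the *pipeline* — parsing,
segmentation, reordering, QC, measures, models — not the psychological
realism of any particular trajectory.

`simulate_measures()` complements this with a trial-*level* generator used
for statistical calibration: continuous outcomes are built as
`effect × ambiguous + subject intercept + trial noise` with unit total
variance, so a planted effect is exact on the standardized scale, and
trials within a subject share an exchangeable correlation (default 0.3).
Counts are Poisson with log-normal subject frailty. Calibration questions
(type-I error, bias, coverage) need an estimand known in closed form, which
trajectory dynamics cannot provide: the mapping from dynamics knobs to a
standardized effect size is not analytically invertible.

## Calibration and problem sizes

The test suite and `scripts/acceptance.R` compute, among others:

- oracle equivalence of the four trajectory measures against brute-force
  references on 1000 random trajectories (exact for x-flips, 1e-12 relative
  otherwise), plus hand-derived closed-form cases;
- exact round-trip recovery (sample counts, durations, latencies, stimulus
  permutation, ambiguity labels) on a clean 200-subject cohort;
- QC flag fractions against planted idiosyncrasy rates on 500 subjects,
  judged by exact binomial 95% bands;
- alert-rule fidelity on 10,000 trials (100% agreement required);
- GEE type-I error over 500 null replicates of 50 subjects × 10 trials
  (observed ≈ 0.06 at α = 0.05 — the expected mild small-cluster
  anticonservatism of sandwich inference — inside the binomial band);
- recovery of a planted 0.5 SD effect over 200 replicates (|bias| < 0.05;
  ≈ 94% interval coverage).

These replicate counts and cohort sizes were chosen to make Monte-Carlo
error small relative to the tolerances being checked while keeping the
default test run in the minutes range on a single core.

## Known limitations

- The GEE implementation supports the two link/variance pairs the analysis
  needs (Gaussian-identity, Poisson-log) and the exchangeable working
  structure; it is not a general-purpose GEE replacement.
- Exclusion accounting follows the stated conservative rule; with few
  clusters the sandwich test is mildly liberal, and a small-sample df
  correction is out of scope.
- The reader ingests files only; there is no live survey-platform API.
- No imputation or smoothing of lost samples is attempted anywhere: data
  loss is flagged, reported, and excluded by policy.
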