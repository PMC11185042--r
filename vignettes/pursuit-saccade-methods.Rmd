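---
title: "Methods: saccade-pursuit interaction analysis for step-ramp tracking"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: saccade-pursuit interaction analysis for step-ramp tracking}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(pursuitlink)
```

## The scientific problem

When a primate tracks a moving object it combines two eye-movement systems:
saccades, which reposition gaze rapidly, and smooth pursuit, which matches eye
velocity to target velocity. In step-ramp (Rashbass) tasks the pursuit
velocity immediately *after* the first catch-up saccade is systematically
higher than immediately before it ("post-saccadic enhancement"), and when two
targets move in different directions the post-saccadic pursuit becomes
selective for the target chosen by the saccade. `pursuitlink` implements the
measurement pipeline that quantifies both effects from 1 kHz gaze recordings
-- velocity estimation, peri-saccadic windowing, inclusion rules, bootstrap
pursuit-latency fitting, selection-weight decomposition, and ROC choice
probability -- together with a synthetic trial generator that supplies ground
truth, so every estimator in the chain can be validated by parameter recovery
without animal data.

## The generative trial model

`simulate_eye_trace()` produces one trial of a step-ramp task. The target
sits at the fixation point, steps by a signed offset along its motion
direction at motion onset (a negative step makes the ramp re-cross the
fixation point `|step|/speed` seconds later, the classic Rashbass
configuration), and then moves at constant speed for 700--800 ms. The eye
model is deliberately first-order:

* **Pursuit** is piecewise-constant-gain velocity matching. The eye is still
  until `pursuit_latency_ms` after motion onset, then moves at
  `pre_gain` x target velocity; after the saccade it moves at `post_gain` x
  target velocity. The analysis only ever reads 30 ms window means, so an
  acceleration transient would add realism without changing any measured
  quantity; we omit it. For the same reason the latent latency is a fixed
  per-condition value rather than a per-trial draw.
* **The catch-up saccade** occurs at a Gaussian latency (draws at or below
  the pursuit latency are redrawn), travels to the chosen target's current
  position plus Gaussian landing error, and follows a minimum-jerk profile
  whose duration is an amplitude main-sequence, `floor + slope x amplitude`
  (defaults 15 ms + 2.5 ms/deg). The profile only matters to the optional
  velocity-threshold detector; window measures never look inside the
  saccade.
* **Two-target selection.** The pre-saccadic velocity is the blended vector
  `w v1 + (1 - w) v2` with `w` drawn from a bimodal Gaussian mixture
  (default modes 0.2/0.8, sd 0.1) -- the structure that the weight
  decomposition later inverts. The saccade goes to the target favoured by
  `w` with probability `selection_coupling` (default 0.7), and the
  post-saccadic weight is drawn tightly around the saccade choice (sd 0.1).
  These defaults produce pre-saccadic choice probabilities near 0.65 and
  post-saccadic choice probabilities near 1, i.e. weak pre-saccadic and
  strong post-saccadic linkage.
* **Noise** is white Gaussian position noise per channel (default
  0.1 deg), the simplest model consistent with a median-filter front end;
  colored noise is deferred. An optional pupil-tracker artifact
  (`inject_tracker_artifact()`) adds a brief reversal around each saccade
  edge, emulating the distortion that motivates the 25 ms analysis buffer.

What the generator does *not* emulate: blinks, torsion/vergence, per-trial
latency variability, gain drift within a trial, or colored tracker noise.
Passing recovery tests therefore demonstrates that the estimators invert
this model faithfully at realistic noise levels -- not that every feature of
real recordings is handled.

## Velocity estimation and peri-saccadic windows

`estimate_velocity()` median-filters each position channel over 25 ms and
then averages two central differences with 40 ms and 20 ms spans (the 25 Hz
and 50 Hz differentiation rates), scaled to deg/s. The span convention --
one period of the stated rate, difference across the span -- is a choice;
both spans are arguments. Filtering precedes differentiation. The median
filter passes locally monotone traces exactly (a pure ramp is recovered to
machine precision) while rejecting up to 12 contaminated samples per 25 ms
window, which is what makes the 25 ms buffer effective against brief edge
artifacts.

Window measures (`peri_saccadic_measures()`) follow fixed arithmetic:
fixation = 30 ms ending at motion onset; pre = [onset-54, onset-25] ms;
post = [offset+25, offset+54] ms; post-saccadic position = [offset+25,
offset+34] ms. The measurement time of a window is its center relative to
motion onset. Windows that do not fit inside the trace (or the velocity
filter's full-support region) invalidate the trial rather than shrink, so
all retained measures are directly comparable. The "amplitude" gate used by
the inclusion rules is the Euclidean norm of the window-mean velocity
vector, a direction-agnostic guard for the unit-vector normalization in the
weight analysis; reported velocities are signed projections onto the motion
direction.

Trials are retained (`apply_inclusion_filters()`) iff the saccade latency
exceeds the pursuit latency by more than 55 ms (30 ms window + 25 ms
buffer, guaranteeing pursuit occupies the whole pre-saccadic window), both
window speeds exceed 0.5 deg/s, and the windows are in range.

Two numerical caveats worth knowing. First, for trials whose saccade
latency sits just above the margin, the leading pre-window samples lean on
velocity estimates whose 40 ms support straddles pursuit onset, deflating
the pre-saccadic mean by a few percent for those trials. Second, with noisy
data the median filter is slightly biased at the convex velocity kinks at
the saccade edges, inflating the post window by about 0.05--0.1 deg/s at
default noise. Both effects are intrinsic to the filter cascade (real
recordings analyzed this way share them) and are an order of magnitude
smaller than the enhancement effect; the null-calibration test verifies
that they do not produce spurious pre/post significance at realistic trial
counts.

## Pursuit latency

Latency is estimated per condition from saccade-free trials (no saccade
onset within 200 ms of motion onset). Each trial's position projected on
the motion direction over [0, 200] ms (201 samples, window endpoint
inclusive) is median-filtered (length 5) and baseline-subtracted (mean of
the first 50 ms). The trial-average trace is fit with the threshold-linear
(rectified) model `ep(t) = g max(t - l, 0) + c` -- rectification, not
floor: the fit names a response onset, and the objective is piecewise
quadratic in `l`. The optimizer exploits that structure: conditional linear
least squares for `(g, c)` on a 1 ms grid of `l` brackets the global
minimum exactly up to grid resolution, followed by sub-ms refinement;
objective ties resolve to the smallest `l`, and an all-flat trace is
returned as a flagged degenerate fit since any `l` fits with `g = 0`.
Uncertainty comes from resampling trials with replacement 1000 times and
refitting; the reported latency is the mean of the bootstrap distribution.
Recovery tests show the procedure is within a few ms of truth for 100-trial
conditions at 0.05 deg position noise across the latency range the task
produces (roughly 175--195 ms).

For two-target trials -- whose latency cannot be estimated this way because
the pre-saccadic drive is blended -- the inclusion rule uses the mean of
the two single-target partner latencies.

## Selection weights and choice statistics

The decomposition `w T1 + (1 - w) T2 = E` is solved in least squares for
unit 2-vectors: `w = ((E - T2) . (T1 - T2)) / ||T1 - T2||^2`. Saccade
weights use the target-position unit vectors at saccade *onset* (the
movement is programmed before it starts; the reference time is
configurable) and the unit vector of the 10 ms post-saccadic mean eye
position. Pursuit weights use epoch-matched references: the renormalized
mean of per-trial unit pursuit-velocity vectors from the single-target
trials of each pairing direction, with target-1 identity fixed by the
pairing's first-listed direction. Weights are kept raw (unclipped):
clipping to [0, 1] would discard separability information, so regressions
and ROC analyses consume raw values and only histogram views may clip.
Because unit vectors are chords, a blend weight `w` maps to a slightly
more extreme recovered weight (0.8 recovers near 0.86 for orthogonal
references); recovery tests budget for this geometric distortion.

The pursuit-saccade linkage is quantified three ways:

* **Regression** of pursuit weight on saccade weight (`y = m x + c`, OLS);
  a slope near 1 means pursuit follows the saccade choice.
* **Choice probability**: the area under the ROC curve separating pursuit
  weights grouped by the binarized saccade choice (threshold 0.5, exact
  ties excluded -- the decomposition's natural midpoint; the paper-trail
  for this rule is the package's own choice). The criterion sweep equals
  the tie-half-weighted pairwise dominance probability exactly, and the
  bootstrap CI resamples weight-label pairs jointly 1000 times
  (stratified resampling is exposed as an option).
* **Time-resolved choice probability**: weights recomputed from 30 ms
  windows stepped away from the saccade at gaps of 25, 55 and 85 ms from
  the relevant edge. Gaps measured from the edge keep every window clear
  of the 25 ms buffer by construction, and the innermost gap reproduces
  the standard windows exactly, so the headline values appear unchanged in
  the time-resolved curve. (A center-offset grid was considered and
  rejected: centers 30 ms from the edge would overlap the buffer.)

The matched/mismatched analysis asks whether post-saccadic enhancement
cares about the pre-saccadic choice: within each saccade choice,
post-saccadic projected velocities are compared between trials whose
pre-saccadic pursuit choice matched vs mismatched the saccade, by
two-sample KS test, computed only when both subgroups have at least 30
trials. Pre/post and fixation/pre velocity comparisons use Welch's
two-sample t test by default (a paired option exists; the table-style
comparison treats the epochs as distributions).

## Pipeline, reproducibility, problem sizes

`run_single_target_analysis()` and `run_two_target_analysis()` compose the
stages under a single `run_config()` whose defaults are the standard
analysis values (25 ms buffer, 30 ms windows, 55 ms margin, 0.5 deg/s
gate, B = 1000). One global seed fans out to named substreams for
simulation, latency bootstrap and CP bootstrap, so stages are
independently reproducible and a rerun with the same config is
byte-identical. Reports are plain CSV plus a text summary; the thin
command-line wrapper (`inst/cli/pursuitlink.R`) exposes `simulate`,
`analyze-single`, `analyze-two` and `full-run`.

The test suite validates the chain at the sizes the method is used at:
single conditions of 100--200 trials for latency and gain recovery,
two-target datasets of 300 trials with 40--80 single-target reference
trials per direction, 100-replicate checks for the selection signature,
and 200-replicate null calibrations. Tests assert recovery at those sizes
(e.g. bootstrap latency within 8 ms of truth, gain step within 0.3 deg/s)
rather than asymptotic behaviour.

## Known limitations

* The estimators are validated against the generator's first-order pursuit
  model; systematic effects absent from it (anticipatory pursuit, blink
  artifacts, latency jitter, colored noise) are untested.
* The differentiation-span convention for the "25 and 50 Hz" velocity
  estimate is one of several defensible readings; spans are configurable
  and all downstream results go through the same cascade.
* Reference vectors inherit angular noise from the single-target trial
  sets; with few reference trials the weight scale (and hence slopes)
  shifts accordingly.
* The weight decomposition is strictly two-target; more targets would need
  a different (non-scalar) parameterization.
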