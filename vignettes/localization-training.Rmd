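---
title: "Methods: simulating and analysing sound-localization training"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: simulating and analysing sound-localization training}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(soundloc)
library(dplyr)
```

This vignette documents the models, conventions and numerical choices
behind `soundloc`: what exactly is computed, which decisions were open and
how they were resolved, and what the synthetic-listener simulations do and
do not establish about real data.

## Coordinate systems

Two spherical systems are used, as is standard in spatial hearing.

**Single-pole azimuth/elevation.** Azimuth θ ∈ [0°, 360°) rotates about
the vertical axis (0° straight ahead, 90° to the *left*); elevation
φ ∈ [−90°, 90°] is the angle above the horizontal plane. The unit-vector
frame is x = front, y = left, z = up, so a direction maps to
(cos φ cos θ, cos φ sin θ, sin φ).

**Interaural-polar (double-pole).** The lateral angle λ = arcsin(y)
measures the angle off the median plane (±90° at the poles on the
interaural axis); the polar angle ρ = atan2(z, x) rotates around the
interaural axis (0° front-horizontal, 90° overhead, 180° rear-horizontal)
and locates a direction on its cone of confusion. This puts the
binaurally-determined component (λ, driven by interaural time and level
differences) and the spectrally-determined component (ρ) on separate axes.

One convention needed fixing: descriptions of the lateral angle sometimes
read as the angle *from the interaural axis* rather than from the median
plane, but the standard eligibility gate for front-back scoring
("|lateral| > 65°, i.e. within 25° of the interaural axis") is only
self-consistent with λ = 0 on the median plane and ±90 on the axis. That
is the convention adopted throughout.

On the interaural axis ρ is undefined. `to_interaural()` flags such
directions (|y| = 1 within 10⁻¹²) as `degenerate` and sets ρ = 0 by
convention; all polar-angle computations downstream skip degenerate
trials. The front/rear hemisphere boundary (the ear plane, x = 0) is
classified *front*; the samplers produce boundary directions with
probability zero, so the convention only matters for hand-constructed
data, and it is covered by a test.

Angles are degrees at every interface; radians appear only inside
trigonometric internals.

## Error metrics and their gates

For each trial with target **t** and response **r**:

- **Spherical angle error**: arccos(**t** · **r**), the great-circle
  angle, in [0°, 180°].
- **Lateral error**: |λ(r) − λ(t)|.
- **Front-back eligibility and confusion**: a trial enters the confusion
  measure only if |λ(t)| ≤ 65° — the gate uses the *target's* lateral
  angle only. Among eligible trials, a confusion is a response in the
  wrong front/rear hemisphere; the block-level rate is
  100 · confused/eligible, reported as absent (and flagged) if no trial
  was eligible.
- **Polar angle error (PAE)**: wrap(|ρ(r) − ρ(t)|) · cos λ(t), where
  wrap maps the absolute difference to the shortest arc in [0°, 180°].
  The cosine rescales arc length on the cone of confusion, whose radius
  shrinks as the target approaches the interaural axis. PAE is absent for
  confused trials, fb-ineligible trials, and degenerate targets or
  responses. Wrapping is a choice (sources rarely state it); the shortest
  arc is the only rotation-invariant option.
- **Signed measures**: signed lateral = |λ(r)| − |λ(t)| (positive =
  response more lateral — the magnitude form matches the "more laterally /
  more medially" reading); signed elevation = φ(r) − φ(t) using
  single-pole elevation; both computed only when the response lies in the
  target's front/rear hemisphere. Signed front-back is +1 for a rear
  target perceived in front, −1 for the reverse, 0 otherwise, over
  eligible trials.

Block summaries take per-participant *medians* of the unsigned errors
(medians of an even count are the midpoint of the central pair) because
error distributions are heavily right-skewed — most errors below 90° with
a tail to nearly 180° — and means track the tail, not the central
tendency. Signed measures are summarised by means, since cancellation is
the point of a signed measure.

## The protocol simulator

The simulated study follows the three-day design: day 1 interleaves
testing and training ([test, train] × 3 + test) to capture rapid early
learning; days 2 and 3 are [test, train × 3, test]. That yields 9 training
and 8 testing blocks, with testing blocks at completed-training counts
{0, 1, 2, 3, 3, 6, 6, 9}. Control participants sit out the training slots
but follow the same testing schedule.

**Testing blocks**: 12 centroids (8 on the horizon at 45° azimuth steps,
4 at 45° elevation over azimuths 45/135/225/315) × 4 repeats, each repeat
independently jittered within a 20° spherical cap; 3 repeats per centroid
use the trained HRTF set and 1 the untrained set; order shuffled. Cap
jitter is *area-uniform* (cos-deviation uniform on [cos 20°, 1]) rather
than independent azimuth/elevation perturbation — the only
rotation-invariant reading of "deviated by up to 20°".

**Training blocks**: targets drawn area-uniformly over the upper
hemisphere via θ = 360u, φ = arcsin(v) with u, v ~ U[0, 1] (sources only
above the horizon, matching a virtual environment with a floor). A
response is a *hit* when the spherical error is within the current
staircase threshold.

**The staircase.** The target is a sphere whose radius shrinks by 10% per
level: r = 0.9^(L−1) d sin 25°. A response ray hits it when its angular
deviation is at most arcsin(0.9^(L−1) sin 25°) — the ray-sphere reading of
the printed radius formula, not a linear 0.9-scaling of the 25° angle
(the two differ from level 2 onward). Three *consecutive* hits advance a
level; five misses *accumulated at a level* (hits do not clear the miss
counter — "at a given target size" scopes the count to the level) revert
one level, never below 1. Counters reset on any level change. The
staircase restarts at level 1 each day; nothing downstream depends on the
staircase state, since analyses use only target/response geometry.

**Trial counts and presentations.** The human protocol ran training blocks
for a fixed 12 minutes, so per-block trial counts varied and are
unreported. The simulator fixes them per group: 60 for the non-gamified
and gamified variants (~12 s/trial) and 45 for the active variant, whose
looped stimulus slows trials. Stimulus presentations per trial are 2 for
the non-active variants (stimulus + feedback replay) and 6 for the active
variant (looping until response), so active listeners hear more stimuli
per trial but complete fewer trials — reproducing the dissociation in
which total exposure differs sharply between groups while improvement
does not track it. These are calibration knobs in
`protocol_config()`, not facts about the original study.

**Determinism.** All randomness flows from one integer seed through
arithmetic per-participant-per-block sub-seeds, so a seed fully determines
a trial log; equal seeds give byte-identical CSVs.

## The virtual listener

`respond()` is a phenomenological generative model — it emulates the
*statistics* of naive localization with non-individualized HRTFs, not the
acoustics (no ITD/ILD or spectral-cue modelling). Per target:

1. **Front-back confusion** with probability `p_fb0 · s`: the direction is
   mirrored across the ear plane.
2. **Lateral overshoot**: |λ| inflated by `lateral_bias0 · s` at fixed
   polar angle (clamped to ±90°); the inflated azimuth is kept.
3. **Elevation bias**: the pre-noise elevation is set to the target
   elevation plus `elevation_bias0 · s_polar` (clamped to ±90°). Anchoring
   on the target elevation — rather than shifting the output of step 2 —
   makes the pre-noise signed elevation error *exactly* the generative
   bias; applying the lateral step to polar coordinates otherwise leaks a
   few degrees into elevation, which would make the generative parameter
   unrecoverable from its own measurement.
4. **Isotropic noise**: a von Mises–Fisher perturbation with concentration
   `noise_kappa0 / s` (angular spread roughly 1/√κ radians).

The application order (confusion → lateral → elevation → noise) is a
modelling choice; it is seed-stable and irrelevant to the correctness of
the metric layer, which is tested against hand-constructed logs.

**Adaptation.** A single state
s = floor + (1 − floor) · exp(−b · completed_blocks) scales every bias
component; it advances only when a training block completes (no latent
learning between days, matching the empirical picture). Defaults:
`p_fb0 = 0.40` (naive confusion rates near 40%), `lateral_bias0 = +9°`
and `elevation_bias0 = −15°` (mid-range of the reported naive group means,
+7.5 to +11° and −11 to −20°), `noise_kappa0 = 10` (≈18° spread),
`floor_fraction = 0.55` (so the asymptotic error is roughly 55–60% of the
initial, the ratio implied by the published initial/final summary), and
learning rates b = 0.270 / 0.320 / 0.710 per block for the non-gamified /
gamified / active-gamified groups (0 for control), seeded from the
published group-level fits. `make_cohort()` jitters all parameters per
participant (SDs: 0.08 on p_fb, 3° and 4° on the biases, 0.25 lognormal
on κ, 20% relative on b, 0.05 on the floor) to emulate the large
between-subject variability these studies report; the reported
per-participant distributions are unknown, so these magnitudes are free
choices made once.

**Untrained-HRTF transfer.** Adaptation of the confusion, lateral and
noise components transfers fully to the untrained set; the elevation
(polar) component transfers with fraction `polar_transfer = 0.45`,
echoing the reported ratio of pooled PAE improvements for untrained vs
trained conditions (−2.9/−6.74 ≈ 0.43). This is a configuration knob, not
a fitted claim.

**What passing tests show — and don't.** The generator produces the right
*marginal* signatures (confusion rate, signed biases, exponential decay
with group-ordered rates, partial polar transfer) but is phenomenological:
it has no spectral cues, no cue reweighting, no response-time structure,
no trial-to-trial learning within a block, and isotropic noise with a
single concentration rather than direction-dependent precision. Pipeline
correctness on simulated data therefore demonstrates that the measurement
and inference chain recovers known generative structure — not that real
listeners satisfy the model.

## Learning curves

`fit_exponential()` fits a·exp(−bx) + c by bounded Levenberg–Marquardt
(a ≥ 0, b ≥ 0), multi-started from c₀ = min y, a₀ = max y − min y,
b₀ ∈ {0.1, 0.3, 1.0}; the lowest RSS wins and ties go to the smallest b.
A profiled grid over b (with (a, c) solved linearly, a clamped at 0)
backs up the LM starts, which guarantees a converged answer on flat or
otherwise degenerate series where the exponential's gradient is singular;
exactly constant y lands on the b = 0 edge with R² defined as 0, hence a
negative adjusted R². The adjusted R² uses p = 3 parameters,
1 − (1 − R²)(n − 1)/(n − 4), and is NA at n = 4.

Fits operate on *group means of per-participant medians* at each testing
block, not pooled trials. The time axis is schedule-matched: a testing
block's x is the number of training blocks the schedule has delivered at
that point ({0, 1, 2, 3, 3, 6, 6, 9}), with repeated counts kept as
separate points. The control group completes no training, but collapsing
its series onto x = 0 would make the exponential unidentifiable; placing
it on the schedule axis matches how such control curves are plotted and
fitted alongside trained groups, and yields the expected near-zero b and
negative adjusted R² on flat data.

`derived_summary()` averages parameters across fits: mean initial error
ā + c̄, mean final error c̄, half-life ln 2 / b̄ in blocks and (×12 min)
in minutes — the same arithmetic that turns the published group fits into
the printed 43.4° / 25.5° / 1.60-block / ≈19-minute summary, which the
package reproduces from the shipped `reference_fits()` table.
`consolidation_deltas()` computes per-participant overnight changes
(first test of day n+1 minus last test of day n); values near zero mean
gains are retained but nothing is learned during rest.

## Group statistics

- `paired_change_test()`: two-sided paired t from the closed form
  t = d̄ / (s_d/√n), df = n − 1. Zero-variance differences are flagged
  degenerate rather than erroring: all-zero differences report t = 0,
  p = 1; constant non-zero differences report NA statistics.
- `ancova_group_effect()`: the homogeneous-slopes one-way ANCOVA,
  final ~ initial + group, testing the group factor with the covariate
  already in the model; adjusted means at the grand-mean covariate and
  Tukey HSD over all pairwise group contrasts (one metric = one family;
  no cross-metric correction, matching the practice of running separate
  tests per measure). Slope heterogeneity (initial × group) is reported
  as a diagnostic only. Tests are two-sided, α = 0.05.
- `presentations_vs_improvement()`: Pearson correlation of total training
  presentations against initial-minus-final median spherical error,
  trained participants only; constant inputs are flagged degenerate.
- `trained_vs_untrained()`: per metric, each trained participant's
  initial-to-final change per HRTF condition; a paired t on the
  difference of changes pooled over training groups, plus an ANCOVA of
  final on initial with HRTF condition as the fixed factor.

The printed t/F/p values of any particular human dataset are
data-dependent and are not reproduction targets; the module is validated
against closed-form oracles and by calibration — under a no-learning null
(all groups generated with control dynamics), the ANCOVA group test
rejects at the nominal 5% rate within Monte-Carlo tolerance over 500
simulated studies.

## Numerical and I/O choices

- Dot products and cos-deviations are clamped to [−1, 1] before
  arccos/arcsin; angular identities therefore hold to ~10⁻⁹ degrees, the
  tolerance used throughout the geometry tests.
- Trial logs are plain CSV with angles written at 17 significant digits
  and parsed with correctly-rounded base-R conversion, so a write/read
  round-trip is bit-exact. Seed and config hash travel as `#` header
  comments. Validation is loud and row-numbered: missing columns, angles
  out of range, unknown group labels and duplicate trial keys are errors.
- YAML configs: missing keys fall back to defaults; unknown keys are
  errors (a silent typo would silently change a simulation).
- The von Mises–Fisher sampler uses exact inversion of the cos-deviation
  CDF, w = 1 + log(u + (1 − u)e^(−2κ))/κ, clamped to [−1, 1]; κ = ∞ is
  honoured as noise-free.

## Problem sizes used by the test suite

Geometry oracles run on 10⁴ random directions; distributional checks on
10⁵ draws (KS tests at α = 0.01). The end-to-end recovery test simulates
50 complete 36-participant studies (~27,000 trials each); the null
calibration runs 500 pre/post studies. The whole suite completes in a few
minutes on one core.

## Known limitations

- The listener model is phenomenological (see above); it cannot address
  mechanism-level questions (parallel HRTF representations vs cue
  reweighting) — only the measurement chain built on top of it.
- Head-movement trial cancellation (>2.5° during playback) is not
  modelled; no head-motion traces exist in the simulation.
- Lateral-bias inflation saturates at the ±90° poles, so extreme lateral
  targets compress the overshoot.
- The exponential fit treats the two same-x testing blocks (end of one
  day, start of the next) as exchangeable; systematic overnight effects
  would violate that, and `consolidation_deltas()` is the tool to check.
- `fit_group_curves()` requires at least one non-control group in the
  summaries to define the schedule-matched axis; an all-control log
  yields a constant axis and an unidentifiable fit, reported via the
  b = 0 edge.
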