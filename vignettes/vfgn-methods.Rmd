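---
title: "Models and methods behind the vfgn simulator"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and methods behind the vfgn simulator}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(vfgn)
```

## The task

The virtual Four Goals Navigation (vFGN) task is a human analog of the
Morris water maze.  A subject stands in a large enclosed circular arena
(56 m diameter — a twenty-fold enlargement of a 2.8 m physical apparatus),
oriented by three distal cues near the wall, and must find a hidden
circular goal on the floor whose diameter is 10% of the arena diameter.
Each trial begins at a pseudorandom start position near the wall: the
subject first *points* toward where it believes the goal is, then has 60 s
to walk to it.  Entering the goal region ends the search; on timeout the
goal is revealed and walked to.  Either way the trial ends with a 10 s
memorize phase on the goal.

Two session protocols are encoded exactly:

* **Reference memory (RM)** — 11 trials with a fixed goal: one free-search
  trial (T1, no pointing), four blocks of two standard trials (T2–T5,
  T7–T10), a probe trial with the goal inactivated in mid-session (T6), and
  a final visible-goal control trial (T11).
* **Delayed matching to place (DMP)** — 18 trials over three goals A, B, C
  placed in geometrically identical positions: nine acquisition trials
  (three consecutive per goal, the first of each announced as a new
  position), six recall trials (two rounds of the sequence A, B, C), and
  three probe trials (a final round with the goals inactivated).

This package runs the task headlessly: a 2D kinematic simulator replaces
the 3D engine, and parameterized agents replace subjects.  Everything else
— schedules, trial state machine, measures, statistics — follows the task
as specified.

## Coordinate conventions and geometry

Coordinates are Cartesian meters with the origin at the arena center;
azimuths are degrees counterclockwise from the +x axis, normalized to
[0, 360).  These conventions are stated in every output file header.

Two readings of "the goal occupied about 10% of the arena diameter" are
possible; we read it as the goal *diameter* being 10% of the arena
diameter, i.e. a 2.8 m goal radius in the 28 m arena, because the phrase
describes a linear extent.  The goal boundary is inclusive (entering means
distance ≤ radius, with a 1e-9 relative tolerance so boundary points are
not lost to rounding).

The *goal quadrant* is the 90° angular sector centered on the azimuth of
the goal center, extending over the full arena radius.  Sector bounds are
half-open (lower inclusive), so the four rotated sectors tile the disk
without double counting; by symmetry a spatially uniform path spends 25%
of its time in each sector, which matches the task's stated chance level.
Whether the original apparatus also bounded the quadrant radially is not
documented; full-radius sectors are the only choice consistent with a 25%
chance level.

Start positions lie on a circle of radius 0.92 R at one of eight azimuths
on a 45° grid, excluding azimuths within 45° of the goal and the previous
trial's start.  The grid is an assumption (the task states only
"pseudo-randomized" starts); the exclusion prevents trials that begin
already facing the goal quadrant.

## Simulator kinematics

Agents translate at 7 m/s with a turn rate capped at 90°/s, sampled at
dt = 0.1 s.  The task gives no speeds; these values make a direct path
cross the arena in about 8 s — comfortably within the 60 s limit — while a
random walk usually needs most of it.  Positions that would leave the
arena are clipped to the wall (navigators) or reflected (the exploratory
walk).  Post-timeout walks to the revealed goal are logged with a
`post_reveal` flag and excluded from every metric: the measures
characterize *search*, and the visible-goal walk would dilute path
efficiency.  The walk to the start sphere and the 10 s memorize phase are
not simulated; the memorize phase enters only as a learning event
delivered to the agent.

## The generative agent model

The navigator's spatial memory for a goal holds the true goal center (the
memorize phase shows the real position) and two counters: `n`, the number
of observations, and `s`, the *staleness* — intervening trials of other
goals since the last observation.  On each trial the recalled estimate is
the true center plus isotropic Gaussian noise with

$$\sigma = \sigma_0 \, \lambda^{\,n-1} + \phi\, s,$$

where `memory_sd0` ($\sigma_0$, meters) is the spread after one
observation, `memory_decay` ($\lambda \in (0,1]$) the per-observation
consolidation factor, and `forget_sd` ($\phi$, meters per intervening
trial) the interference term.  Learning therefore rides on observation
*count* and forgetting on intervening-*trial* count, not on wall-clock
time — the task itself manipulates delay through trial counts (six trials
intervene before goal A's recall, four before B's, two before C's).

The agent points at the recalled estimate plus angular noise
(`pointing_sd`, degrees), walks straight to the estimate, and if the goal
is not there searches with an outward Archimedean spiral whose pitch
equals the goal radius — guaranteeing that a goal within about two goal
radii of the estimate is swept.  When the spiral radius passes three goal
radii the agent returns to the estimate and spirals again, concentrating
probe-trial search near the believed location.  With probability
`lapse_rate` a trial is executed instead as pure random exploration — a
trial-wise (not step-wise) attention-lapse model.  An unobserved goal and
the announced first-search trials also fall back to exploration.  A
visible goal is walked to directly.

The exploratory baseline is a correlated random walk (heading noise
`heading_sd` degrees per step, wall reflection) that uses no goal
information; its pointing is uniform on the circle, so its expected
pointing error is 90° and its expected quadrant occupancy 25%.

The exponential-decay form of learning is a stand-in — human learning
curves cannot constrain it — and is isolated behind the policy interface.

### Shipped presets

Two fixed presets bracket the performance range the task is designed to
resolve:

| parameter      | healthy_like | impaired_like | units |
|----------------|--------------|---------------|-------|
| pointing_sd    | 6            | 12            | deg   |
| memory_sd0     | 9            | 14            | m     |
| memory_decay   | 0.75         | 0.92          | –     |
| forget_sd      | 0            | 2.5           | m/trial |
| heading_sd     | 25           | 25            | deg/step |
| lapse_rate     | 0.01         | 0.08          | –     |

`healthy_like` consolidates quickly and does not forget across intervening
trials; `impaired_like` starts coarser, consolidates slowly, accumulates
interference, and lapses more often.  The presets were calibrated once so
that simulated 29 + 29 cohorts reproduce the *qualitative* pattern of the
task's group effects — faster learning curves, higher probe-trial spatial
bias, and no recall drop in the healthy-like group — and are not tuned to
any particular human numbers.  They make no claim of cognitive realism.

Cohorts drawn with `make_cohort()` spread parameters across subjects with
a 20% coefficient of variation (rates such as `memory_decay` and
`lapse_rate` vary on the logit scale so the spread respects their bounds).
Ages are uniform on 18–35 years and sexes alternate within groups,
mirroring the matched-group design.

## The four measures

* **Pointing error** — absolute angular difference between the pointed
  azimuth and the straight-line azimuth from the start to the goal
  *center*; degrees in [0, 180], absent on trials without pointing.
* **Path efficiency** — `path_min / path_real` in (0, 1].  `path_min` is
  the straight-line distance from the start to the goal *boundary*
  (‖start − center‖ − radius): the search ends at the first boundary
  crossing, so measuring to the center would make 1.0 unattainable and
  break the stated range.  `path_real` is the polyline length of the
  search-phase samples up to and including the first in-goal sample.  The
  ratio is capped at 1 because discrete sampling can place the entry
  sample slightly inside the boundary.  Absent when the goal was not found
  during search.
* **Goal-quadrant preference** — fraction of samples in the goal quadrant.
  With constant-rate sampling this equals the fraction of trial time, so
  samples are weighted equally rather than trapezoidally; externally
  supplied logs with variable sampling should be resampled first.  Probe
  trials are scored over the full 60 s by default (instructed subjects
  keep searching the whole trial); `max_time = 30` reproduces the
  early-window scoring used in rodent probe analyses.
* **Entrances** — maximal runs of consecutive in-goal samples; an
  entrance is an out-to-in transition and an initial in-goal run counts as
  one.

Latency is deliberately not a measure: the decision about the goal
position is already expressed at pointing time.

RM block aggregates are means over the standard-trial pairs (T2, T3),
(T4, T5), (T7, T8), (T9, T10); the probe trial contributes preference and
entrances only, the visible trial pointing error and path efficiency.

## Statistics

All tests are computed from closed-form sums of squares and checked
against independent oracles in the test suite:

* one-sample and two-sample *t* tests (pooled by default, Welch optional),
  used for probe preference against the 0.25 chance level and for group
  contrasts;
* a split-plot (mixed-design) ANOVA with one between-subjects factor and
  one within-subjects factor.  The between effect is tested against
  subjects-within-groups, the within effect and interaction against the
  block-by-subjects residual.  The repeated factor must be balanced
  (every subject in every block — the ANOVA names offending subjects
  otherwise); group sizes may differ.  Sphericity corrections are not
  applied, a documented limitation.  A single between factor is supported;
  a second crossed factor such as sex can be analyzed by passing the
  combined group-by-sex label as the between factor (its cell
  decomposition) or by subsetting, but separate main-effect terms for two
  between factors are not decomposed;
* per-group Pearson age correlations with
  $t = r\sqrt{(n-2)/(1-r^2)}$.

Stepwise post-hoc procedures of the Newman–Keuls type are not provided:
they lack familywise error control.  `pairwise_groups()` offers pairwise
*t* tests with Holm correction instead.

A null-calibration utility (`null_rejection_rate()`) simulates cohorts in
which both groups share a preset and reports the group-effect rejection
rate, which should sit near the nominal level; the shipped acceptance
checks run it at 1,000 replicates with 10 subjects per group — a size
chosen to keep the check inside a couple of minutes on one CPU while
leaving the Monte-Carlo error of the rate near half a percentage point.

## Chance-level estimation

The Monte-Carlo chance baseline (`chance_preference()`) runs goal-naive
exploratory probe trials with start azimuths uniform over the *full*
eight-point grid rather than the goal-excluded protocol grid: a naive
agent has no trained goal to exclude around, and the unrestricted grid is
closed under 90° rotation, which makes the expected occupancy exactly
0.25 by symmetry.  Under the protocol's exclusion rule the early part of
the walk is biased away from the goal quadrant and the time average sits
measurably below 25%; the unconstrained design is the correct reading of
"chance level" because it averages over configurations.

## What the synthetic data do and do not show

The generator reproduces the statistical *structure* the task assumes:
improvement with repeated exposure, degradation with interference,
chance-level naive search, and probe-trial spatial bias between chance and
ceiling.  It does not model thigmotaxis or other wall-following search
taxonomies, landmark-specific cue use, sex differences, motor-skill
learning, or any clinical covariate, and its human-like numbers (e.g. the
precise probe percentages) are emergent properties of the presets, not
fits to human data — the original human group values derive from subjects
whose raw data are not public, so agreement is assessed qualitatively
(direction and significance of effects), never numerically.  Passing
tests therefore certify the pipeline and its measures, not cognitive
fidelity.

## Numerical and degenerate-input choices

* Angle normalization is idempotent; non-finite angles are rejected.
* A start inside the goal is a malformed trial (path efficiency would
  divide by zero) and raises an error.
* Probe trajectories shorter than 1 s are rejected rather than scored.
* Zero-variance samples in the *t* tests warn and return p = 0 when the
  means differ, and raise an error when the test is undefined.
* An all-constant ANOVA table reports F = 0 with a warning rather than
  NaN.
* Trajectory CSVs serialize doubles at 17 significant digits, so a
  write–read round trip is bit exact; schema versions are checked and
  mismatches name both versions.

## Problem sizes used by the shipped checks

The acceptance checks simulate 29 subjects per group (the task's group
size) for the direction-of-effect comparisons, 1,000 exploratory probe
trials for the chance level, and 1,000 null cohorts of 10 + 10 subjects
for calibration.  These sizes keep the whole battery within a few minutes
on a single CPU while holding Monte-Carlo error well inside the decision
margins.
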