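# vfgn

Headless simulator and analysis pipeline for the **virtual Four Goals
Navigation (vFGN) task**, a human analog of the Morris water maze used to
study spatial learning and memory in clinical populations.

In the task, a subject inside a large enclosed circular arena (56 m
diameter, three distal cues) must repeatedly find a hidden circular goal
on the floor.  Each trial starts near the wall: the subject points toward
the remembered goal, then has 60 s to navigate to it; afterwards 10 s on
the goal serve to memorize its position.  Two protocols probe different
memory systems: a **reference-memory (RM)** session (11 trials, fixed
goal, with a mid-session probe trial and a final visible-goal control) and
a **delayed-matching-to-place (DMP)** session (18 trials over a sequence
of three goals: 9 acquisition, 6 recall, 3 probe).

This package re-creates the whole task without subjects or a 3D engine:

* **geometry** — arena, goal and cue specifications, azimuth conventions,
  goal-centered quadrants (`arena_spec()`, `goal_spec()`,
  `goal_quadrant()`);
* **protocols** — exact RM and DMP schedules and the per-trial state
  machine (`build_rm_session()`, `build_dmp_session()`, `run_trial()`);
* **agents** — synthetic navigators with noisy, decaying spatial memory
  plus a random-exploration chance baseline (`memory_navigator()`,
  `random_explorer()`, `make_cohort()`);
* **measures** — the task's four behavioral parameters
  (`pointing_error()`, `path_efficiency()`, `quadrant_preference()`,
  `count_entrances()`, `score_session()`);
* **statistics** — closed-form t tests, split-plot group × block ANOVA,
  age correlations and Holm-corrected pairwise contrasts
  (`one_sample_t()`, `two_sample_t()`, `mixed_anova()`,
  `age_correlation()`, `analyze_cohort()`);
* **I/O** — plain-text trajectory logs, YAML session/agent configurations,
  checksummed run manifests and a deterministic fixture bundle.

The core measures, in the field's notation: pointing error is the absolute
angular difference between the pointed direction and the true direction to
the goal; path efficiency is `path_min / path_real` in (0, 1]; quadrant
preference is the fraction of probe-trial time spent in the 90° arena
sector centered on the goal azimuth (chance = 0.25); entrances count
crossings of the inactivated goal.  The agent's recalled goal position is
the true position plus Gaussian noise with spread
`memory_sd0 * memory_decay^(n_obs - 1) + forget_sd * staleness`, so
accuracy improves with repeated observation and degrades with intervening
trials.  See the methods vignette (`vignettes/vfgn-methods.Rmd`) for the
full model.

## Worked example

Simulate one healthy-like agent through a reference-memory session and
score it:

```r
library(vfgn)
set.seed(42)
session <- build_rm_session(seed = 42)
agent   <- memory_navigator(preset_params("healthy_like"))
trajs   <- run_session(session, agent)
score_session(session, trajs)
#> vFGN RM session scores: 11 trials
#>    block              metric      value
#>       B1      pointing_error 10.7804395
#>       B2      pointing_error  4.2978586
#>       B3      pointing_error  4.4573964
#>       B4      pointing_error  3.2220575
#>    probe      pointing_error  0.8820813
#>  visible      pointing_error  3.7085980
#>       B1     path_efficiency  0.6546857
#>       B2     path_efficiency  0.9772183
#>       B3     path_efficiency  0.9775761
#>       B4     path_efficiency  0.9841569
#>  visible     path_efficiency  0.9962264
#>    probe quadrant_preference  0.9550749
#>    probe           entrances 10.0000000
```

The pointing error falls from ~11° in the first block of standard trials
to ~3° in the last as the agent's goal memory sharpens, and path
efficiency climbs toward 1 (a perfectly straight approach).  On the probe
trial the agent spends 95% of its time in the goal quadrant — far above
the 25% chance level, which the naive random explorer recovers:

```r
prefs <- chance_preference(1000, seed = 42)
mean(prefs)
#> [1] 0.2478519
```

Cohort-level comparisons mirror the task's group analyses:

```r
cohort <- make_cohort(list(healthy  = preset_params("healthy_like"),
                           impaired = preset_params("impaired_like")),
                      n_per_group = 29, seed = 1)
table  <- run_cohort(cohort, "both", seed = 2)
rm_res <- analyze_cohort(table, "rm")
rm_res$anova_pointing_error     # group x block split-plot ANOVA
write_analysis_report(rm_res, "report/")
```

A thin command-line front end wraps the same functions:

```sh
Rscript inst/cli/vfgn.R simulate --config session.yaml --agent agent.yaml --out runs/
Rscript inst/cli/vfgn.R score    --runs runs/ --out metrics.csv
Rscript inst/cli/vfgn.R analyze  --metrics metrics.csv --design rm --out report/
```

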