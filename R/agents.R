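#' Agent parameter set
#'
#' Generative parameters of the synthetic navigator.  The spatial-memory
#' model is: after `n` true observations of a goal and `s` intervening trials
#' of other goals since the last one, the per-trial recalled goal estimate is
#' the true center plus isotropic Gaussian noise with standard deviation
#'
#' \deqn{\sigma = memory\_sd0 \cdot memory\_decay^{\,n-1} + forget\_sd \cdot s.}
#'
#' Learning is therefore driven by observation count, not elapsed time, and
#' forgetting by the number of intervening trials (staleness), matching how
#' the task manipulates delay.
#'
#' @param pointing_sd Angular noise (degrees, SD) added to the pointed
#'   direction.
#' @param memory_sd0 Initial spread (meters, SD) of the recalled goal
#'   estimate after a single observation.
#' @param memory_decay Multiplicative shrink factor per additional
#'   observation, in (0, 1].
#' @param forget_sd Meters of spread added per intervening trial of a
#'   different goal.
#' @param heading_sd Step-wise heading noise (degrees per step) of the
#'   exploratory random walk.
#' @param lapse_rate Probability that a trial is executed as pure
#'   exploration, ignoring memory (attention-lapse model).
#' @param seed Optional integer; when given, [memory_navigator()] and
#'   [random_explorer()] seed the R random number stream once at creation.
#' @return A `vfgn_agent_params` list.
#' @export
agent_params <- function(pointing_sd = 10, memory_sd0 = 6,
                         memory_decay = 0.7, forget_sd = 0,
                         heading_sd = 25, lapse_rate = 0.05, seed = NULL) {
  stopifnot(pointing_sd >= 0, memory_sd0 >= 0, forget_sd >= 0,
            heading_sd >= 0, memory_decay > 0, memory_decay <= 1,
            lapse_rate >= 0, lapse_rate <= 1)
  structure(list(pointing_sd = pointing_sd, memory_sd0 = memory_sd0,
                 memory_decay = memory_decay, forget_sd = forget_sd,
                 heading_sd = heading_sd, lapse_rate = lapse_rate,
                 seed = seed),
            class = "vfgn_agent_params")
}

#' Shipped agent presets
#'
#' Two calibrated parameter sets bracketing the performance range the task
#' is designed to resolve.  `healthy_like` learns quickly, retains the goal
#' across intervening trials (`forget_sd = 0`) and rarely lapses;
#' `impaired_like` starts with a coarser spatial memory, consolidates more
#' slowly, loses precision over intervening trials and lapses into
#' exploration more often.  The presets are fixed; they make no claim of
#' cognitive realism beyond reproducing the qualitative ordering of group
#' effects (learning curves, probe spatial bias, recall decline).
#'
#' @param name `"healthy_like"` or `"impaired_like"`.
#' @return A `vfgn_agent_params` list.
#' @export
#' @examples
#' preset_params("healthy_like")
preset_params <- function(name = c("healthy_like", "impaired_like")) {
  name <- match.arg(name)
  switch(name,
         healthy_like = agent_params(pointing_sd = 6, memory_sd0 = 9,
                                     memory_decay = 0.75, forget_sd = 0,
                                     heading_sd = 25, lapse_rate = 0.01),
         impaired_like = agent_params(pointing_sd = 12, memory_sd0 = 14,
                                      memory_decay = 0.92, forget_sd = 2.5,
                                      heading_sd = 25, lapse_rate = 0.08))
}

#' Goal-naive random-exploration policy
#'
#' A correlated random walk: the heading is perturbed by Gaussian noise at
#' every step and reflected at the arena wall.  The policy uses no goal
#' information; pointed directions are uniform on the circle.  It is the
#' chance baseline of the task: its expected goal-quadrant preference is
#' 25% and its expected pointing error is 90 degrees.
#'
#' @param heading_sd Heading noise in degrees per step.
#' @param seed Optional integer seed applied once at creation.
#' @return A policy usable with [run_trial()].
#' @export
random_explorer <- function(heading_sd = 25, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  list(
    point = function(trial) runif(1, 0, 360),
    plan = function(trial) {
      list(mode = "explore", heading0 = runif(1, 0, 360),
           heading_sd = heading_sd)
    },
    end_trial = NULL
  )
}

#' Memory-based navigator policy
#'
#' On each trial the navigator recalls the goal as the true center plus
#' Gaussian noise whose spread shrinks with repeated observations and grows
#' with staleness (see [agent_params()]), points at the recalled position
#' (plus angular pointing noise), navigates straight to it, and searches the
#' neighborhood with an outward Archimedean spiral (pitch = goal radius,
#' restarted when it grows past three goal radii) until the goal is entered
#' or time runs out.  With probability `lapse_rate`, or whenever the goal has
#' never been observed, the trial is executed as pure random exploration.
#' A visible goal is navigated to directly regardless of memory.  Every
#' trial that ends on the goal (including after a timeout reveal) records a
#' true observation and resets that goal's staleness; each trial of a
#' different goal increments staleness by one.
#'
#' @param params A `vfgn_agent_params` from [agent_params()] or
#'   [preset_params()].
#' @param arena An [arena_spec()]; recalled estimates are clamped inside it.
#' @return A policy usable with [run_trial()]; the internal memory store is
#'   inspectable via `policy$memory()`.
#' @export
memory_navigator <- function(params = agent_params(),
                             arena = arena_spec()) {
  stopifnot(inherits(params, "vfgn_agent_params"))
  if (!is.null(params$seed)) set.seed(params$seed)
  store <- list()   # per goal_id: list(center, n_obs, staleness)
  current <- NULL   # per-trial recalled estimate, shared by point() and plan()
  prepared_for <- NULL

  recall_sd <- function(mem) {
    params$memory_sd0 * params$memory_decay^(mem$n_obs - 1) +
      params$forget_sd * mem$staleness
  }

  prepare <- function(trial) {
    # one recall draw per trial, reused for pointing and navigation
    if (identical(prepared_for, trial$index)) return(invisible(NULL))
    prepared_for <<- trial$index
    mem <- store[[trial$goal_id]]
    lapse <- runif(1) < params$lapse_rate
    if (trial$goal$visible) {
      current <<- trial$goal$center
    } else if (is.null(mem) || trial$first_search || lapse) {
      current <<- NULL
    } else {
      est <- mem$center + rnorm(2, 0, recall_sd(mem))
      r <- sqrt(sum(est^2))
      lim <- 0.98 * arena$radius
      if (r > lim) est <- est * lim / r
      current <<- est
    }
    invisible(NULL)
  }

  list(
    point = function(trial) {
      prepare(trial)
      if (is.null(current)) return(runif(1, 0, 360))
      normalize_angle(azimuth(current, trial$start) +
                        rnorm(1, 0, params$pointing_sd))
    },
    plan = function(trial) {
      prepare(trial)
      on.exit({current <<- NULL; prepared_for <<- NULL})
      if (is.null(current)) {
        list(mode = "explore", heading0 = runif(1, 0, 360),
             heading_sd = params$heading_sd)
      } else {
        list(mode = "seek", target = current)
      }
    },
    end_trial = function(goal_id, ended_on_goal, true_center) {
      for (id in names(store)) {
        if (id != goal_id) store[[id]]$staleness <<- store[[id]]$staleness + 1
      }
      if (ended_on_goal) {
        if (is.null(store[[goal_id]])) {
          store[[goal_id]] <<- list(center = true_center, n_obs = 1L,
                                    staleness = 0L)
        } else {
          store[[goal_id]]$center <<- true_center
          store[[goal_id]]$n_obs <<- store[[goal_id]]$n_obs + 1L
          store[[goal_id]]$staleness <<- 0L
        }
      }
    },
    memory = function() store
  )
}

#' Assemble a synthetic cohort
#'
#' Draws per-subject agent parameters around group-level presets.  Each
#' positive-valued parameter is drawn from a Normal centered on the preset
#' value with coefficient of variation `cv`, truncated at zero
#' (`memory_decay` is clamped to (0, 1] and `lapse_rate` to [0, 1]).  Ages
#' are drawn uniformly on 18--35 years and sexes alternate M/F within each
#' group, mirroring the task's matched-group design.  The true per-subject
#' parameters are kept in the output as ground truth for parameter-recovery
#' checks.
#'
#' @param group_presets Named list mapping group label to a
#'   `vfgn_agent_params` (e.g. `list(HC = preset_params("healthy_like"))`).
#' @param n_per_group Subjects per group (at least 2).
#' @param seed Integer seed, or `NULL` to use the current stream.
#' @param cv Coefficient of variation of between-subject parameter spread;
#'   `0` makes all subjects identical to their preset.
#' @return A `vfgn_cohort`: a list of subjects, each with `subject_id`,
#'   `group`, `sex`, `age` and `params`.
#' @export
make_cohort <- function(group_presets, n_per_group, seed = NULL, cv = 0.2) {
  stopifnot(is.list(group_presets), length(names(group_presets)) > 0,
            n_per_group >= 2)
  if (!is.null(seed)) set.seed(seed)
  subjects <- list()
  k <- 0L
  for (g in names(group_presets)) {
    preset <- group_presets[[g]]
    stopifnot(inherits(preset, "vfgn_agent_params"))
    for (i in seq_len(n_per_group)) {
      k <- k + 1L
      draw <- function(mu) {
        if (cv == 0 || mu == 0) return(mu)
        max(0, rnorm(1, mu, cv * mu))
      }
      # rates in (0, 1) vary on the logit scale so the spread respects the
      # bounds instead of piling up at the clamp
      draw_rate <- function(mu) {
        if (cv == 0 || mu <= 0 || mu >= 1) return(mu)
        stats::plogis(rnorm(1, stats::qlogis(mu), cv))
      }
      p <- agent_params(
        pointing_sd = draw(preset$pointing_sd),
        memory_sd0 = draw(preset$memory_sd0),
        memory_decay = draw_rate(preset$memory_decay),
        forget_sd = draw(preset$forget_sd),
        heading_sd = draw(preset$heading_sd),
        lapse_rate = draw_rate(preset$lapse_rate))
      subjects[[k]] <- list(subject_id = sprintf("%s%02d", g, i),
                            group = g,
                            sex = if (i %% 2 == 1) "M" else "F",
                            age = runif(1, 18, 35),
                            params = p)
    }
  }
  structure(subjects, class = "vfgn_cohort")
}

#' @export
print.vfgn_cohort <- function(x, ...) {
  grp <- table(vapply(x, function(s) s$group, character(1)))
  cat("vFGN cohort:", length(x), "subjects (",
      paste(sprintf("%s: %d", names(grp), grp), collapse = ", "), ")\n")
  invisible(x)
}

#' Monte-Carlo chance level of the quadrant-preference measure
#'
#' Simulates goal-naive random-exploration probe trials and returns their
#' goal-quadrant preferences.  Start azimuths are drawn uniformly over the
#' full eight-point grid (a naive agent has no trained goal to exclude
#' around), so by the four-fold symmetry of the quadrant partition the
#' expected preference is exactly 0.25; the simulation recovers it to within
#' Monte-Carlo error.
#'
#' @param n_trials Number of simulated probe trials.
#' @param seed Integer seed, or `NULL`.
#' @param arena,kin Geometry and kinematics.
#' @param goal_pos Goal center used to define the scored quadrant.
#' @param heading_sd Explorer heading noise, degrees per step.
#' @return Numeric vector of per-trial quadrant preferences.
#' @export
chance_preference <- function(n_trials = 1000, seed = NULL,
                              arena = arena_spec(), kin = kinematics(),
                              goal_pos = default_rm_goal(arena),
                              heading_sd = 25) {
  if (!is.null(seed)) set.seed(seed)
  goal <- goal_spec(goal_pos, active = FALSE)
  explorer <- random_explorer(heading_sd)
  vapply(seq_len(n_trials), function(i) {
    az <- sample(seq(0, 315, by = 45), 1)
    start <- 0.92 * arena$radius * c(cos(az * pi / 180), sin(az * pi / 180))
    tr <- trial_spec(i, "RM_probe", "RM", goal, start,
                     pointing_required = FALSE)
    traj <- run_trial(tr, explorer, kin, arena)$trajectory
    quadrant_preference(traj, goal, arena)
  }, numeric(1))
}
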