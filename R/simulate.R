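#' Navigator kinematics
#'
#' Constant translation speed with a bounded turn rate, sampled at a fixed
#' time step.  The defaults (7 m/s, 90 deg/s, dt = 0.1 s) let a direct path
#' cross the default arena in about 8 s, comfortably inside the 60 s search
#' limit, while a random walk usually needs most of the limit.
#'
#' @param speed Translation speed, meters per second.
#' @param turn_max Maximum turn rate, degrees per second.
#' @param dt Sampling/integration step, seconds.
#' @return A `vfgn_kinematics` list.
#' @export
kinematics <- function(speed = 7, turn_max = 90, dt = 0.1) {
  stopifnot(speed >= 0, turn_max > 0, dt > 0)
  structure(list(speed = speed, turn_max = turn_max, dt = dt),
            class = "vfgn_kinematics")
}

new_trajectory <- function(samples, start, pointed_azimuth, dt, goal, arena,
                           found, entry_time, search_limit, reveal,
                           trial_index = NA_integer_,
                           phase_label = NA_character_,
                           goal_id = NA_character_) {
  structure(list(samples = samples, start = as.numeric(start),
                 pointed_azimuth = pointed_azimuth, dt = dt, goal = goal,
                 arena = arena, found = found, entry_time = entry_time,
                 search_limit = search_limit, reveal = reveal,
                 trial_index = trial_index, phase_label = phase_label,
                 goal_id = goal_id),
            class = "vfgn_trajectory")
}

#' @export
print.vfgn_trajectory <- function(x, ...) {
  cat(sprintf(
    "vFGN trajectory: %d samples at dt = %g s, %s%s\n",
    nrow(x$samples), x$dt,
    if (isTRUE(x$found)) sprintf("goal entered at t = %.1f s", x$entry_time)
    else "goal not entered during search",
    if (isTRUE(x$reveal)) " (revealed after timeout)" else ""))
  invisible(x)
}

#' Run one trial of a session under an agent policy
#'
#' Executes the per-trial state machine: the policy first reports a pointed
#' azimuth (recorded before movement is enabled; skipped when the trial does
#' not require pointing), then a movement plan which the kinematics engine
#' integrates at fixed `dt`.  For active goals the search ends at the first
#' goal entry; on timeout the goal is revealed and the walk to it is logged
#' with a post-reveal flag (those samples are excluded from all metrics).
#' Probe trials always run the full search limit.  Afterwards the policy is
#' notified whether the trial ended on the goal (the memorize-phase learning
#' event).
#'
#' @param trial A [trial_spec()].
#' @param policy A policy from [random_explorer()] or [memory_navigator()].
#' @param kin A [kinematics()] object.
#' @param arena An [arena_spec()].
#' @return A list with elements `trajectory` (a `vfgn_trajectory`) and
#'   `trace` (phase timestamps: `pointing_time`, `search_start`,
#'   `goal_entry_time`, `timeout`, `reveal`).
#' @export
run_trial <- function(trial, policy, kin = kinematics(),
                      arena = arena_spec()) {
  stopifnot(inherits(trial, "vfgn_trial"))
  pointed <- if (trial$pointing_required) policy$point(trial) else NA_real_

  plan <- policy$plan(trial)
  mode <- match(plan$mode, c("explore", "seek", "hold")) - 1L
  if (is.na(mode)) stop("unknown plan mode: ", plan$mode)
  target <- if (is.null(plan$target)) trial$goal$center else plan$target
  heading0 <- if (is.null(plan$heading0)) {
    azimuth(target, trial$start)
  } else {
    plan$heading0
  }
  heading_sd <- if (is.null(plan$heading_sd)) 0 else plan$heading_sd
  speed <- if (is.null(plan$speed)) kin$speed else plan$speed

  goal <- trial$goal
  res <- sim_search_cpp(trial$start, heading0, mode, target, goal$center,
                        goal$radius,
                        goal_stop = goal$active && !is_probe(trial),
                        reveal_after = goal$active && !is_probe(trial),
                        arena_radius = arena$radius, speed = speed,
                        dt = kin$dt, search_limit = trial$search_limit,
                        heading_sd = heading_sd, turn_max = kin$turn_max,
                        spiral_pitch = goal$radius,
                        spiral_rmax = if (is.null(plan$spiral_rmax)) {
                          3 * goal$radius
                        } else {
                          plan$spiral_rmax
                        })

  n <- length(res$x)
  post <- rep(FALSE, n)
  if (res$post_start > 0) post[seq(res$post_start, n)] <- TRUE
  samples <- structure(list(t = (seq_len(n) - 1) * kin$dt,
                            x = res$x, y = res$y, post_reveal = post),
                       class = "data.frame", row.names = seq_len(n))

  found <- isTRUE(res$found) && goal$active && !is_probe(trial)
  entry_time <- if (found) (res$entry - 1) * kin$dt else NA_real_
  traj <- new_trajectory(samples, trial$start, pointed, kin$dt, goal, arena,
                         found, entry_time, trial$search_limit,
                         reveal = isTRUE(res$reveal),
                         trial_index = trial$index,
                         phase_label = trial$phase_label,
                         goal_id = trial$goal_id)

  # memorize-phase learning event: any trial that ends on the goal (by
  # search success or after reveal) yields a true observation
  ended_on_goal <- found || isTRUE(res$reveal)
  if (!is.null(policy$end_trial)) {
    policy$end_trial(trial$goal_id, ended_on_goal, goal$center)
  }

  trace <- list(pointing_time = 0, search_start = 0,
                goal_entry_time = entry_time,
                timeout = !found && !is_probe(trial) && goal$active,
                reveal = isTRUE(res$reveal))
  list(trajectory = traj, trace = trace)
}

#' Run a whole session for one agent
#'
#' Trials are executed in schedule order so the agent's memory carries over
#' between trials exactly as in the task.
#'
#' @param session A `vfgn_session` from [build_rm_session()] or
#'   [build_dmp_session()].
#' @param policy An agent policy.
#' @param kin A [kinematics()] object.
#' @return A list of `vfgn_trajectory` objects, one per trial.
#' @export
run_session <- function(session, policy, kin = kinematics()) {
  stopifnot(inherits(session, "vfgn_session"))
  lapply(session$trials, function(tr) {
    run_trial(tr, policy, kin, session$arena)$trajectory
  })
}
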