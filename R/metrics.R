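#' Polyline length of a set of ordered samples
#'
#' @param x,y Numeric coordinate vectors of equal length.
#' @return Sum of Euclidean segment lengths.
#' @export
polyline_length <- function(x, y) {
  stopifnot(length(x) == length(y))
  if (length(x) < 2L) return(0)
  sum(sqrt(diff(x)^2 + diff(y)^2))
}

search_samples <- function(traj) {
  traj$samples[!traj$samples$post_reveal, , drop = FALSE]
}

#' Pointing error
#'
#' Absolute angular difference, in degrees, between the pointed direction
#' and the straight-line direction from the start point to the goal center.
#' Smaller is better; chance level for uniform random pointing is 90
#' degrees.  Absent (`NA`) when the trial required no pointing.
#'
#' @param traj A `vfgn_trajectory`.
#' @param goal A [goal_spec()] (defaults to the trajectory's own goal).
#' @return Degrees in `[0, 180]`, or `NA` if no pointed azimuth was logged.
#' @export
pointing_error <- function(traj, goal = traj$goal) {
  if (is.null(traj$pointed_azimuth) || is.na(traj$pointed_azimuth)) {
    return(NA_real_)
  }
  true_az <- azimuth(goal$center, traj$start)
  angular_difference(traj$pointed_azimuth, true_az)
}

#' Path efficiency
#'
#' Ratio of the minimal possible path length to the path actually traveled,
#' `path_min / path_real`, in (0, 1].  `path_min` is the straight-line
#' distance from the start to the goal *boundary* along the line to the goal
#' center (`‖start − center‖ − radius`), since the search ends at the first
#' boundary crossing; `path_real` is the polyline length of the search-phase
#' samples up to and including the first in-goal sample.  The ratio is
#' capped at 1 (sampling can place the entry sample slightly inside the
#' boundary).  Absent (`NA`) when the goal was not found during the search
#' phase; post-reveal samples never contribute.
#'
#' @param traj A `vfgn_trajectory` with `found = TRUE`.
#' @param goal A [goal_spec()].
#' @return Ratio in (0, 1], or `NA` when the goal was not found.
#' @export
path_efficiency <- function(traj, goal = traj$goal) {
  if (!isTRUE(traj$found)) return(NA_real_)
  s <- traj$samples
  inside <- in_goal(cbind(s$x, s$y), goal) & !s$post_reveal
  entry <- which(inside)[1]
  if (is.na(entry)) return(NA_real_)
  path_min <- sqrt(sum((traj$start - goal$center)^2)) - goal$radius
  if (entry == 1L || path_min <= 0) {
    stop("malformed trial: start position inside or on the goal")
  }
  path_real <- polyline_length(s$x[1:entry], s$y[1:entry])
  min(1, path_min / path_real)
}

#' Goal-quadrant preference
#'
#' Fraction of search-phase samples lying in the goal quadrant (the
#' 90-degree arena sector centered on the goal azimuth).  With constant-rate
#' sampling this equals the proportion of trial time spent there; chance
#' level is 0.25.  Intended for probe trials, which always run the full
#' search limit.
#'
#' By default the whole trajectory is scored (instructed subjects keep
#' searching for the full trial); `max_time` restricts scoring to an early
#' window (e.g. 30 s), mirroring rodent probe analyses in which animals
#' abandon the unrewarded location in the second half of the trial.
#'
#' @param traj A `vfgn_trajectory`.
#' @param goal A [goal_spec()].
#' @param arena An [arena_spec()].
#' @param max_time Optional scoring window in seconds from trial start;
#'   `NULL` scores the full search phase.
#' @return Fraction in `[0, 1]`.
#' @export
quadrant_preference <- function(traj, goal = traj$goal,
                                arena = traj$arena, max_time = NULL) {
  s <- search_samples(traj)
  if (!is.null(max_time)) s <- s[s$t <= max_time, , drop = FALSE]
  if (nrow(s) * traj$dt < 1) stop("trajectory shorter than 1 s")
  quad <- goal_quadrant(goal, arena)
  mean(in_quadrant(cbind(s$x, s$y), quad))
}

#' Number of entrances into the goal region
#'
#' Counts maximal runs of consecutive in-goal samples in the search phase:
#' an entrance is an out-to-in transition, and a trajectory that starts
#' inside counts its initial run as one entrance.  Used on probe trials,
#' where the inactivated goal can be crossed repeatedly.
#'
#' @param traj A `vfgn_trajectory`.
#' @param goal A [goal_spec()].
#' @return Non-negative integer count.
#' @export
count_entrances <- function(traj, goal = traj$goal) {
  s <- search_samples(traj)
  if (nrow(s) == 0L) return(0L)
  inside <- in_goal(cbind(s$x, s$y), goal)
  sum(diff(c(FALSE, inside)) == 1L)
}

rm_block_label <- function(index, phase_label) {
  if (phase_label == "RM_search") return("T1")
  if (phase_label == "RM_probe") return("probe")
  if (phase_label == "RM_visible") return("visible")
  switch(as.character(index),
         "2" = , "3" = "B1", "4" = , "5" = "B2",
         "7" = , "8" = "B3", "9" = , "10" = "B4")
}

dmp_block_label <- function(index, phase_label, goal_id) {
  if (phase_label == "DMP_acq") {
    rep_no <- ((index - 1) %% 3) + 1
    return(sprintf("%s%d", goal_id, rep_no))
  }
  if (phase_label == "DMP_recall") {
    round_no <- if (index <= 12) 1L else 2L
    return(sprintf("recall%d", round_no))
  }
  "probe"
}

#' Score a session
#'
#' Computes the per-trial metrics for every trial of a session and the
#' block-level aggregates the protocols are analyzed by.  Standard and
#' visible trials contribute pointing error and path efficiency; probe
#' trials contribute quadrant preference and entrance count instead (there
#' is no goal to reach, so path efficiency is undefined there).  RM blocks
#' are the means over the standard-trial pairs (T2,T3), (T4,T5), (T7,T8),
#' (T9,T10); DMP aggregates are per goal-by-repetition cell in acquisition
#' and per round in recall.
#'
#' @param session A `vfgn_session`.
#' @param trajectories List of `vfgn_trajectory` objects aligned with
#'   `session$trials`; elements may be `NULL` (that trial's metrics are
#'   absent and flagged as missing).
#' @return A list of class `vfgn_scores` with data frames `trials` (one row
#'   per trial) and `blocks` (one row per block-by-metric aggregate).
#' @export
score_session <- function(session, trajectories) {
  stopifnot(inherits(session, "vfgn_session"),
            length(trajectories) == length(session$trials))
  arena <- session$arena
  rows <- lapply(seq_along(session$trials), function(i) {
    tr <- session$trials[[i]]
    block <- if (session$protocol == "rm") {
      rm_block_label(tr$index, tr$phase_label)
    } else {
      dmp_block_label(tr$index, tr$phase_label, tr$goal_id)
    }
    traj <- trajectories[[i]]
    if (is.null(traj)) {
      return(data.frame(trial = tr$index, phase = tr$phase_label,
                        goal_id = tr$goal_id, block = block, missing = TRUE,
                        found = NA, search_duration = NA_real_,
                        pointing_error = NA_real_,
                        path_efficiency = NA_real_,
                        quadrant_preference = NA_real_,
                        entrances = NA_integer_))
    }
    probe <- is_probe(tr)
    s <- search_samples(traj)
    data.frame(
      trial = tr$index, phase = tr$phase_label, goal_id = tr$goal_id,
      block = block, missing = FALSE, found = traj$found,
      search_duration = if (traj$found) traj$entry_time else
        (nrow(s) - 1) * traj$dt,
      pointing_error = pointing_error(traj, tr$goal),
      path_efficiency = if (probe) NA_real_ else
        path_efficiency(traj, tr$goal),
      quadrant_preference = if (probe)
        quadrant_preference(traj, tr$goal, arena) else NA_real_,
      entrances = if (probe) count_entrances(traj, tr$goal) else
        NA_integer_)
  })
  trials <- do.call(rbind, rows)

  metrics <- c("pointing_error", "path_efficiency",
               "quadrant_preference", "entrances")
  agg <- lapply(metrics, function(m) {
    v <- trials[[m]]
    ok <- !is.na(v)
    if (!any(ok)) return(NULL)
    means <- tapply(v[ok], trials$block[ok], mean)
    data.frame(block = names(means), metric = m,
               value = as.numeric(means), row.names = NULL)
  })
  blocks <- do.call(rbind, agg)
  structure(list(trials = trials, blocks = blocks,
                 protocol = session$protocol),
            class = "vfgn_scores")
}

#' @export
print.vfgn_scores <- function(x, ...) {
  cat(sprintf("vFGN %s session scores: %d trials\n",
              toupper(x$protocol), nrow(x$trials)))
  print(x$blocks, row.names = FALSE)
  invisible(x)
}

#' Simulate and score a cohort
#'
#' Runs every subject of a cohort through freshly built RM and/or DMP
#' sessions (each subject gets its own pseudorandom start sequence) and
#' returns the long-format cohort table the analysis stage consumes: one row
#' per subject, trial and metric.
#'
#' @param cohort A `vfgn_cohort` from [make_cohort()].
#' @param protocol `"rm"`, `"dmp"`, or `"both"`.
#' @param seed Integer seed governing session builds and agent behavior, or
#'   `NULL` to use the current stream.
#' @param arena,kin Geometry and kinematics.
#' @return A data frame with columns `subject_id`, `group`, `sex`, `age`,
#'   `protocol`, `trial`, `phase`, `goal_id`, `block`, `metric`, `value`.
#' @export
run_cohort <- function(cohort, protocol = c("rm", "dmp", "both"),
                       seed = NULL, arena = arena_spec(),
                       kin = kinematics()) {
  protocol <- match.arg(protocol)
  stopifnot(inherits(cohort, "vfgn_cohort"))
  if (!is.null(seed)) set.seed(seed)
  protos <- if (protocol == "both") c("rm", "dmp") else protocol
  out <- list()
  for (subj in cohort) {
    policy <- memory_navigator(subj$params, arena)
    for (pr in protos) {
      session <- if (pr == "rm") {
        build_rm_session(arena)
      } else {
        build_dmp_session(arena, cues = cue_set(
          arena, ids = c("dmp1", "dmp2", "dmp3")))
      }
      trajs <- run_session(session, policy, kin)
      sc <- score_session(session, trajs)$trials
      long <- do.call(rbind, lapply(
        c("pointing_error", "path_efficiency", "quadrant_preference",
          "entrances"),
        function(m) {
          data.frame(subject_id = subj$subject_id, group = subj$group,
                     sex = subj$sex, age = subj$age, protocol = pr,
                     trial = sc$trial, phase = sc$phase,
                     goal_id = sc$goal_id, block = sc$block, metric = m,
                     value = as.numeric(sc[[m]]))
        }))
      out[[length(out) + 1L]] <- long[!is.na(long$value), , drop = FALSE]
    }
  }
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}

#' Subject-by-block means of one metric
#'
#' Collapses a cohort table to one value per subject and block, the balanced
#' layout required by [mixed_anova()].
#'
#' @param table A cohort table from [run_cohort()].
#' @param metric Metric name.
#' @param blocks Optional character vector restricting (and ordering) the
#'   blocks.
#' @return Data frame with `subject_id`, `group`, `sex`, `age`, `block`,
#'   `value`.
#' @export
block_means <- function(table, metric, blocks = NULL) {
  d <- table[table$metric == metric, , drop = FALSE]
  if (!is.null(blocks)) d <- d[d$block %in% blocks, , drop = FALSE]
  if (nrow(d) == 0L) stop("no rows for metric ", metric)
  key <- interaction(d$subject_id, d$block, drop = TRUE)
  agg <- aggregate(value ~ subject_id + group + sex + age + block,
                   data = d, FUN = mean)
  if (!is.null(blocks)) {
    agg$block <- factor(agg$block, levels = blocks)
    agg <- agg[order(agg$subject_id, agg$block), , drop = FALSE]
    agg$block <- as.character(agg$block)
  }
  rownames(agg) <- NULL
  agg
}
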