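#' Single-trial specification
#'
#' One trial of a session: its phase label, goal, start point and timing.
#' Probe trials carry an inactive goal; the visible-goal control trial a
#' visible one.  Pointing is required on every trial except the very first
#' search trial of a goal (when the goal position is still unknown).
#'
#' @param index Ordinal position of the trial within its session.
#' @param phase_label One of `"RM_search"`, `"RM_standard"`, `"RM_probe"`,
#'   `"RM_visible"`, `"DMP_acq"`, `"DMP_recall"`, `"DMP_probe"`.
#' @param goal_id Goal identity: `"RM"` or one of `"A"`, `"B"`, `"C"`.
#' @param goal A [goal_spec()] with `active`/`visible` flags set per phase.
#' @param start Numeric length-2 start point.
#' @param search_limit Search time limit in seconds (default 60).
#' @param memorize_time Memorize-phase duration in seconds (default 10);
#'   bookkeeping only, no motion is simulated during it.
#' @param pointing_required Logical; `FALSE` only for first-search trials.
#' @param first_search Logical; `TRUE` when the goal position is announced as
#'   new/unknown so the agent explores freely.
#' @return A `vfgn_trial` object.
#' @export
trial_spec <- function(index, phase_label, goal_id, goal, start,
                       search_limit = 60, memorize_time = 10,
                       pointing_required = TRUE, first_search = FALSE) {
  phases <- c("RM_search", "RM_standard", "RM_probe", "RM_visible",
              "DMP_acq", "DMP_recall", "DMP_probe")
  if (!(is.character(phase_label) && phase_label %in% phases)) {
    stop("unknown phase label: ", phase_label)
  }
  stopifnot(search_limit > 0, memorize_time >= 0,
            is.numeric(start), length(start) == 2L)
  if (phase_label %in% c("RM_probe", "DMP_probe") && goal$active) {
    stop("probe trials must carry an inactive goal")
  }
  if (phase_label == "RM_visible" && !goal$visible) {
    stop("the control trial must carry a visible goal")
  }
  structure(list(index = index, phase_label = phase_label,
                 goal_id = goal_id, goal = goal, start = as.numeric(start),
                 search_limit = search_limit, memorize_time = memorize_time,
                 pointing_required = isTRUE(pointing_required),
                 first_search = isTRUE(first_search)),
            class = "vfgn_trial")
}

is_probe <- function(trial) trial$phase_label %in% c("RM_probe", "DMP_probe")

#' Pseudorandom start position near the arena wall
#'
#' Starts lie on a circle of radius `0.92 * R` at one of eight azimuths on a
#' 45-degree grid.  Azimuths within 45 degrees of the goal azimuth are
#' excluded (so a trial never starts facing straight onto the goal quadrant),
#' as is the previous trial's start azimuth; at least four candidates always
#' remain.  Draws use the current R random number stream.
#'
#' @param arena An [arena_spec()].
#' @param goal A [goal_spec()], or `NULL` for an unconstrained draw over the
#'   full eight-azimuth grid (used for goal-naive chance baselines).
#' @param previous_start Numeric length-2 previous start point, or `NULL`.
#' @return Numeric length-2 start point.
#' @export
sample_start <- function(arena = arena_spec(), goal = NULL,
                         previous_start = NULL) {
  grid <- seq(0, 315, by = 45)
  keep <- rep(TRUE, length(grid))
  if (!is.null(goal)) {
    g_az <- azimuth(goal$center, arena$center)
    keep <- angular_difference(grid, g_az) > 45 + 1e-9
  }
  if (!is.null(previous_start)) {
    prev_az <- azimuth(previous_start, arena$center)
    keep <- keep & angular_difference(grid, prev_az) > 1e-9
  }
  cand <- grid[keep]
  az <- cand[sample.int(length(cand), 1L)]
  0.92 * arena$radius * c(cos(az * pi / 180), sin(az * pi / 180))
}

#' Default goal positions
#'
#' The RM goal sits at mid-radius at azimuth 45 degrees; the three DMP goals
#' sit at mid-radius at azimuths 0, 120 and 240 degrees, i.e. in identical
#' geometric relation to the arena (so recall of the sequence is compared
#' across goals on equal footing).
#'
#' @param arena An [arena_spec()].
#' @return A length-2 point (`default_rm_goal`) or a named list of three
#'   points `A`, `B`, `C` (`default_dmp_goals`).
#' @export
default_rm_goal <- function(arena = arena_spec()) {
  0.5 * arena$radius * c(cos(45 * pi / 180), sin(45 * pi / 180))
}

#' @rdname default_rm_goal
#' @export
default_dmp_goals <- function(arena = arena_spec()) {
  r <- 0.5 * arena$radius
  az <- c(A = 0, B = 120, C = 240)
  lapply(az, function(a) r * c(cos(a * pi / 180), sin(a * pi / 180)))
}

new_session <- function(trials, arena, cues, goal_positions, seed, protocol) {
  structure(list(trials = trials, arena = arena, cue_set = cues,
                 goal_positions = goal_positions, seed = seed,
                 protocol = protocol),
            class = "vfgn_session")
}

#' @export
print.vfgn_session <- function(x, ...) {
  cat(sprintf("vFGN %s session: %d trials (seed %s)\n",
              toupper(x$protocol), length(x$trials),
              if (is.null(x$seed)) "from current stream" else x$seed))
  lab <- vapply(x$trials, function(t) t$phase_label, character(1))
  print(table(factor(lab, levels = unique(lab))))
  invisible(x)
}

#' Build a reference-memory (RM) session
#'
#' Eleven trials with a stable hidden-goal position: a first free-search
#' trial (T1, no pointing), four blocks of two standard trials (T2--T5 and
#' T7--T10), one probe trial with the goal inactivated inserted mid-session
#' (T6), and a final visible-goal control trial (T11).
#'
#' @param arena An [arena_spec()].
#' @param cues A [cue_set()].
#' @param goal_pos Numeric length-2 goal center (defaults to mid-radius at
#'   azimuth 45 degrees).
#' @param goal_radius Goal radius in meters.
#' @param seed Integer seed for the start-position draws, or `NULL` to use
#'   the current random number stream.
#' @return A `vfgn_session` with 11 `vfgn_trial`s.
#' @export
#' @examples
#' s <- build_rm_session(seed = 1)
#' length(s$trials)  # 11
build_rm_session <- function(arena = arena_spec(), cues = cue_set(arena),
                             goal_pos = default_rm_goal(arena),
                             goal_radius = 2.8, seed = NULL) {
  if (all(goal_pos == arena$center)) {
    stop("goal at the arena center: quadrant and start sampling undefined")
  }
  proto <- goal_spec(goal_pos, goal_radius)
  check_goal_in_arena(proto, arena)
  if (!is.null(seed)) set.seed(seed)
  phases <- c("RM_search", rep("RM_standard", 4), "RM_probe",
              rep("RM_standard", 4), "RM_visible")
  trials <- vector("list", 11L)
  prev <- NULL
  for (i in seq_len(11L)) {
    start <- sample_start(arena, proto, prev)
    goal <- goal_spec(goal_pos, goal_radius,
                      active = phases[i] != "RM_probe",
                      visible = phases[i] == "RM_visible")
    trials[[i]] <- trial_spec(i, phases[i], "RM", goal, start,
                              pointing_required = i > 1L,
                              first_search = i == 1L)
    prev <- start
  }
  new_session(trials, arena, cues, list(RM = as.numeric(goal_pos)),
              seed, "rm")
}

#' Build a delayed-matching-to-place (DMP) session
#'
#' Eighteen trials over three goal positions A, B, C: an acquisition phase of
#' nine trials (three consecutive trials per goal, in sequence A, B, C; the
#' first trial of each goal is an announced free search without pointing), a
#' recall phase of two rounds of the sequence A, B, C (pointing required,
#' goals active), and a probe phase of one final round A, B, C with
#' inactivated goals.
#'
#' @param arena An [arena_spec()].
#' @param cues A [cue_set()]; pass a DMP-specific cue set to model the cue
#'   change between sessions.
#' @param goal_positions Named list with elements `A`, `B`, `C`, each a
#'   length-2 goal center.  The three goal circles must be pairwise disjoint.
#' @param goal_radius Goal radius in meters.
#' @param seed Integer seed for start draws, or `NULL`.
#' @return A `vfgn_session` with 18 `vfgn_trial`s.
#' @export
build_dmp_session <- function(arena = arena_spec(), cues = cue_set(arena),
                              goal_positions = default_dmp_goals(arena),
                              goal_radius = 2.8, seed = NULL) {
  stopifnot(all(c("A", "B", "C") %in% names(goal_positions)))
  goal_positions <- lapply(goal_positions[c("A", "B", "C")], as.numeric)
  for (id in c("A", "B", "C")) {
    g <- goal_spec(goal_positions[[id]], goal_radius)
    if (all(g$center == arena$center)) {
      stop("goal at the arena center: quadrant undefined")
    }
    check_goal_in_arena(g, arena)
  }
  for (pair in list(c("A", "B"), c("A", "C"), c("B", "C"))) {
    d <- sqrt(sum((goal_positions[[pair[1]]] - goal_positions[[pair[2]]])^2))
    if (d <= 2 * goal_radius) {
      stop(sprintf("goal circles %s and %s overlap", pair[1], pair[2]))
    }
  }
  if (!is.null(seed)) set.seed(seed)
  ids <- c(rep(c("A", "B", "C"), each = 3),   # acquisition
           rep(c("A", "B", "C"), 2),          # recall rounds 1 and 2
           c("A", "B", "C"))                  # probe round
  phases <- c(rep("DMP_acq", 9), rep("DMP_recall", 6), rep("DMP_probe", 3))
  first <- c(rep(c(TRUE, FALSE, FALSE), 3), rep(FALSE, 9))
  trials <- vector("list", 18L)
  prev <- NULL
  for (i in seq_len(18L)) {
    goal <- goal_spec(goal_positions[[ids[i]]], goal_radius,
                      active = phases[i] != "DMP_probe")
    start <- sample_start(arena, goal, prev)
    trials[[i]] <- trial_spec(i, phases[i], ids[i], goal, start,
                              pointing_required = !first[i],
                              first_search = first[i])
    prev <- start
  }
  new_session(trials, arena, cues, goal_positions, seed, "dmp")
}
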