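#' Circular arena specification
#'
#' The arena is a disk centered at the origin.  The default radius of 28 m
#' corresponds to a virtual arena scaled up 20-fold from a 2.8 m diameter
#' physical apparatus (diameter 56 m).
#'
#' @param radius Arena radius in meters; must be positive.
#' @return An object of class `vfgn_arena` with fields `radius` and `center`.
#' @export
#' @examples
#' arena_spec()
arena_spec <- function(radius = 28) {
  stopifnot(is.numeric(radius), length(radius) == 1L, is.finite(radius))
  if (radius <= 0) stop("arena radius must be positive")
  structure(list(radius = radius, center = c(0, 0)), class = "vfgn_arena")
}

#' @export
print.vfgn_arena <- function(x, ...) {
  cat(sprintf("vFGN arena: radius %.2f m, center at origin\n", x$radius))
  invisible(x)
}

#' Hidden goal specification
#'
#' The goal is a circle on the arena floor.  Its default radius, 2.8 m, makes
#' the goal diameter 10% of the default arena diameter.  Probe trials carry
#' `active = FALSE` (entering the goal region ends nothing and triggers no
#' reveal); the visible-goal control trial carries `visible = TRUE`.
#'
#' @param center Numeric length-2: goal center (meters).
#' @param radius Goal radius in meters; must be positive.
#' @param active Logical; `FALSE` for probe trials.
#' @param visible Logical; `TRUE` for the visible-goal control trial.
#' @return An object of class `vfgn_goal`.
#' @export
goal_spec <- function(center, radius = 2.8, active = TRUE, visible = FALSE) {
  stopifnot(is.numeric(center), length(center) == 2L, all(is.finite(center)),
            is.numeric(radius), length(radius) == 1L, is.finite(radius))
  if (radius <= 0) stop("goal radius must be positive")
  structure(list(center = as.numeric(center), radius = radius,
                 active = isTRUE(active), visible = isTRUE(visible)),
            class = "vfgn_goal")
}

#' @export
print.vfgn_goal <- function(x, ...) {
  cat(sprintf("vFGN goal: center (%.2f, %.2f), radius %.2f m%s%s\n",
              x$center[1], x$center[2], x$radius,
              if (!x$active) ", inactive (probe)" else "",
              if (x$visible) ", visible" else ""))
  invisible(x)
}

# goal circle must lie entirely inside the arena disk
check_goal_in_arena <- function(goal, arena) {
  if (sqrt(sum(goal$center^2)) + goal$radius > arena$radius) {
    stop("goal circle extends beyond the arena wall")
  }
  invisible(TRUE)
}

#' Distal cue set
#'
#' Exactly three orientation cues placed near the arena wall.  The cue
#' identity tags distinguish the reference-memory cue set from the
#' delayed-matching-to-place cue set (the visual appearance of cues is not
#' modeled, only their positions and identities).
#'
#' @param arena An [arena_spec()].
#' @param azimuths Numeric length-3: cue azimuths in degrees.
#' @param radius_frac Cue distance from center as a fraction of the arena
#'   radius; must lie in `[0.9, 1]`.
#' @param ids Character length-3: cue identity tags.
#' @return A `vfgn_cues` data frame with columns `id`, `x`, `y`.
#' @export
cue_set <- function(arena = arena_spec(),
                    azimuths = c(90, 210, 330),
                    radius_frac = 0.95,
                    ids = c("cue1", "cue2", "cue3")) {
  stopifnot(length(azimuths) == 3L, length(ids) == 3L, !anyDuplicated(ids))
  if (radius_frac < 0.9 || radius_frac > 1) {
    stop("cues must sit within [0.9, 1.0] of the arena radius")
  }
  az <- normalize_angle(azimuths)
  r <- radius_frac * arena$radius
  out <- data.frame(id = as.character(ids),
                    x = r * cos(az * pi / 180),
                    y = r * sin(az * pi / 180),
                    stringsAsFactors = FALSE)
  class(out) <- c("vfgn_cues", "data.frame")
  out
}

#' Normalize an azimuth to [0, 360)
#'
#' Azimuths are measured in degrees counterclockwise from the +x axis.
#' Normalization is idempotent.
#'
#' @param a Numeric vector of angles in degrees.
#' @return Angles reduced modulo 360 into `[0, 360)`.
#' @export
normalize_angle <- function(a) {
  if (!all(is.finite(a))) stop("non-finite angle")
  a %% 360
}

#' Absolute angular difference on the circle
#'
#' Returns the unsigned angular distance between two azimuths, in degrees in
#' `[0, 180]`.  This is the distance used by the pointing-error measure: the
#' absolute angular difference between a pointed direction and the true
#' direction toward the goal.
#'
#' @param a,b Azimuths in degrees (any finite values; vectorized).
#' @return Degrees in `[0, 180]`; symmetric in its arguments.
#' @export
#' @examples
#' angular_difference(350, 30)  # 40, wrapping through 0
angular_difference <- function(a, b) {
  if (!all(is.finite(a)) || !all(is.finite(b))) stop("non-finite angle")
  d <- abs(a - b) %% 360
  pmin(d, 360 - d)
}

#' Azimuth of a point or direction
#'
#' @param p Numeric length-2 point, or a 2-column matrix of points.
#' @param origin Reference point (defaults to the arena center).
#' @return Azimuth(s) in degrees in `[0, 360)`.  The azimuth of the origin
#'   itself is undefined and returned as 0 (the `atan2(0, 0)` convention).
#' @export
azimuth <- function(p, origin = c(0, 0)) {
  if (is.matrix(p)) {
    normalize_angle(atan2(p[, 2] - origin[2], p[, 1] - origin[1]) * 180 / pi)
  } else {
    normalize_angle(atan2(p[2] - origin[2], p[1] - origin[1]) * 180 / pi)
  }
}

#' Is a point inside the goal circle?
#'
#' The boundary counts as inside: entering the goal is detected the moment
#' the distance to the goal center is at most the goal radius.
#'
#' @param p Numeric length-2 point or a 2-column matrix of points.
#' @param goal A [goal_spec()].
#' @return Logical (vectorized over matrix rows).
#' @export
in_goal <- function(p, goal) {
  # tolerance keeps points at exactly the boundary inside despite rounding
  lim <- goal$radius + 1e-9 * max(1, goal$radius)
  if (is.matrix(p)) {
    sqrt((p[, 1] - goal$center[1])^2 + (p[, 2] - goal$center[2])^2) <= lim
  } else {
    sqrt(sum((p - goal$center)^2)) <= lim
  }
}

#' Goal-centered arena quadrant
#'
#' The goal quadrant is the 90-degree angular sector of the arena centered on
#' the azimuth of the goal center, i.e. the quadrant that contains the hidden
#' goal in its middle.  Rotating the sector in 90-degree steps yields four
#' sectors that partition the arena; by symmetry a spatially uniform
#' trajectory spends 25% of its time in each, which is the chance level for
#' the quadrant-preference measure.
#'
#' @param goal A [goal_spec()]; its center must not coincide with the arena
#'   center (the azimuth would be undefined).
#' @param arena An [arena_spec()].
#' @return A `vfgn_quadrant` object with fields `lo` and `hi` (azimuth bounds
#'   in degrees; lower bound inclusive, upper exclusive, possibly wrapping
#'   through 0).
#' @export
goal_quadrant <- function(goal, arena = arena_spec()) {
  if (all(goal$center == arena$center)) {
    stop("goal at the arena center: quadrant azimuth undefined")
  }
  th <- azimuth(goal$center, arena$center)
  structure(list(lo = normalize_angle(th - 45), hi = normalize_angle(th + 45),
                 goal_azimuth = th),
            class = "vfgn_quadrant")
}

#' Membership in an angular sector
#'
#' Lower bound inclusive, upper bound exclusive, so the four rotated sectors
#' tile the disk without double counting.  Points exactly at the arena center
#' are assigned by the azimuth-0 convention of [azimuth()].
#'
#' @param p Numeric length-2 point or a 2-column matrix of points.
#' @param quadrant A `vfgn_quadrant` from [goal_quadrant()].
#' @return Logical (vectorized over matrix rows).
#' @export
in_quadrant <- function(p, quadrant) {
  az <- azimuth(p)
  # offset from the sector's lower bound, reduced mod 360: inside iff < 90
  (az - quadrant$lo) %% 360 < 90
}
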