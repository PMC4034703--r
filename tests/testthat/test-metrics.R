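test_that("pointing error matches hand geometry", {
  goal <- goal_spec(c(8, 0), radius = 1)
  xy <- rbind(c(-20, 0), c(8, 0))
  true_az <- azimuth(goal$center, c(-20, 0))  # 0 degrees
  expect_equal(pointing_error(make_traj(xy, goal, pointed = true_az)), 0)
  expect_equal(pointing_error(make_traj(xy, goal, pointed = true_az + 180)),
               180)
  # start (-20, 0), goal center (8, 0), pointed azimuth 90 -> error 90
  expect_equal(pointing_error(make_traj(xy, goal, pointed = 90)), 90)
  # absent pointing yields an absent metric, not zero
  expect_true(is.na(pointing_error(make_traj(xy, goal))))
})

test_that("pointing error is invariant under global rotation of the scene", {
  set.seed(41)
  for (i in 1:50) {
    start <- runif(2, -20, 20)
    center <- start + runif(2, 5, 15)
    pointed <- runif(1, 0, 360)
    base <- pointing_error(make_traj(rbind(start, center),
                                     goal_spec(center, 1), pointed))
    phi <- runif(1, 0, 360)
    rot <- function(p) {
      a <- phi * pi / 180
      c(cos(a) * p[1] - sin(a) * p[2], sin(a) * p[1] + cos(a) * p[2])
    }
    rotated <- pointing_error(make_traj(rbind(rot(start), rot(center)),
                                        goal_spec(rot(center), 1),
                                        normalize_angle(pointed + phi)))
    expect_equal(rotated, base, tolerance = 1e-9)
  }
})

test_that("path efficiency identities: straight 1.0, doubled 0.5, two-leg 50/70", {
  r <- 0.5
  # straight approach ending on the boundary
  g1 <- goal_spec(c(10 + r, 0), radius = r)
  straight <- make_traj(rbind(c(0, 0), c(5, 0), c(10, 0)), g1)
  expect_equal(path_efficiency(straight), 1.0)
  # detour of exactly twice the minimal length (10 vs 20)
  doubled <- make_traj(rbind(c(0, 0), c(0, 7.5), c(10, 0)), g1)
  expect_equal(path_efficiency(doubled), 0.5)
  # right-angle legs 30 + 40 to a goal with straight entry distance 50
  endp <- c(40, 30)
  center <- endp * (50 + r) / 50
  g2 <- goal_spec(center, radius = r)
  legs <- make_traj(rbind(c(0, 0), c(0, 30), c(40, 30)), g2)
  expect_equal(path_efficiency(legs), 50 / 70, tolerance = 1e-9)
  # not found -> absent
  nf <- make_traj(rbind(c(0, 0), c(1, 0)), goal_spec(c(20, 0), radius = r),
                  found = FALSE)
  expect_true(is.na(path_efficiency(nf)))
  # start inside the goal is a malformed trial
  inside <- make_traj(rbind(c(10 + r, 0), c(11, 0)), g1)
  expect_error(path_efficiency(inside), "malformed")
})

test_that("path efficiency is scale invariant", {
  set.seed(43)
  for (k in c(0.1, 2, 17)) {
    xy <- rbind(c(0, 0), c(3, 4), c(9, 2), c(14.5, 0.5))
    g <- goal_spec(c(15, 0), radius = 1)
    base <- path_efficiency(make_traj(xy, g))
    scaled <- path_efficiency(make_traj(xy * k, goal_spec(c(15, 0) * k,
                                                          radius = k)))
    expect_equal(scaled, base, tolerance = 1e-12)
  }
})

test_that("quadrant preference fractions behave and partition to one", {
  arena <- arena_spec()
  goal <- goal_spec(c(14, 0), active = FALSE)
  # trajectory entirely inside the goal quadrant
  xy_in <- cbind(seq(5, 20, length.out = 120), rep(0, 120))
  tin <- make_traj(xy_in, goal, arena = arena, found = FALSE, dt = 0.5)
  expect_equal(quadrant_preference(tin, goal, arena), 1.0)
  # equal time in two opposite quadrants: half each, none orthogonal
  xy_half <- rbind(cbind(rep(10, 60), rep(0, 60)),
                   cbind(rep(-10, 60), rep(0, 60)))
  th <- make_traj(xy_half, goal, arena = arena, found = FALSE, dt = 0.5)
  expect_equal(quadrant_preference(th, goal, arena), 0.5)
  east <- goal_quadrant(goal, arena)
  north <- goal_quadrant(goal_spec(c(0, 14)), arena)
  s <- th$samples
  expect_equal(mean(in_quadrant(cbind(s$x, s$y), north)), 0)
  # the four rotated quadrants account for all samples
  set.seed(44)
  r <- sqrt(runif(400)) * arena$radius
  a <- runif(400, 0, 2 * pi)
  walk <- make_traj(cbind(r * cos(a), r * sin(a)), goal, arena = arena,
                    found = FALSE, dt = 0.5)
  total <- sum(vapply(c(0, 90, 180, 270), function(off) {
    gq <- goal_spec(14 * c(cos(off * pi / 180), sin(off * pi / 180)))
    quadrant_preference(walk, gq, arena)
  }, numeric(1)))
  expect_equal(total, 1)
  # too-short trajectories are rejected
  short <- make_traj(rbind(c(0, 0), c(1, 0)), goal, arena = arena, dt = 0.1)
  expect_error(quadrant_preference(short, goal, arena), "1 s")
  # early-window scoring uses only samples inside the window
  xy_late <- rbind(cbind(rep(10, 30), 0), cbind(rep(-10, 30), 0))
  tl <- make_traj(xy_late, goal, arena = arena, found = FALSE, dt = 1)
  expect_equal(quadrant_preference(tl, goal, arena), 0.5)
  expect_equal(quadrant_preference(tl, goal, arena, max_time = 29), 1)
})

test_that("entrance counting follows the run-length convention", {
  g <- goal_spec(c(0, 0), radius = 1)
  never <- make_traj(cbind(seq(5, 20, length.out = 20), 0), g, found = FALSE)
  expect_equal(count_entrances(never, g), 0)
  twice <- make_traj(cbind(c(3, 0, 0, 3, 3, 0), 0), g, found = FALSE)
  expect_equal(count_entrances(twice, g), 2)
  dwell <- make_traj(cbind(c(0, 0.2, -0.2, 0.1), 0), g, found = FALSE)
  expect_equal(count_entrances(dwell, g), 1)
})

test_that("incremental polyline length matches the brute-force oracle", {
  set.seed(46)
  for (i in 1:20) {
    n <- sample(2:400, 1)
    x <- rnorm(n, sd = 10); y <- rnorm(n, sd = 10)
    expect_equal(polyline_length(x, y), polyline_oracle(x, y),
                 tolerance = 1e-9)
  }
})

test_that("session scoring assigns metrics to the right trial types", {
  set.seed(47)
  s <- build_rm_session(seed = 3)
  pol <- memory_navigator(preset_params("healthy_like"))
  trajs <- run_session(s, pol)
  sc <- score_session(s, trajs)
  expect_equal(nrow(sc$trials), 11)
  # exactly 4 RM block means per trial-wise metric
  for (m in c("pointing_error", "path_efficiency")) {
    bl <- sc$blocks[sc$blocks$metric == m & grepl("^B", sc$blocks$block), ]
    expect_equal(sort(bl$block), c("B1", "B2", "B3", "B4"))
  }
  probe_row <- sc$trials[sc$trials$phase == "RM_probe", ]
  expect_false(is.na(probe_row$quadrant_preference))
  expect_false(is.na(probe_row$entrances))
  expect_true(is.na(probe_row$path_efficiency))
  vis_row <- sc$trials[sc$trials$phase == "RM_visible", ]
  expect_false(is.na(vis_row$pointing_error))
  expect_false(is.na(vis_row$path_efficiency))
  # missing trajectory -> flagged, metrics absent
  trajs2 <- trajs
  trajs2[[4]] <- NULL
  trajs2 <- append(trajs2, list(NULL), after = 3)
  sc2 <- score_session(s, trajs2)
  expect_true(sc2$trials$missing[4])
  expect_true(is.na(sc2$trials$pointing_error[4]))
})
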