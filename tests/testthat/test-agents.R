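test_that("a noiseless navigator points exactly and walks straight after one observation", {
  params <- agent_params(pointing_sd = 0, memory_sd0 = 0, memory_decay = 1,
                         forget_sd = 0, lapse_rate = 0)
  pol <- memory_navigator(params)
  goal <- goal_spec(c(14, 0))
  pol$end_trial("RM", TRUE, goal$center)   # one true observation
  tr <- trial_spec(2, "RM_standard", "RM", goal, c(-20, 0))
  res <- run_trial(tr, pol)
  traj <- res$trajectory
  expect_equal(pointing_error(traj, goal), 0)
  expect_true(traj$found)
  expect_gt(path_efficiency(traj, goal), 0.97)
})

test_that("an unobserved goal or a lapse falls back to random exploration", {
  set.seed(51)
  params <- agent_params(lapse_rate = 0)
  pol <- memory_navigator(params)
  goal <- goal_spec(c(14, 0))
  tr <- trial_spec(1, "RM_standard", "RM", goal, c(-20, 0))
  plan <- pol$plan(tr)
  expect_equal(plan$mode, "explore")
  # with certain lapse, even a trained navigator explores
  pol2 <- memory_navigator(agent_params(lapse_rate = 1))
  pol2$end_trial("RM", TRUE, goal$center)
  plan2 <- pol2$plan(trial_spec(2, "RM_standard", "RM", goal, c(-20, 0)))
  expect_equal(plan2$mode, "explore")
})

test_that("random pointing has mean error near 90 degrees and exploration finds the goal sometimes", {
  set.seed(52)
  pe <- replicate(3000, angular_difference(runif(1, 0, 360), 123))
  expect_lt(abs(mean(pe) - 90), 3 * sd(pe) / sqrt(length(pe)))

  ex <- random_explorer()
  goal <- goal_spec(default_rm_goal())
  found <- replicate(60, {
    tr <- trial_spec(1, "RM_standard", "RM", goal,
                     sample_start(goal = goal), pointing_required = FALSE)
    run_trial(tr, ex)$trajectory$found
  })
  expect_gt(mean(found), 0)
  expect_lt(mean(found), 1)
})

test_that("random exploration occupancy is rotation invariant across quadrants", {
  set.seed(53)
  arena <- arena_spec()
  prefs <- matrix(NA_real_, 400, 4)
  ex <- random_explorer()
  base_goal <- goal_spec(c(14, 0), active = FALSE)
  for (i in seq_len(nrow(prefs))) {
    az <- sample(seq(0, 315, by = 45), 1)
    start <- 0.92 * arena$radius * c(cos(az * pi / 180), sin(az * pi / 180))
    tr <- trial_spec(1, "RM_probe", "RM", base_goal, start,
                     pointing_required = FALSE)
    traj <- run_trial(tr, ex, kinematics(), arena)$trajectory
    prefs[i, ] <- vapply(c(0, 90, 180, 270), function(off) {
      g <- goal_spec(14 * c(cos(off * pi / 180), sin(off * pi / 180)))
      quadrant_preference(traj, g, arena)
    }, numeric(1))
  }
  means <- colMeans(prefs)
  se <- apply(prefs, 2, sd) / sqrt(nrow(prefs))
  expect_true(all(abs(means - 0.25) < 2 * pmax(se, 1e-6) + 0.02))
  # sectors tile up to boundary samples (starts sit on sector boundaries)
  expect_equal(sum(means), 1, tolerance = 2 / 600)
})

test_that("expected recall spread is non-increasing in observation count", {
  p <- preset_params("impaired_like")
  sigma <- function(n, s) p$memory_sd0 * p$memory_decay^(n - 1) +
    p$forget_sd * s
  n <- 1:20
  expect_true(all(diff(sigma(n, 0)) <= 0))
  # staleness strictly inflates the spread
  expect_true(all(sigma(n, 3) > sigma(n, 0)))
})

test_that("healthy-preset cohorts show a decreasing pointing-error learning curve", {
  set.seed(54)
  coh <- make_cohort(list(HC = preset_params("healthy_like")), 29)
  tab <- run_cohort(coh, "rm")
  bm <- block_means(tab, "pointing_error", c("B1", "B2", "B3", "B4"))
  mat <- matrix(bm$value, ncol = 4, byrow = TRUE)
  # per-subject rows are ordered B1..B4 by block_means
  expect_lt(page_trend_p(mat), 0.05)
  grp <- colMeans(mat)
  expect_gt(grp[1], grp[4])
})

test_that("impaired probe preference lies between the explorer's and the healthy preset's", {
  set.seed(55)
  arena <- arena_spec()
  probe_pref <- function(preset_name) {
    coh <- make_cohort(list(G = preset_params(preset_name)), 20)
    tab <- run_cohort(coh, "rm")
    mean(tab$value[tab$metric == "quadrant_preference"])
  }
  healthy <- probe_pref("healthy_like")
  impaired <- probe_pref("impaired_like")
  chance <- mean(chance_preference(300))
  expect_gt(impaired, chance)
  expect_lt(impaired, healthy)
})

test_that("cohorts are reproducible and degenerate spreads collapse", {
  c1 <- make_cohort(list(HC = preset_params("healthy_like")), 5, seed = 8)
  c2 <- make_cohort(list(HC = preset_params("healthy_like")), 5, seed = 8)
  expect_identical(c1, c2)
  c0 <- make_cohort(list(HC = preset_params("healthy_like")), 4, seed = 9,
                    cv = 0)
  ps <- lapply(c0, function(s) s$params)
  expect_true(all(vapply(ps[-1], identical, logical(1), ps[[1]])))
  expect_error(make_cohort(list(HC = preset_params("healthy_like")), 1),
               "n_per_group")
})

test_that("observed pointing error recovers the ranking of true memory spread", {
  set.seed(56)
  # vary only the initial memory spread; other parameters held at the preset
  sd0 <- runif(100, 2, 16)
  coh <- structure(lapply(seq_along(sd0), function(i) {
    list(subject_id = sprintf("G%03d", i), group = "G",
         sex = if (i %% 2) "M" else "F", age = runif(1, 18, 35),
         params = agent_params(pointing_sd = 6, memory_sd0 = sd0[i],
                               memory_decay = 0.75, forget_sd = 0,
                               heading_sd = 25, lapse_rate = 0.01))
  }), class = "vfgn_cohort")
  tab <- run_cohort(coh, "rm")
  bm <- block_means(tab, "pointing_error", c("B1", "B2", "B3", "B4"))
  obs <- aggregate(value ~ subject_id, bm, mean)
  truth <- data.frame(subject_id = sprintf("G%03d", seq_along(sd0)),
                      sd0 = sd0)
  m <- merge(obs, truth, by = "subject_id")
  expect_gt(cor(m$value, m$sd0, method = "spearman"), 0.5)
})
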