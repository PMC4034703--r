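# Independent oracles used to cross-check the implementation.

# circular distance by explicit minimization over both rotation directions
circ_dist_oracle <- function(a, b) {
  min(abs(a - b + 360 * (-2:2)))
}

# sector membership decided from signed angles, independent of in_quadrant()
in_sector_oracle <- function(p, center_azimuth) {
  az <- atan2(p[2], p[1]) * 180 / pi
  d <- (az - (center_azimuth - 45)) %% 360
  d >= 0 && d < 90
}

# brute-force pairwise polyline length
polyline_oracle <- function(x, y) {
  s <- 0
  for (i in seq_len(length(x) - 1)) {
    s <- s + sqrt((x[i + 1] - x[i])^2 + (y[i + 1] - y[i])^2)
  }
  s
}

# split-plot ANOVA sums of squares by explicit projection matrices
anova_projection_oracle <- function(y, group, block, subject) {
  proj <- function(X) X %*% solve(crossprod(X), t(X))
  n <- length(y)
  P1 <- matrix(1 / n, n, n)
  Pg <- proj(stats::model.matrix(~ factor(group) - 1))
  Pb <- proj(stats::model.matrix(~ factor(block) - 1))
  Ps <- proj(stats::model.matrix(~ factor(subject) - 1))
  Pgb <- proj(stats::model.matrix(~ factor(group):factor(block) - 1))
  qf <- function(P) as.numeric(t(y) %*% P %*% y)
  ss_group <- qf(Pg - P1)
  ss_subj <- qf(Ps - Pg)
  ss_block <- qf(Pb - P1)
  ss_gb <- qf(Pgb - Pg - Pb + P1)
  ss_total <- qf(diag(n) - P1)
  ss_err <- ss_total - ss_group - ss_subj - ss_block - ss_gb
  list(group = ss_group, subjects = ss_subj, block = ss_block,
       interaction = ss_gb, error = ss_err, total = ss_total)
}

# Page trend test (L statistic, normal approximation, one-sided for a
# monotone decrease across ordered conditions)
page_trend_p <- function(mat) {
  # mat: subjects x ordered conditions; tests decreasing trend
  ranks <- t(apply(-mat, 1, rank))
  b <- ncol(mat)
  n <- nrow(mat)
  L <- sum(colSums(ranks) * seq_len(b))
  mu <- n * b * (b + 1)^2 / 4
  sigma <- sqrt(n * b^2 * (b + 1) * (b^2 - 1) / 144)
  stats::pnorm((L - mu) / sigma, lower.tail = FALSE)
}

# straight-to-goal policy (oracle navigator, no noise)
oracle_policy <- function() {
  list(point = function(trial) azimuth(trial$goal$center, trial$start),
       plan = function(trial) list(mode = "seek",
                                   target = trial$goal$center),
       end_trial = NULL)
}

stationary_policy <- function() {
  list(point = function(trial) 0,
       plan = function(trial) list(mode = "hold"),
       end_trial = NULL)
}

# hand-built trajectory for metric unit tests (vertex samples; metrics do
# not require equal spacing for the path-length identities)
make_traj <- function(xy, goal, pointed = NA_real_, dt = 1,
                      arena = arena_spec(100), found = TRUE) {
  n <- nrow(xy)
  samples <- data.frame(t = (seq_len(n) - 1) * dt, x = xy[, 1], y = xy[, 2],
                        post_reveal = FALSE)
  structure(list(samples = samples, start = xy[1, ],
                 pointed_azimuth = pointed, dt = dt, goal = goal,
                 arena = arena, found = found,
                 entry_time = (n - 1) * dt, search_limit = 60,
                 reveal = FALSE, trial_index = 1L,
                 phase_label = "RM_standard", goal_id = "RM"),
            class = "vfgn_trajectory")
}
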