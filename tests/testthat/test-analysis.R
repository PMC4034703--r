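test_that("one-sample t matches hand computation and the reference implementation", {
  r1 <- one_sample_t(c(0.25, 0.25, 0.26, 0.24), 0.25)
  expect_equal(r1$t, 0)
  expect_equal(r1$p, 1)
  # mean 3, sd sqrt(2.5): t = 3 / (1.5811 / sqrt(5)) = 4.2426
  r2 <- one_sample_t(1:5, 0)
  expect_equal(r2$t, sqrt(10) * 3 / sqrt(10 * 2.5 / 5), tolerance = 1e-12)
  expect_equal(r2$t, 4.2426, tolerance = 1e-4)
  expect_equal(r2$df, 4)
  ref <- stats::t.test(1:5, mu = 0)
  expect_equal(r2$t, unname(ref$statistic))
  expect_equal(r2$p, ref$p.value)
  expect_error(one_sample_t(rep(1, 4), 1), "degenerate")
  expect_warning(r3 <- one_sample_t(rep(1, 4), 0), "zero variance")
  expect_equal(r3$p, 0)
})

test_that("two-sample t matches hand computation and the reference implementation", {
  same <- two_sample_t(c(1, 2, 3), c(1, 2, 3))
  expect_equal(same$t, 0)
  expect_equal(same$p, 1)
  r <- two_sample_t(c(1, 2, 3), c(4, 5, 6))
  expect_equal(r$t, -3.674, tolerance = 1e-3)  # pooled SD 1.0
  expect_equal(r$df, 4)
  ref <- stats::t.test(c(1, 2, 3), c(4, 5, 6), var.equal = TRUE)
  expect_equal(r$t, unname(ref$statistic))
  expect_equal(r$p, ref$p.value)
  set.seed(61)
  a <- rnorm(12); b <- rnorm(9, sd = 3)
  w <- two_sample_t(a, b, pooled = FALSE)
  refw <- stats::t.test(a, b)
  expect_equal(w$t, unname(refw$statistic))
  expect_equal(w$df, unname(refw$parameter))
  expect_equal(w$p, refw$p.value)
})

test_that("paired and unpaired reductions agree between the two t tests", {
  set.seed(62)
  x <- rnorm(10); y <- rnorm(10)
  # one-sample t on differences equals the paired t
  d <- one_sample_t(x - y, 0)
  ref <- stats::t.test(x, y, paired = TRUE)
  expect_equal(d$t, unname(ref$statistic))
  expect_equal(d$p, ref$p.value)
})

test_that("mixed ANOVA matches the projection-matrix oracle on all toy designs", {
  set.seed(63)
  for (a in 2:3) for (n in 2:4) for (b in 2:4) {
    grp <- rep(paste0("g", seq_len(a)), each = n * b)
    subj <- rep(sprintf("s%02d", seq_len(a * n)), each = b)
    blk <- rep(paste0("b", seq_len(b)), times = a * n)
    y <- rnorm(a * n * b, mean = as.integer(factor(grp)))
    d <- data.frame(subject_id = subj, group = grp, block = blk, value = y)
    fit <- mixed_anova(d)
    orc <- anova_projection_oracle(y, grp, blk, subj)
    expect_equal(fit$ss[fit$effect == "group"], orc$group, tolerance = 1e-9)
    expect_equal(fit$ss[fit$effect == "subjects_within_groups"],
                 orc$subjects, tolerance = 1e-9)
    expect_equal(fit$ss[fit$effect == "block"], orc$block, tolerance = 1e-9)
    expect_equal(fit$ss[fit$effect == "group:block"], orc$interaction,
                 tolerance = 1e-9)
    expect_equal(fit$ss[fit$effect == "residual"], orc$error,
                 tolerance = 1e-8)
    expect_equal(sum(fit$df), a * n * b - 1)
  }
  # unequal group sizes: repeated factor balanced, groups 3 vs 5
  grp <- rep(c("g1", "g2"), times = c(3 * 3, 5 * 3))
  subj <- rep(sprintf("s%02d", 1:8), each = 3)
  blk <- rep(paste0("b", 1:3), times = 8)
  y <- rnorm(24)
  fit <- mixed_anova(data.frame(subject_id = subj, group = grp,
                                block = blk, value = y))
  orc <- anova_projection_oracle(y, grp, blk, subj)
  expect_equal(fit$ss, c(orc$group, orc$subjects, orc$block,
                         orc$interaction, orc$error), tolerance = 1e-9)
})

test_that("mixed ANOVA agrees with the split-plot aov stratification", {
  set.seed(64)
  grp <- rep(c("g1", "g2"), each = 4 * 3)
  subj <- rep(sprintf("s%d", 1:8), each = 3)
  blk <- rep(paste0("b", 1:3), times = 8)
  y <- rnorm(24) + ifelse(grp == "g2", 1, 0) + as.integer(factor(blk)) / 2
  d <- data.frame(subject_id = subj, group = grp, block = blk, value = y)
  fit <- mixed_anova(d)
  ref <- summary(stats::aov(value ~ group * block + Error(subject_id),
                            data = d))
  s1 <- ref[["Error: subject_id"]][[1]]
  s2 <- ref[["Error: Within"]][[1]]
  expect_equal(fit$F[fit$effect == "group"], s1["group", "F value"],
               tolerance = 1e-8)
  expect_equal(fit$p[fit$effect == "group"], s1["group", "Pr(>F)"],
               tolerance = 1e-8)
  expect_equal(fit$F[fit$effect == "block"], s2["block", "F value"],
               tolerance = 1e-8)
  expect_equal(fit$F[fit$effect == "group:block"],
               s2["group:block", "F value"], tolerance = 1e-8)
})

test_that("mixed ANOVA sums of squares are shift invariant and additive", {
  set.seed(65)
  grp <- rep(c("g1", "g2"), each = 3 * 4)
  subj <- rep(sprintf("s%d", 1:6), each = 4)
  blk <- rep(paste0("b", 1:4), times = 6)
  y <- rnorm(24)
  d <- data.frame(subject_id = subj, group = grp, block = blk, value = y)
  f1 <- mixed_anova(d)
  d2 <- d; d2$value <- d2$value + 1000
  f2 <- mixed_anova(d2)
  expect_equal(f1$ss, f2$ss, tolerance = 1e-6)
  expect_equal(sum(f1$ss), sum((y - mean(y))^2), tolerance = 1e-9)
})

test_that("mixed ANOVA rejects malformed tables informatively", {
  grp <- rep(c("g1", "g2"), each = 2 * 2)
  subj <- rep(sprintf("s%d", 1:4), each = 2)
  blk <- rep(c("b1", "b2"), times = 4)
  d <- data.frame(subject_id = subj, group = grp, block = blk,
                  value = rnorm(8))
  expect_error(mixed_anova(d[-1, ]), "s1")
  d_allsame <- d; d_allsame$value <- 5
  expect_warning(fit <- mixed_anova(d_allsame), "all values equal")
  expect_true(all(fit$ss == 0))
  expect_equal(fit$F[1], 0)
})

test_that("age correlation recovers exact dependence and calibrates under the null", {
  mk_table <- function(vals, ages, group = "G") {
    data.frame(subject_id = sprintf("%s%02d", group, seq_along(vals)),
               group = group, sex = "M", age = ages, protocol = "rm",
               trial = 2, phase = "RM_standard", goal_id = "RM",
               block = "B1", metric = "m", value = vals)
  }
  ages <- seq(20, 34, length.out = 8)
  perfect <- age_correlation(mk_table(ages, ages), "m")
  expect_equal(perfect$r, 1)
  expect_equal(perfect$p, 0)
  expect_error(age_correlation(mk_table(rep(1, 8), ages), "m"), "constant")
  # reference-implementation cross-check
  set.seed(66)
  v <- rnorm(12); a <- runif(12, 18, 35)
  got <- age_correlation(mk_table(v, a), "m")
  ref <- stats::cor.test(a, v)
  expect_equal(got$r, unname(ref$estimate))
  expect_equal(got$t, unname(ref$statistic))
  expect_equal(got$p, ref$p.value)
  # type-I error of the age test at n = 29 over independent replicates
  set.seed(67)
  rej <- mean(replicate(1000, {
    age_correlation(mk_table(rnorm(29), runif(29, 18, 35)), "m")$p < 0.05
  }))
  expect_lt(abs(rej - 0.05), 0.02)
})

test_that("pairwise group tests apply the Holm correction", {
  set.seed(68)
  tab <- do.call(rbind, lapply(c("A", "B", "C"), function(g) {
    data.frame(subject_id = sprintf("%s%02d", g, 1:10), group = g,
               sex = "M", age = 25, protocol = "rm", trial = 2,
               phase = "RM_standard", goal_id = "RM", block = "B1",
               metric = "m",
               value = rnorm(10, mean = match(g, c("A", "B", "C"))))
  }))
  res <- pairwise_groups(tab, "m")
  expect_equal(nrow(res), 3)
  expect_true(all(res$p_holm >= res$p))
  expect_true(all(res$p_holm <= 1))
})
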