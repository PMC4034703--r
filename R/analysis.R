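#' One-sample t test from closed forms
#'
#' Classical one-sample t statistic `t = (mean − mu0) / (sd / sqrt(n))` with
#' a two-sided p value from the t distribution on `n − 1` degrees of
#' freedom.  Used to test probe-trial quadrant preferences against the
#' chance level 0.25.
#'
#' @param values Numeric vector, `n >= 2`, finite.
#' @param mu0 Reference constant.
#' @return List with `t`, `df`, `p`, `mean`, `n`.
#' @export
#' @examples
#' one_sample_t(c(1, 2, 3, 4, 5), 0)  # t = 4.243, df = 4
one_sample_t <- function(values, mu0 = 0) {
  stopifnot(is.numeric(values), all(is.finite(values)), length(values) >= 2)
  n <- length(values)
  m <- mean(values)
  s <- sd(values)
  if (s == 0) {
    if (m == mu0) stop("degenerate sample: zero variance with mean == mu0")
    warning("zero variance: p value degenerates to 0")
    return(list(t = sign(m - mu0) * Inf, df = n - 1, p = 0, mean = m, n = n))
  }
  t <- (m - mu0) / (s / sqrt(n))
  list(t = t, df = n - 1, p = 2 * pt(-abs(t), n - 1), mean = m, n = n)
}

#' Two-sample t test for independent groups
#'
#' Pooled-variance t by default (the classical independent-groups test);
#' Welch's unequal-variance form when `pooled = FALSE`.
#'
#' @param a,b Numeric vectors, each with at least 2 finite values.
#' @param pooled Logical; pooled-variance (default) or Welch.
#' @return List with `t`, `df`, `p`, `mean_a`, `mean_b`.
#' @export
#' @examples
#' two_sample_t(c(1, 2, 3), c(4, 5, 6))  # t = -3.674, df = 4
two_sample_t <- function(a, b, pooled = TRUE) {
  stopifnot(all(is.finite(a)), all(is.finite(b)),
            length(a) >= 2, length(b) >= 2)
  na <- length(a); nb <- length(b)
  va <- stats::var(a); vb <- stats::var(b)
  if (va == 0 && vb == 0) {
    if (mean(a) == mean(b)) stop("degenerate samples: both variances zero")
    warning("zero variance: p value degenerates to 0")
    return(list(t = sign(mean(a) - mean(b)) * Inf, df = na + nb - 2, p = 0,
                mean_a = mean(a), mean_b = mean(b)))
  }
  if (pooled) {
    sp2 <- ((na - 1) * va + (nb - 1) * vb) / (na + nb - 2)
    t <- (mean(a) - mean(b)) / sqrt(sp2 * (1 / na + 1 / nb))
    df <- na + nb - 2
  } else {
    se2 <- va / na + vb / nb
    t <- (mean(a) - mean(b)) / sqrt(se2)
    df <- se2^2 / ((va / na)^2 / (na - 1) + (vb / nb)^2 / (nb - 1))
  }
  list(t = t, df = df, p = 2 * pt(-abs(t), df), mean_a = mean(a),
       mean_b = mean(b))
}

#' Mixed-design (split-plot) analysis of variance
#'
#' Two-way mixed ANOVA with one between-subjects factor (e.g. group) and
#' one within-subjects factor (e.g. trial block), computed from closed-form
#' sums of squares on a balanced design.  The between-subjects effect is
#' tested against subjects-within-groups; the within effect and the
#' interaction against the block-by-subjects-within-groups residual.  This
#' is the group-by-repeated-block comparison used throughout the task's
#' cohort analysis.
#'
#' Every subject must contribute every block exactly once (the repeated
#' factor is balanced); group sizes need not be equal.
#'
#' @param data Data frame with one row per subject-by-block cell.
#' @param value,subject,between,within Column names.
#' @return A `vfgn_anova` data frame with one row per source: `effect`,
#'   `df`, `ss`, `ms`, `F`, `p`.
#' @export
mixed_anova <- function(data, value = "value", subject = "subject_id",
                        between = "group", within = "block") {
  y <- data[[value]]
  subj <- as.character(data[[subject]])
  grp <- as.character(data[[between]])
  blk <- as.character(data[[within]])
  stopifnot(is.numeric(y), all(is.finite(y)))

  # balance checks, naming offenders
  tab <- table(subj, blk)
  if (any(tab != 1)) {
    bad <- rownames(tab)[apply(tab != 1, 1, any)]
    stop("unbalanced design: subjects with missing or duplicated blocks: ",
         paste(bad, collapse = ", "))
  }
  subj_grp <- tapply(grp, subj, function(g) unique(g))
  if (any(lengths(subj_grp) != 1)) {
    stop("subjects assigned to more than one group: ",
         paste(names(subj_grp)[lengths(subj_grp) != 1], collapse = ", "))
  }
  subj_grp <- unlist(subj_grp)
  n_per_group <- table(subj_grp)
  if (any(n_per_group < 2)) stop("need at least 2 subjects per group")

  a <- length(unique(grp))   # groups
  N <- length(unique(subj))  # total subjects
  b <- length(unique(blk))   # blocks

  gm <- mean(y)
  m_g <- tapply(y, grp, mean)
  m_b <- tapply(y, blk, mean)
  m_s <- tapply(y, subj, mean)
  m_gb <- tapply(y, list(grp, blk), mean)
  n_g <- as.numeric(n_per_group[rownames(m_gb)])

  ss_total <- sum((y - gm)^2)
  ss_group <- b * sum(as.numeric(n_per_group[names(m_g)]) * (m_g - gm)^2)
  ss_subj <- b * sum((m_s - m_g[subj_grp[names(m_s)]])^2)
  ss_block <- N * sum((m_b - gm)^2)
  ss_gb <- sum(n_g * (sweep(sweep(m_gb, 1, m_g), 2, m_b) + gm)^2)
  ss_err <- ss_total - ss_group - ss_subj - ss_block - ss_gb
  ss_err <- max(0, ss_err)

  df <- c(group = a - 1, subjects = N - a, block = b - 1,
          interaction = (a - 1) * (b - 1), error = (N - a) * (b - 1))
  ss <- c(ss_group, ss_subj, ss_block, ss_gb, ss_err)
  ms <- ifelse(df > 0, ss / df, NA_real_)

  degenerate <- FALSE
  f_of <- function(num, den) {
    if (is.na(ms[den]) || ms[den] == 0) {
      if (ss[num] == 0) {
        degenerate <<- TRUE
        return(0)
      }
      return(Inf)
    }
    ms[num] / ms[den]
  }
  F_group <- f_of(1, 2)
  F_block <- f_of(3, 5)
  F_gb <- f_of(4, 5)
  if (degenerate) warning("all values equal: F undefined, reported as 0")
  p_of <- function(F, d1, d2) {
    if (!is.finite(F)) return(0)
    pf(F, d1, d2, lower.tail = FALSE)
  }

  out <- data.frame(
    effect = c(between, "subjects_within_groups", within,
               paste(between, within, sep = ":"), "residual"),
    df = unname(df), ss = ss, ms = ms,
    F = c(F_group, NA, F_block, F_gb, NA),
    p = c(p_of(F_group, df[1], df[2]), NA,
          p_of(F_block, df[3], df[5]), p_of(F_gb, df[4], df[5]), NA))
  class(out) <- c("vfgn_anova", "data.frame")
  out
}

#' @export
print.vfgn_anova <- function(x, ...) {
  cat("Mixed-design ANOVA\n")
  y <- x
  y$ss <- signif(y$ss, 6); y$ms <- signif(y$ms, 6)
  y$F <- signif(y$F, 4); y$p <- signif(y$p, 4)
  print.data.frame(y, row.names = FALSE)
  invisible(x)
}

#' Age correlation per group
#'
#' Pearson correlation between subject age and the subject-level mean of a
#' metric, computed separately within each group, with
#' `t = r * sqrt((n − 2) / (1 − r^2))` and a two-sided p value.
#'
#' @param table Cohort table from [run_cohort()].
#' @param metric Metric name.
#' @param blocks Optional block restriction before averaging.
#' @return Data frame with one row per group: `group`, `n`, `r`, `t`, `p`.
#' @export
age_correlation <- function(table, metric, blocks = NULL) {
  bm <- block_means(table, metric, blocks)
  per_subj <- aggregate(value ~ subject_id + group + age, data = bm,
                        FUN = mean)
  out <- lapply(split(per_subj, per_subj$group), function(d) {
    n <- nrow(d)
    if (n < 3) stop("need at least 3 subjects per group")
    if (sd(d$value) == 0) stop("metric is constant within group ",
                               d$group[1])
    r <- cor(d$age, d$value)
    t <- r * sqrt((n - 2) / (1 - r^2))
    data.frame(group = d$group[1], n = n, r = r, t = t,
               p = 2 * pt(-abs(t), n - 2))
  })
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}

#' Null calibration of the mixed-ANOVA group test
#'
#' Simulates cohorts in which both groups share one preset (so the group
#' null hypothesis is true by construction), runs the full pipeline --
#' reference-memory sessions, pointing-error block means, [mixed_anova()] --
#' and returns the fraction of replicates in which the group effect is
#' rejected at `alpha`.  A well-calibrated test rejects at about `alpha`.
#'
#' @param n_reps Number of simulated cohorts.
#' @param n_per_group Subjects per group in each replicate.
#' @param preset Preset name shared by both groups.
#' @param alpha Nominal significance level.
#' @param seed Integer seed, or `NULL`.
#' @param arena,kin Geometry and kinematics.
#' @return List with `rate` (rejection fraction), `n_reps` and the vector
#'   of per-replicate p values.
#' @export
null_rejection_rate <- function(n_reps = 1000, n_per_group = 10,
                                preset = "healthy_like", alpha = 0.05,
                                seed = NULL, arena = arena_spec(),
                                kin = kinematics()) {
  if (!is.null(seed)) set.seed(seed)
  pp <- preset_params(preset)
  std_idx <- c(2:5, 7:10)
  blocks <- rep(c("B1", "B2", "B3", "B4"), each = 2)
  pvals <- vapply(seq_len(n_reps), function(r) {
    cohort <- make_cohort(list(G1 = pp, G2 = pp), n_per_group)
    rows <- lapply(cohort, function(subj) {
      policy <- memory_navigator(subj$params, arena)
      session <- build_rm_session(arena)
      trajs <- run_session(session, policy, kin)
      pe <- vapply(trajs[std_idx], pointing_error, numeric(1))
      bm <- tapply(pe, blocks, mean)
      data.frame(subject_id = subj$subject_id, group = subj$group,
                 block = names(bm), value = as.numeric(bm))
    })
    an <- mixed_anova(do.call(rbind, rows))
    an$p[1]
  }, numeric(1))
  list(rate = mean(pvals < alpha), n_reps = n_reps, pvals = pvals)
}

#' Pairwise group comparisons with Holm correction
#'
#' All pairwise pooled-variance two-sample tests between groups on the
#' subject-level means of a metric, with Holm-adjusted p values.  Provided
#' as the post-hoc surface following a significant group effect.
#'
#' @param table Cohort table from [run_cohort()].
#' @param metric Metric name.
#' @param blocks Optional block restriction.
#' @return Data frame with one row per group pair.
#' @export
pairwise_groups <- function(table, metric, blocks = NULL) {
  bm <- block_means(table, metric, blocks)
  per_subj <- aggregate(value ~ subject_id + group, data = bm, FUN = mean)
  groups <- sort(unique(per_subj$group))
  pairs <- utils::combn(groups, 2, simplify = FALSE)
  rows <- lapply(pairs, function(p) {
    tt <- two_sample_t(per_subj$value[per_subj$group == p[1]],
                       per_subj$value[per_subj$group == p[2]])
    data.frame(group_a = p[1], group_b = p[2], t = tt$t, df = tt$df,
               p = tt$p)
  })
  res <- do.call(rbind, rows)
  res$p_holm <- stats::p.adjust(res$p, method = "holm")
  rownames(res) <- NULL
  res
}
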