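#' Cohort-level analysis of a metric table
#'
#' Runs the standard analysis battery on a cohort table: for the RM design,
#' mixed group-by-block ANOVAs on pointing error and path efficiency,
#' probe-trial tests (per-group one-sample t against the 0.25 chance level,
#' two-sample group comparison of quadrant preference and entrance count)
#' and per-group age correlations; for the DMP design, the group-by-round
#' ANOVA on pointing error across the last acquisition trials and the two
#' recall rounds, the recall-drop contrast per group, and the probe-phase
#' tests.
#'
#' @param table Cohort table from [run_cohort()] (or a CSV read back with
#'   the same columns).
#' @param design `"rm"` or `"dmp"`.
#' @return A named list of result objects, class `vfgn_analysis`.
#' @export
analyze_cohort <- function(table, design = c("rm", "dmp")) {
  design <- match.arg(design)
  table <- table[table$protocol == design, , drop = FALSE]
  if (nrow(table) == 0) stop("no rows for design ", design)
  groups <- sort(unique(table$group))
  out <- list(design = design, groups = groups)

  grp_vals <- function(d, g) d$value[d$group == g]

  if (design == "rm") {
    blocks <- c("B1", "B2", "B3", "B4")
    for (m in c("pointing_error", "path_efficiency")) {
      bm <- block_means(table, m, blocks)
      # subjects with an unscored block (e.g. goal never found in a pair of
      # trials) cannot enter the repeated-measures ANOVA
      complete <- names(which(table(bm$subject_id) == length(blocks)))
      dropped <- setdiff(unique(bm$subject_id), complete)
      bm <- bm[bm$subject_id %in% complete, , drop = FALSE]
      if (length(dropped) > 0) {
        message("dropping ", length(dropped),
                " subject(s) with incomplete blocks for ", m)
      }
      per_group <- table(unique(bm[c("subject_id", "group")])$group)
      if (length(per_group) == length(groups) && all(per_group >= 2)) {
        out[[paste0("anova_", m)]] <- mixed_anova(bm)
      }
      out[[paste0("blocks_", m)]] <-
        aggregate(value ~ group + block, bm, mean)
    }
    pr <- table[table$metric == "quadrant_preference", , drop = FALSE]
    out$probe_vs_chance <- lapply(stats::setNames(groups, groups),
                                  function(g) {
                                    one_sample_t(grp_vals(pr, g), 0.25)
                                  })
    if (length(groups) == 2) {
      out$probe_group_test <- two_sample_t(grp_vals(pr, groups[1]),
                                           grp_vals(pr, groups[2]))
      en <- table[table$metric == "entrances", , drop = FALSE]
      out$entrances_group_test <- two_sample_t(grp_vals(en, groups[1]),
                                               grp_vals(en, groups[2]))
    }
    out$age_pointing <- age_correlation(table, "pointing_error", blocks)
    out$age_path <- age_correlation(table, "path_efficiency", blocks)
  } else {
    dm <- table[table$metric == "pointing_error", , drop = FALSE]
    rounds <- c("acq3", "recall1", "recall2")
    dm$round <- ifelse(dm$block %in% c("A3", "B3", "C3"), "acq3",
                       ifelse(dm$block %in% c("recall1", "recall2"),
                              dm$block, NA))
    dm <- dm[!is.na(dm$round), , drop = FALSE]
    per <- aggregate(value ~ subject_id + group + round, dm, mean)
    names(per)[names(per) == "round"] <- "block"
    out$anova_recall <- mixed_anova(per)
    out$rounds_pointing <- aggregate(value ~ group + block, per, mean)
    wide <- stats::reshape(per, idvar = c("subject_id", "group"),
                           timevar = "block", direction = "wide")
    drop <- wide$value.recall1 - wide$value.acq3
    out$recall_drop <- lapply(stats::setNames(groups, groups), function(g) {
      d <- drop[wide$group == g]
      t <- mean(d) / (sd(d) / sqrt(length(d)))
      list(mean_drop = mean(d), t = t, df = length(d) - 1,
           p_one_sided = pt(t, length(d) - 1, lower.tail = FALSE))
    })
    pr <- table[table$metric == "quadrant_preference", , drop = FALSE]
    prs <- aggregate(value ~ subject_id + group, pr, mean)
    out$probe_vs_chance <- lapply(stats::setNames(groups, groups),
                                  function(g) {
                                    one_sample_t(grp_vals(prs, g), 0.25)
                                  })
    if (length(groups) == 2) {
      out$probe_group_test <- two_sample_t(grp_vals(prs, groups[1]),
                                           grp_vals(prs, groups[2]))
    }
  }
  class(out) <- "vfgn_analysis"
  out
}

fmt_t <- function(x) {
  sprintf("t(%.4g) = %.3f, p = %.4g", x$df, x$t, x$p)
}

#' Write a human-readable analysis report
#'
#' Emits a Markdown report, a tidy CSV of the ANOVA tables, and a
#' learning-curve plot into `dir`.
#'
#' @param res A `vfgn_analysis` from [analyze_cohort()].
#' @param dir Output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_analysis_report <- function(res, dir) {
  stopifnot(inherits(res, "vfgn_analysis"))
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  lines <- c(sprintf("# vFGN %s analysis", toupper(res$design)), "",
             sprintf("Groups: %s", paste(res$groups, collapse = ", ")), "")
  anovas <- list()
  for (nm in names(res)) {
    obj <- res[[nm]]
    if (inherits(obj, "vfgn_anova")) {
      anovas[[nm]] <- cbind(analysis = nm, obj)
      lines <- c(lines, sprintf("## %s", nm), "",
                 utils::capture.output(print(obj)), "")
    }
  }
  if (!is.null(res$probe_vs_chance)) {
    lines <- c(lines, "## Probe quadrant preference vs chance (0.25)", "")
    for (g in names(res$probe_vs_chance)) {
      x <- res$probe_vs_chance[[g]]
      lines <- c(lines, sprintf("- %s: mean %.3f, %s", g, x$mean, fmt_t(x)))
    }
    lines <- c(lines, "")
  }
  if (!is.null(res$probe_group_test)) {
    lines <- c(lines, sprintf("Group comparison of probe preference: %s",
                              fmt_t(res$probe_group_test)), "")
  }
  if (!is.null(res$recall_drop)) {
    lines <- c(lines, "## Recall-phase drop (first recall round - last acquisition)", "")
    for (g in names(res$recall_drop)) {
      x <- res$recall_drop[[g]]
      lines <- c(lines,
                 sprintf("- %s: %.2f deg, t(%d) = %.2f, one-sided p = %.4g",
                         g, x$mean_drop, x$df, x$t, x$p_one_sided))
    }
    lines <- c(lines, "")
  }
  writeLines(lines, file.path(dir, "report.md"))
  if (length(anovas) > 0) {
    write.csv(do.call(rbind, anovas), file.path(dir, "anova_tables.csv"),
              row.names = FALSE)
  }
  curves <- res$blocks_pointing_error
  if (is.null(curves)) curves <- res$rounds_pointing
  if (!is.null(curves)) {
    grDevices::png(file.path(dir, "learning_curve.png"), width = 720,
                   height = 480)
    plot_learning_curve(curves, ylab = "pointing error (deg)")
    grDevices::dev.off()
  }
  invisible(dir)
}

#' Plot group learning curves
#'
#' @param curves Data frame with columns `group`, `block`, `value` (group
#'   means per block, as produced inside [analyze_cohort()]).
#' @param ylab Y-axis label.
#' @return Invisibly, the matrix of plotted means.
#' @export
plot_learning_curve <- function(curves, ylab = "metric") {
  blocks <- sort(unique(curves$block))
  groups <- sort(unique(curves$group))
  mat <- sapply(groups, function(g) {
    v <- curves$value[curves$group == g]
    names(v) <- curves$block[curves$group == g]
    v[blocks]
  })
  graphics::matplot(seq_along(blocks), mat, type = "b", pch = 19, lty = 1,
                    xaxt = "n", xlab = "block", ylab = ylab,
                    ylim = c(0, max(mat) * 1.15))
  graphics::axis(1, at = seq_along(blocks), labels = blocks)
  graphics::legend("topright", legend = groups, col = seq_len(ncol(mat)),
                   pch = 19, lty = 1, bty = "n")
  invisible(mat)
}
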