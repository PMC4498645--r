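#' Summarize lesion areas for one group
#'
#' Mean, sample standard deviation (n - 1 denominator) and standard error
#' of the mean (`sem = sd / sqrt(n)`), the form in which group results are
#' reported (mean +/- SEM).
#'
#' @param areas Lesion areas, square micrometers (n >= 2).
#' @param label Group label.
#' @return One-row data frame of class `group_summary` with `group`, `n`,
#'   `mean`, `sd`, `sem`.
#' @export
summarize_group <- function(areas, label = "group") {
  areas <- areas[is.finite(areas)]
  if (length(areas) < 2L) {
    abort_input("group summary needs at least 2 lesions (dispersion undefined)")
  }
  n <- length(areas)
  s <- sd(areas)
  structure(
    data.frame(group = label, n = n, mean = mean(areas), sd = s,
               sem = s / sqrt(n), stringsAsFactors = FALSE),
    class = c("group_summary", "data.frame")
  )
}

#' Group mean as a percentage of a reference group's mean
#'
#' @param summary,reference_summary [summarize_group()] rows (or any list
#'   with a `mean` field).
#' @return `100 * mean / reference mean`, displayed at 3 significant
#'   figures by convention (use [signif()] for display).
#' @examples
#' percent_relative(list(mean = 17627.4), list(mean = 30433.0)) # 57.92...
#' @export
percent_relative <- function(summary, reference_summary) {
  ref <- reference_summary$mean
  if (!is.finite(ref) || ref <= 0) {
    abort_input("reference mean must be positive")
  }
  100 * summary$mean / ref
}

#' Compare two groups of lesion areas
#'
#' Two-sided t test at alpha = 0.05. The default is the unequal-variance
#' (Welch) form — robust when group spreads differ, as they do across
#' laser powers; the classic pooled Student form is available via
#' `var_equal = TRUE`.
#'
#' @param areas_a,areas_b Lesion areas per group (each n >= 2, non-zero
#'   spread in at least one group).
#' @param labels Character vector of length 2 naming the groups.
#' @param var_equal Use the pooled-variance form?
#' @param alpha Significance level.
#' @return Data frame of class `comparison_result` with `comparison`,
#'   `test`, `statistic`, `p_value`, `significant`.
#' @export
compare_two <- function(areas_a, areas_b, labels = c("a", "b"),
                        var_equal = FALSE, alpha = 0.05) {
  if (length(areas_a) < 2L || length(areas_b) < 2L) {
    abort_input("each group needs at least 2 lesions")
  }
  if (sd(areas_a) == 0 && sd(areas_b) == 0) {
    abort_input("both groups are constant; t test undefined")
  }
  tt <- t.test(areas_a, areas_b, var.equal = var_equal)
  structure(
    data.frame(comparison = paste(labels, collapse = " vs "),
               test = if (var_equal) "t_pooled" else "t_welch",
               statistic = unname(tt$statistic),
               p_value = tt$p.value,
               significant = tt$p.value <= alpha,
               stringsAsFactors = FALSE),
    class = c("comparison_result", "data.frame")
  )
}

#' Compare three or more groups by one-way ANOVA
#'
#' Classic one-way fixed-effects ANOVA (equal-variance F test) across all
#' groups. With exactly two groups, use [compare_two()].
#'
#' @param groups Named list of numeric vectors of lesion areas.
#' @param alpha Significance level.
#' @return Data frame of class `comparison_result` (statistic is the
#'   ANOVA F).
#' @export
compare_many <- function(groups, alpha = 0.05) {
  if (length(groups) < 3L) {
    abort_input("compare_many needs >= 3 groups; use compare_two for 2")
  }
  if (any(lengths(groups) < 2L)) {
    abort_input("each group needs at least 2 lesions")
  }
  if (is.null(names(groups))) names(groups) <- seq_along(groups)
  values <- unlist(groups, use.names = FALSE)
  fac <- factor(rep(names(groups), lengths(groups)))
  ow <- oneway.test(values ~ fac, var.equal = TRUE)
  structure(
    data.frame(comparison = paste(names(groups), collapse = " vs "),
               test = "anova_oneway",
               statistic = unname(ow$statistic),
               p_value = ow$p.value,
               significant = ow$p.value <= alpha,
               stringsAsFactors = FALSE),
    class = c("comparison_result", "data.frame")
  )
}

fmt3 <- function(x) format(signif3(x), trim = TRUE, scientific = FALSE)

#' Write the study report
#'
#' Emits machine-readable CSVs (`tally.csv`, `group_summary.csv`,
#' `comparisons.csv`, `leakage.csv`) plus a human-readable
#' `report.md` in which percentages and ratios are displayed at 3
#' significant figures and area means at 1 decimal. Output is
#' deterministic: identical inputs give byte-identical files.
#'
#' @param tallies A [tally_lesion_types()] data frame, or `NULL`.
#' @param summaries Data frame of stacked [summarize_group()] rows.
#' @param comparisons Data frame of stacked comparison rows, or `NULL`.
#' @param leakage_records Leakage data frame, or `NULL`.
#' @param out_dir Output directory (created if missing).
#' @param reference Label of the reference group for the relative-area
#'   column; defaults to the first summary row.
#' @return Paths of the written files, invisibly.
#' @export
build_report <- function(tallies = NULL, summaries, comparisons = NULL,
                         leakage_records = NULL, out_dir,
                         reference = summaries$group[1]) {
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  paths <- character(0)

  ref_row <- summaries[summaries$group == reference, , drop = FALSE]
  if (nrow(ref_row) != 1L) abort_input("reference group not found: ", reference)
  summaries$pct_of_reference <- signif3(
    vapply(seq_len(nrow(summaries)),
           function(i) percent_relative(summaries[i, ], ref_row), numeric(1)))

  wr <- function(df, name) {
    p <- file.path(out_dir, name)
    utils::write.csv(df, p, row.names = FALSE)
    p
  }
  paths <- c(paths, wr(summaries, "group_summary.csv"))
  if (!is.null(tallies)) paths <- c(paths, wr(tallies, "tally.csv"))
  if (!is.null(comparisons) && nrow(comparisons)) {
    paths <- c(paths, wr(comparisons, "comparisons.csv"))
  }
  if (!is.null(leakage_records) && nrow(leakage_records)) {
    paths <- c(paths, wr(leakage_records, "leakage.csv"))
  }

  md <- c("# CNV lesion study report", "",
          "## Group summaries (areas in um^2, mean +/- SEM)", "")
  for (i in seq_len(nrow(summaries))) {
    s <- summaries[i, ]
    md <- c(md, sprintf("- %s: n = %d, mean = %.1f +/- %.1f (SD %.1f), %s%% of %s",
                        s$group, s$n, s$mean, s$sem, s$sd,
                        fmt3(s$pct_of_reference), reference))
  }
  if (!is.null(tallies)) {
    md <- c(md, "", "## Per-shot outcomes", "")
    for (i in seq_len(nrow(tallies))) {
      t <- tallies[i, ]
      md <- c(md, sprintf(
        "- %s: %d shots, included %d (%s%%), no rupture %d (%s%%), bleeding %d (%s%%), damage %d (%s%%), fused %d (%s%%), outlier %d (%s%%)",
        t$group, t$total_shots, t$included, fmt3(t$pct_included),
        t$no_bm_rupture, fmt3(t$pct_no_bm_rupture),
        t$bleeding_g1_g2, fmt3(t$pct_bleeding_g1_g2),
        t$choroidal_damage, fmt3(t$pct_choroidal_damage),
        t$fused, fmt3(t$pct_fused), t$outlier, fmt3(t$pct_outlier)))
    }
  }
  if (!is.null(comparisons) && nrow(comparisons)) {
    md <- c(md, "", "## Comparisons (alpha = 0.05)", "")
    for (i in seq_len(nrow(comparisons))) {
      cmp <- comparisons[i, ]
      md <- c(md, sprintf("- %s [%s]: statistic = %s, p = %s%s",
                          cmp$comparison, cmp$test, fmt3(cmp$statistic),
                          format(signif3(cmp$p_value)),
                          if (cmp$significant) " *" else ""))
    }
  }
  if (!is.null(leakage_records) && nrow(leakage_records)) {
    md <- c(md, "", "## FFA leakage (mean 10-5 min intensity difference)", "",
            sprintf("- lesions measured: %d, mean delta = %s",
                    nrow(leakage_records),
                    fmt3(mean(leakage_records$delta_intensity))))
  }
  p <- file.path(out_dir, "report.md")
  writeLines(md, p)
  invisible(c(paths, p))
}
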