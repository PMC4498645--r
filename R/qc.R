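EXCLUSION_REASONS <- c("none", "no_bm_rupture", "bleeding_g1",
                       "eye_excluded_g2", "choroidal_damage", "fused",
                       "outlier", "sole_survivor")

#' Grade a choroidal hemorrhage
#'
#' Grades bleeding severity by the ratio of the bleed's major axis to the
#' lesion diameter (LD): grade 0 when the axis is smaller than LD (the
#' lesion stays includable), grade 1 when it lies between one and two LD
#' (the lesion is excluded), grade 2 when it reaches two LD or more (the
#' whole eye is excluded). Band boundaries are closed upward: an axis
#' exactly equal to LD grades 1, exactly 2 LD grades 2 — conservative
#' toward exclusion. Vectorized; absence of bleeding (`axis = 0`) grades 0.
#'
#' @param lesion_diameter Lesion equivalent diameter, micrometers (> 0).
#' @param bleed_major_axis Bleed-region major axis, micrometers (>= 0).
#' @return Integer grade(s) in `{0, 1, 2}`.
#' @examples
#' grade_hemorrhage(100, c(80, 150, 250)) # 0 1 2
#' @export
grade_hemorrhage <- function(lesion_diameter, bleed_major_axis) {
  if (any(!is.finite(lesion_diameter)) || any(lesion_diameter <= 0)) {
    abort_input("lesion_diameter must be positive")
  }
  if (any(bleed_major_axis < 0)) {
    abort_input("bleed_major_axis must be >= 0")
  }
  ratio <- bleed_major_axis / lesion_diameter
  as.integer(findInterval(ratio, c(1, 2)))
}

#' Flag outlier lesions by the 5x-mean rule
#'
#' A lesion is an outlier when its area exceeds `factor` times the mean
#' area of the other lesions in scope (leave-one-out mean: comparing a
#' lesion against a mean that contains it would dilute the test).
#'
#' @param areas Lesion areas in scope, square micrometers.
#' @param factor Outlier multiplier; the field convention is 5.
#' @return Logical vector of flags, same length as `areas`.
#' @examples
#' flag_outliers(c(10000, 11000, 12000, 170000)) # only the last is flagged
#' @export
flag_outliers <- function(areas, factor = 5) {
  n <- length(areas)
  if (n < 2L) {
    warning("outlier rule needs at least 2 lesions in scope; none flagged")
    return(rep(FALSE, n))
  }
  loo_mean <- (sum(areas) - areas) / (n - 1)
  areas > factor * loo_mean
}

#' Apply the lesion/eye exclusion rules to one eye
#'
#' Applies the quality-control rules in a fixed order, the first firing
#' rule recording the exclusion reason:
#' \enumerate{
#'   \item failed Bruch's membrane rupture (`no_bm_rupture`);
#'   \item choroidal damage;
#'   \item fused lesions;
#'   \item any grade-2 hemorrhage in the eye excludes every lesion of the
#'     eye (`eye_excluded_g2`);
#'   \item grade-1 hemorrhage excludes that lesion (`bleeding_g1`);
#'   \item the 5x-mean outlier rule over the still-eligible lesions
#'     (scope `"eye"` by default, or the whole experimental condition via
#'     `condition_areas`);
#'   \item an eye whose only remaining eligible lesion stands alone loses
#'     it too (`sole_survivor`).
#' }
#' Structural exclusions run before the outlier rule so outlier means are
#' computed over structurally valid lesions; the sole-survivor rule runs
#' last. The function is idempotent and preserves input order.
#'
#' @param eye_lesions Data frame for one eye with columns `area_um2`,
#'   `grade` (hemorrhage grade 0/1/2), and logical `no_rupture`,
#'   `choroidal_damage`, `fused`. An `eye_id` column, if present, must be
#'   constant.
#' @param outlier_factor Multiplier for the outlier rule.
#' @param outlier_scope `"eye"` (default) or `"condition"`.
#' @param condition_areas With scope `"condition"`: areas of all eligible
#'   lesions under the same experimental condition, including this eye's.
#' @return `eye_lesions` with added logical `outlier`, `included` and
#'   character `exclusion_reason` columns.
#' @export
apply_exclusions <- function(eye_lesions, outlier_factor = 5,
                             outlier_scope = c("eye", "condition"),
                             condition_areas = NULL) {
  outlier_scope <- match.arg(outlier_scope)
  if (!is.null(eye_lesions$eye_id) &&
      length(unique(eye_lesions$eye_id)) > 1L) {
    abort_input("apply_exclusions expects lesions from a single eye")
  }
  if (outlier_factor <= 1) abort_input("outlier_factor must be > 1")
  n <- nrow(eye_lesions)
  reason <- rep("none", n)

  reason[eye_lesions$no_rupture] <- "no_bm_rupture"
  hit <- reason == "none" & eye_lesions$choroidal_damage
  reason[hit] <- "choroidal_damage"
  hit <- reason == "none" & eye_lesions$fused
  reason[hit] <- "fused"
  if (any(eye_lesions$grade == 2L & !eye_lesions$no_rupture)) {
    reason[reason == "none"] <- "eye_excluded_g2"
  }
  hit <- reason == "none" & eye_lesions$grade == 1L
  reason[hit] <- "bleeding_g1"

  eligible <- which(reason == "none")
  outlier <- rep(FALSE, n)
  if (length(eligible) >= 2L) {
    if (outlier_scope == "eye") {
      outlier[eligible] <- flag_outliers(eye_lesions$area_um2[eligible],
                                         outlier_factor)
    } else {
      if (is.null(condition_areas)) {
        abort_input("outlier_scope = 'condition' needs condition_areas")
      }
      pool_sum <- sum(condition_areas)
      pool_n <- length(condition_areas)
      if (pool_n >= 2L) {
        loo <- (pool_sum - eye_lesions$area_um2[eligible]) / (pool_n - 1)
        outlier[eligible] <- eye_lesions$area_um2[eligible] >
          outlier_factor * loo
      }
    }
    reason[outlier] <- "outlier"
  }

  if (sum(reason == "none") == 1L) {
    reason[reason == "none"] <- "sole_survivor"
  }

  eye_lesions$outlier <- outlier
  eye_lesions$included <- reason == "none"
  eye_lesions$exclusion_reason <- reason
  eye_lesions
}

#' Tabulate per-shot outcome categories by group
#'
#' Produces the study-level bookkeeping table: per group, counts and
#' percentages of shots that failed Bruch's membrane rupture, were
#' included, or were excluded for grade-1/2 bleeding (lesion- or
#' eye-level), choroidal damage, fusion, the 5x outlier rule, or as sole
#' survivors. Counts partition the total shots; percentages are
#' `100 * count / total_shots`, displayed at 3 significant figures.
#'
#' @param graded Data frame with `group` and `exclusion_reason` columns
#'   (one row per shot), e.g. pooled output of [apply_exclusions()].
#' @param eyes_per_mouse Eyes lasered per mouse, used to report the mouse
#'   count (`total_mice = number of eyes / eyes_per_mouse`, rounded up).
#' @return Data frame of class `lesion_type_tally`: one row per group with
#'   count columns and matching `pct_*` columns.
#' @export
tally_lesion_types <- function(graded, eyes_per_mouse = 2L) {
  groups <- unique(graded$group)
  rows <- lapply(groups, function(g) {
    sub <- graded[graded$group == g, , drop = FALSE]
    total <- nrow(sub)
    counts <- c(
      no_bm_rupture = sum(sub$exclusion_reason == "no_bm_rupture"),
      included = sum(sub$exclusion_reason == "none"),
      bleeding_g1_g2 = sum(sub$exclusion_reason %in%
                             c("bleeding_g1", "eye_excluded_g2")),
      choroidal_damage = sum(sub$exclusion_reason == "choroidal_damage"),
      fused = sum(sub$exclusion_reason == "fused"),
      outlier = sum(sub$exclusion_reason == "outlier"),
      sole_survivor = sum(sub$exclusion_reason == "sole_survivor")
    )
    n_eyes <- if (!is.null(sub$eye_id)) length(unique(sub$eye_id)) else NA
    pct <- if (total > 0) signif3(100 * counts / total) else rep(NA_real_, 7)
    out <- data.frame(group = g, total_shots = total,
                      total_mice = if (is.na(n_eyes)) NA_integer_ else
                        as.integer(ceiling(n_eyes / eyes_per_mouse)),
                      t(counts))
    out[paste0("pct_", names(counts))] <- as.list(pct)
    out
  })
  tally <- do.call(rbind, rows)
  rownames(tally) <- NULL
  class(tally) <- c("lesion_type_tally", "data.frame")
  tally
}
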