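#' Published calibration statistics for laser-induced CNV lesion areas
#'
#' Group-level lesion-area statistics from a published calibration study of
#' the image-guided laser CNV model in C57BL/6J mice: four laser power
#' levels (532 nm, 70 ms, 50 um spot; day-7 flat-mount quantification),
#' four age-by-sex strata, and an omega-6 vs omega-3 dietary comparison.
#' These numbers are the targets the synthetic-data generator is
#' moment-matched to, and the inputs for relative-area arithmetic checks.
#'
#' The dispersion column `sd_area_um2` is the group standard deviation; the
#' standard error `sem_area_um2` equals `sd_area_um2 / sqrt(n_lesions)`.
#' `pct_of_reference` is the published mean relative to the study's
#' reference group (240 mW, 6-8 week males, and omega-6 feed respectively),
#' displayed at 3 significant figures.
#'
#' @param study One of `"power"`, `"age_sex"`, `"diet"`, or `"all"`.
#' @return A data frame with columns `study`, `group`, `n_lesions`,
#'   `mean_area_um2`, `sd_area_um2`, `sem_area_um2`, `pct_of_reference`,
#'   `is_reference`.
#' @export
cnv_reference_areas <- function(study = c("all", "power", "age_sex", "diet")) {
  study <- match.arg(study)
  df <- data.frame(
    study = c(rep("power", 4L), rep("age_sex", 4L), rep("diet", 2L)),
    group = c("180mW", "240mW", "300mW", "360mW",
              "6-8wk_female", "6-8wk_male", "12-16wk_female", "12-16wk_male",
              "omega6", "omega3"),
    n_lesions = c(46L, 75L, 63L, 49L, 67L, 58L, 66L, 60L, 110L, 105L),
    mean_area_um2 = c(17627.4, 30433.0, 47067.9, 76326.2,
                      33202.5, 29445.4, 71770.9, 52104.9,
                      38893.5, 28960.5),
    sd_area_um2 = c(12582.2, 20368.9, 28330.5, 31594.9,
                    10835.0, 13059.7, 35599.2, 26895.8,
                    18796.5, 11896.3),
    sem_area_um2 = c(1855.14, 2352.00, 3569.30, 4513.55,
                     1323.70, 1714.82, 4381.96, 3472.23,
                     1792.17, 1160.96),
    pct_of_reference = c(57.9, 100, 155, 251,
                         113, 100, 244, 177,
                         100, 74.5),
    is_reference = c(FALSE, TRUE, FALSE, FALSE,
                     FALSE, TRUE, FALSE, FALSE,
                     TRUE, FALSE),
    stringsAsFactors = FALSE
  )
  if (study != "all") df <- df[df$study == study, , drop = FALSE]
  rownames(df) <- NULL
  df
}

#' Published per-shot outcome counts by laser power
#'
#' Counts of per-shot outcome categories from the same calibration study:
#' for each laser power level, how many of the total shots failed to
#' rupture Bruch's membrane, were included, or were excluded for grade-1/2
#' bleeding, choroidal damage, lesion fusion, or the 5x-mean outlier rule.
#'
#' @return A data frame with one row per power level and columns `group`,
#'   `total_shots`, `total_mice`, `no_bm_rupture`, `included`,
#'   `bleeding_g1_g2`, `choroidal_damage`, `fused`, `outlier`.
#' @export
cnv_reference_outcomes <- function() {
  data.frame(
    group = c("180mW", "240mW", "300mW", "360mW"),
    total_shots = c(72L, 80L, 76L, 76L),
    total_mice = c(10L, 10L, 10L, 10L),
    no_bm_rupture = c(20L, 2L, 1L, 0L),
    included = c(46L, 75L, 63L, 49L),
    bleeding_g1_g2 = c(0L, 1L, 5L, 14L),
    choroidal_damage = c(0L, 0L, 2L, 5L),
    fused = c(0L, 0L, 2L, 4L),
    outlier = c(6L, 2L, 3L, 4L),
    stringsAsFactors = FALSE
  )
}

#' Default simulation groups calibrated to the published statistics
#'
#' Builds [group_params()] objects whose area moments match
#' [cnv_reference_areas()] and, for the power study, whose complication
#' probabilities match the outcome frequencies in
#' [cnv_reference_outcomes()]. Published counts pool grade-1 and grade-2
#' bleeding; the split defaults to 3:1 in favour of grade 1, since eye-wide
#' grade-2 events are the rarer, more severe outcome. A small probability
#' of cosmetic grade-0 bleeding (included lesions) is added so the grading
#' path is exercised.
#'
#' @param study `"power"`, `"age_sex"` or `"diet"`.
#' @param p_bleed_g0 Probability of grade-0 (includable) bleeding.
#' @return Named list of `group_params`, in reference-table order.
#' @export
reference_groups <- function(study = c("power", "age_sex", "diet"),
                             p_bleed_g0 = 0.05) {
  study <- match.arg(study)
  areas <- cnv_reference_areas(study)
  out <- cnv_reference_outcomes()
  groups <- lapply(seq_len(nrow(areas)), function(i) {
    g <- areas[i, ]
    if (study == "power") {
      o <- out[out$group == g$group, ]
      p_bleed <- o$bleeding_g1_g2 / o$total_shots
      group_params(
        label = g$group,
        mean_area = g$mean_area_um2,
        sd_area = g$sd_area_um2,
        p_no_rupture = o$no_bm_rupture / o$total_shots,
        p_bleed_g0 = p_bleed_g0,
        p_bleed_g1 = 0.75 * p_bleed,
        p_bleed_g2 = 0.25 * p_bleed,
        p_damage = o$choroidal_damage / o$total_shots,
        p_fused = o$fused / o$total_shots,
        p_outlier = o$outlier / o$total_shots
      )
    } else {
      # complication frequencies were only published for the power study;
      # other studies default to the 240 mW-like low-complication profile
      group_params(
        label = g$group,
        mean_area = g$mean_area_um2,
        sd_area = g$sd_area_um2,
        p_no_rupture = 0.025,
        p_bleed_g0 = p_bleed_g0,
        p_outlier = 0.025
      )
    }
  })
  names(groups) <- areas$group
  groups
}

#' Expand published outcome counts into a per-shot QC fixture
#'
#' Converts the per-group outcome counts of [cnv_reference_outcomes()]
#' (or any table with the same columns) into a per-shot table of QC flags
#' and hemorrhage grades, arranged into eyes of 4 shots such that running
#' [apply_exclusions()] on every eye reproduces the counts exactly:
#' full or partial failed-rupture eyes, grade-2 eyes (4 bleeding shots
#' each) plus single grade-1 shots, damage split at most 2 per eye so no
#' eye collapses to a sole survivor, fused pairs, and one 5x outlier per
#' affected eye. All regular lesions share one area so the outlier rule
#' fires only where intended.
#'
#' @param outcomes Data frame as returned by [cnv_reference_outcomes()].
#' @param base_area Area given to regular lesions, square micrometers.
#' @return Per-shot data frame with columns `group`, `eye_id`, `site`,
#'   `area_um2`, `grade`, `no_rupture`, `choroidal_damage`, `fused`.
#' @export
reference_outcome_shots <- function(outcomes = cnv_reference_outcomes(),
                                    base_area = 10000) {
  one_group <- function(o) {
    eyes <- list()
    add_eye <- function(no_rupture = 0L, g1 = 0L, g2 = FALSE, damage = 0L,
                        fused = FALSE, outlier = FALSE) {
      stopifnot(no_rupture + g1 + damage <= 4L)
      df <- data.frame(site = 0:3, area_um2 = base_area, grade = 0L,
                       no_rupture = FALSE, choroidal_damage = FALSE,
                       fused = FALSE)
      slot <- 1L
      take <- function(k) { s <- seq_len(k) + slot - 1L; slot <<- slot + k; s }
      if (no_rupture > 0L) {
        i <- take(no_rupture); df$no_rupture[i] <- TRUE; df$area_um2[i] <- 0
      }
      if (g2) df$grade[take(1L)] <- 2L
      if (g1 > 0L) df$grade[take(g1)] <- 1L
      if (damage > 0L) df$choroidal_damage[take(damage)] <- TRUE
      if (fused) df$fused[take(2L)] <- TRUE
      if (outlier) df$area_um2[take(1L)] <- 17 * base_area
      eyes[[length(eyes) + 1L]] <<- df
    }
    n0 <- o$no_bm_rupture
    while (n0 >= 4L) { add_eye(no_rupture = 4L); n0 <- n0 - 4L }
    if (n0 == 3L) { add_eye(no_rupture = 2L); n0 <- 1L }
    if (n0 > 0L) add_eye(no_rupture = n0)
    b <- o$bleeding_g1_g2
    while (b >= 4L) { add_eye(g2 = TRUE); b <- b - 4L }
    while (b > 0L) { add_eye(g1 = 1L); b <- b - 1L }
    d <- o$choroidal_damage
    while (d > 0L) { k <- min(d, 2L); add_eye(damage = k); d <- d - k }
    f <- o$fused
    stopifnot(f %% 2L == 0L)
    while (f > 0L) { add_eye(fused = TRUE); f <- f - 2L }
    for (i in seq_len(o$outlier)) add_eye(outlier = TRUE)
    used <- 4L * length(eyes)
    stopifnot((o$total_shots - used) %% 4L == 0L)
    for (i in seq_len((o$total_shots - used) / 4L)) add_eye()
    for (i in seq_along(eyes)) {
      eyes[[i]] <- cbind(group = o$group,
                         eye_id = sprintf("%s_f%02d", o$group, i), eyes[[i]])
    }
    do.call(rbind, eyes)
  }
  shots <- do.call(rbind, lapply(seq_len(nrow(outcomes)),
                                 function(i) one_group(outcomes[i, ])))
  rownames(shots) <- NULL
  shots
}
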