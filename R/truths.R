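LESION_CATEGORIES <- c("no_rupture", "normal", "bleed_g0", "bleed_g1",
                       "bleed_g2", "choroidal_damage", "fused", "outlier")

#' Sample ground-truth lesion records for a group of synthetic eyes
#'
#' Draws per-shot outcome categories and lesion areas for `n_eyes` eyes
#' with 4 burn sites each. Areas come from a log-normal moment-matched to
#' the group's `mean_area`/`sd_area`; outlier lesions are drawn uniformly
#' between 5 and 8 times the group mean so the downstream 5x exclusion
#' rule must fire; failed ruptures have area 0. Bleeding categories carry
#' a bleed major axis placed inside the corresponding grade band relative
#' to the lesion's equivalent diameter. Lesion fusion is drawn as an
#' eye-level event (probability `2 * p_fused`) that marks one random
#' adjacent site pair as fused, so the marginal per-shot fused frequency
#' equals `p_fused` while fused lesions always occur in renderable pairs.
#'
#' Each eye uses a deterministic substream derived from `(seed, eye
#' index)`, so studies are bit-reproducible and insensitive to eye order.
#'
#' @param group A [group_params()] object.
#' @param n_eyes Number of eyes (4 truths per eye).
#' @param seed Integer study seed.
#' @param leak_increment Fluorescein leakage increment (intensity units)
#'   rendered between the 5- and 10-minute angiography frames for each
#'   developed lesion; 0 for failed ruptures.
#' @param damage_shrink Multiplier applied to the drawn area of
#'   choroidal-damage lesions (excessive burns yield lesions smaller than
#'   their fellows).
#' @return A data frame of class `lesion_truth` with columns `eye_id`,
#'   `site`, `category`, `true_area_um2`, `bleed_major_axis_um`,
#'   `leak_increment`.
#' @export
sample_lesion_truths <- function(group, n_eyes, seed = 1L,
                                 leak_increment = 25,
                                 damage_shrink = 0.4) {
  stopifnot(inherits(group, "group_params"))
  if (n_eyes < 1) abort_input("n_eyes must be >= 1")
  lm <- lognormal_match(group$mean_area, group$sd_area)
  if (group$p_fused > 0.5) {
    abort_input("p_fused > 0.5 cannot be realized by adjacent-pair fusion")
  }

  # per-shot categories other than fused, conditioned on not-fused
  other <- c(no_rupture = group$p_no_rupture, bleed_g0 = group$p_bleed_g0,
             bleed_g1 = group$p_bleed_g1, bleed_g2 = group$p_bleed_g2,
             choroidal_damage = group$p_damage, outlier = group$p_outlier)
  p_normal <- 1 - sum(other) - group$p_fused
  if (p_normal < -1e-12) {
    abort_input("complication probabilities leave no mass for normal lesions")
  }
  probs <- c(other, normal = max(p_normal, 0)) / (1 - group$p_fused)

  rows <- vector("list", n_eyes)
  for (i in seq_len(n_eyes)) {
    set.seed(eye_seed(seed, i))
    eye_id <- sprintf("%s_e%03d", group$label, i)
    category <- rep(NA_character_, 4L)
    if (runif(1L) < 2 * group$p_fused) {
      first <- sample.int(4L, 1L) - 1L
      category[c(first, (first + 1L) %% 4L) + 1L] <- "fused"
    }
    free <- which(is.na(category))
    category[free] <- sample(names(probs), length(free),
                             replace = TRUE, prob = probs)

    area <- if (group$sd_area == 0) {
      rep(group$mean_area, 4L)
    } else {
      rlnorm(4L, lm$meanlog, lm$sdlog)
    }
    area[category == "no_rupture"] <- 0
    is_out <- category == "outlier"
    area[is_out] <- runif(sum(is_out), 5, 8) * group$mean_area
    is_dmg <- category == "choroidal_damage"
    area[is_dmg] <- area[is_dmg] * damage_shrink

    eq_d <- 2 * sqrt(area / pi)
    axis <- numeric(4L)
    g0 <- category == "bleed_g0"
    g1 <- category == "bleed_g1"
    g2 <- category == "bleed_g2"
    axis[g0] <- runif(sum(g0), 0.3, 0.9) * eq_d[g0]
    axis[g1] <- runif(sum(g1), 1.05, 1.90) * eq_d[g1]
    axis[g2] <- runif(sum(g2), 2.10, 3.00) * eq_d[g2]

    leak <- ifelse(area > 0, leak_increment, 0)
    rows[[i]] <- data.frame(
      eye_id = eye_id, site = 0:3, category = category,
      true_area_um2 = area, bleed_major_axis_um = axis,
      leak_increment = leak, stringsAsFactors = FALSE
    )
  }
  truths <- do.call(rbind, rows)
  rownames(truths) <- NULL
  class(truths) <- c("lesion_truth", "data.frame")
  truths
}

#' Write / read a ground-truth table
#'
#' The truth table is a plain CSV with one row per burn site; when a
#' geometry is supplied it is written alongside as
#' `<path>.geometry.yaml` so a study can be reconstructed from disk.
#' `read_truth()` round-trips the table losslessly.
#'
#' @param truths A `lesion_truth` data frame.
#' @param path Output CSV path.
#' @param geometry Optional [layout_burn_sites()] geometry to persist.
#' @return `path`, invisibly (`write_truth`); the truth data frame
#'   (`read_truth`).
#' @export
write_truth <- function(truths, path, geometry = NULL) {
  utils::write.csv(as.data.frame(truths), path, row.names = FALSE)
  if (!is.null(geometry)) {
    yaml::write_yaml(
      list(image_size = as.integer(geometry$image_size),
           on_center = as.numeric(geometry$on_center),
           disc_diameter = geometry$disc_diameter,
           pixel_scale = geometry$pixel_scale,
           burn_sites = apply(geometry$burn_sites, 1, as.numeric,
                              simplify = FALSE)),
      paste0(path, ".geometry.yaml")
    )
  }
  invisible(path)
}

#' @rdname write_truth
#' @export
read_truth <- function(path) {
  truths <- utils::read.csv(path, stringsAsFactors = FALSE,
                            colClasses = c(eye_id = "character"))
  class(truths) <- c("lesion_truth", "data.frame")
  truths
}
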