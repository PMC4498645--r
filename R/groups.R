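#' Group-level simulation parameters
#'
#' Bundles the lesion-area moments and per-shot complication probabilities
#' that define one experimental group (a laser power level, an age/sex
#' stratum, or a dietary arm). Areas are simulated from a log-normal whose
#' parameters are moment-matched to `mean_area`/`sd_area`; complications
#' are drawn per shot from the stated probabilities, with the remainder
#' producing an ordinary includable lesion.
#'
#' @param label Group label (e.g. `"240mW"`).
#' @param mean_area Target mean lesion area, square micrometers.
#' @param sd_area Target lesion-area standard deviation, square micrometers
#'   (0 gives a degenerate distribution at `mean_area`).
#' @param p_no_rupture Probability a shot fails to rupture Bruch's membrane
#'   (no lesion develops).
#' @param p_bleed_g0 Probability of a minor hemorrhage (bleed major axis
#'   smaller than the lesion diameter; the lesion stays includable).
#' @param p_bleed_g1 Probability of a grade-1 hemorrhage (axis between one
#'   and two lesion diameters).
#' @param p_bleed_g2 Probability of a grade-2 hemorrhage (axis above two
#'   lesion diameters; excludes the whole eye).
#' @param p_damage Probability of excessive burn with choroidal damage
#'   (a dark "hole" in the bright-field channel).
#' @param p_fused Probability a shot initiates a fused lesion pair with its
#'   clockwise neighbour.
#' @param p_outlier Probability of an outlier lesion, drawn uniformly
#'   between 5 and 8 times the group mean area.
#' @return An object of class `group_params`.
#' @export
group_params <- function(label,
                         mean_area,
                         sd_area,
                         p_no_rupture = 0,
                         p_bleed_g0 = 0,
                         p_bleed_g1 = 0,
                         p_bleed_g2 = 0,
                         p_damage = 0,
                         p_fused = 0,
                         p_outlier = 0) {
  p <- c(p_no_rupture = p_no_rupture, p_bleed_g0 = p_bleed_g0,
         p_bleed_g1 = p_bleed_g1, p_bleed_g2 = p_bleed_g2,
         p_damage = p_damage, p_fused = p_fused, p_outlier = p_outlier)
  if (any(p < 0 | p > 1)) {
    abort_input("complication probabilities must lie in [0, 1]")
  }
  if (sum(p) > 1 + 1e-12) {
    abort_input("complication probabilities sum to more than 1")
  }
  if (!is.numeric(mean_area) || mean_area <= 0) {
    abort_input("mean_area must be > 0")
  }
  if (!is.numeric(sd_area) || sd_area < 0) {
    abort_input("sd_area must be >= 0")
  }
  structure(
    c(list(label = as.character(label), mean_area = mean_area,
           sd_area = sd_area), as.list(p)),
    class = "group_params"
  )
}

#' @export
print.group_params <- function(x, ...) {
  cat("Group '", x$label, "': area ", x$mean_area, " +/- ", x$sd_area,
      " um^2\n", sep = "")
  p <- unlist(x[startsWith(names(x), "p_")])
  cat("  per-shot complication probabilities:\n")
  print(p)
  invisible(x)
}

# Log-normal meanlog/sdlog matched to an arithmetic mean and SD.
lognormal_match <- function(mean_area, sd_area) {
  if (mean_area <= 0) abort_input("cannot moment-match: mean_area <= 0")
  cv2 <- (sd_area / mean_area)^2
  sdlog <- sqrt(log(1 + cv2))
  meanlog <- log(mean_area) - sdlog^2 / 2
  list(meanlog = meanlog, sdlog = sdlog)
}
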