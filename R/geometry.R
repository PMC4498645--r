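#' Eye geometry for laser burn placement
#'
#' Describes one synthetic eye: image canvas, optic-nerve (disc) center,
#' disc diameter, pixel calibration and the four burn-site coordinates.
#' Burns are placed on a circle of radius twice the disc diameter around
#' the optic nerve, at the 12, 3, 6 and 9 o'clock positions, which keeps
#' every pair of sites at least two disc diameters apart so lesions of
#' typical size do not fuse.
#'
#' @param image_size Integer vector `c(rows, cols)` of the image canvas.
#' @param on_center Optic-nerve center as `c(row, col)`, 0-based pixels;
#'   defaults to the canvas center.
#' @param disc_diameter Optic disc diameter in pixels.
#' @param pixel_scale Calibration in micrometers per pixel.
#' @param jitter_deg Half-width of uniform angular jitter (degrees) applied
#'   to each site around its clock position; 0 gives the exact circle
#'   geometry. Uses the current RNG state, so seed before calling for
#'   reproducible layouts.
#' @param margin Free pixels required between any site and the image border
#'   (room for the lesion footprint).
#' @return An object of class `eye_geometry`: a list with the fields above
#'   plus `burn_sites`, a 4x2 matrix of 0-based `(row, col)` coordinates.
#' @examples
#' g <- layout_burn_sites(image_size = c(512, 512), disc_diameter = 40,
#'                        pixel_scale = 1, jitter_deg = 0, margin = 10)
#' g$burn_sites
#' @export
layout_burn_sites <- function(image_size = c(1024L, 1024L),
                              on_center = (image_size - 1) / 2,
                              disc_diameter = 135,
                              pixel_scale = 1.5,
                              jitter_deg = 0,
                              margin = 64) {
  stopifnot(length(image_size) == 2L, all(image_size > 0),
            length(on_center) == 2L)
  if (disc_diameter <= 0) abort_input("disc_diameter must be > 0")
  if (pixel_scale <= 0) abort_input("pixel_scale must be > 0")

  radius <- 2 * disc_diameter
  theta <- c(0, 90, 180, 270) # 12, 3, 6, 9 o'clock
  if (jitter_deg > 0) {
    if (jitter_deg >= 35) {
      abort_input("jitter_deg >= 35 cannot guarantee pairwise site ",
                  "separation of two disc diameters")
    }
    theta <- theta + runif(4L, -jitter_deg, jitter_deg)
  }
  rad <- theta * pi / 180
  sites <- cbind(row = on_center[1] + radius * sin(rad),
                 col = on_center[2] + radius * cos(rad))

  if (any(sites < margin) ||
      any(sites[, 1] > image_size[1] - 1 - margin) ||
      any(sites[, 2] > image_size[2] - 1 - margin)) {
    abort_input("image too small to contain burn sites with margin ",
                margin, " px")
  }
  d <- as.matrix(dist(sites))
  if (min(d[upper.tri(d)]) < 2 * disc_diameter - 1e-9) {
    abort_input("burn sites closer than two disc diameters")
  }

  structure(
    list(image_size = as.integer(image_size),
         on_center = as.numeric(on_center),
         disc_diameter = disc_diameter,
         pixel_scale = pixel_scale,
         burn_sites = sites),
    class = "eye_geometry"
  )
}

#' @export
print.eye_geometry <- function(x, ...) {
  cat("Eye geometry:", x$image_size[1], "x", x$image_size[2], "px,",
      x$pixel_scale, "um/px\n")
  cat("  optic nerve at (", paste(round(x$on_center, 1), collapse = ", "),
      "), disc diameter ", x$disc_diameter, " px\n", sep = "")
  cat("  burn sites (row, col):\n")
  print(round(x$burn_sites, 1))
  invisible(x)
}
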