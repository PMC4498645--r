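#' Rendering parameters for synthetic flat-mount and angiography images
#'
#' Intensities are on the 8-bit (0-255) scale by default. The three
#' bright-field intensity levels are deliberately well separated: the
#' background is bright, hemorrhage regions mid-dark, and choroidal-damage
#' "holes" near black, so the bleed detector (band
#' `(damage_darkness_threshold, bleed_threshold]`) and the damage detector
#' (`<= damage_darkness_threshold`) see disjoint pixel sets.
#'
#' @param bg_fluor,fg_fluor Background / lesion intensity on the
#'   IB4-fluorescence channel.
#' @param bg_bright Bright-field background intensity.
#' @param bleed_intensity Bright-field intensity inside hemorrhage regions.
#' @param hole_intensity Bright-field intensity inside damage holes.
#' @param ffa_bg,ffa_lesion Baseline 5-minute angiography background and
#'   lesion intensities.
#' @param noise_sd Gaussian pixel noise standard deviation (0 = noiseless).
#' @param bits Image bit depth (8 or 16).
#' @param hole_scale Damage-hole diameter as a multiple of the lesion's
#'   equivalent diameter.
#' @param bleed_aspect Minor/major axis ratio of rendered bleed ellipses.
#' @return A list of class `render_params`.
#' @export
render_params <- function(bg_fluor = 30, fg_fluor = 180,
                          bg_bright = 200, bleed_intensity = 80,
                          hole_intensity = 10,
                          ffa_bg = 60, ffa_lesion = 120,
                          noise_sd = 5, bits = 8L,
                          hole_scale = 1.2, bleed_aspect = 0.5) {
  stopifnot(bits %in% c(8L, 16L), noise_sd >= 0)
  structure(as.list(environment()), class = "render_params")
}

# Linear indices of exactly n pixels forming a disc of n pixels around
# `center` (row, col; 0-based): the n grid points nearest the center,
# ties broken by index, so the rendered pixel count matches the requested
# area to within half a pixel of rounding.
disc_indices <- function(center, n_px, image_size) {
  if (n_px <= 0) return(integer(0))
  r <- sqrt(n_px / pi) + 1
  if (center[1] - r < 0 || center[2] - r < 0 ||
      center[1] + r > image_size[1] - 1 || center[2] + r > image_size[2] - 1) {
    abort_input("lesion footprint exceeds image bounds")
  }
  rows <- floor(center[1] - r):ceiling(center[1] + r)
  cols <- floor(center[2] - r):ceiling(center[2] + r)
  rr <- rep(rows, times = length(cols))
  cc <- rep(cols, each = length(rows))
  d2 <- (rr - center[1])^2 + (cc - center[2])^2
  keep <- order(d2)[seq_len(n_px)]
  rr[keep] + cc[keep] * image_size[1] + 1L # column-major linear index
}

# Linear indices of a filled ellipse (major axis full length, px).
ellipse_indices <- function(center, major_px, aspect, theta, image_size) {
  a <- major_px / 2
  b <- a * aspect
  if (a <= 0) return(integer(0))
  r <- ceiling(a) + 2
  rows <- max(0, floor(center[1] - r)):min(image_size[1] - 1, ceiling(center[1] + r))
  cols <- max(0, floor(center[2] - r)):min(image_size[2] - 1, ceiling(center[2] + r))
  rr <- rep(rows, times = length(cols))
  cc <- rep(cols, each = length(rows))
  dr <- rr - center[1]
  dc <- cc - center[2]
  u <- dr * cos(theta) + dc * sin(theta)
  v <- -dr * sin(theta) + dc * cos(theta)
  keep <- (u / a)^2 + (v / b)^2 <= 1
  rr[keep] + cc[keep] * image_size[1] + 1L
}

add_noise <- function(img, sd, bits) {
  if (sd > 0) img <- img + rnorm(length(img), 0, sd)
  matrix(pmin(pmax(round(img), 0), 2^bits - 1), nrow(img), ncol(img))
}

# Pixels within `halfwidth` of the segment c1-c2: the connecting bar that
# turns a fused lesion pair into one component spanning both sites.
bar_indices <- function(c1, c2, halfwidth, image_size) {
  lo <- pmax(0, floor(pmin(c1, c2) - halfwidth))
  hi <- pmin(image_size - 1, ceiling(pmax(c1, c2) + halfwidth))
  rows <- lo[1]:hi[1]; cols <- lo[2]:hi[2]
  rr <- rep(rows, times = length(cols))
  cc <- rep(cols, each = length(rows))
  v <- c2 - c1
  len2 <- sum(v^2)
  t <- pmin(pmax(((rr - c1[1]) * v[1] + (cc - c1[2]) * v[2]) / len2, 0), 1)
  d2 <- (rr - (c1[1] + t * v[1]))^2 + (cc - (c1[2] + t * v[2]))^2
  keep <- d2 <= halfwidth^2
  rr[keep] + cc[keep] * image_size[1] + 1L
}

# Indices of the connecting bars for fused site pairs (adjacent sites both
# categorized fused); width scales with the smaller lesion of the pair.
fused_bar_indices <- function(truths, geometry) {
  fused <- which(truths$category == "fused")
  out <- integer(0)
  r_px <- sqrt(truths$true_area_um2 / pi) / geometry$pixel_scale
  for (i in fused) {
    j <- fused[truths$site[fused] == (truths$site[i] + 1L) %% 4L]
    if (length(j) != 1L) next
    out <- c(out, bar_indices(geometry$burn_sites[truths$site[i] + 1L, ],
                              geometry$burn_sites[truths$site[j] + 1L, ],
                              halfwidth = 0.5 * min(r_px[i], r_px[j]),
                              geometry$image_size))
  }
  out
}

#' Render a synthetic flat-mount image pair
#'
#' Produces the IB4-fluorescence channel (bright lesions on a dark
#' background) and the aligned bright-field channel (dark hemorrhage
#' ellipses and near-black choroidal-damage holes on a bright background)
#' for one eye. Each developed lesion is rendered as a filled disc of
#' exactly `round(true_area / pixel_scale^2)` pixels, so the pixel-count
#' area contract holds to rounding precision; fused pairs keep their discs
#' at their burn sites and are joined by a connecting bar, so they form a
#' single connected component spanning both sites.
#'
#' Noise uses the current RNG state; seed before calling (the study
#' generator seeds a per-eye substream).
#'
#' @param truths `lesion_truth` rows for one eye.
#' @param geometry An [layout_burn_sites()] geometry.
#' @param params A [render_params()] list.
#' @return List with intensity matrices `fluor` and `bright`.
#' @export
render_flatmount <- function(truths, geometry, params = render_params()) {
  stopifnot(inherits(geometry, "eye_geometry"))
  if (length(unique(truths$eye_id)) > 1L) {
    abort_input("render_flatmount expects truths from a single eye")
  }
  sz <- geometry$image_size
  fluor <- matrix(params$bg_fluor, sz[1], sz[2])
  bright <- matrix(params$bg_bright, sz[1], sz[2])
  centers <- geometry$burn_sites[truths$site + 1L, , drop = FALSE]
  fluor[fused_bar_indices(truths, geometry)] <- params$fg_fluor

  for (i in seq_len(nrow(truths))) {
    n_px <- round(truths$true_area_um2[i] / geometry$pixel_scale^2)
    if (n_px > 0) {
      fluor[disc_indices(centers[i, ], n_px, sz)] <- params$fg_fluor
    }
    if (truths$bleed_major_axis_um[i] > 0) {
      idx <- ellipse_indices(
        geometry$burn_sites[truths$site[i] + 1L, ],
        truths$bleed_major_axis_um[i] / geometry$pixel_scale,
        params$bleed_aspect, theta = runif(1L, 0, pi), sz
      )
      bright[idx] <- params$bleed_intensity
    }
    if (truths$category[i] == "choroidal_damage") {
      eq_d <- 2 * sqrt(truths$true_area_um2[i] / pi)
      hole_px <- round(pi * (params$hole_scale * eq_d / 2)^2 /
                         geometry$pixel_scale^2)
      bright[disc_indices(centers[i, ], hole_px, sz)] <- params$hole_intensity
    }
  }
  list(fluor = add_noise(fluor, params$noise_sd, params$bits),
       bright = add_noise(bright, params$noise_sd, params$bits))
}

#' Render a synthetic fundus fluorescein angiography pair
#'
#' The 5-minute frame shows each developed lesion at a baseline intensity;
#' the 10-minute frame adds each lesion's `leak_increment` inside its
#' footprint, emulating fluorescein leakage from permeable CNV vessels.
#' Independent pixel noise is added to the two frames.
#'
#' @inheritParams render_flatmount
#' @return List with intensity matrices `ffa_5min` and `ffa_10min`.
#' @export
render_ffa_pair <- function(truths, geometry, params = render_params()) {
  stopifnot(inherits(geometry, "eye_geometry"))
  sz <- geometry$image_size
  base <- matrix(params$ffa_bg, sz[1], sz[2])
  leak <- matrix(0, sz[1], sz[2])
  centers <- geometry$burn_sites[truths$site + 1L, , drop = FALSE]
  bar <- fused_bar_indices(truths, geometry)
  if (length(bar)) {
    base[bar] <- params$ffa_lesion
    leak[bar] <- mean(truths$leak_increment[truths$category == "fused"])
  }
  for (i in seq_len(nrow(truths))) {
    n_px <- round(truths$true_area_um2[i] / geometry$pixel_scale^2)
    if (n_px > 0) {
      idx <- disc_indices(centers[i, ], n_px, sz)
      base[idx] <- params$ffa_lesion
      leak[idx] <- truths$leak_increment[i]
    }
  }
  list(ffa_5min = add_noise(base, params$noise_sd, params$bits),
       ffa_10min = add_noise(base + leak, params$noise_sd, params$bits))
}
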