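#' Segmentation parameters
#'
#' The fluorescence threshold is the study's established constant: it is
#' fixed once per study and applied unchanged to every image, which is the
#' methodological core of reproducible lesion quantification here —
#' per-image adaptive thresholding is deliberately not offered.
#'
#' @param fluor_threshold Global intensity threshold on the IB4 channel;
#'   pixels at or above it are lesion candidates.
#' @param min_area Minimum component area in square micrometers; smaller
#'   components (noise specks, debris) are dropped.
#' @param pixel_scale Micrometers per pixel.
#' @param bleed_threshold Bright-field intensity at or below which (but
#'   above the damage threshold) a pixel counts as hemorrhage.
#' @param damage_darkness_threshold Bright-field intensity at or below
#'   which a pixel belongs to a choroidal-damage "hole".
#' @param bits Image bit depth the thresholds refer to.
#' @return A list of class `segmentation_params`.
#' @export
segmentation_params <- function(fluor_threshold = 100,
                                min_area = 1000,
                                pixel_scale = 1.5,
                                bleed_threshold = 120,
                                damage_darkness_threshold = 30,
                                bits = 8L) {
  maxv <- 2^bits - 1
  if (fluor_threshold < 0 || fluor_threshold > maxv ||
      bleed_threshold < 0 || bleed_threshold > maxv ||
      damage_darkness_threshold < 0 || damage_darkness_threshold > maxv) {
    abort_input("thresholds must lie within the image bit depth")
  }
  if (min_area < 0) abort_input("min_area must be >= 0")
  if (pixel_scale <= 0) abort_input("pixel_scale must be > 0")
  structure(as.list(environment())[c("fluor_threshold", "min_area",
                                     "pixel_scale", "bleed_threshold",
                                     "damage_darkness_threshold", "bits")],
            class = "segmentation_params")
}

# Connected-component labeling with 8-connectivity: EBImage::bwlabel is
# 4-connected, so labels that touch diagonally are merged afterwards with
# a small union-find over the label adjacency pairs.
label_components8 <- function(mask) {
  lbl <- EBImage::bwlabel(mask * 1)
  lbl <- matrix(as.integer(lbl), nrow(mask), ncol(mask))
  n <- max(lbl)
  if (n <= 1L) return(lbl)
  nr <- nrow(lbl); nc <- ncol(lbl)
  a1 <- lbl[-nr, -nc]; b1 <- lbl[-1, -1]   # down-right diagonal
  a2 <- lbl[-nr, -1]; b2 <- lbl[-1, -nc]   # down-left diagonal
  pr <- rbind(cbind(as.vector(a1), as.vector(b1)),
              cbind(as.vector(a2), as.vector(b2)))
  pr <- pr[pr[, 1] > 0 & pr[, 2] > 0 & pr[, 1] != pr[, 2], , drop = FALSE]
  if (nrow(pr) == 0L) return(lbl)
  parent <- seq_len(n)
  find <- function(x) { while (parent[x] != x) x <- parent[x] <<- parent[parent[x]]; x }
  for (k in seq_len(nrow(pr))) {
    ra <- find(pr[k, 1]); rb <- find(pr[k, 2])
    if (ra != rb) parent[max(ra, rb)] <- min(ra, rb)
  }
  root <- vapply(seq_len(n), find, integer(1))
  relab <- match(root, sort(unique(root)))
  lbl[lbl > 0] <- relab[lbl[lbl > 0]]
  lbl
}

measure_components <- function(lbl, pixel_scale) {
  n <- max(lbl)
  if (n == 0L) {
    return(data.frame(lesion_id = integer(0), site = integer(0),
                      area_um2 = numeric(0), eq_diameter_um = numeric(0),
                      centroid_row = numeric(0), centroid_col = numeric(0),
                      fused = logical(0), pixel_count = integer(0)))
  }
  px <- tabulate(lbl[lbl > 0], nbins = n)
  idx <- which(lbl > 0)
  labv <- lbl[idx]
  rows0 <- (idx - 1L) %% nrow(lbl)        # 0-based
  cols0 <- (idx - 1L) %/% nrow(lbl)
  cr <- vapply(split(rows0, labv), mean, numeric(1))
  cc <- vapply(split(cols0, labv), mean, numeric(1))
  area <- px * pixel_scale^2
  df <- data.frame(lesion_id = seq_len(n), site = NA_integer_,
                   area_um2 = area, eq_diameter_um = 2 * sqrt(area / pi),
                   centroid_row = as.numeric(cr), centroid_col = as.numeric(cc),
                   fused = FALSE, pixel_count = as.integer(px))
  df[order(df$centroid_row, df$centroid_col), , drop = FALSE]
}

#' Segment lesions on the IB4-fluorescence channel
#'
#' Thresholds the image at the study's constant fluorescence threshold,
#' labels 8-connected components, drops components smaller than
#' `min_area`, and measures each remaining component: pixel count,
#' calibrated area, equivalent circular diameter `2 * sqrt(area / pi)`,
#' and centroid. Components are returned in deterministic row-major
#' centroid order and renumbered 1..k.
#'
#' @param fluor_image Grayscale intensity matrix.
#' @param params A [segmentation_params()] list.
#' @return List with `measurements` (data frame) and `labels` (the label
#'   matrix, renumbered to match `lesion_id`).
#' @export
segment_lesions <- function(fluor_image, params = segmentation_params()) {
  stopifnot(is.matrix(fluor_image))
  lbl <- label_components8(fluor_image >= params$fluor_threshold)
  m <- measure_components(lbl, params$pixel_scale)
  keep <- m$area_um2 >= params$min_area
  m <- m[keep, , drop = FALSE]
  relab <- integer(max(lbl, 1L))
  relab[m$lesion_id] <- seq_len(nrow(m))
  lbl[lbl > 0] <- relab[lbl[lbl > 0]]
  m$lesion_id <- seq_len(nrow(m))
  rownames(m) <- NULL
  list(measurements = m, labels = lbl)
}

# Minimum distance from each burn-site center to the pixels of each label;
# a site is "claimed" by a component if the site center lies inside it or
# within one disc radius of it.
site_claims <- function(labels, geometry) {
  n <- max(labels)
  radius <- geometry$disc_diameter / 2
  claims <- matrix(FALSE, nrow = 4L, ncol = max(n, 1L))
  if (n == 0L) return(claims)
  for (s in 1:4) {
    ctr <- geometry$burn_sites[s, ]
    rows <- max(0, floor(ctr[1] - radius)):min(nrow(labels) - 1, ceiling(ctr[1] + radius))
    cols <- max(0, floor(ctr[2] - radius)):min(ncol(labels) - 1, ceiling(ctr[2] + radius))
    sub <- labels[rows + 1L, cols + 1L, drop = FALSE]
    rr <- rep(rows, times = length(cols))
    cc <- rep(cols, each = length(rows))
    inside <- sqrt((rr - ctr[1])^2 + (cc - ctr[2])^2) <= radius
    lab <- unique(sub[inside & sub > 0])
    claims[s, lab] <- TRUE
  }
  claims
}

#' Assign segmented components to burn sites and flag fusion
#'
#' A component claims every burn site whose center lies inside it or
#' within one disc radius of its pixels; a component claiming two or more
#' sites is a fused lesion. Each component is assigned the nearest claimed
#' site (0-based index, `NA` if unclaimed). Burn sites claimed by no
#' component are candidate failed-rupture sites, returned in the
#' `unclaimed_sites` attribute.
#'
#' @param measurements Data frame from [segment_lesions()].
#' @param labels Label matrix from [segment_lesions()].
#' @param geometry The eye's [layout_burn_sites()] geometry.
#' @return `measurements` with `site` and `fused` filled in, and an
#'   `unclaimed_sites` attribute (0-based site indices).
#' @export
assign_to_sites <- function(measurements, labels, geometry) {
  claims <- site_claims(labels, geometry)
  if (nrow(measurements)) {
    for (i in seq_len(nrow(measurements))) {
      id <- measurements$lesion_id[i]
      sites <- which(claims[, id])
      measurements$fused[i] <- length(sites) >= 2L
      if (length(sites)) {
        ctr <- c(measurements$centroid_row[i], measurements$centroid_col[i])
        d <- sqrt(rowSums((geometry$burn_sites[sites, , drop = FALSE] -
                             matrix(ctr, length(sites), 2, byrow = TRUE))^2))
        measurements$site[i] <- sites[which.min(d)] - 1L
      }
    }
  }
  attr(measurements, "unclaimed_sites") <- which(rowSums(claims) == 0L) - 1L
  attr(measurements, "claims") <- claims
  measurements
}

#' Detect hemorrhage regions on the bright-field channel
#'
#' Hemorrhage pixels are those with intensity in
#' `(damage_darkness_threshold, bleed_threshold]` — darker than tissue
#' background but lighter than a choroidal-damage hole. Components at
#' least `min_area` large are measured by the major axis of their
#' second-central-moment ellipse (converted to micrometers) and linked to
#' the nearest burn site.
#'
#' @param brightfield Bright-field intensity matrix, aligned with the
#'   fluorescence channel.
#' @param params A [segmentation_params()] list.
#' @param geometry The eye's geometry.
#' @return Data frame with `region_id`, `major_axis_um`, `site` (0-based
#'   nearest burn site).
#' @export
detect_bleeding <- function(brightfield, params, geometry) {
  mask <- brightfield <= params$bleed_threshold &
    brightfield > params$damage_darkness_threshold
  lbl <- label_components8(mask)
  empty <- data.frame(region_id = integer(0), major_axis_um = numeric(0),
                      site = integer(0))
  if (max(lbl) == 0L) return(empty)
  px <- tabulate(lbl[lbl > 0], nbins = max(lbl))
  keep <- which(px * params$pixel_scale^2 >= params$min_area)
  if (!length(keep)) return(empty)
  fm <- EBImage::computeFeatures.moment(lbl)
  out <- data.frame(
    region_id = seq_along(keep),
    major_axis_um = fm[keep, "m.majoraxis"] * params$pixel_scale,
    site = NA_integer_
  )
  # on an R matrix, EBImage's m.cx runs along rows and m.cy along columns
  for (k in seq_along(keep)) {
    ctr <- c(fm[keep[k], "m.cx"] - 1, fm[keep[k], "m.cy"] - 1)
    d <- sqrt(rowSums((geometry$burn_sites -
                         matrix(ctr, 4, 2, byrow = TRUE))^2))
    out$site[k] <- which.min(d) - 1L
  }
  rownames(out) <- NULL
  out
}

#' Detect choroidal-damage holes on the bright-field channel
#'
#' A burn site is damage-flagged when a connected near-black region
#' (intensity at or below `damage_darkness_threshold`) of at least
#' `min_area` overlaps it (site center inside the region or within one
#' disc radius of it).
#'
#' @inheritParams detect_bleeding
#' @param fluor_image Fluorescence channel (accepted for interface
#'   symmetry; the decision uses only the bright-field channel).
#' @return Logical vector of length 4: damage flag per burn site.
#' @export
detect_choroidal_damage <- function(brightfield, fluor_image = NULL,
                                    params = segmentation_params(),
                                    geometry) {
  lbl <- label_components8(brightfield <= params$damage_darkness_threshold)
  if (max(lbl) == 0L) return(rep(FALSE, 4L))
  px <- tabulate(lbl[lbl > 0], nbins = max(lbl))
  big <- which(px * params$pixel_scale^2 >= params$min_area)
  if (!length(big)) return(rep(FALSE, 4L))
  claims <- site_claims(lbl, geometry)
  as.vector(rowSums(claims[, big, drop = FALSE]) > 0L)
}
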