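# Small, fast fixtures shared across the suite. Images are built in code;
# nothing is read from disk.

# Compact geometry for unit tests: small canvas, small lesions.
tiny_geometry <- function() {
  layout_burn_sites(image_size = c(256L, 256L), disc_diameter = 30,
                    pixel_scale = 1, jitter_deg = 0, margin = 20)
}

tiny_group <- function(...) {
  group_params("tiny", mean_area = 2500, sd_area = 800, ...)
}

noiseless <- function(...) render_params(noise_sd = 0, ...)

# A filled disc of the given radius (px) at `center` (row, col; 0-based)
# painted onto a constant background.
disc_image <- function(size = c(256L, 256L), center = c(127.5, 127.5),
                       radius = 50, fg = 200, bg = 0) {
  img <- matrix(bg, size[1], size[2])
  rr <- rep(0:(size[1] - 1), times = size[2])
  cc <- rep(0:(size[2] - 1), each = size[1])
  img[(rr - center[1])^2 + (cc - center[2])^2 <= radius^2] <- fg
  img
}

# One synthetic eye from explicit truth rows (category, area, bleed axis).
make_eye <- function(categories, areas, bleed_axes = rep(0, length(areas)),
                     geometry = layout_burn_sites(), params = noiseless(),
                     eye_id = "eye1", seed = 99) {
  truths <- data.frame(eye_id = eye_id, site = seq_along(categories) - 1L,
                       category = categories, true_area_um2 = areas,
                       bleed_major_axis_um = bleed_axes, leak_increment = 25)
  set.seed(seed)
  imgs <- render_flatmount(truths, geometry, params)
  list(truths = truths, fluor = imgs$fluor, bright = imgs$bright)
}

# Per-shot rows ready for apply_exclusions().
shot_rows <- function(grades, areas = rep(10000, length(grades)),
                      no_rupture = rep(FALSE, length(grades)),
                      damage = rep(FALSE, length(grades)),
                      fused = rep(FALSE, length(grades)),
                      eye_id = "eyeA") {
  data.frame(eye_id = eye_id, site = seq_along(grades) - 1L,
             area_um2 = areas, grade = as.integer(grades),
             no_rupture = no_rupture, choroidal_damage = damage,
             fused = fused)
}
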