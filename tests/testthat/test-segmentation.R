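test_that("a filled disc is measured with circle-geometry area and diameter", {
  img <- disc_image(radius = 50, fg = 200)
  seg <- segment_lesions(img, segmentation_params(fluor_threshold = 100,
                                                  min_area = 100,
                                                  pixel_scale = 1))
  expect_equal(nrow(seg$measurements), 1L)
  m <- seg$measurements
  expect_lt(abs(m$area_um2 - pi * 50^2) / (pi * 50^2), 0.02)
  expect_lt(abs(m$eq_diameter_um - 100) / 100, 0.02)
  expect_equal(m$eq_diameter_um, 2 * sqrt(m$area_um2 / pi))
  expect_equal(m$area_um2, m$pixel_count * 1^2)
})

test_that("background-only and degenerate images give empty results", {
  sp <- segmentation_params(pixel_scale = 1)
  expect_equal(nrow(segment_lesions(matrix(0, 64, 64), sp)$measurements), 0L)
  expect_equal(nrow(segment_lesions(matrix(0, 1, 1), sp)$measurements), 0L)
})

test_that("components use 8-connectivity", {
  img <- matrix(0, 32, 32)
  img[10, 10] <- 255; img[11, 11] <- 255; img[12, 12] <- 255
  seg <- segment_lesions(img, segmentation_params(fluor_threshold = 100,
                                                  min_area = 0,
                                                  pixel_scale = 1))
  expect_equal(nrow(seg$measurements), 1L)
  expect_equal(seg$measurements$pixel_count, 3L)
})

test_that("raising the threshold never grows a lesion", {
  set.seed(21)
  img <- disc_image(radius = 40, fg = 180, bg = 20) +
    matrix(rnorm(256^2, 0, 30), 256, 256)
  sp <- function(t) segmentation_params(fluor_threshold = t, min_area = 0,
                                        pixel_scale = 1)
  counts <- vapply(seq(60, 170, by = 10), function(t) {
    sum(segment_lesions(img, sp(t))$measurements$pixel_count)
  }, numeric(1))
  expect_true(all(diff(counts) <= 0))
})

test_that("min_area filters small components deterministically", {
  img <- disc_image(radius = 30)
  img[5:6, 5:6] <- 255 # 4-px speck
  seg <- segment_lesions(img, segmentation_params(fluor_threshold = 100,
                                                  min_area = 50,
                                                  pixel_scale = 1))
  expect_equal(nrow(seg$measurements), 1L)
  # measurement ordering is row-major by centroid
  img2 <- disc_image(radius = 20, center = c(60, 200)) +
    disc_image(radius = 20, center = c(180, 40))
  seg2 <- segment_lesions(img2, segmentation_params(fluor_threshold = 100,
                                                    min_area = 50,
                                                    pixel_scale = 1))
  expect_equal(seg2$measurements$centroid_row, c(60, 180), tolerance = 0.01)
})

test_that("site assignment, fusion flags and unclaimed sites are recovered", {
  geo <- layout_burn_sites()
  sp <- segmentation_params(pixel_scale = geo$pixel_scale)

  eye <- make_eye(rep("normal", 4), rep(20000, 4), geometry = geo)
  seg <- segment_lesions(eye$fluor, sp)
  m <- assign_to_sites(seg$measurements, seg$labels, geo)
  expect_setequal(m$site, 0:3)
  expect_false(any(m$fused))
  expect_length(attr(m, "unclaimed_sites"), 0L)

  eye <- make_eye(c("fused", "fused", "normal", "normal"),
                  c(20000, 20000, 15000, 15000), geometry = geo)
  seg <- segment_lesions(eye$fluor, sp)
  m <- assign_to_sites(seg$measurements, seg$labels, geo)
  expect_equal(sum(m$fused), 1L)
  expect_equal(nrow(m), 3L)

  eye <- make_eye(c("normal", "normal", "normal", "no_rupture"),
                  c(20000, 20000, 15000, 0), geometry = geo)
  seg <- segment_lesions(eye$fluor, sp)
  m <- assign_to_sites(seg$measurements, seg$labels, geo)
  expect_equal(attr(m, "unclaimed_sites"), 3L)
})

test_that("bleed regions are measured by ellipse major axis and linked to sites", {
  geo <- layout_burn_sites()
  sp <- segmentation_params(pixel_scale = geo$pixel_scale)

  expect_equal(nrow(detect_bleeding(matrix(200, 256, 256),
                                    segmentation_params(pixel_scale = 1),
                                    tiny_geometry())), 0L)

  area <- 25000; eqd <- 2 * sqrt(area / pi)
  eye <- make_eye(c("bleed_g0", "normal", "bleed_g1", "normal"),
                  rep(area, 4),
                  bleed_axes = c(150, 0, 1.5 * eqd, 0), geometry = geo)
  bl <- detect_bleeding(eye$bright, sp, geo)
  expect_equal(nrow(bl), 2L)
  expect_setequal(bl$site, c(0L, 2L))
  expect_lt(abs(bl$major_axis_um[bl$site == 0] - 150), 5)
  expect_lt(abs(bl$major_axis_um[bl$site == 2] - 1.5 * eqd), 5)
})

test_that("choroidal damage is flagged only for overlapped, large holes", {
  geo <- layout_burn_sites()
  sp <- segmentation_params(pixel_scale = geo$pixel_scale)
  eye <- make_eye(c("normal", "normal", "choroidal_damage", "normal"),
                  c(20000, 20000, 8000, 20000), geometry = geo)
  expect_equal(detect_choroidal_damage(eye$bright, eye$fluor, sp, geo),
               c(FALSE, FALSE, TRUE, FALSE))
  expect_equal(detect_choroidal_damage(matrix(200, 1024, 1024),
                                       params = sp, geometry = geo),
               rep(FALSE, 4L))
  # a hole smaller than min_area is ignored
  small <- matrix(200, 1024, 1024)
  ctr <- round(geo$burn_sites[2, ]) + 1L
  small[ctr[1] + (-5:5), ctr[2] + (-5:5)] <- 5 # 121 px < min_area at 1.5 um/px
  expect_equal(detect_choroidal_damage(small, params = sp, geometry = geo),
               rep(FALSE, 4L))
})
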