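test_that("burn sites lie on the 2-disc-diameter circle at clock positions", {
  g <- layout_burn_sites(image_size = c(512, 512), on_center = c(256, 256),
                         disc_diameter = 40, pixel_scale = 1, jitter_deg = 0)
  expect_equal(unname(g$burn_sites),
               rbind(c(256, 336), c(336, 256), c(256, 176), c(176, 256)))
  d <- as.matrix(dist(g$burn_sites))
  expect_true(all(d[upper.tri(d)] >= 2 * 40))
})

test_that("jittered layouts are seeded-deterministic and keep separation", {
  set.seed(5)
  g1 <- layout_burn_sites(disc_diameter = 100, jitter_deg = 10)
  set.seed(5)
  g2 <- layout_burn_sites(disc_diameter = 100, jitter_deg = 10)
  expect_identical(g1, g2)
  for (s in 1:20) {
    set.seed(s)
    g <- layout_burn_sites(disc_diameter = 100, jitter_deg = 10)
    d <- as.matrix(dist(g$burn_sites))
    expect_true(all(d[upper.tri(d)] >= 2 * 100))
  }
})

test_that("impossible geometry is a configuration error", {
  expect_error(layout_burn_sites(image_size = c(64, 64), disc_diameter = 40),
               "too small")
  expect_error(layout_burn_sites(disc_diameter = -1), "disc_diameter")
})

test_that("degenerate and boundary truth sampling behaves as specified", {
  g0 <- group_params("g0", mean_area = 5000, sd_area = 0)
  tr <- sample_lesion_truths(g0, 10, seed = 1)
  expect_true(all(tr$true_area_um2 == 5000))

  gn <- group_params("gn", mean_area = 5000, sd_area = 1000, p_no_rupture = 1)
  tr <- sample_lesion_truths(gn, 5, seed = 1)
  expect_true(all(tr$category == "no_rupture"))
  expect_true(all(tr$true_area_um2 == 0))

  expect_error(group_params("bad", mean_area = -1, sd_area = 0), "mean_area")
  expect_error(group_params("bad", mean_area = 1, sd_area = 0,
                            p_no_rupture = 0.7, p_outlier = 0.7), "sum")
})

test_that("log-normal moment matching reproduces target mean and SD", {
  g <- group_params("mm", mean_area = 30433.0, sd_area = 12582.2)
  tr <- sample_lesion_truths(g, 25000, seed = 7) # 1e5 draws
  a <- tr$true_area_um2
  expect_lt(abs(mean(a) - 30433.0) / 30433.0, 0.01)
  expect_lt(abs(sd(a) - 12582.2) / 12582.2, 0.03)
})

test_that("category frequencies match the configured probabilities", {
  g <- group_params("freq", mean_area = 30000, sd_area = 15000,
                    p_no_rupture = 0.10, p_bleed_g0 = 0.05,
                    p_bleed_g1 = 0.04, p_bleed_g2 = 0.02,
                    p_damage = 0.05, p_fused = 0.04, p_outlier = 0.05)
  tr <- sample_lesion_truths(g, 5000, seed = 13) # 2e4 burns
  n <- nrow(tr)
  freq <- table(factor(tr$category, levels = LESION_CATEGORIES)) / n
  probs <- c(no_rupture = 0.10, bleed_g0 = 0.05, bleed_g1 = 0.04,
             bleed_g2 = 0.02, choroidal_damage = 0.05, fused = 0.04,
             outlier = 0.05)
  for (cat in names(probs)) {
    se <- sqrt(probs[[cat]] * (1 - probs[[cat]]) / n)
    expect_lt(abs(freq[[cat]] - probs[[cat]]), 3 * se)
  }
})

test_that("bleed axes respect their grade band and outliers exceed 5x mean", {
  g <- group_params("bands", mean_area = 30000, sd_area = 10000,
                    p_bleed_g0 = 0.2, p_bleed_g1 = 0.2, p_bleed_g2 = 0.2,
                    p_outlier = 0.2)
  tr <- sample_lesion_truths(g, 500, seed = 3)
  eq_d <- 2 * sqrt(tr$true_area_um2 / pi)
  ratio <- tr$bleed_major_axis_um / eq_d
  expect_true(all(ratio[tr$category == "bleed_g0"] < 1))
  expect_true(all(ratio[tr$category == "bleed_g1"] >= 1 &
                    ratio[tr$category == "bleed_g1"] < 2))
  expect_true(all(ratio[tr$category == "bleed_g2"] >= 2))
  out <- tr$true_area_um2[tr$category == "outlier"]
  expect_true(all(out > 5 * 30000 & out <= 8 * 30000))
})

test_that("truth tables round-trip losslessly through CSV", {
  g <- tiny_group(p_no_rupture = 0.1, p_bleed_g1 = 0.1)
  tr <- sample_lesion_truths(g, 10, seed = 2)
  expect_equal(nrow(tr), 40L)
  p <- withr::local_tempfile(fileext = ".csv")
  write_truth(tr, p, geometry = tiny_geometry())
  back <- read_truth(p)
  expect_equal(as.data.frame(back), as.data.frame(tr))
  expect_true(file.exists(paste0(p, ".geometry.yaml")))

  empty <- tr[0, ]
  write_truth(empty, p)
  expect_equal(nrow(read_truth(p)), 0L)
})

test_that("rendered lesion pixel count honours the area contract", {
  geo <- tiny_geometry()
  eye <- make_eye("normal", 7850, geometry = geo, params = noiseless())
  px <- sum(eye$fluor >= 100)
  expect_lt(abs(px * geo$pixel_scale^2 - 7850), 0.02 * 7850)

  # fused pair renders as one component overlapping both sites
  geo2 <- layout_burn_sites()
  eye2 <- make_eye(c("fused", "fused"), c(20000, 20000), geometry = geo2)
  lbl <- lasercnv:::label_components8(eye2$fluor >= 100)
  expect_equal(max(lbl), 1L)
  s0 <- round(geo2$burn_sites[1, ]) + 1L
  s1 <- round(geo2$burn_sites[2, ]) + 1L
  expect_gt(lbl[s0[1], s0[2]], 0)
  expect_gt(lbl[s1[1], s1[2]], 0)
})

test_that("footprints beyond the canvas raise a generation error", {
  geo <- tiny_geometry()
  expect_error(
    render_flatmount(data.frame(eye_id = "e", site = 0L, category = "normal",
                                true_area_um2 = 5e5, bleed_major_axis_um = 0,
                                leak_increment = 0),
                     geo, noiseless()),
    "bounds")
})

test_that("angiography pairs encode the configured leak increment", {
  geo <- tiny_geometry()
  tr <- data.frame(eye_id = "e", site = 0:3, category = "normal",
                   true_area_um2 = 2500, bleed_major_axis_um = 0,
                   leak_increment = 0)
  ffa <- render_ffa_pair(tr, geo, noiseless())
  expect_identical(ffa$ffa_5min, ffa$ffa_10min)

  tr$leak_increment <- 25
  ffa <- render_ffa_pair(tr, geo, noiseless())
  mask <- ffa$ffa_5min > 100
  expect_equal(mean(ffa$ffa_10min[mask] - ffa$ffa_5min[mask]), 25)

  set.seed(4)
  ffa <- render_ffa_pair(tr, geo, render_params(noise_sd = 2))
  expect_gt(sum(mask), 500)
  expect_lt(abs(mean(ffa$ffa_10min[mask] - ffa$ffa_5min[mask]) - 25), 1)
})

test_that("same seed gives bit-identical truths and images", {
  g <- tiny_group(p_bleed_g0 = 0.2)
  tr1 <- sample_lesion_truths(g, 4, seed = 77)
  tr2 <- sample_lesion_truths(g, 4, seed = 77)
  expect_identical(tr1, tr2)
  geo <- tiny_geometry()
  e1 <- tr1[tr1$eye_id == tr1$eye_id[1], ]
  set.seed(1); im1 <- render_flatmount(e1, geo, render_params(noise_sd = 4))
  set.seed(1); im2 <- render_flatmount(e1, geo, render_params(noise_sd = 4))
  expect_identical(im1, im2)
})
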