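test_that("hemorrhage grades follow the axis/diameter bands", {
  expect_equal(grade_hemorrhage(100, 80), 0L)
  expect_equal(grade_hemorrhage(100, 150), 1L)
  expect_equal(grade_hemorrhage(100, 250), 2L)
  expect_equal(grade_hemorrhage(100, 0), 0L)
  # boundary closure: equality grades upward
  expect_equal(grade_hemorrhage(100, c(100, 200)), c(1L, 2L))
  expect_error(grade_hemorrhage(0, 10), "positive")
  expect_error(grade_hemorrhage(100, -1), ">= 0")
})

test_that("grade bands partition all (LD, axis) pairs and match a brute-force oracle", {
  # independent three-band enumeration, written out longhand
  oracle <- function(ld, axis) {
    if (axis < ld) 0L else if (axis < 2 * ld) 1L else 2L
  }
  set.seed(42)
  ld <- runif(100, 10, 400)
  axis <- runif(100, 0, 1000)
  grid <- expand.grid(ld = ld, axis = axis) # 1e4 pairs
  got <- grade_hemorrhage(grid$ld, grid$axis)
  want <- mapply(oracle, grid$ld, grid$axis)
  expect_identical(got, as.integer(want))
  expect_true(all(got %in% 0:2))
})

test_that("the 5x leave-one-out outlier rule fires exactly as computed by hand", {
  expect_equal(flag_outliers(c(10000, 11000, 12000, 170000)),
               c(FALSE, FALSE, FALSE, TRUE)) # mean of others 11000, 5x = 55000
  expect_equal(flag_outliers(rep(9000, 4)), rep(FALSE, 4))
  expect_equal(flag_outliers(c(10000, 49000)), c(FALSE, FALSE)) # 49000 <= 50000
  expect_warning(f <- flag_outliers(30000), "at least 2")
  expect_equal(f, FALSE)
})

test_that("exclusion rules fire in order with the documented reasons", {
  # a grade-2 bleed excludes the whole eye
  ex <- apply_exclusions(shot_rows(c(0, 0, 2, 0)))
  expect_true(all(!ex$included))
  expect_true(all(ex$exclusion_reason == "eye_excluded_g2"))

  # grade-1 excludes only that lesion
  ex <- apply_exclusions(shot_rows(c(0, 1, 0, 0)))
  expect_equal(sum(ex$included), 3L)
  expect_equal(ex$exclusion_reason[2], "bleeding_g1")

  # structural flags leave one eligible lesion -> sole survivor, none included
  ex <- apply_exclusions(shot_rows(c(0, 0, 0, 0),
                                   no_rupture = c(TRUE, TRUE, FALSE, FALSE),
                                   fused = c(FALSE, FALSE, TRUE, FALSE)))
  expect_equal(sum(ex$included), 0L)
  expect_equal(ex$exclusion_reason,
               c("no_bm_rupture", "no_bm_rupture", "fused", "sole_survivor"))

  # clean eye: everything included
  ex <- apply_exclusions(shot_rows(c(0, 0, 0, 0)))
  expect_true(all(ex$included))
  expect_true(all(ex$exclusion_reason == "none"))

  # outliers are assessed among structurally valid lesions only
  ex <- apply_exclusions(shot_rows(c(0, 0, 0, 0),
                                   areas = c(10000, 11000, 12000, 170000)))
  expect_equal(ex$exclusion_reason[4], "outlier")
  expect_equal(sum(ex$included), 3L)

  expect_error(apply_exclusions(shot_rows(c(0, 0), eye_id = c("a", "b"))),
               "single eye")
})

test_that("exclusion engine is idempotent and partitions every eye", {
  set.seed(8)
  for (rep in 1:50) {
    n <- sample(2:6, 1)
    shots <- shot_rows(sample(0:2, n, replace = TRUE, prob = c(.7, .2, .1)),
                       areas = rlnorm(n, 10, 0.6),
                       no_rupture = runif(n) < 0.15,
                       damage = runif(n) < 0.1,
                       fused = runif(n) < 0.1)
    ex <- apply_exclusions(shots)
    expect_identical(apply_exclusions(ex), ex)
    expect_equal(sum(ex$included) + sum(!ex$included), n)
    expect_true(all((ex$exclusion_reason == "none") == ex$included))
    expect_true(all(ex$exclusion_reason %in% lasercnv:::EXCLUSION_REASONS))
    if (any(ex$grade == 2 & !ex$no_rupture)) {
      expect_equal(sum(ex$included), 0L)
    }
  }
})

test_that("removing a grade-2 lesion never reduces the included count", {
  set.seed(9)
  for (rep in 1:30) {
    shots <- shot_rows(c(2, sample(0:1, 3, replace = TRUE)),
                       areas = rlnorm(4, 10, 0.5))
    with_g2 <- sum(apply_exclusions(shots)$included)
    without <- sum(apply_exclusions(shots[-1, ])$included)
    expect_gte(without, with_g2)
  }
})

test_that("condition-scope outlier flagging pools areas across the condition", {
  shots <- shot_rows(c(0, 0, 0, 0), areas = c(10000, 10000, 10000, 60000))
  pool <- c(rep(10000, 20), 60000)
  ex <- apply_exclusions(shots, outlier_scope = "condition",
                         condition_areas = pool)
  expect_equal(ex$exclusion_reason[4], "outlier") # 60000 > 5 * 10000
  # same eye judged within-eye: leave-one-out mean 10000, 5x = 50000 -> also fires
  expect_error(apply_exclusions(shots, outlier_scope = "condition"),
               "condition_areas")
})

test_that("outcome tallies partition shots and reproduce percentages", {
  graded <- rbind(
    cbind(shot_rows(c(0, 0, 0, 0), eye_id = "e1"), group = "A"),
    cbind(shot_rows(c(0, 1, 0, 0), eye_id = "e2"), group = "A"),
    cbind(shot_rows(c(0, 0, 0, 0), no_rupture = c(TRUE, FALSE, FALSE, FALSE),
                    eye_id = "e3"), group = "B")
  )
  graded <- do.call(rbind, lapply(split(graded, graded$eye_id),
                                  apply_exclusions))
  tally <- tally_lesion_types(graded)
  a <- tally[tally$group == "A", ]
  expect_equal(a$total_shots, 8L)
  expect_equal(a$included, 7L)
  expect_equal(a$bleeding_g1_g2, 1L)
  expect_equal(a$pct_included, signif(100 * 7 / 8, 3))
  sums <- a$no_bm_rupture + a$included + a$bleeding_g1_g2 +
    a$choroidal_damage + a$fused + a$outlier + a$sole_survivor
  expect_equal(sums, a$total_shots)
  b <- tally[tally$group == "B", ]
  expect_equal(b$no_bm_rupture, 1L)
  expect_equal(b$included, 3L)
})
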