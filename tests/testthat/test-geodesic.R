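test_that("edge_weight implements the two weight kinds", {
  expect_equal(edge_weight(5, 5, 1, "gradient_squared"), 0)
  expect_equal(edge_weight(0, 10, 1, "gradient_squared"), 100)
  expect_equal(edge_weight(0, 10, sqrt(2), "gradient_squared"),
               100 / sqrt(2))
  expect_equal(edge_weight(123, -42, sqrt(2), "unit"), sqrt(2))
  expect_equal(edge_weight(0, 0, 1, "unit"), 1)
})

test_that("unit-weight distance from a point seed is the 8-connected chamfer distance", {
  seeds <- matrix(FALSE, 21, 21)
  seeds[11, 11] <- TRUE
  dm <- raster_scan_distance(NULL, seeds, "unit")
  expect_equal(dm$data[11, 11], 0)
  # offset (3, 4): 3 diagonal steps + 1 axial step
  expect_equal(dm$data[14, 15], 3 * sqrt(2) + 1, tolerance = 1e-9)
  expect_equal(dm$data[11, 21], 10, tolerance = 1e-9)
  expect_equal(dm$data[1, 1], 10 * sqrt(2), tolerance = 1e-9)
})

test_that("gradient-squared distance is zero everywhere on a constant image", {
  seeds <- matrix(FALSE, 15, 15); seeds[8, 8] <- TRUE
  dm <- raster_scan_distance(matrix(7, 15, 15), seeds, "gradient_squared")
  expect_true(all(dm$data == 0))
})

test_that("raster scans match the Dijkstra oracle on random images (both kinds)", {
  set.seed(1234)
  for (rep in 1:6) {
    img <- matrix(rnorm(32 * 32, 100, 40), 32, 32)
    seeds <- matrix(FALSE, 32, 32)
    seeds[cbind(sample(32, 3), sample(32, 3))] <- TRUE
    for (kind in c("unit", "gradient_squared")) {
      dm <- raster_scan_distance(img, seeds, kind)
      oracle <- dijkstra_oracle(img, seeds, kind)
      expect_lt(max(abs(dm$data - oracle)), 1e-6)
      expect_true(dm$converged)
    }
  }
})

test_that("seeded disc distances separate interior from exterior as Dijkstra does", {
  img <- matrix(20, 40, 40)
  img[disc_matrix(40, 40, 20, 20, 10)] <- 300
  seeds <- matrix(FALSE, 40, 40); seeds[21, 21] <- TRUE
  dm <- raster_scan_distance(img, seeds, "gradient_squared")
  oracle <- dijkstra_oracle(img, seeds, "gradient_squared")
  expect_lt(max(abs(dm$data - oracle)), 1e-6)
  inside <- disc_matrix(40, 40, 20, 20, 8)
  outside <- !disc_matrix(40, 40, 20, 20, 13)
  expect_lt(max(dm$data[inside]), min(dm$data[outside]))
})

test_that("distance maps are invariant to adding a constant to the image", {
  set.seed(77)
  img <- matrix(rnorm(24 * 24, 0, 30), 24, 24)
  seeds <- matrix(FALSE, 24, 24); seeds[5, 19] <- TRUE
  a <- raster_scan_distance(img, seeds, "gradient_squared")
  b <- raster_scan_distance(img + 500, seeds, "gradient_squared")
  expect_equal(a$data, b$data, tolerance = 1e-9)
})

test_that("adding seeds never increases any distance", {
  set.seed(55)
  img <- matrix(rnorm(24 * 24, 0, 30), 24, 24)
  s1 <- matrix(FALSE, 24, 24); s1[3, 3] <- TRUE
  s2 <- s1; s2[20, 14] <- TRUE; s2[9, 22] <- TRUE
  for (kind in c("unit", "gradient_squared")) {
    d1 <- raster_scan_distance(img, s1, kind)$data
    d2 <- raster_scan_distance(img, s2, kind)$data
    expect_true(all(d2 <= d1 + 1e-12))
  }
})

test_that("empty seed sets are rejected", {
  expect_error(raster_scan_distance(NULL, matrix(FALSE, 5, 5), "unit"),
               "empty")
})

test_that("segment_slice recovers a bright disc from centre/ring seeds", {
  img <- matrix(50, 90, 90)
  img[disc_matrix(90, 90, 45, 45, 14)] <- 350
  img <- aortaseg:::gaussian_blur_2d(img, 1)
  seeds <- initial_seeds_from_circle(list(x = 45, y = 45, r = 14),
                                     c(90L, 90L))
  lab <- segment_slice(img, seeds)
  truth <- disc_matrix(90, 90, 45, 45, 14)
  inter <- sum(lab == 1L & truth)
  dsc <- 2 * inter / (sum(lab == 1L) + sum(truth))
  expect_gte(dsc, 0.95)
})

test_that("swapping seed classes yields the complementary labeling", {
  img <- matrix(50, 70, 70)
  img[disc_matrix(70, 70, 35, 35, 12)] <- 350
  img <- aortaseg:::gaussian_blur_2d(img, 1)
  seeds <- initial_seeds_from_circle(list(x = 35, y = 35, r = 12),
                                     c(70L, 70L))
  swapped <- seeds
  swapped[seeds == 1L] <- 2L
  swapped[seeds == 2L] <- 1L
  lab <- segment_slice(img, seeds)
  lab_sw <- segment_slice(img, swapped)
  # the boundary may move only where the tie rule differs; interiors flip
  core <- disc_matrix(70, 70, 35, 35, 9)
  far <- !disc_matrix(70, 70, 35, 35, 16) & disc_matrix(70, 70, 35, 35, 30)
  expect_true(all(lab[core] == 1L) && all(lab_sw[core] == 0L))
  expect_true(all(lab[far] == 0L) && all(lab_sw[far] == 1L))
})

test_that("on a constant image ties go to background", {
  img <- matrix(100, 40, 40)
  seeds <- matrix(0L, 40, 40)
  seeds[20, 20] <- 1L
  seeds[5, 5] <- 2L
  lab <- segment_slice(img, seeds)
  # all gradient weights are zero: both distances are 0 everywhere, and the
  # tie rule labels the whole zero-cost component background
  expect_true(all(lab == 0L))
})

test_that("segment_slice requires both seed classes", {
  img <- matrix(0, 10, 10)
  s <- matrix(0L, 10, 10); s[5, 5] <- 1L
  expect_error(segment_slice(img, s), "background seeds")
  s2 <- matrix(0L, 10, 10); s2[2, 2] <- 2L
  expect_error(segment_slice(img, s2), "aorta seeds")
})

test_that("initial seeds sit at the centre with a clipped background ring", {
  seeds <- initial_seeds_from_circle(list(x = 64, y = 64, r = 14),
                                     c(128L, 128L))
  expect_equal(seeds[65, 65], 1L)
  expect_equal(sum(seeds == 1L), 1L)
  ring <- which(seeds == 2L, arr.ind = TRUE)
  d <- sqrt((ring[, 1] - 1 - 64)^2 + (ring[, 2] - 1 - 64)^2)
  expect_true(all(abs(d - 42) <= 0.5 + 1e-9))
  # near-corner centre: ring clipped but still nonempty
  seeds2 <- initial_seeds_from_circle(list(x = 5, y = 5, r = 14),
                                      c(128L, 128L))
  expect_gt(sum(seeds2 == 2L), 0)
  expect_equal(seeds2[6, 6], 1L)
  expect_error(initial_seeds_from_circle(list(x = 5, y = 5, r = 0),
                                         c(128L, 128L)), "positive")
})
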