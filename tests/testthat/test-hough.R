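make_disc_slice <- function(ny, nx, discs, background = 50) {
  sl <- matrix(background, ny, nx)
  for (d in discs) sl[disc_matrix(ny, nx, d$x, d$y, d$r)] <- d$value
  sl
}

test_that("detect_circles recovers clean discs within 2 px", {
  sl <- make_disc_slice(120, 120, list(list(x = 60, y = 50, r = 12, value = 350)))
  cand <- detect_circles(sl, r_min = 8, r_max = 20)
  expect_gt(nrow(cand), 0)
  expect_lt(abs(cand$x[1] - 60), 2)
  expect_lt(abs(cand$y[1] - 50), 2)
  expect_lt(abs(cand$r[1] - 12), 2)
})

test_that("detect_circles returns an empty list on constant slices", {
  expect_equal(nrow(detect_circles(matrix(100, 80, 80))), 0)
})

test_that("detect_circles finds both discs of a two-tube slice", {
  sl <- make_disc_slice(120, 120,
                        list(list(x = 40, y = 45, r = 14, value = 350),
                             list(x = 85, y = 80, r = 9, value = 350)))
  cand <- detect_circles(sl, r_min = 6, r_max = 20)
  expect_gte(nrow(cand), 2)
  d_big <- sqrt((cand$x - 40)^2 + (cand$y - 45)^2)
  d_small <- sqrt((cand$x - 85)^2 + (cand$y - 80)^2)
  expect_true(any(d_big < 2 & abs(cand$r - 14) <= 2))
  expect_true(any(d_small < 2 & abs(cand$r - 9) <= 2))
})

test_that("detect_circles enforces its preconditions", {
  sl <- matrix(0, 40, 40)
  expect_error(detect_circles(sl, r_min = 2, r_max = 10), "r_min")
  expect_error(detect_circles(sl, r_min = 10, r_max = 10), "r_max")
})

test_that("intensity_ratio measures the in-window interior fraction", {
  sl <- matrix(0, 100, 100)
  circ <- list(x = 50, y = 50, r = 10)
  sl[disc_matrix(100, 100, 50, 50, 10)] <- 300
  expect_equal(intensity_ratio(sl, circ, 200, 500), 1.0)
  expect_equal(intensity_ratio(sl, circ, 400, 500), 0.0)
  # half the interior in-range: left half 300, right half 0
  sl2 <- matrix(0, 100, 100)
  half <- disc_matrix(100, 100, 50, 50, 10) &
    matrix(0:99, 100, 100, byrow = TRUE) <= 50
  sl2[half] <- 300
  expect_lt(abs(intensity_ratio(sl2, list(x = 50, y = 50, r = 10),
                                200, 500) - 0.5), 0.05)
  # fully outside the image is an error
  expect_error(intensity_ratio(sl, list(x = 500, y = 500, r = 5), 0, 1),
               "outside")
})

test_that("select_aorta_pair prefers contrast-filled circles and labels by radius", {
  sl <- make_disc_slice(120, 120,
                        list(list(x = 40, y = 45, r = 14, value = 350),
                             list(x = 85, y = 80, r = 9, value = 350),
                             list(x = 85, y = 25, r = 12, value = 100)))
  cand <- detect_circles(sl, r_min = 6, r_max = 20)
  pair <- select_aorta_pair(cand, sl)
  expect_false(is.null(pair))
  expect_lt(abs(pair$ascending$x - 40), 2)
  expect_equal(pair$ascending$r > pair$descending$r, TRUE)
  # the dark distractor never enters the pair
  expect_gt(min(pair$ascending$intensity_ratio,
                pair$descending$intensity_ratio), 0.8)
  expect_gt(sqrt((pair$descending$x - 85)^2 + (pair$descending$y - 80)^2) <
              3, 0)
})

test_that("select_aorta_pair returns NULL with fewer than two eligible circles", {
  sl <- make_disc_slice(120, 120, list(list(x = 60, y = 60, r = 12, value = 350)))
  cand <- detect_circles(sl, r_min = 6, r_max = 20)
  expect_null(select_aorta_pair(cand, sl))
})

test_that("stability_energy matches hand-computable windows", {
  base <- data.frame(slice = 1:11, x = 10, y = 20, r = 5)
  expect_equal(stability_energy(base, 6), 0)
  # diameters one px larger on the 10 non-central slices -> 10 x |1|
  shifted <- base
  shifted$r[shifted$slice != 6] <- 5.5
  expect_equal(stability_energy(shifted, 6), 10)
  # centres drifting 1 px per slice in x, constant diameter -> 2*(1+..+5)
  drift <- base
  drift$x <- 10 + drift$slice
  expect_equal(stability_energy(drift, 6), 30)
})

test_that("stability_energy equals a direct-summation oracle on random windows", {
  set.seed(31)
  for (rep in 1:100) {
    k <- sample(6:50, 1)
    circles <- data.frame(slice = (k - 5):(k + 5),
                          x = runif(11, 0, 100), y = runif(11, 0, 100),
                          r = runif(11, 5, 20))
    ck <- circles[circles$slice == k, ]
    oracle <- sum(abs(2 * circles$r - 2 * ck$r) +
                    sqrt((circles$x - ck$x)^2 + (circles$y - ck$y)^2))
    expect_equal(stability_energy(circles, k), oracle, tolerance = 1e-12)
  }
})

test_that("stability_energy is symmetric under relabeling of the off-centre slices", {
  set.seed(17)
  circles <- data.frame(slice = 1:11, x = runif(11, 0, 50),
                        y = runif(11, 0, 50), r = runif(11, 5, 15))
  e <- stability_energy(circles, 6)
  expect_gte(e, 0)
  perm <- circles
  others <- perm$slice != 6
  reord <- sample(which(others))
  perm[others, c("x", "y", "r")] <- circles[reord, c("x", "y", "r")]
  expect_equal(stability_energy(perm, 6), e, tolerance = 1e-12)
})

test_that("strict mode yields Inf on windows with missing slices; best-effort normalises", {
  circles <- data.frame(slice = c(1:4, 6:11), x = 10, y = 10, r = 5)
  expect_equal(stability_energy(circles, 6, strict = TRUE), Inf)
  expect_equal(stability_energy(circles, 6, strict = FALSE), 0)
})

test_that("select_initial_circle lands on the true ascending tube", {
  ph <- small_phantom(seed = 3L)
  sel <- select_initial_circle(ph$volume)
  z <- sel$chosen$slice
  true_x <- 30 + 0.2 * (z - 1)
  expect_lt(abs(sel$chosen$x - true_x), 2)
  expect_lt(abs(sel$chosen$y - 40), 2)
  expect_lt(abs(sel$chosen$r - 12), 2)
})

test_that("an 11-slice-stable selection survives a 3-slice bright distractor", {
  nz <- 24L
  asc <- tube_spec(30, 40, 12, intensity = 350, nz = nz)
  desc <- tube_spec(68, 64, 8, intensity = 350, nz = nz)
  spec <- phantom_spec(c(nz, 96L, 96L), asc, desc,
                       distractors = list(
                         list(z1 = 10, z2 = 12, x = 30, y = 75, r = 13,
                              intensity = 350)),
                       background_intensity = 50, noise_sigma = 5,
                       blur_sigma = 1, seed = 5L)
  ph <- generate_phantom(spec)
  sel <- select_initial_circle(ph$volume)
  expect_lt(abs(sel$chosen$x - 30), 2)
  expect_lt(abs(sel$chosen$y - 40), 2)
})

test_that("volumes with no bright circles raise a detection failure", {
  vol <- aorta_volume(array(100, c(20, 64, 64)))
  expect_error(select_initial_circle(vol), "detection failure")
})

test_that("detection is equivariant to integer translation of the content", {
  ph <- small_phantom(seed = 9L, nz = 16L, noise = 0)
  sel1 <- select_initial_circle(ph$volume)
  shifted <- ph$volume$data
  shifted <- shifted[, c(9:dim(shifted)[2], 1:8), c(5:dim(shifted)[3], 1:4)]
  # content moved by (-8, -4) in (y, x); wrap-around regions are far away
  sel2 <- select_initial_circle(aorta_volume(shifted))
  expect_equal(sel2$chosen$x, sel1$chosen$x - 4, tolerance = 1)
  expect_equal(sel2$chosen$y, sel1$chosen$y - 8, tolerance = 1)
  expect_equal(sel2$chosen$r, sel1$chosen$r)
})
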