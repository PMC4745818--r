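ellipse_matrix <- function(ny, nx, cx, cy, a, b) {
  yy <- matrix(0:(ny - 1), ny, nx)
  xx <- matrix(0:(nx - 1), ny, nx, byrow = TRUE)
  ((xx - cx) / a)^2 + ((yy - cy) / b)^2 <= 1
}

crescent_matrix <- function(ny, nx) {
  disc_matrix(ny, nx, 32, 32, 18) & !disc_matrix(ny, nx, 40, 32, 14)
}

to_labels <- function(logical_mask) {
  out <- matrix(0L, nrow(logical_mask), ncol(logical_mask))
  out[logical_mask] <- 1L
  out
}

# independent neighbourhood-scan oracle for the border set
border_scan_oracle <- function(lab) {
  ny <- nrow(lab); nx <- ncol(lab)
  out <- matrix(FALSE, ny, nx)
  for (i in 1:ny) for (j in 1:nx) {
    for (di in -1:1) for (dj in -1:1) {
      if (di == 0 && dj == 0) next
      pi <- i + di; pj <- j + dj
      if (pi < 1 || pi > ny || pj < 1 || pj > nx) next
      if (lab[pi, pj] != lab[i, j]) out[i, j] <- TRUE
    }
  }
  out
}

test_that("border_pixels marks exactly the label discontinuities", {
  expect_equal(sum(border_pixels(matrix(0L, 20, 20))), 0)
  single <- matrix(0L, 9, 9); single[5, 5] <- 1L
  b <- border_pixels(single)
  expect_true(b[5, 5])
  expect_equal(sum(b), 9)  # the pixel and its 8 neighbours
  # filled disc: matches a direct neighbourhood-scan oracle, and the
  # double-ring size is on the order of two circumferences
  lab <- to_labels(disc_matrix(64, 64, 32, 32, 10))
  b2 <- border_pixels(lab)
  expect_identical(b2, border_scan_oracle(lab))
  expect_lt(abs(sum(b2) - 2 * 2 * pi * 10) / (2 * 2 * pi * 10), 0.35)
})

test_that("border_distance approximates Euclidean distance to the boundary", {
  lab <- to_labels(disc_matrix(41, 41, 20, 20, 10))
  dm <- border_distance(lab)
  expect_true(all(dm$data >= 0))
  border <- border_pixels(lab)
  expect_true(all(dm$data[border] == 0))
  # centre pixel roughly one radius from the border (chamfer error <= 8%,
  # plus rasterization of the digital ring)
  centre_d <- dm$data[21, 21]
  expect_lt(abs(centre_d - 10) / 10, 0.08 + 0.1)
  expect_error(border_distance(matrix(1L, 10, 10)), "constant")
})

test_that("transferred aorta seeds equal disc erosion within chamfer tolerance", {
  shapes <- list(
    disc = disc_matrix(64, 64, 32, 32, 10),
    ellipse = ellipse_matrix(64, 64, 32, 32, 16, 9),
    crescent = crescent_matrix(64, 64)
  )
  t_a <- 3
  for (nm in names(shapes)) {
    lab <- to_labels(shapes[[nm]])
    seeds <- transfer_seeds(lab, transfer_config(t_a = t_a))
    fg <- seeds == 1L
    # Euclidean erosion oracle: depth = distance to the background class;
    # the chamfer metric overestimates Euclidean by at most ~8.2%
    depth <- euclid_dist_to_set(lab == 0L)
    definitely_kept <- lab == 1L & depth > t_a * 1.0824
    definitely_dropped <- !(lab == 1L & depth > t_a)
    expect_true(all(fg[definitely_kept]), info = nm)
    expect_true(!any(fg & definitely_dropped & depth <= t_a / 1.0824),
                info = nm)
  }
})

test_that("seed area matches the morphological erosion oracle within 10%", {
  skip_if_not_installed("EBImage")
  t_a <- 3
  for (shape in list(disc_matrix(64, 64, 32, 32, 10),
                     ellipse_matrix(64, 64, 32, 32, 16, 9))) {
    lab <- to_labels(shape)
    seeds <- transfer_seeds(lab, transfer_config(t_a = t_a))
    brush <- EBImage::makeBrush(2 * t_a + 1, shape = "disc")
    eroded <- EBImage::erode(EBImage::Image(lab), brush)
    n_oracle <- sum(eroded@.Data == 1)
    expect_lt(abs(sum(seeds == 1L) - n_oracle) / n_oracle, 0.10)
  }
})

test_that("a threshold above the inradius empties the aorta seed class", {
  lab <- to_labels(disc_matrix(64, 64, 32, 32, 10))
  seeds <- transfer_seeds(lab, transfer_config(t_a = 12))
  expect_equal(sum(seeds == 1L), 0)
  st <- should_stop(seeds)
  expect_true(st$stop)
  expect_equal(st$reason, "no_foreground_seed")
})

test_that("background seeds fall inside the (t_min, t_max) band outside the shape", {
  lab <- to_labels(disc_matrix(64, 64, 32, 32, 10))
  seeds <- transfer_seeds(lab, transfer_config(t_a = 3, t_min = 2, t_max = 6))
  bg <- which(seeds == 2L, arr.ind = TRUE)
  expect_gt(nrow(bg), 0)
  # all background seeds are in the reference background
  expect_true(all(lab[bg] == 0L))
  # and within the (t_min, t_max) band of Euclidean distance to the shape,
  # allowing the ~8% chamfer overestimate
  d_fg <- euclid_dist_to_set(lab == 1L)[bg]
  expect_true(all(d_fg > 2 / 1.0824 - 1e-9))
  expect_true(all(d_fg < 6))
  # none inside the disc
  expect_true(!any(disc_matrix(64, 64, 32, 32, 10)[bg]))
})

test_that("transfer is monotone in t_a and classes are disjoint", {
  lab <- to_labels(ellipse_matrix(64, 64, 30, 34, 14, 10))
  prev <- NULL
  for (t_a in c(0.5, 2, 4, 6, 9)) {
    seeds <- transfer_seeds(lab, transfer_config(t_a = t_a))
    fg <- seeds == 1L
    expect_equal(sum(fg & seeds == 2L), 0)
    if (!is.null(prev)) expect_true(all(fg <= prev))
    prev <- fg
  }
  # t_a -> 0+ is the identity erosion: the full reference foreground
  seeds0 <- transfer_seeds(lab, transfer_config(t_a = 1e-9))
  expect_identical(seeds0 == 1L, lab == 1L)
})

test_that("adaptive t_a scales with the foreground equivalent radius", {
  small <- to_labels(disc_matrix(64, 64, 32, 32, 6))
  big <- to_labels(disc_matrix(64, 64, 32, 32, 20))
  s_small <- transfer_seeds(small, transfer_config())
  s_big <- transfer_seeds(big, transfer_config())
  expect_equal(attr(s_small, "t_a"), 4)          # floored at t_a_min
  expect_equal(attr(s_big, "t_a"), 0.25 * sqrt(sum(big) / pi))
  expect_gt(attr(s_big, "t_a"), attr(s_small, "t_a"))
})

test_that("should_stop only fires on an empty aorta class", {
  s <- matrix(0L, 8, 8)
  s[3, 3] <- 1L
  expect_false(should_stop(s)$stop)
  s[3, 3] <- 0L
  expect_true(should_stop(s)$stop)
})

test_that("transfer_config validates its thresholds", {
  expect_error(transfer_config(t_a = -1), "positive")
  expect_error(transfer_config(t_min = 5, t_max = 3), "t_min")
  expect_error(transfer_seeds(matrix(0L, 8, 8)), "no foreground")
})
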