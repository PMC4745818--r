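# 8-connected binary dilation by one pixel (matrix shifts).
dilate8 <- function(m) {
  ny <- nrow(m); nx <- ncol(m)
  out <- m
  sh <- function(di, dj) {
    s <- matrix(FALSE, ny, nx)
    ys <- max(1, 1 + di):min(ny, ny + di)
    xs <- max(1, 1 + dj):min(nx, nx + dj)
    s[ys, xs] <- m[ys - di, xs - dj]
    s
  }
  for (di in -1:1) for (dj in -1:1)
    if (di != 0 || dj != 0) out <- out | sh(di, dj)
  out
}

# Keep the 8-connected foreground component(s) reachable from `seeds`.
seed_component <- function(labels, seeds) {
  fg <- labels == 1L
  comp <- fg & seeds
  if (!any(comp)) {
    if (!any(fg)) return(matrix(0L, nrow(labels), ncol(labels)))
    # no seed inside the foreground: fall back to the largest component
    comp <- largest_component_seed(fg)
  }
  repeat {
    grown <- dilate8(comp) & fg
    if (sum(grown) == sum(comp)) break
    comp <- grown
  }
  out <- matrix(0L, nrow(labels), ncol(labels))
  out[comp] <- 1L
  out
}

largest_component_seed <- function(fg) {
  remaining <- fg
  best <- NULL; best_n <- -1L
  while (any(remaining)) {
    idx <- which(remaining)[1]
    comp <- matrix(FALSE, nrow(fg), ncol(fg)); comp[idx] <- TRUE
    repeat {
      grown <- dilate8(comp) & remaining
      if (sum(grown) == sum(comp)) break
      comp <- grown
    }
    if (sum(comp) > best_n) { best <- comp; best_n <- sum(comp) }
    remaining <- remaining & !comp
  }
  best
}

# Ring-rule fallback when the background band transfers no seeds: place a
# 1-px ring of background seeds 1.5 equivalent diameters from the current
# foreground centroid.
fallback_background_ring <- function(seeds) {
  fg <- which(seeds == 1L, arr.ind = TRUE)
  d_eq <- 2 * sqrt(nrow(fg) / pi)
  cy <- mean(fg[, 1]) - 1; cx <- mean(fg[, 2]) - 1
  ring_r <- 1.5 * d_eq
  ny <- nrow(seeds); nx <- ncol(seeds)
  yy <- matrix(0:(ny - 1), ny, nx)
  xx <- matrix(0:(nx - 1), ny, nx, byrow = TRUE)
  ring <- abs(sqrt((xx - cx)^2 + (yy - cy)^2) - ring_r) <= 0.5
  ring <- ring & seeds == 0L
  seeds[ring] <- 2L
  seeds
}

#' Segment the ascending aorta in a 3D CT volume
#'
#' The full automatic pipeline: detect the most stable ascending aortic
#' circle ([select_initial_circle()]), build the VOI around it
#' ([build_voi()]), segment the initial slice from the circle seeds
#' ([initial_seeds_from_circle()], [segment_slice()]), then propagate
#' downward (toward the valve) and upward (toward the arch), each direction
#' independently from the initial slice, by transferring seeds to the next
#' slice ([transfer_seeds()]) and re-segmenting, until the aorta seed class
#' empties ([should_stop()]) or the volume ends. Each slice keeps only the
#' foreground component connected to its seeds, so the 3D result is a
#' single connected tube.
#'
#' @param volume An [aorta_volume()].
#' @param config Configuration from [aortaseg_config()].
#' @return List of class `segmentation_result`: `mask` ([label_mask()] over
#'   the full volume), `initial_slice` (1-based z), `initial_circle`,
#'   `voi`, `per_slice_log` (data.frame: z, direction, n_fg_seeds,
#'   n_bg_seeds, n_fg_pixels, passes), `termination` (list up/down with
#'   reasons `no_foreground_seed`, `volume_boundary` or `leak_guard`),
#'   `selection_mode`.
#' @export
segment_aorta <- function(volume, config = aortaseg_config()) {
  stopifnot(inherits(volume, "aorta_volume"))
  sel <- select_initial_circle(volume, config)
  shape <- dim(volume$data)
  nz <- shape[1]
  voi <- if (isTRUE(config$pipeline$use_voi)) {
    build_voi(sel$chosen, shape)
  } else {
    structure(list(x1 = 0L, x2 = as.integer(shape[3]),
                   y1 = 0L, y2 = as.integer(shape[2]),
                   z1 = 0L, z2 = as.integer(nz)), class = "voi_box")
  }
  circle_voi <- list(x = sel$chosen$x - voi$x1, y = sel$chosen$y - voi$y1,
                     r = sel$chosen$r)
  m <- sel$chosen$slice
  gp <- config$geodesic
  tc <- transfer_config(t_a = config$transfer$t_a_px,
                        t_min = config$transfer$t_min_px,
                        t_max = config$transfer$t_max_px,
                        t_a_fraction = config$transfer$t_a_fraction,
                        t_a_min = config$transfer$t_a_min_px)

  crop <- function(z) crop_slice_to_voi(axial_slice(volume, z), voi)
  seg_one <- function(z, seeds) {
    lab <- segment_slice(crop(z), seeds, max_passes = gp$max_passes,
                         tolerance = gp$tolerance)
    passes <- attr(lab, "passes")
    lab <- seed_component(lab, seeds == 1L)
    attr(lab, "passes") <- passes
    lab
  }

  seeds0 <- initial_seeds_from_circle(circle_voi,
                                      c(voi$y2 - voi$y1, voi$x2 - voi$x1))
  lab_m <- seg_one(m, seeds0)
  if (!any(lab_m == 1L))
    stop("segmentation produced no foreground on the initial slice",
         call. = FALSE)
  initial_area <- sum(lab_m == 1L)
  guard <- config$pipeline$leak_guard_ratio

  slices <- vector("list", nz)
  slices[[m]] <- lab_m
  log_rows <- list(
    data.frame(z = m, direction = "initial", n_fg_seeds = sum(seeds0 == 1L),
               n_bg_seeds = sum(seeds0 == 2L), n_fg_pixels = initial_area,
               passes = max(attr(lab_m, "passes")))
  )
  termination <- list(up = NA_character_, down = NA_character_)

  for (dir_name in c("down", "up")) {
    step <- if (dir_name == "down") -1L else 1L
    ref <- lab_m
    z <- m + step
    reason <- NA_character_
    while (z >= 1L && z <= nz) {
      seeds <- transfer_seeds(ref, tc)
      st <- should_stop(seeds)
      if (st$stop) { reason <- st$reason; break }
      if (!any(seeds == 2L)) {
        warning("degenerate seeds on slice ", z,
                ": background band empty, falling back to ring seeds")
        seeds <- fallback_background_ring(seeds)
      }
      lab <- seg_one(z, seeds)
      n_fg <- sum(lab == 1L)
      if (n_fg == 0L) { reason <- "no_foreground_seed"; break }
      if (is.finite(guard) && n_fg > guard * initial_area) {
        reason <- "leak_guard"; break
      }
      slices[[z]] <- lab
      log_rows[[length(log_rows) + 1L]] <-
        data.frame(z = z, direction = dir_name,
                   n_fg_seeds = sum(seeds == 1L),
                   n_bg_seeds = sum(seeds == 2L), n_fg_pixels = n_fg,
                   passes = max(attr(lab, "passes")))
      ref <- lab
      z <- z + step
    }
    if (is.na(reason)) reason <- "volume_boundary"
    termination[[dir_name]] <- reason
  }

  mask_arr <- array(0L, dim = shape)
  for (z in seq_len(nz)) {
    if (!is.null(slices[[z]]))
      mask_arr[z, (voi$y1 + 1):voi$y2, (voi$x1 + 1):voi$x2] <- slices[[z]]
  }
  log_df <- do.call(rbind, log_rows)
  log_df <- log_df[order(log_df$z), , drop = FALSE]
  rownames(log_df) <- NULL
  structure(list(mask = label_mask(mask_arr, spacing = volume$spacing),
                 initial_slice = m, initial_circle = sel$chosen, voi = voi,
                 per_slice_log = log_df, termination = termination,
                 selection_mode = sel$mode, energy = sel$energy),
            class = "segmentation_result")
}

#' @export
print.segmentation_result <- function(x, ...) {
  zr <- range(x$per_slice_log$z)
  cat(sprintf("<segmentation_result> %d foreground voxels on slices %d..%d (initial %d)\n",
              sum(x$mask$data), zr[1], zr[2], x$initial_slice))
  cat(sprintf("  termination: up = %s, down = %s\n",
              x$termination$up, x$termination$down))
  invisible(x)
}

#' Plot one axial slice with optional mask and circle overlay
#'
#' Base-graphics viewer for quick inspection: grey-scale slice, mask
#' boundary in red, circle in blue.
#'
#' @param volume An [aorta_volume()].
#' @param z 1-based slice index.
#' @param mask Optional [label_mask()] overlay.
#' @param circle Optional circle (`x`, `y`, `r`, 0-based px).
#' @export
plot_slice <- function(volume, z, mask = NULL, circle = NULL) {
  sl <- axial_slice(volume, z)
  ny <- nrow(sl); nx <- ncol(sl)
  graphics::image(0:(nx - 1), 0:(ny - 1), t(sl)[, ny:1],
                  col = grDevices::gray.colors(256), asp = 1,
                  xlab = "x (px)", ylab = "y (px)",
                  main = sprintf("slice %d", z), useRaster = TRUE)
  if (!is.null(mask)) {
    ms <- axial_slice(mask, z)
    b <- which(border_pixels(ms) & ms == 1L, arr.ind = TRUE)
    if (nrow(b)) graphics::points(b[, 2] - 1, ny - b[, 1], pch = ".",
                                  col = "red", cex = 2)
  }
  if (!is.null(circle)) {
    th <- seq(0, 2 * pi, length.out = 200)
    graphics::lines(circle$x + circle$r * cos(th),
                    ny - 1 - (circle$y + circle$r * sin(th)), col = "blue")
  }
  invisible(NULL)
}
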