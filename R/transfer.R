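#' Seed-transfer thresholds
#'
#' Bundles the thresholds of the adaptive seed transfer. `t_a` erodes the
#' reference foreground: only pixels deeper than `t_a` from the boundary
#' transfer as aorta seeds, so the foreground seed shrinks with the vessel
#' and transfer self-terminates once the cross-section becomes small.
#' `t_min`/`t_max` delimit the band of reference-background pixels, just
#' outside the moving boundary, that transfer as background seeds.
#'
#' When `t_a` is `NA` it is chosen adaptively per slice as
#' `max(t_a_min, t_a_fraction * r_eq)` where `r_eq = sqrt(area/pi)` is the
#' equivalent radius of the reference foreground; a fixed threshold tuned
#' to a large section would otherwise terminate early on small ones.
#'
#' @param t_a Foreground erosion threshold in px, or `NA` for adaptive.
#' @param t_min,t_max Background band bounds in px (`0 < t_min < t_max`).
#' @param t_a_fraction,t_a_min Adaptive rule parameters.
#' @return List of class `transfer_config`.
#' @export
transfer_config <- function(t_a = NA_real_, t_min = 2, t_max = 10,
                            t_a_fraction = 0.25, t_a_min = 4) {
  if (!is.na(t_a) && t_a <= 0) stop("t_a must be positive", call. = FALSE)
  if (!(t_min > 0 && t_max > t_min))
    stop("need 0 < t_min < t_max", call. = FALSE)
  structure(list(t_a = t_a, t_min = t_min, t_max = t_max,
                 t_a_fraction = t_a_fraction, t_a_min = t_a_min),
            class = "transfer_config")
}

#' Border pixels of a binary label image
#'
#' A pixel (of either class) is a border pixel when at least one of its 8
#' neighbours carries the other label. Constant label maps have no border.
#'
#' @param labels 2D 0/1 integer matrix.
#' @return Logical matrix marking the border set.
#' @export
border_pixels <- function(labels) {
  storage.mode(labels) <- "integer"
  .border_pixels_cpp(labels)
}

#' Distance to the segmentation border
#'
#' Unit-weight raster-scan (chamfer) distance from the border set of a
#' binary label image — the fast approximation of the Euclidean distance to
#' the nearest boundary pixel that the seed-transfer thresholds are
#' compared against.
#'
#' @param labels 2D 0/1 integer matrix with both labels present.
#' @param max_passes,tolerance Passed to [raster_scan_distance()].
#' @return A `distance_map` (unit weights).
#' @export
border_distance <- function(labels, max_passes = 64, tolerance = 1e-8) {
  border <- border_pixels(labels)
  if (!any(border))
    stop("label map is constant: no border to measure from", call. = FALSE)
  raster_scan_distance(NULL, border, "unit", max_passes, tolerance)
}

#' Transfer segmentation seeds to the adjacent slice
#'
#' Given the segmented reference slice, marks the seed mask for its
#' neighbour at the same (x, y) coordinates: a pixel becomes an aorta seed
#' when the reference pixel is aorta and lies deeper than `t_a` from the
#' boundary; it becomes a background seed when the reference pixel is
#' background and its border distance falls inside the `(t_min, t_max)`
#' band. Everything else stays unlabeled and is decided by the geodesic
#' segmentation of the new slice.
#'
#' The border distance each threshold is compared against is the chamfer
#' distance to the *opposite* class (for an aorta pixel, to the nearest
#' background pixel, and vice versa). Measured this way, thresholding at
#' `t_a` is exactly morphological erosion of the foreground by a disc of
#' radius `t_a` (up to the ~8\% chamfer-metric overestimate), and the
#' background band is the annulus `t_min`..`t_max` px outside the moving
#' boundary; measuring to the border set itself would silently shift both
#' thresholds by one pixel.
#'
#' @param reference_labels 2D 0/1 integer matrix with at least one
#'   foreground pixel.
#' @param config A [transfer_config()].
#' @return Integer seed matrix (0/1/2). The aorta class may come back empty
#'   — that is the propagation stop signal, see [should_stop()].
#' @export
transfer_seeds <- function(reference_labels, config = transfer_config()) {
  storage.mode(reference_labels) <- "integer"
  n_fg <- sum(reference_labels == 1L)
  if (n_fg == 0L)
    stop("reference slice has no foreground to transfer from", call. = FALSE)
  t_a <- config$t_a
  if (is.na(t_a)) {
    r_eq <- sqrt(n_fg / pi)
    t_a <- max(config$t_a_min, config$t_a_fraction * r_eq)
  }
  seeds <- matrix(0L, nrow(reference_labels), ncol(reference_labels))
  if (any(reference_labels == 0L)) {
    d_to_bg <- raster_scan_distance(NULL, reference_labels == 0L, "unit")$data
    d_to_fg <- raster_scan_distance(NULL, reference_labels == 1L, "unit")$data
    seeds[reference_labels == 1L & d_to_bg > t_a] <- 1L
    seeds[reference_labels == 0L & d_to_fg > config$t_min &
            d_to_fg < config$t_max] <- 2L
  } else {
    seeds[] <- 1L  # all-foreground reference: everything transfers
  }
  attr(seeds, "t_a") <- t_a
  seeds
}

#' Decide whether slice propagation should stop
#'
#' Propagation stops when no aorta seed survives the transfer: the
#' reference foreground has become too small to erode, which is how the
#' method detects the end of the vessel.
#'
#' @param next_seeds Seed matrix from [transfer_seeds()].
#' @return List `stop` (logical) and `reason` (`"no_foreground_seed"` or
#'   `NA`).
#' @export
should_stop <- function(next_seeds) {
  if (!any(next_seeds == 1L))
    list(stop = TRUE, reason = "no_foreground_seed")
  else
    list(stop = FALSE, reason = NA_character_)
}
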