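#' Per-edge cost of a step between two pixels
#'
#' The geodesic transform accumulates these costs along 8-connected paths.
#' With `weight_kind = "gradient_squared"` the cost discretises the
#' squared-gradient path integral: the finite-difference gradient along the
#' step, squared, times the step length — `((Ib - Ia)/len)^2 * len`. With
#' `weight_kind = "unit"` the cost is the step length itself, so the
#' accumulated distance is pure (chamfer) path length.
#'
#' @param intensity_a,intensity_b Intensities at the two endpoints.
#' @param step_length 1 for axial steps, `sqrt(2)` for diagonal steps.
#' @param weight_kind `"gradient_squared"` or `"unit"`.
#' @return Nonnegative scalar cost.
#' @export
edge_weight <- function(intensity_a, intensity_b, step_length,
                        weight_kind = c("gradient_squared", "unit")) {
  weight_kind <- match.arg(weight_kind)
  if (weight_kind == "unit") return(step_length)
  (intensity_b - intensity_a)^2 / step_length
}

#' Seeded geodesic distance map by multi-pass raster scans
#'
#' Computes, for every pixel, the minimum accumulated path cost to the seed
#' set over 8-connected paths, by alternating forward and backward chamfer
#' sweeps until no pixel changes by more than `tolerance` within a full
#' forward+backward cycle (or `max_passes` sweeps run). With nonnegative
#' costs the sweeps converge to the exact shortest-path distances on the
#' pixel graph; the convergence check makes the pass count self-limiting.
#'
#' @param slice_image 2D numeric matrix (y, x); may be `NULL` for unit
#'   weights.
#' @param seeds Logical or 0/1 matrix marking the seed pixels of one class.
#' @param weight_kind `"gradient_squared"` or `"unit"` (see
#'   [edge_weight()]).
#' @param max_passes Maximum number of sweeps (default 64).
#' @param tolerance Convergence tolerance on the per-cycle max change.
#' @return List of class `distance_map`: `data` (numeric matrix, 0 on
#'   seeds), `weight_kind`, `passes`, `converged`.
#' @export
raster_scan_distance <- function(slice_image, seeds,
                                 weight_kind = c("gradient_squared", "unit"),
                                 max_passes = 64, tolerance = 1e-8) {
  weight_kind <- match.arg(weight_kind)
  if (is.numeric(seeds)) seeds <- seeds != 0
  storage.mode(seeds) <- "logical"
  if (!any(seeds)) stop("seed set is empty", call. = FALSE)
  if (weight_kind == "gradient_squared" && is.null(slice_image))
    stop("slice_image is required for gradient weights", call. = FALSE)
  res <- .raster_scan_cpp(slice_image, seeds,
                          if (weight_kind == "gradient_squared") 1L else 0L,
                          as.integer(max_passes), tolerance)
  structure(list(data = res$distance, weight_kind = weight_kind,
                 passes = res$passes, converged = res$converged),
            class = "distance_map")
}

#' @export
print.distance_map <- function(x, ...) {
  cat(sprintf("<distance_map> %d x %d, %s weights, %d passes (%s)\n",
              nrow(x$data), ncol(x$data), x$weight_kind, x$passes,
              if (x$converged) "converged" else "pass limit"))
  invisible(x)
}

#' Binary geodesic segmentation of one axial slice
#'
#' Computes gradient-weighted geodesic distance maps from the aorta seeds
#' and from the background seeds, then labels each pixel by the shorter
#' distance: aorta where `D_A < D_B`, background otherwise (ties go to
#' background, the conservative choice against leakage toward the
#' ventricle).
#'
#' @param slice_image 2D numeric matrix (y, x).
#' @param seeds Integer matrix: 0 = unlabeled, 1 = aorta seed,
#'   2 = background seed. Both classes must be nonempty.
#' @param max_passes,tolerance Passed to [raster_scan_distance()].
#' @return Integer matrix of 0/1 labels, same shape as the slice.
#' @export
segment_slice <- function(slice_image, seeds, max_passes = 64,
                          tolerance = 1e-8) {
  if (!any(seeds == 1L)) stop("no aorta seeds", call. = FALSE)
  if (!any(seeds == 2L)) stop("no background seeds", call. = FALSE)
  da <- raster_scan_distance(slice_image, seeds == 1L, "gradient_squared",
                             max_passes, tolerance)
  db <- raster_scan_distance(slice_image, seeds == 2L, "gradient_squared",
                             max_passes, tolerance)
  lab <- matrix(0L, nrow(slice_image), ncol(slice_image))
  lab[da$data < db$data] <- 1L
  attr(lab, "passes") <- c(aorta = da$passes, background = db$passes)
  lab
}

#' Initial seed mask from the detected aortic circle
#'
#' The circle centre pixel becomes the single aorta seed; a 1-px-thick ring
#' of radius 1.5 diameters from the centre — comfortably outside the aorta
#' — becomes the background seeds, clipped to the slice.
#'
#' @param circle List or one-row data.frame with `x`, `y` (0-based) and `r`.
#' @param slice_shape Integer `(ny, nx)`.
#' @return Integer seed matrix (0 unlabeled / 1 aorta / 2 background).
#' @export
initial_seeds_from_circle <- function(circle, slice_shape) {
  ny <- slice_shape[1]; nx <- slice_shape[2]
  r <- circle$r
  if (is.null(r) || !is.finite(r) || r <= 0)
    stop("circle diameter must be positive", call. = FALSE)
  cx <- circle$x; cy <- circle$y
  seeds <- matrix(0L, ny, nx)
  ci <- round(cy) + 1L; cj <- round(cx) + 1L
  if (ci < 1L || ci > ny || cj < 1L || cj > nx)
    stop("circle centre outside the slice", call. = FALSE)
  ring_r <- 1.5 * 2 * r
  yy <- matrix(0:(ny - 1), ny, nx)
  xx <- matrix(0:(nx - 1), ny, nx, byrow = TRUE)
  dist <- sqrt((xx - cx)^2 + (yy - cy)^2)
  ring <- abs(dist - ring_r) <= 0.5
  if (!any(ring))
    stop("background ring lies entirely outside the slice", call. = FALSE)
  seeds[ring] <- 2L
  seeds[ci, cj] <- 1L
  seeds
}
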