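#' Build the volume of interest around the detected aortic circle
#'
#' The VOI is a box padded 3 circle-diameters away from the detected centre
#' in x and y, clamped to the image, and spanning the full z-range (the
#' ascending aorta slants in x as it reaches the chamber, so the box must
#' be generous):
#' \deqn{X_1 = \max(C_m(x) - 3\o C_m,\ 0),\quad X_2 = \min(C_m(x) + 3\o C_m,\ x_{size})}
#' and likewise for Y. Bounds are stored half-open `[x1, x2)` in 0-based
#' pixel coordinates after `floor`/`ceiling` rounding, so they compose
#' directly with array slicing.
#'
#' @param circle List or one-row data.frame with `x`, `y` (0-based px) and
#'   `r` (px).
#' @param volume_shape Integer length-3 `(nz, ny, nx)`.
#' @return List of class `voi_box` with `x1`, `x2`, `y1`, `y2`, `z1`, `z2`
#'   (half-open, 0-based).
#' @export
build_voi <- function(circle, volume_shape) {
  r <- circle$r
  if (is.null(r) || !is.finite(r) || r <= 0)
    stop("circle radius must be positive to build a VOI", call. = FALSE)
  d <- 2 * r
  nz <- volume_shape[1]; ny <- volume_shape[2]; nx <- volume_shape[3]
  x1 <- max(circle$x - 3 * d, 0)
  x2 <- min(circle$x + 3 * d, nx)
  y1 <- max(circle$y - 3 * d, 0)
  y2 <- min(circle$y + 3 * d, ny)
  structure(list(x1 = as.integer(floor(x1)), x2 = as.integer(ceiling(x2)),
                 y1 = as.integer(floor(y1)), y2 = as.integer(ceiling(y2)),
                 z1 = 0L, z2 = as.integer(nz)),
            class = "voi_box")
}

#' @export
print.voi_box <- function(x, ...) {
  cat(sprintf("<voi_box> x [%d, %d), y [%d, %d), z [%d, %d)\n",
              x$x1, x$x2, x$y1, x$y2, x$z1, x$z2))
  invisible(x)
}

# Crop a (y, x) slice matrix to the VOI. Returns the submatrix.
crop_slice_to_voi <- function(slice, voi) {
  slice[(voi$y1 + 1):voi$y2, (voi$x1 + 1):voi$x2, drop = FALSE]
}
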