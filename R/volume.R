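#' 3D scalar volume with voxel spacing
#'
#' Internal container for a CT volume. Voxel data are stored in a 3D array
#' indexed `(z, y, x)`: the first index is the axial slice, increasing toward
#' the aortic arch ("up"); the second is the image row (y); the third the
#' image column (x). Spacing is `(dz, dy, dx)` in millimetres.
#'
#' @param data 3D numeric array indexed `(z, y, x)`.
#' @param spacing Numeric length-3, `(dz, dy, dx)` in mm, all positive.
#' @param origin Numeric length-3 physical offset in mm.
#' @param intensity_units Label for the intensity scale, e.g. `"HU"`.
#' @return An object of class `aorta_volume`.
#' @export
aorta_volume <- function(data, spacing = c(1, 1, 1), origin = c(0, 0, 0),
                         intensity_units = "HU") {
  if (!is.array(data) || length(dim(data)) != 3L)
    stop("volume data must be a 3D array (z, y, x)", call. = FALSE)
  spacing <- as.numeric(spacing)
  if (length(spacing) != 3L || any(!is.finite(spacing)) || any(spacing <= 0))
    stop("spacing must be three positive numbers (dz, dy, dx)", call. = FALSE)
  structure(
    list(data = data, spacing = spacing, origin = as.numeric(origin),
         intensity_units = intensity_units),
    class = "aorta_volume"
  )
}

#' @export
print.aorta_volume <- function(x, ...) {
  d <- dim(x$data)
  cat(sprintf("<aorta_volume> %d slices of %d x %d (y x x), spacing %.3g/%.3g/%.3g mm (dz/dy/dx), units %s\n",
              d[1], d[2], d[3], x$spacing[1], x$spacing[2], x$spacing[3],
              x$intensity_units))
  invisible(x)
}

#' @export
dim.aorta_volume <- function(x) dim(x$data)

#' Binary label mask companion to a volume
#'
#' Integer-valued 3D mask on the same `(z, y, x)` grid as its volume.
#' Encoding: 0 = background, 1 = aorta.
#'
#' @param data 3D array of 0/1 values.
#' @param spacing Voxel spacing `(dz, dy, dx)` in mm.
#' @param origin Physical offset in mm.
#' @return An object of class `label_mask`.
#' @export
label_mask <- function(data, spacing = c(1, 1, 1), origin = c(0, 0, 0)) {
  if (!is.array(data) || length(dim(data)) != 3L)
    stop("mask data must be a 3D array (z, y, x)", call. = FALSE)
  vals <- unique(as.vector(data))
  if (!all(vals %in% c(0, 1)))
    stop("mask values must be exactly {0, 1}", call. = FALSE)
  storage.mode(data) <- "integer"
  structure(
    list(data = data, spacing = as.numeric(spacing), origin = as.numeric(origin)),
    class = "label_mask"
  )
}

#' @export
print.label_mask <- function(x, ...) {
  d <- dim(x$data)
  cat(sprintf("<label_mask> %d x %d x %d (z, y, x), %d foreground voxels\n",
              d[1], d[2], d[3], sum(x$data)))
  invisible(x)
}

#' @export
dim.label_mask <- function(x) dim(x$data)

# Check that a mask matches its companion volume grid.
check_mask_matches <- function(mask, volume) {
  if (!identical(dim(mask$data), dim(volume$data)))
    stop("mask shape does not match volume shape", call. = FALSE)
  invisible(TRUE)
}

#' Extract one axial slice as a 2D (y, x) matrix
#'
#' @param volume An `aorta_volume` or `label_mask`.
#' @param z 1-based slice index.
#' @return A numeric matrix indexed (y, x).
#' @export
axial_slice <- function(volume, z) {
  d <- if (inherits(volume, "aorta_volume") || inherits(volume, "label_mask"))
    volume$data else volume
  nz <- dim(d)[1]
  if (z < 1L || z > nz) stop("slice index out of range", call. = FALSE)
  matrix(d[z, , ], nrow = dim(d)[2], ncol = dim(d)[3])
}
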