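#' Tube description for the synthetic phantom
#'
#' A tube is a stack of filled discs, one per axial slice: per-slice centre
#' path `(x, y)` in 0-based pixels, per-slice radius in pixels (0 = tube
#' absent on that slice) and a constant intensity. Scalars are recycled
#' over `nz` slices.
#'
#' @param x,y Centre path (px, 0-based), scalar or length-`nz`.
#' @param r Radius per slice (px), scalar or length-`nz`.
#' @param intensity Disc intensity before blur/noise.
#' @param nz Number of slices to recycle to.
#' @return List of class `tube_spec`.
#' @export
tube_spec <- function(x, y, r, intensity, nz) {
  out <- list(x = rep_len(as.numeric(x), nz), y = rep_len(as.numeric(y), nz),
              r = rep_len(as.numeric(r), nz), intensity = intensity)
  class(out) <- "tube_spec"
  out
}

#' Specification of a synthetic CT phantom
#'
#' Describes a CT-like test volume with known ground truth: a bright
#' ascending-aorta-like tube (the only structure in the ground-truth mask),
#' a parallel narrower descending-aorta-like tube, optional distractor
#' discs and blobs, Gaussian blur and additive Gaussian noise. The
#' ascending radius must exceed the descending radius wherever both exist
#' — the caliber cue the circle selector relies on.
#'
#' @param shape Integer `(nz, ny, nx)`.
#' @param ascending_tube,descending_tube [tube_spec()] objects
#'   (`descending_tube` may be `NULL`).
#' @param distractors List of lists with `z1`, `z2` (1-based slice range),
#'   `x`, `y`, `r`, `intensity` — circular structures that are not aorta.
#' @param background_intensity Background level (default 50).
#' @param noise_sigma Additive Gaussian noise sd (applied after blur).
#' @param blur_sigma Gaussian blur sd in px (0 = none).
#' @param spacing Voxel spacing `(dz, dy, dx)` mm.
#' @param seed RNG seed making the phantom fully deterministic.
#' @return List of class `phantom_spec`.
#' @export
phantom_spec <- function(shape, ascending_tube, descending_tube = NULL,
                         distractors = list(), background_intensity = 50,
                         noise_sigma = 0, blur_sigma = 0,
                         spacing = c(1, 1, 1), seed = 0L) {
  stopifnot(length(shape) == 3L)
  nz <- shape[1]
  if (!inherits(ascending_tube, "tube_spec"))
    stop("ascending_tube must be a tube_spec", call. = FALSE)
  present <- ascending_tube$r > 0
  if (any(present & ascending_tube$r < 3))
    stop("tube radii must be >= 3 px where present", call. = FALSE)
  if (!is.null(descending_tube)) {
    both <- present & descending_tube$r > 0
    if (any(both & descending_tube$r >= ascending_tube$r))
      stop("ascending tube radius must exceed descending tube radius",
           call. = FALSE)
    dctr <- sqrt((ascending_tube$x - descending_tube$x)^2 +
                 (ascending_tube$y - descending_tube$y)^2)
    if (any(both & dctr < ascending_tube$r + descending_tube$r))
      stop("tubes overlap", call. = FALSE)
  }
  structure(list(shape = as.integer(shape), ascending_tube = ascending_tube,
                 descending_tube = descending_tube, distractors = distractors,
                 background_intensity = background_intensity,
                 noise_sigma = noise_sigma, blur_sigma = blur_sigma,
                 spacing = as.numeric(spacing), seed = as.integer(seed)),
            class = "phantom_spec")
}

# Rasterize a filled disc onto a (y, x) logical matrix; 0-based centre.
disc_mask <- function(ny, nx, cx, cy, r) {
  if (r <= 0) return(matrix(FALSE, ny, nx))
  yy <- matrix(0:(ny - 1), ny, nx)
  xx <- matrix(0:(nx - 1), ny, nx, byrow = TRUE)
  (xx - cx)^2 + (yy - cy)^2 <= r^2
}

# Separable Gaussian blur with edge replication.
gaussian_blur_2d <- function(img, sigma) {
  if (sigma <= 0) return(img)
  m <- max(1L, as.integer(ceiling(3 * sigma)))
  k <- exp(-((-m:m)^2) / (2 * sigma^2)); k <- k / sum(k)
  ny <- nrow(img); nx <- ncol(img)
  pad_idx <- function(n) pmin(pmax(seq_len(n + 2L * m) - m, 1L), n)
  # rows (y direction)
  p <- img[pad_idx(ny), , drop = FALSE]
  out <- matrix(0, ny, nx)
  for (o in -m:m) out <- out + k[o + m + 1L] * p[(m + o) + seq_len(ny), , drop = FALSE]
  # columns (x direction)
  p <- out[, pad_idx(nx), drop = FALSE]
  out2 <- matrix(0, ny, nx)
  for (o in -m:m) out2 <- out2 + k[o + m + 1L] * p[, (m + o) + seq_len(nx), drop = FALSE]
  out2
}

# Run code with a private RNG state, restoring the caller's afterwards.
with_phantom_seed <- function(seed, code) {
  old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
    get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
        rm(".Random.seed", envir = globalenv())
    } else assign(".Random.seed", old, envir = globalenv())
  })
  set.seed(seed)
  force(code)
}

#' Generate a synthetic phantom volume and its ground truth
#'
#' Renders the structures of a [phantom_spec()] slice by slice: background,
#' then distractors, then the descending and ascending tubes (drawn last so
#' the aorta-like tube overwrites anything it merges into), Gaussian blur,
#' then additive Gaussian noise. The ground-truth mask contains the
#' ascending tube discs only, rasterized by the centre-distance test, and
#' is never blurred or noised. Deterministic given `spec$seed`.
#'
#' @param spec A [phantom_spec()].
#' @return List with `volume` ([aorta_volume()]), `mask` ([label_mask()]).
#' @export
generate_phantom <- function(spec) {
  stopifnot(inherits(spec, "phantom_spec"))
  nz <- spec$shape[1]; ny <- spec$shape[2]; nx <- spec$shape[3]
  vol <- array(spec$background_intensity, dim = c(nz, ny, nx))
  msk <- array(0L, dim = c(nz, ny, nx))
  asc <- spec$ascending_tube; desc <- spec$descending_tube
  for (z in seq_len(nz)) {
    sl <- matrix(spec$background_intensity, ny, nx)
    for (d in spec$distractors) {
      if (z >= d$z1 && z <= d$z2)
        sl[disc_mask(ny, nx, d$x, d$y, d$r)] <- d$intensity
    }
    if (!is.null(desc) && desc$r[z] > 0)
      sl[disc_mask(ny, nx, desc$x[z], desc$y[z], desc$r[z])] <- desc$intensity
    if (asc$r[z] > 0) {
      dm <- disc_mask(ny, nx, asc$x[z], asc$y[z], asc$r[z])
      sl[dm] <- asc$intensity
      msk[z, , ][dm] <- 1L
    }
    if (spec$blur_sigma > 0) sl <- gaussian_blur_2d(sl, spec$blur_sigma)
    vol[z, , ] <- sl
  }
  if (spec$noise_sigma > 0) {
    vol <- vol + with_phantom_seed(spec$seed,
      array(stats::rnorm(length(vol), 0, spec$noise_sigma), dim = dim(vol)))
  }
  list(volume = aorta_volume(vol, spacing = spec$spacing,
                             intensity_units = "HU"),
       mask = label_mask(msk, spacing = spec$spacing))
}

#' Standard aorta phantom fixture
#'
#' A 80 x 128 x 128 volume emulating the mid-thoracic CCTA appearance the
#' segmenter expects: an ascending-aorta-like tube (radius 14 px, contrast
#' intensity 350, slanting +0.3 px/slice in x) that merges into a large,
#' more weakly enhanced ventricle-like blob at the low-z (valve) end and
#' tapers out before the high-z (arch) end; a parallel descending-aorta
#' tube (radius 9 px); a dark distractor disc and a short-lived bright
#' distractor disc that matches the aortic intensity for 3 slices only.
#' Background 50, blur sigma 1 px, noise sigma 8 (about 2.7% of the 300
#' contrast step).
#'
#' @param seed RNG seed for the noise.
#' @return List with `volume`, `mask` and the `spec` used.
#' @export
default_aorta_phantom <- function(seed = 0L) {
  nz <- 80L; ny <- 128L; nx <- 128L
  z <- seq_len(nz)
  r_asc <- numeric(nz)
  r_asc[5:70] <- 14
  r_asc[71:76] <- c(12, 10, 8, 6, 4, 3)
  x_asc <- 45 + 0.3 * pmax(z - 5, 0)
  y_asc <- rep(52, nz)
  asc <- tube_spec(x_asc, y_asc, r_asc, intensity = 350, nz = nz)
  r_desc <- numeric(nz)
  r_desc[5:68] <- 9
  r_desc[69:71] <- c(7, 5, 3)
  desc <- tube_spec(88, 84, r_desc, intensity = 350, nz = nz)
  distractors <- list(
    # ventricle-like blob the tube merges into at the valve end
    list(z1 = 1, z2 = 8, x = 58, y = 56, r = 30, intensity = 260),
    # dark circular structure (outside the contrast window)
    list(z1 = 10, z2 = 70, x = 30, y = 95, r = 12, intensity = 120),
    # bright circle matching the aorta, present on 3 slices only
    list(z1 = 40, z2 = 42, x = 100, y = 30, r = 11, intensity = 350)
  )
  spec <- phantom_spec(shape = c(nz, ny, nx), ascending_tube = asc,
                       descending_tube = desc, distractors = distractors,
                       background_intensity = 50, noise_sigma = 8,
                       blur_sigma = 1, spacing = c(1, 1, 1), seed = seed)
  ph <- generate_phantom(spec)
  list(volume = ph$volume, mask = ph$mask, spec = spec)
}
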