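#' Detect circle candidates on one axial slice
#'
#' Runs a circular Hough transform: pixels whose gradient magnitude exceeds
#' `edge_threshold` vote for every centre at distance r over the configured
#' radius range; accumulator peaks, normalised by circumference so different
#' radii compete fairly, are extracted greedily with non-maximum suppression
#' (each picked circle suppresses centres within its own radius, floored at
#' `r_min`). Candidates whose circle touches the image border are discarded.
#'
#' Coordinates follow the package convention: `(x, y)` are 0-based column /
#' row indices, radii in pixels.
#'
#' @param slice_image 2D numeric matrix indexed (y, x).
#' @param r_min,r_max Integer radius bounds in px (`r_min >= 3`).
#' @param max_candidates Maximum number of circles returned.
#' @param edge_threshold Gradient-magnitude threshold for edge voting.
#' @param min_score Minimum circumference-normalised vote fraction.
#' @return A data.frame with columns `x`, `y`, `r`, `score` (perimeter
#'   support fraction), sorted by decreasing score; zero rows if the slice
#'   is degenerate or nothing passes.
#' @export
detect_circles <- function(slice_image, r_min = 8, r_max = 30,
                           max_candidates = 8, edge_threshold = 40,
                           min_score = 0.3) {
  stopifnot(is.matrix(slice_image))
  r_min <- as.integer(round(r_min)); r_max <- as.integer(round(r_max))
  if (r_min < 3L) stop("r_min must be >= 3 px", call. = FALSE)
  if (r_max <= r_min) stop("r_max must exceed r_min", call. = FALSE)
  ny <- nrow(slice_image); nx <- ncol(slice_image)

  g <- gradient_magnitude(slice_image)
  edge <- which(g > edge_threshold, arr.ind = TRUE)
  empty <- data.frame(x = numeric(0), y = numeric(0), r = numeric(0),
                      score = numeric(0))
  if (nrow(edge) == 0L) return(empty)

  radii <- seq.int(r_min, r_max)
  acc <- .hough_vote_cpp(as.integer(edge[, 1] - 1L), as.integer(edge[, 2] - 1L),
                         ny, nx, as.integer(radii))
  # normalise votes by the number of perimeter samples at each radius
  nang <- pmax(16, ceiling(2 * pi * radii))
  score <- array(as.numeric(acc), dim(acc))
  for (ir in seq_along(radii)) score[, , ir] <- score[, , ir] / nang[ir]

  # best radius per centre, then greedy peak picking with NMS
  best_score <- apply(score, c(1, 2), max)
  best_r_idx <- apply(score, c(1, 2), which.max)
  out <- empty
  for (k in seq_len(max_candidates)) {
    idx <- which.max(best_score)
    s <- best_score[idx]
    if (!is.finite(s) || s < min_score) break
    cy <- (idx - 1L) %% ny + 1L
    cx <- (idx - 1L) %/% ny + 1L
    r <- radii[best_r_idx[cy, cx]]
    # suppress the picked circle's interior: centres closer than its radius
    # are arcs of the same structure, not independent circles
    sup <- max(r_min, r)
    ys <- max(1L, cy - sup):min(ny, cy + sup)
    xs <- max(1L, cx - sup):min(nx, cx + sup)
    best_score[ys, xs] <- -Inf
    # discard circles touching the border
    if (cx - 1 - r < 0 || cx - 1 + r > nx - 1 ||
        cy - 1 - r < 0 || cy - 1 + r > ny - 1) next
    out <- rbind(out, data.frame(x = cx - 1, y = cy - 1, r = r, score = s))
  }
  if (nrow(out)) out <- out[order(-out$score), , drop = FALSE]
  rownames(out) <- NULL
  out
}

# Central-difference gradient magnitude (replicated borders).
gradient_magnitude <- function(img) {
  ny <- nrow(img); nx <- ncol(img)
  gx <- img[, c(2:nx, nx)] - img[, c(1, 1:(nx - 1))]
  gy <- img[c(2:ny, ny), ] - img[c(1, 1:(ny - 1)), ]
  # central differences span 2 px except at borders
  span_x <- matrix(2, ny, nx); span_x[, c(1, nx)] <- 1
  span_y <- matrix(2, ny, nx); span_y[c(1, ny), ] <- 1
  sqrt((gx / span_x)^2 + (gy / span_y)^2)
}

#' Fraction of a circle's interior inside an intensity window
#'
#' The interior is every pixel whose centre lies within `r` of the circle
#' centre (clipped to the image); the ratio is the fraction of those pixels
#' with `lo <= I <= hi`. Used as the contrast-agent cue when ranking circle
#' candidates.
#'
#' @param slice_image 2D numeric matrix (y, x).
#' @param circle List or one-row data.frame with `x`, `y` (0-based) and `r`.
#' @param lo,hi Intensity window bounds.
#' @return Fraction in \[0, 1\].
#' @export
intensity_ratio <- function(slice_image, circle, lo, hi) {
  ny <- nrow(slice_image); nx <- ncol(slice_image)
  cx <- circle$x; cy <- circle$y; r <- circle$r
  if (r <= 0) stop("circle radius must be positive", call. = FALSE)
  xs <- max(0, floor(cx - r)):min(nx - 1, ceiling(cx + r))
  ys <- max(0, floor(cy - r)):min(ny - 1, ceiling(cy + r))
  if (length(xs) == 0L || length(ys) == 0L ||
      cx + r < 0 || cx - r > nx - 1 || cy + r < 0 || cy - r > ny - 1)
    stop("circle lies outside the image", call. = FALSE)
  dx2 <- outer(rep(1, length(ys)), (xs - cx)^2)
  dy2 <- outer((ys - cy)^2, rep(1, length(xs)))
  inside <- (dx2 + dy2) <= r^2
  if (!any(inside)) stop("circle interior empty within image", call. = FALSE)
  vals <- slice_image[cbind(rep(ys + 1, length(xs))[as.vector(inside)],
                            rep(xs + 1, each = length(ys))[as.vector(inside)])]
  mean(vals >= lo & vals <= hi)
}

#' Pick the ascending/descending aorta pair from circle candidates
#'
#' Among candidates within the radius bounds, the two with the highest
#' interior intensity ratio (ties broken by accumulator score) are taken as
#' the aortic pair; the larger-radius circle is labelled ascending. When the
#' position prior is enabled and the radii are nearly equal (within 1 px),
#' the more patient-right circle (smaller x) is preferred as ascending.
#' Returns `NULL` when fewer than two candidates reach
#' `min_intensity_ratio`.
#'
#' @param candidates data.frame from [detect_circles()].
#' @param slice_image The slice the candidates were detected on.
#' @param intensity_lo,intensity_hi Contrast window for [intensity_ratio()].
#' @param min_intensity_ratio Eligibility threshold.
#' @param ascending_smaller_x Position prior (see Details).
#' @return List with elements `ascending` and `descending` (each a one-row
#'   data.frame with `x`, `y`, `r`, `score`, `intensity_ratio`), or `NULL`.
#' @export
select_aorta_pair <- function(candidates, slice_image,
                              intensity_lo = 200, intensity_hi = 600,
                              min_intensity_ratio = 0.8,
                              ascending_smaller_x = TRUE) {
  if (is.null(candidates) || nrow(candidates) < 2L) return(NULL)
  ir <- vapply(seq_len(nrow(candidates)), function(i) {
    intensity_ratio(slice_image, candidates[i, ], intensity_lo, intensity_hi)
  }, numeric(1))
  candidates$intensity_ratio <- ir
  ok <- candidates[candidates$intensity_ratio >= min_intensity_ratio, ,
                   drop = FALSE]
  if (nrow(ok) < 2L) return(NULL)
  ok <- ok[order(-ok$intensity_ratio, -ok$score), , drop = FALSE]
  pair <- ok[1:2, , drop = FALSE]
  asc <- which.max(pair$r); desc <- 3L - asc
  if (abs(pair$r[1] - pair$r[2]) <= 1 && ascending_smaller_x) {
    asc <- which.min(pair$x); desc <- 3L - asc
  }
  list(ascending = pair[asc, , drop = FALSE],
       descending = pair[desc, , drop = FALSE])
}

#' Circle-stability energy over an 11-slice window
#'
#' For a window centred at slice `k` the energy is the sum over the window
#' of the absolute diameter difference plus the Euclidean centre distance
#' between the circle on slice i and the circle on slice k:
#' \deqn{E(k) = \sum_{i=k-h}^{k+h} |\o C_i - \o C_k| + \|C_i(x,y) - C_k(x,y)\|}
#' with half-width h = 5 by default. The i = k term contributes zero. The
#' slice whose window minimises this energy carries the most stable —
#' hence most trustworthy — ascending circle.
#'
#' @param circles_by_slice data.frame with columns `slice` (integer z, any
#'   base), `x`, `y`, `r`; at most one circle per slice.
#' @param k Centre slice index (must appear in `circles_by_slice` for the
#'   energy to be finite in strict mode).
#' @param halfwidth Window half-width (default 5 slices each way).
#' @param strict If TRUE, any missing slice in the window yields `Inf`; if
#'   FALSE, missing slices are skipped and the sum is normalised by the
#'   number of slices present (count-normalised best effort).
#' @return Scalar energy (>= 0, possibly `Inf`).
#' @export
stability_energy <- function(circles_by_slice, k, halfwidth = 5,
                             strict = TRUE) {
  stopifnot(all(c("slice", "x", "y", "r") %in% names(circles_by_slice)))
  ck <- circles_by_slice[circles_by_slice$slice == k, , drop = FALSE]
  if (nrow(ck) != 1L) {
    if (strict) return(Inf)
    stop("no circle on the centre slice", call. = FALSE)
  }
  window <- (k - halfwidth):(k + halfwidth)
  rows <- circles_by_slice[circles_by_slice$slice %in% window, , drop = FALSE]
  if (strict && nrow(rows) < length(window)) return(Inf)
  dd <- abs(2 * rows$r - 2 * ck$r)
  cd <- sqrt((rows$x - ck$x)^2 + (rows$y - ck$y)^2)
  e <- sum(dd + cd)
  if (!strict) e <- e * length(window) / nrow(rows)
  e
}

#' Select the initial ascending-aorta circle for a volume
#'
#' Runs circle detection and aortic-pair selection on every axial slice,
#' evaluates the stability energy at every admissible window centre, and
#' returns the argmin circle — the starting point of the whole
#' segmentation. If no window is admissible in strict mode (detections too
#' sparse), the selector retries in count-normalised best-effort mode.
#'
#' @param volume An [aorta_volume()].
#' @param config Configuration list from [aortaseg_config()].
#' @return List of class `circle_selection`: `chosen` (one-row data.frame
#'   with `slice` — 1-based z index — `x`, `y`, `r`, `score`,
#'   `intensity_ratio`), `energy`, `per_slice_pairs` (data.frame of the
#'   ascending/descending candidates per slice), `mode` ("strict" or
#'   "best_effort").
#' @export
select_initial_circle <- function(volume, config = aortaseg_config()) {
  stopifnot(inherits(volume, "aorta_volume"))
  hc <- config$hough
  nz <- dim(volume$data)[1]
  r_min <- hc$r_min_px; r_max <- hc$r_max_px
  if (isTRUE(hc$scale_by_spacing)) {
    dx <- volume$spacing[3]
    if (is.finite(dx) && dx > 0 && abs(dx - 1) > 1e-9) {
      sc <- 0.38 / dx
      r_min <- max(3, round(r_min * sc)); r_max <- max(r_min + 2, round(r_max * sc))
    }
  }
  asc_rows <- list(); pair_rows <- list()
  for (z in seq_len(nz)) {
    sl <- axial_slice(volume, z)
    cand <- detect_circles(sl, r_min = r_min, r_max = r_max,
                           max_candidates = hc$max_candidates,
                           edge_threshold = hc$edge_threshold,
                           min_score = hc$min_score)
    pair <- select_aorta_pair(cand, sl,
                              intensity_lo = hc$intensity_lo,
                              intensity_hi = hc$intensity_hi,
                              min_intensity_ratio = hc$min_intensity_ratio,
                              ascending_smaller_x = hc$ascending_smaller_x)
    if (!is.null(pair)) {
      asc_rows[[length(asc_rows) + 1L]] <- cbind(slice = z, pair$ascending)
      pair_rows[[length(pair_rows) + 1L]] <-
        data.frame(slice = z,
                   asc_x = pair$ascending$x, asc_y = pair$ascending$y,
                   asc_r = pair$ascending$r,
                   desc_x = pair$descending$x, desc_y = pair$descending$y,
                   desc_r = pair$descending$r)
    }
  }
  if (length(asc_rows) == 0L)
    stop("aorta detection failure: no slice yielded an aortic circle pair",
         call. = FALSE)
  asc <- do.call(rbind, asc_rows)
  pairs <- do.call(rbind, pair_rows)
  h <- hc$window_halfwidth

  eval_windows <- function(strict) {
    ks <- asc$slice[asc$slice - h >= 1 & asc$slice + h <= nz]
    if (length(ks) == 0L) return(NULL)
    e <- vapply(ks, function(k) stability_energy(asc, k, halfwidth = h,
                                                 strict = strict), numeric(1))
    if (all(!is.finite(e))) return(NULL)
    list(k = ks[which.min(e)], energy = min(e))
  }

  mode <- "strict"
  best <- if (isTRUE(hc$strict_window)) eval_windows(TRUE) else NULL
  if (is.null(best)) {
    mode <- "best_effort"
    best <- eval_windows(FALSE)
  }
  if (is.null(best))
    stop("aorta detection failure: no admissible stability window",
         call. = FALSE)
  chosen <- asc[asc$slice == best$k, , drop = FALSE]
  rownames(chosen) <- NULL
  structure(list(chosen = chosen, energy = best$energy,
                 per_slice_pairs = pairs, mode = mode),
            class = "circle_selection")
}

#' @export
print.circle_selection <- function(x, ...) {
  cat(sprintf("<circle_selection> slice %d, centre (%.1f, %.1f) px, r = %.1f px, energy = %.3f (%s)\n",
              x$chosen$slice, x$chosen$x, x$chosen$y, x$chosen$r, x$energy,
              x$mode))
  invisible(x)
}
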