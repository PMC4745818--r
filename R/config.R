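#' Default segmentation configuration
#'
#' Returns the full configuration tree with every tunable of the pipeline.
#' All distances and radii are in pixels on the axial grid; intensities are
#' in the units of the input volume (HU for CT). Values given in `...` or
#' via a flat `section.key = value` config file override the defaults.
#'
#' Keys:
#' \describe{
#'   \item{hough.r_min_px, hough.r_max_px}{Radius bounds for circle
#'     candidates (default 8 and 30 px, sized for the aorta at ~0.38 mm
#'     pixels; scaled by `hough.scale_by_spacing`).}
#'   \item{hough.edge_threshold}{Gradient-magnitude threshold (per px)
#'     above which a pixel votes in the accumulator (default 40).}
#'   \item{hough.max_candidates}{Candidates kept per slice (default 8).}
#'   \item{hough.min_score}{Minimum perimeter-normalised accumulator score
#'     (fraction of the circumference supported by edges, default 0.3).}
#'   \item{hough.intensity_lo, hough.intensity_hi}{Contrast-agent intensity
#'     window used for the interior intensity ratio (default 200..600 HU).}
#'   \item{hough.min_intensity_ratio}{Minimum interior fraction inside the
#'     contrast window for a candidate to be aorta-eligible (default 0.8).}
#'   \item{hough.window_halfwidth}{Half-width of the stability window
#'     (default 5, i.e. 11 slices).}
#'   \item{hough.strict_window}{If TRUE a window is admissible only when an
#'     ascending candidate exists on all its slices; on failure the selector
#'     falls back to the count-normalised best-effort mode.}
#'   \item{hough.ascending_smaller_x}{Position prior: the ascending aorta is
#'     the more patient-right (smaller x) of the pair (default TRUE).}
#'   \item{hough.scale_by_spacing}{Rescale the radius bounds by
#'     0.38 mm / dx when the volume spacing is known (default TRUE).}
#'   \item{geodesic.max_passes, geodesic.tolerance}{Raster-scan sweep limit
#'     (default 64) and convergence tolerance (default 1e-8).}
#'   \item{transfer.t_a_px}{Foreground erosion threshold T_A in px; NA means
#'     adaptive: max(t_a_min_px, t_a_fraction * equivalent radius).}
#'   \item{transfer.t_a_fraction, transfer.t_a_min_px}{Adaptive T_A
#'     parameters (defaults 0.25 and 4 px).}
#'   \item{transfer.t_min_px, transfer.t_max_px}{Background seed band
#'     (defaults 2 and 10 px outside the boundary).}
#'   \item{pipeline.leak_guard_ratio}{If finite, abort a direction once the
#'     per-slice foreground area exceeds this multiple of the initial disc
#'     area (default NA = off).}
#'   \item{pipeline.use_voi}{Restrict computation to the detected VOI
#'     (default TRUE).}
#' }
#'
#' @param ... Named overrides using flat keys, e.g.
#'   `aortaseg_config(hough.r_min_px = 5)`.
#' @return Nested named list of configuration sections.
#' @export
aortaseg_config <- function(...) {
  cfg <- list(
    hough = list(
      r_min_px = 8, r_max_px = 30,
      edge_threshold = 40,
      max_candidates = 8,
      min_score = 0.3,
      intensity_lo = 200, intensity_hi = 600,
      min_intensity_ratio = 0.8,
      window_halfwidth = 5,
      strict_window = TRUE,
      ascending_smaller_x = TRUE,
      scale_by_spacing = TRUE
    ),
    geodesic = list(max_passes = 64, tolerance = 1e-8),
    transfer = list(
      t_a_px = NA_real_, t_a_fraction = 0.25, t_a_min_px = 4,
      t_min_px = 2, t_max_px = 10
    ),
    pipeline = list(leak_guard_ratio = NA_real_, use_voi = TRUE)
  )
  apply_overrides(cfg, list(...))
}

apply_overrides <- function(cfg, overrides) {
  if (length(overrides) == 0L) return(cfg)
  nm <- names(overrides)
  if (is.null(nm) || any(nm == ""))
    stop("config overrides must be named", call. = FALSE)
  for (i in seq_along(overrides)) {
    parts <- strsplit(nm[i], ".", fixed = TRUE)[[1]]
    if (length(parts) != 2L || is.null(cfg[[parts[1]]]))
      stop(sprintf("unknown config key '%s'", nm[i]), call. = FALSE)
    if (!parts[2] %in% names(cfg[[parts[1]]]))
      stop(sprintf("unknown config key '%s'", nm[i]), call. = FALSE)
    cfg[[parts[1]]][[parts[2]]] <- overrides[[i]]
  }
  cfg
}

#' Read a flat key = value configuration file
#'
#' The file holds one `section.key = value` pair per line; `#` starts a
#' comment. Values are parsed as logical (`true`/`false`), numeric, or left
#' as strings. Unknown keys are an error so typos do not pass silently.
#'
#' @param path Path to the config file.
#' @return Full configuration list (defaults plus overrides).
#' @export
read_config <- function(path) {
  lines <- readLines(path, warn = FALSE)
  lines <- sub("#.*$", "", lines)
  lines <- trimws(lines)
  lines <- lines[nzchar(lines)]
  overrides <- list()
  for (ln in lines) {
    kv <- strsplit(ln, "=", fixed = TRUE)[[1]]
    if (length(kv) != 2L)
      stop(sprintf("cannot parse config line '%s'", ln), call. = FALSE)
    key <- trimws(kv[1])
    val <- trimws(kv[2])
    val <- gsub('^"|"$', "", val)
    parsed <- if (tolower(val) %in% c("true", "false")) {
      tolower(val) == "true"
    } else if (tolower(val) %in% c("na", "nan")) {
      NA_real_
    } else {
      num <- suppressWarnings(as.numeric(val))
      if (is.na(num)) val else num
    }
    overrides[[key]] <- parsed
  }
  do.call(aortaseg_config, overrides)
}
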