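#' Triangle surface mesh of a binary mask
#'
#' Extracts the 0.5-isosurface of the binary mask by a marching-tetrahedra
#' isosurfacer (each voxel cell is split into six tetrahedra with face
#' diagonals chosen consistently across cells, so the mesh is watertight).
#' The mask is zero-padded first so the surface closes at the volume
#' boundary. Vertices are returned in millimetres — voxel indices scaled
#' by the spacing — with triangles wound so normals point outward.
#'
#' @param mask A [label_mask()] (or 0/1 3D array).
#' @param spacing Voxel spacing `(dz, dy, dx)` mm; defaults to the mask's.
#' @return List of class `surface_mesh`: `vertices` (n x 3 matrix, columns
#'   x/y/z in mm), `faces` (m x 3 integer matrix of 1-based vertex ids).
#' @export
extract_mesh <- function(mask, spacing = NULL) {
  m <- if (inherits(mask, "label_mask")) mask$data else mask
  if (is.null(spacing))
    spacing <- if (inherits(mask, "label_mask")) mask$spacing else c(1, 1, 1)
  if (sum(m) == 0L) stop("mask is empty: no surface to extract", call. = FALSE)
  d <- dim(m)
  padded <- array(0, dim = d + 2L)
  padded[2:(d[1] + 1L), 2:(d[2] + 1L), 2:(d[3] + 1L)] <- m
  tri <- .marching_tetra_cpp(padded, 0.5)
  # vertex coords come back as (x, y, z) in padded voxel units; un-pad and
  # scale to mm (spacing is (dz, dy, dx))
  tri[, 1] <- (tri[, 1] - 1) * spacing[3]
  tri[, 2] <- (tri[, 2] - 1) * spacing[2]
  tri[, 3] <- (tri[, 3] - 1) * spacing[1]
  # merge identical vertices so the mesh is indexed
  key <- paste(sprintf("%.9g", tri[, 1]), sprintf("%.9g", tri[, 2]),
               sprintf("%.9g", tri[, 3]))
  ids <- match(key, unique(key))
  verts <- tri[!duplicated(key), , drop = FALSE]
  faces <- matrix(ids, ncol = 3, byrow = TRUE)
  colnames(verts) <- c("x", "y", "z")
  structure(list(vertices = verts, faces = faces), class = "surface_mesh")
}

#' @export
print.surface_mesh <- function(x, ...) {
  cat(sprintf("<surface_mesh> %d vertices, %d triangles, enclosed volume %.1f mm^3\n",
              nrow(x$vertices), nrow(x$faces), mesh_volume(x)))
  invisible(x)
}

#' Volume enclosed by a watertight surface mesh
#'
#' Signed-tetrahedron (divergence theorem) volume; positive when triangle
#' normals point outward.
#'
#' @param mesh A `surface_mesh`.
#' @return Enclosed volume in mm^3.
#' @export
mesh_volume <- function(mesh) {
  v <- mesh$vertices; f <- mesh$faces
  p1 <- v[f[, 1], , drop = FALSE]
  p2 <- v[f[, 2], , drop = FALSE]
  p3 <- v[f[, 3], , drop = FALSE]
  cr <- cbind(p2[, 2] * p3[, 3] - p2[, 3] * p3[, 2],
              p2[, 3] * p3[, 1] - p2[, 1] * p3[, 3],
              p2[, 1] * p3[, 2] - p2[, 2] * p3[, 1])
  sum(rowSums(p1 * cr)) / 6
}

#' Euler characteristic of a surface mesh
#'
#' V - E + F on the indexed mesh; 2 for a closed genus-0 surface.
#'
#' @param mesh A `surface_mesh`.
#' @return Integer Euler characteristic.
#' @export
mesh_euler_characteristic <- function(mesh) {
  f <- mesh$faces
  edges <- rbind(f[, c(1, 2)], f[, c(2, 3)], f[, c(3, 1)])
  ek <- paste(pmin(edges[, 1], edges[, 2]), pmax(edges[, 1], edges[, 2]))
  nrow(mesh$vertices) - length(unique(ek)) + nrow(f)
}

#' Write a surface mesh to PLY or STL
#'
#' ASCII formats, chosen by file extension.
#'
#' @param mesh A `surface_mesh`.
#' @param path Output path ending in `.ply` or `.stl`.
#' @export
write_mesh <- function(mesh, path) {
  ext <- tolower(tools::file_ext(path))
  if (ext == "ply") {
    con <- file(path, "w")
    on.exit(close(con))
    writeLines(c("ply", "format ascii 1.0",
                 sprintf("element vertex %d", nrow(mesh$vertices)),
                 "property float x", "property float y", "property float z",
                 sprintf("element face %d", nrow(mesh$faces)),
                 "property list uchar int vertex_indices", "end_header"), con)
    writeLines(apply(mesh$vertices, 1, function(p)
      sprintf("%.6f %.6f %.6f", p[1], p[2], p[3])), con)
    writeLines(apply(mesh$faces - 1L, 1, function(f)
      sprintf("3 %d %d %d", f[1], f[2], f[3])), con)
  } else if (ext == "stl") {
    con <- file(path, "w")
    on.exit(close(con))
    writeLines("solid mask", con)
    v <- mesh$vertices
    for (i in seq_len(nrow(mesh$faces))) {
      tri <- v[mesh$faces[i, ], , drop = FALSE]
      writeLines(c("facet normal 0 0 0", "outer loop",
                   sprintf("vertex %.6f %.6f %.6f", tri[, 1], tri[, 2], tri[, 3]),
                   "endloop", "endfacet"), con)
    }
    writeLines("endsolid mask", con)
  } else stop("unsupported mesh format: use .ply or .stl", call. = FALSE)
  invisible(path)
}
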