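# Independent oracles and fixture builders used across the suite.

# Exact shortest-path distances on the 8-connected weighted pixel graph,
# via igraph's Dijkstra. `image` may be NULL for unit weights. Seeds is a
# logical matrix; returns the min distance to the seed set per pixel.
dijkstra_oracle <- function(image, seeds, weight_kind = c("gradient_squared", "unit")) {
  weight_kind <- match.arg(weight_kind)
  ny <- nrow(seeds); nx <- ncol(seeds)
  id <- function(i, j) (j - 1L) * ny + i
  ij <- expand.grid(i = 1:ny, j = 1:nx)
  from <- integer(0); to <- integer(0); w <- numeric(0)
  for (off in list(c(0L, 1L, 1), c(1L, 0L, 1),
                   c(1L, 1L, sqrt(2)), c(1L, -1L, sqrt(2)))) {
    i2 <- ij$i + off[1]; j2 <- ij$j + off[2]
    ok <- i2 >= 1L & i2 <= ny & j2 >= 1L & j2 <= nx
    f <- id(ij$i[ok], ij$j[ok]); t <- id(i2[ok], j2[ok])
    wt <- if (weight_kind == "unit") rep(off[3], sum(ok)) else
      (image[t] - image[f])^2 / off[3]
    from <- c(from, f); to <- c(to, t); w <- c(w, wt)
  }
  g <- igraph::make_empty_graph(n = ny * nx, directed = FALSE)
  g <- igraph::add_edges(g, rbind(from, to))
  seed_ids <- which(as.vector(seeds))
  dm <- igraph::distances(g, v = seed_ids, weights = w)
  matrix(apply(dm, 2, min), ny, nx)
}

# Filled-disc logical matrix, 0-based centre, centre-distance rasterization.
disc_matrix <- function(ny, nx, cx, cy, r) {
  yy <- matrix(0:(ny - 1), ny, nx)
  xx <- matrix(0:(nx - 1), ny, nx, byrow = TRUE)
  (xx - cx)^2 + (yy - cy)^2 <= r^2
}

# Exact Euclidean distance from every pixel to the nearest pixel of `set`
# (logical matrix), brute force; fine for small fixtures.
euclid_dist_to_set <- function(set) {
  pts <- which(set, arr.ind = TRUE)
  ny <- nrow(set); nx <- ncol(set)
  out <- matrix(Inf, ny, nx)
  for (j in 1:nx) {
    dx2 <- (pts[, 2] - j)^2
    for (i in 1:ny) {
      out[i, j] <- sqrt(min((pts[, 1] - i)^2 + dx2))
    }
  }
  out
}

# --- tiny DICOM fixture writer (explicit VR little endian) ------------------
write_test_dicom <- function(path, pixel_matrix, z_pos, instance_number,
                             pixel_spacing = c(0.5, 0.5)) {
  u16 <- function(x) writeBin(as.integer(x), con, size = 2, endian = "little")
  u32 <- function(x) writeBin(as.integer(x), con, size = 4, endian = "little")
  elem_str <- function(group, el, vr, value) {
    if (nchar(value) %% 2 == 1) value <- paste0(value, " ")
    u16(group); u16(el); writeChar(vr, con, eos = NULL)
    u16(nchar(value)); writeChar(value, con, eos = NULL)
  }
  elem_us <- function(group, el, value) {
    u16(group); u16(el); writeChar("US", con, eos = NULL); u16(2L); u16(value)
  }
  con <- file(path, "wb")
  on.exit(close(con))
  writeBin(raw(128), con)
  writeChar("DICM", con, eos = NULL)
  rows <- nrow(pixel_matrix); cols <- ncol(pixel_matrix)
  elem_str(0x0008, 0x0060, "CS", "CT")
  elem_str(0x0020, 0x0013, "IS", as.character(instance_number))
  elem_str(0x0020, 0x0032, "DS",
           sprintf("0\\0\\%g", z_pos))
  elem_str(0x0018, 0x0050, "DS", "1")
  elem_us(0x0028, 0x0010, rows)
  elem_us(0x0028, 0x0011, cols)
  elem_str(0x0028, 0x0030, "DS",
           sprintf("%g\\%g", pixel_spacing[1], pixel_spacing[2]))
  elem_us(0x0028, 0x0100, 16L)
  elem_us(0x0028, 0x0103, 0L)
  elem_str(0x0028, 0x1052, "DS", "0")
  elem_str(0x0028, 0x1053, "DS", "1")
  # pixel data, row-major
  px <- as.integer(t(pixel_matrix))
  u16(0x7fe0); u16(0x0010); writeChar("OW", con, eos = NULL); u16(0L)
  u32(length(px) * 2L)
  writeBin(px, con, size = 2, endian = "little")
  invisible(path)
}

# --- tiny NRRD fixture writer (raw encoding, int16) -------------------------
write_test_nrrd <- function(path, arr_zyx, spacing = c(1, 1, 1)) {
  con <- file(path, "wb")
  on.exit(close(con))
  d <- dim(arr_zyx)
  header <- c("NRRD0004",
              "type: int16",
              "dimension: 3",
              sprintf("sizes: %d %d %d", d[3], d[2], d[1]),
              sprintf("spacings: %g %g %g", spacing[3], spacing[2], spacing[1]),
              "endian: little",
              "encoding: raw",
              "")
  writeLines(header, con, sep = "\n")
  vals <- as.integer(aperm(arr_zyx, c(3, 2, 1)))
  writeBin(vals, con, size = 2, endian = "little")
  invisible(path)
}

# Small noisy phantom for detection tests (cheaper than the default one).
small_phantom <- function(seed = 1L, nz = 24L, r_asc = 12, r_desc = 8,
                          noise = 5, drift = 0.2) {
  ny <- 96L; nx <- 96L
  asc <- tube_spec(30 + drift * (seq_len(nz) - 1), 40, r_asc,
                   intensity = 350, nz = nz)
  desc <- tube_spec(68, 64, r_desc, intensity = 350, nz = nz)
  spec <- phantom_spec(c(nz, ny, nx), asc, desc,
                       background_intensity = 50, noise_sigma = noise,
                       blur_sigma = 1, seed = seed)
  generate_phantom(spec)
}
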