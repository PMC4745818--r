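#' Read a 3D volume from NIfTI, NRRD, or a DICOM series directory
#'
#' Normalizes any supported input to the internal [aorta_volume()]
#' representation: data indexed `(z, y, x)`, spacing `(dz, dy, dx)` in mm
#' taken from the file metadata, intensities unmodified (rescale
#' slope/intercept applied for DICOM so values are in HU). DICOM series
#' slices are sorted by their physical z position (instance numbering and
#' file order are ignored), ascending z.
#'
#' @param path File path (`.nii`, `.nii.gz`, `.nrrd`) or a directory
#'   containing one DICOM series.
#' @param format Optional explicit format: `"nifti"`, `"nrrd"` or
#'   `"dicom"`; guessed from the path by default.
#' @return An [aorta_volume()].
#' @export
read_volume <- function(path, format = NULL) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  if (is.null(format)) {
    format <- if (dir.exists(path)) "dicom"
    else if (grepl("\\.nii(\\.gz)?$", path, ignore.case = TRUE)) "nifti"
    else if (grepl("\\.nrrd$", path, ignore.case = TRUE)) "nrrd"
    else stop("cannot guess format of ", path,
              "; pass format = 'nifti', 'nrrd' or 'dicom'", call. = FALSE)
  }
  switch(format,
         nifti = read_nifti_volume(path),
         nrrd = read_nrrd_volume(path),
         dicom = read_dicom_series(path),
         stop("unknown format: ", format, call. = FALSE))
}

read_nifti_volume <- function(path) {
  img <- tryCatch(RNifti::readNifti(path),
                  error = function(e) stop("unreadable NIfTI file: ",
                                           conditionMessage(e), call. = FALSE))
  arr <- as.array(img)
  if (length(dim(arr)) == 4L && dim(arr)[4] == 1L)
    arr <- array(arr, dim(arr)[1:3])
  if (length(dim(arr)) != 3L)
    stop("expected 3D data, got ", length(dim(arr)), "D", call. = FALSE)
  pd <- RNifti::pixdim(img)[1:3]           # (dx, dy, dz)
  aorta_volume(aperm(arr, c(3, 2, 1)), spacing = rev(pd),
               intensity_units = "HU")
}

#' Read a mask file as a binary label mask
#'
#' @param path NIfTI file holding 0/1 integer data.
#' @return A [label_mask()].
#' @export
read_mask <- function(path) {
  v <- read_volume(path, format = "nifti")
  label_mask(round(v$data), spacing = v$spacing, origin = v$origin)
}

#' Write a label mask as integer NIfTI
#'
#' Round-trips exactly: `read_mask(write_mask(m, f))` reproduces the array
#' values and the spacing.
#'
#' @param mask A [label_mask()].
#' @param path Output path (`.nii` or `.nii.gz`).
#' @export
write_mask <- function(mask, path) {
  stopifnot(inherits(mask, "label_mask"))
  write_volume_nifti(mask$data, mask$spacing, path, datatype = "int16")
}

#' Write a volume as NIfTI
#'
#' @param volume An [aorta_volume()].
#' @param path Output path (`.nii` or `.nii.gz`).
#' @export
write_volume <- function(volume, path) {
  stopifnot(inherits(volume, "aorta_volume"))
  write_volume_nifti(volume$data, volume$spacing, path, datatype = "double")
}

write_volume_nifti <- function(data, spacing, path, datatype) {
  arr <- aperm(data, c(3, 2, 1))           # back to (x, y, z)
  img <- RNifti::asNifti(arr)
  RNifti::pixdim(img) <- rev(spacing)      # (dx, dy, dz)
  RNifti::writeNifti(img, path, datatype = datatype)
  invisible(path)
}

# --- NRRD -------------------------------------------------------------------
# Minimal NRRD reader (3D, raw or gzip attached encodings) — no installed R
# package reads NRRD.
read_nrrd_volume <- function(path) {
  con <- file(path, "rb")
  on.exit(close(con), add = TRUE)
  magic <- readLines(con, n = 1L, warn = FALSE)
  if (!grepl("^NRRD", magic)) stop("not an NRRD file", call. = FALSE)
  fields <- list()
  repeat {
    line <- readLines(con, n = 1L, warn = FALSE)
    if (length(line) == 0L) stop("NRRD header not terminated", call. = FALSE)
    if (!nzchar(line)) break
    if (grepl("^#", line)) next
    kv <- regmatches(line, regexec("^([^:]+):=?\\s*(.*)$", line))[[1]]
    if (length(kv) == 3L) fields[[tolower(trimws(kv[2]))]] <- trimws(kv[3])
  }
  dimn <- as.integer(fields[["dimension"]])
  if (is.na(dimn) || dimn != 3L)
    stop("expected 3D NRRD data, got ", fields[["dimension"]], "D",
         call. = FALSE)
  sizes <- as.integer(strsplit(fields[["sizes"]], "\\s+")[[1]])
  type <- fields[["type"]]
  spec <- switch(type,
                 "short" = , "int16" = , "signed short" = list(what = "integer", size = 2L, signed = TRUE),
                 "unsigned short" = , "uint16" = list(what = "integer", size = 2L, signed = FALSE),
                 "int" = , "int32" = , "signed int" = list(what = "integer", size = 4L, signed = TRUE),
                 "uchar" = , "uint8" = , "unsigned char" = list(what = "integer", size = 1L, signed = FALSE),
                 "float" = list(what = "numeric", size = 4L, signed = TRUE),
                 "double" = list(what = "numeric", size = 8L, signed = TRUE),
                 stop("unsupported NRRD type: ", type, call. = FALSE))
  endian <- if (!is.null(fields[["endian"]]) &&
                grepl("big", fields[["endian"]])) "big" else "little"
  enc <- tolower(fields[["encoding"]] %||% "raw")
  n <- prod(sizes)
  if (enc == "raw") {
    vals <- readBin(con, what = spec$what, n = n, size = spec$size,
                    signed = spec$signed, endian = endian)
  } else if (enc %in% c("gzip", "gz")) {
    comp <- readBin(con, "raw", n = file.size(path))
    raw <- memDecompress(comp, type = "gzip")
    vals <- readBin(raw, what = spec$what, n = n, size = spec$size,
                    signed = spec$signed, endian = endian)
  } else stop("unsupported NRRD encoding: ", enc, call. = FALSE)
  if (length(vals) < n) stop("truncated NRRD data", call. = FALSE)
  # NRRD sizes are fastest-first: (nx, ny, nz)
  arr <- array(vals, dim = sizes)
  spacing <- c(1, 1, 1)
  if (!is.null(fields[["spacings"]])) {
    sp <- as.numeric(strsplit(fields[["spacings"]], "\\s+")[[1]])
    spacing <- rev(sp)
  } else if (!is.null(fields[["space directions"]])) {
    vecs <- regmatches(fields[["space directions"]],
                       gregexpr("\\(([^)]*)\\)", fields[["space directions"]]))[[1]]
    mags <- vapply(vecs, function(v) {
      nums <- as.numeric(strsplit(gsub("[()]", "", v), ",")[[1]])
      sqrt(sum(nums^2))
    }, numeric(1))
    if (length(mags) == 3L) spacing <- rev(mags)
  }
  aorta_volume(aperm(arr, c(3, 2, 1)), spacing = spacing,
               intensity_units = "HU")
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# --- DICOM ------------------------------------------------------------------
# Minimal DICOM series reader: explicit-VR little-endian, uncompressed pixel
# data — enough for converter output; no installed R package reads DICOM.
parse_dicom_file <- function(path) {
  raw <- readBin(path, "raw", n = file.size(path))
  if (length(raw) < 140L || rawToChar(raw[129:132]) != "DICM")
    stop("not a DICOM part-10 file: ", path, call. = FALSE)
  pos <- 133L
  u16 <- function(p) as.integer(raw[p]) + 256L * as.integer(raw[p + 1L])
  u32 <- function(p) as.integer(raw[p]) + 256 * as.integer(raw[p + 1L]) +
    65536 * as.integer(raw[p + 2L]) + 16777216 * as.integer(raw[p + 3L])
  tags <- list()
  long_vrs <- c("OB", "OW", "OF", "SQ", "UT", "UN")
  while (pos + 7L <= length(raw)) {
    group <- u16(pos); elem <- u16(pos + 2L)
    vr_bytes <- raw[(pos + 4L):(pos + 5L)]
    is_vr <- all(vr_bytes >= as.raw(65L) & vr_bytes <= as.raw(90L))
    vr <- if (is_vr) rawToChar(vr_bytes) else ""
    if (is_vr) {
      if (vr %in% long_vrs) {
        len <- u32(pos + 8L); hdr <- 12L
      } else {
        len <- u16(pos + 6L); hdr <- 8L
      }
    } else {  # implicit VR fallback
      vr <- "UN"; len <- u32(pos + 4L); hdr <- 8L
    }
    if (len == 4294967295) stop("undefined-length DICOM elements unsupported",
                                call. = FALSE)
    key <- sprintf("%04x,%04x", group, elem)
    body <- if (len > 0L) raw[(pos + hdr):(pos + hdr + len - 1L)] else raw(0)
    tags[[key]] <- list(vr = vr, bytes = body)
    pos <- pos + hdr + len
  }
  tags
}

dicom_str <- function(tags, key) {
  t <- tags[[key]]
  if (is.null(t)) return(NULL)
  trimws(rawToChar(t$bytes))
}

dicom_num <- function(tags, key) {
  s <- dicom_str(tags, key)
  if (is.null(s)) return(NULL)
  as.numeric(strsplit(s, "\\\\")[[1]])
}

dicom_u16 <- function(tags, key) {
  t <- tags[[key]]
  if (is.null(t)) return(NULL)
  readBin(t$bytes, "integer", n = 1L, size = 2L, signed = FALSE,
          endian = "little")
}

read_dicom_series <- function(dir) {
  files <- list.files(dir, full.names = TRUE)
  files <- files[!dir.exists(files)]
  if (length(files) == 0L) stop("no files in DICOM directory", call. = FALSE)
  slices <- lapply(files, function(f) {
    tags <- parse_dicom_file(f)
    rows <- dicom_u16(tags, "0028,0010")
    cols <- dicom_u16(tags, "0028,0011")
    bits <- dicom_u16(tags, "0028,0100") %||% 16L
    pixrep <- dicom_u16(tags, "0028,0103") %||% 0L
    if (is.null(rows) || is.null(cols) || is.null(tags[["7fe0,0010"]]))
      stop("missing image data in ", f, call. = FALSE)
    if (bits != 16L) stop("only 16-bit DICOM pixel data supported",
                          call. = FALSE)
    px <- readBin(tags[["7fe0,0010"]]$bytes, "integer",
                  n = rows * cols, size = 2L, signed = pixrep == 1L,
                  endian = "little")
    slope <- (dicom_num(tags, "0028,1053") %||% 1)[1]
    inter <- (dicom_num(tags, "0028,1052") %||% 0)[1]
    ipp <- dicom_num(tags, "0020,0032") %||% c(0, 0, NA)
    spc <- dicom_num(tags, "0028,0030") %||% c(1, 1)
    thick <- (dicom_num(tags, "0018,0050") %||% 1)[1]
    # DICOM pixel data is row-major: first index varies along columns
    img <- matrix(px * slope + inter, nrow = rows, ncol = cols, byrow = TRUE)
    list(img = img, zpos = ipp[3], spc = spc, thick = thick)
  })
  zpos <- vapply(slices, function(s) s$zpos, numeric(1))
  if (any(is.na(zpos))) zpos <- seq_along(slices)
  ord <- order(zpos)
  slices <- slices[ord]; zpos <- zpos[ord]
  dims <- vapply(slices, function(s) dim(s$img), integer(2))
  if (any(dims[1, ] != dims[1, 1]) || any(dims[2, ] != dims[2, 1]))
    stop("inconsistent slice dimensions in DICOM series", call. = FALSE)
  nz <- length(slices)
  dz <- if (nz > 1L) stats::median(diff(zpos)) else slices[[1]]$thick
  if (!is.finite(dz) || dz <= 0) dz <- slices[[1]]$thick
  arr <- array(0, dim = c(nz, dims[1, 1], dims[2, 1]))
  for (i in seq_len(nz)) arr[i, , ] <- slices[[i]]$img
  spc <- slices[[1]]$spc
  aorta_volume(arr, spacing = c(dz, spc[1], spc[2]),
               origin = c(min(zpos), 0, 0), intensity_units = "HU")
}
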