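#' Construct a volume mask
#'
#' A `volume_mask` is an axis-aligned 3D label grid with isotropic physical
#' voxel size. Voxel `(i, j, k)` (0-based) has its center at
#' `origin + (index + 0.5) * voxel_size` nm on each axis; all mask-to-point
#' geometry uses voxel centers.
#'
#' @param grid 3D integer array of labels, 0 = background.
#' @param voxel_size voxel edge length in nm (isotropic).
#' @param origin nm position of the corner of voxel (0,0,0); length-3.
#' @param role one of `"pm"`, `"isg"`, `"tomogram"`.
#' @return an object of class `volume_mask`.
#' @export
volume_mask <- function(grid, voxel_size, origin = c(0, 0, 0),
                        role = c("pm", "isg", "tomogram")) {
  role <- match.arg(role)
  if (length(dim(grid)) != 3) abort("grid must be a 3D array")
  if (!is.numeric(voxel_size) || length(voxel_size) != 1 || voxel_size <= 0) {
    abort("voxel_size must be a single positive number (nm)")
  }
  if (length(origin) != 3) abort("origin must be length 3 (nm)")
  storage.mode(grid) <- "integer"
  m <- structure(
    list(grid = grid, voxel_size = as.double(voxel_size),
         origin = as.double(origin), role = role),
    class = "volume_mask"
  )
  validate_mask(m)
  m
}

#' @export
print.volume_mask <- function(x, ...) {
  d <- dim(x$grid)
  cat(sprintf("<volume_mask role=%s %dx%dx%d voxels @ %.4g nm, %d label(s)>\n",
              x$role, d[1], d[2], d[3], x$voxel_size, n_labels(x)))
  invisible(x)
}

n_labels <- function(mask) {
  u <- unique(as.vector(mask$grid))
  sum(u != 0L)
}

validate_mask <- function(mask) {
  if (mask$role == "pm" && !any(mask$grid != 0L)) {
    abort("pm mask has no nonzero voxels (no PM component)")
  }
  invisible(mask)
}

#' Read a labeled volume from an MRC2014 file
#'
#' Parses the 1024-byte MRC2014 header, converts the header voxel size from
#' Angstrom to nm, and checks that voxels are isotropic. Modes 0 (int8),
#' 1 (int16), 2 (float32) and 6 (uint16) are supported. The MRC origin
#' words (in Angstrom) populate the mask origin.
#'
#' @param path path to an MRC file.
#' @param role mask role, as in [volume_mask()].
#' @param voxel_size_nm explicit voxel size override (nm), required when
#'   the header carries none.
#' @return a [volume_mask()].
#' @export
read_mask <- function(path, role = c("pm", "isg", "tomogram"),
                      voxel_size_nm = NULL) {
  role <- match.arg(role)
  if (!file.exists(path)) abort(paste0("no such file: ", path))
  con <- file(path, "rb")
  on.exit(close(con))
  ints <- readBin(con, "integer", n = 10, size = 4, endian = "little")
  nx <- ints[1]; ny <- ints[2]; nz <- ints[3]; mode <- ints[4]
  mxyz <- ints[8:10]
  cella <- readBin(con, "double", n = 3, size = 4, endian = "little")
  invisible(readBin(con, "double", n = 3, size = 4, endian = "little")) # cellb
  invisible(readBin(con, "integer", n = 3, size = 4, endian = "little")) # mapc/r/s
  invisible(readBin(con, "double", n = 3, size = 4, endian = "little")) # dmin/max/mean
  invisible(readBin(con, "integer", n = 2, size = 4, endian = "little")) # ispg, nsymbt
  invisible(readBin(con, "integer", n = 25, size = 4, endian = "little")) # extra
  origin_a <- readBin(con, "double", n = 3, size = 4, endian = "little")
  seek(con, 1024)
  n <- nx * ny * nz
  if (n <= 0) abort("empty MRC volume")
  data <- switch(as.character(mode),
    "0" = readBin(con, "integer", n = n, size = 1, signed = TRUE, endian = "little"),
    "1" = readBin(con, "integer", n = n, size = 2, signed = TRUE, endian = "little"),
    "2" = readBin(con, "double", n = n, size = 4, endian = "little"),
    "6" = readBin(con, "integer", n = n, size = 2, signed = FALSE, endian = "little"),
    abort(paste0("unsupported MRC mode ", mode))
  )
  vs_a <- cella / mxyz
  if (any(!is.finite(vs_a)) || any(vs_a <= 0)) {
    if (is.null(voxel_size_nm)) {
      abort("MRC header has no voxel size; pass voxel_size_nm explicitly")
    }
    vs_nm <- voxel_size_nm
  } else {
    if (diff(range(vs_a)) > 1e-4 * mean(vs_a)) {
      abort(sprintf("anisotropic voxels (%.4g/%.4g/%.4g A) are not supported",
                    vs_a[1], vs_a[2], vs_a[3]))
    }
    vs_nm <- mean(vs_a) / 10
  }
  grid <- array(as.integer(round(data)), dim = c(nx, ny, nz))
  m <- volume_mask(grid, voxel_size = vs_nm, origin = origin_a / 10, role = role)
  inform(sprintf("read %s mask %dx%dx%d @ %.4g nm with %d label(s)",
                 role, nx, ny, nz, vs_nm, n_labels(m)))
  m
}

#' Write a volume mask to an MRC2014 file (float32)
#'
#' @param mask a [volume_mask()].
#' @param path output path.
#' @export
write_mask <- function(mask, path) {
  d <- dim(mask$grid)
  con <- file(path, "wb")
  on.exit(close(con))
  wi <- function(x) writeBin(as.integer(x), con, size = 4, endian = "little")
  wf <- function(x) writeBin(as.double(x), con, size = 4, endian = "little")
  vals <- as.double(mask$grid)
  wi(c(d[1], d[2], d[3], 2L, 0L, 0L, 0L, d[1], d[2], d[3]))
  wf(d * mask$voxel_size * 10)           # cella in Angstrom
  wf(c(90, 90, 90))                      # cellb
  wi(c(1L, 2L, 3L))                      # mapc, mapr, maps
  wf(c(min(vals), max(vals), mean(vals)))
  wi(c(1L, 0L))                          # ispg, nsymbt
  wi(rep(0L, 25))                        # extra
  wf(mask$origin * 10)                   # origin in Angstrom
  writeChar("MAP ", con, nchars = 4, eos = NULL)
  writeBin(as.raw(c(0x44, 0x44, 0x00, 0x00)), con)
  wf(stats::sd(vals))
  wi(1L)
  lab <- sprintf("%-80s", paste0("filarch ", as.character(packageVersion("filarch"))))
  writeChar(substr(lab, 1, 80), con, nchars = 80, eos = NULL)
  writeChar(paste(rep(" ", 720), collapse = ""), con, nchars = 720, eos = NULL)
  writeBin(as.double(vals), con, size = 4, endian = "little")
  invisible(path)
}

# enclosing-voxel index (0-based) of nm points; clamps to the grid and
# reports which points fell outside
point_voxel_index <- function(points, mask) {
  d <- dim(mask$grid)
  idx <- sweep(points, 2, mask$origin) / mask$voxel_size
  idx <- floor(idx)
  clamped <- idx[, 1] < 0 | idx[, 1] >= d[1] |
    idx[, 2] < 0 | idx[, 2] >= d[2] |
    idx[, 3] < 0 | idx[, 3] >= d[3]
  for (a in 1:3) idx[, a] <- pmin(pmax(idx[, a], 0), d[a] - 1)
  list(index = idx, clamped = clamped)
}

# nm coordinates of voxel centers given 0-based (i,j,k) index matrix
voxel_centers <- function(index, mask) {
  sweep((index + 0.5) * mask$voxel_size, 2, mask$origin, "+")
}
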