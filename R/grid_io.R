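# Voxel-grid data model and MRC2014/CCP4 volume I/O.
#
# Internal convention (honoured by every other module): the density array is
# indexed (i, j, k) = (z, y, x), voxel_size and origin are stored in the same
# (z, y, x) order, and the physical position of the CENTER of voxel
# (i, j, k) (0-based) is origin + (i*vz, j*vy, k*vx).

#' Construct a voxel grid
#'
#' A `voxel_grid` is a 3-D scalar field with physical metadata: a per-axis
#' voxel size (Å) and a physical origin (Å), both stored in `(z, y, x)` order
#' to match the array's index order. The center of voxel `(i, j, k)` (0-based)
#' sits at `origin + (i*vz, j*vy, k*vx)`.
#'
#' @param data 3-D numeric array indexed `(z, y, x)`.
#' @param voxel_size numeric length-3 `(vz, vy, vx)` in Å/voxel, or a single
#'   value recycled to all axes. All components must be positive.
#' @param origin numeric length-3 `(oz, oy, ox)` in Å, or a single value.
#' @return An object of class `voxel_grid` with fields `data`, `voxel_size`,
#'   `origin`.
#' @examples
#' g <- voxel_grid(array(0, dim = c(8, 8, 8)), voxel_size = 1)
#' dim(g$data)
#' @export
voxel_grid <- function(data, voxel_size = 1, origin = 0) {
  if (!is.array(data) || length(dim(data)) != 3L)
    stop("'data' must be a 3-D array", call. = FALSE)
  voxel_size <- rep_len(as.numeric(voxel_size), 3L)
  origin <- rep_len(as.numeric(origin), 3L)
  if (any(!is.finite(voxel_size)) || any(voxel_size <= 0))
    stop("all voxel_size components must be positive and finite", call. = FALSE)
  if (any(!is.finite(origin)))
    stop("origin components must be finite", call. = FALSE)
  structure(
    list(data = data, voxel_size = voxel_size, origin = origin),
    class = "voxel_grid"
  )
}

#' @export
print.voxel_grid <- function(x, ...) {
  d <- dim(x$data)
  cat(sprintf("<voxel_grid> %d x %d x %d (z,y,x)\n", d[1], d[2], d[3]))
  cat(sprintf("  voxel size (z,y,x): %s Å\n",
              paste(format(x$voxel_size, digits = 6), collapse = ", ")))
  cat(sprintf("  origin     (z,y,x): %s Å\n",
              paste(format(x$origin, digits = 6), collapse = ", ")))
  cat(sprintf("  density: min %.4g, max %.4g, mean %.4g\n",
              min(x$data), max(x$data), mean(x$data)))
  invisible(x)
}

#' Test for a voxel grid
#' @param x object to test.
#' @return `TRUE` if `x` is a `voxel_grid`.
#' @export
is.voxel_grid <- function(x) inherits(x, "voxel_grid")

#' Grid shape
#' @param grid a `voxel_grid`.
#' @return Integer length-3 `(nz, ny, nx)`.
#' @export
grid_shape <- function(grid) dim(grid$data)

#' Create an empty (all-zero) grid of a given geometry
#'
#' Convenience for specifying a target geometry without density values, e.g.
#' as the `grid_spec` argument of [simulate_density()].
#'
#' @param shape integer length-3 `(nz, ny, nx)`.
#' @inheritParams voxel_grid
#' @return A `voxel_grid` filled with zeros.
#' @export
empty_grid <- function(shape, voxel_size = 1, origin = 0) {
  shape <- as.integer(rep_len(shape, 3L))
  if (any(shape < 1L)) stop("shape components must be >= 1", call. = FALSE)
  voxel_grid(array(0, dim = shape), voxel_size = voxel_size, origin = origin)
}

#' Per-map metadata
#'
#' Carries deposition-level metadata alongside a map: an identifier, the
#' reported resolution, and a recommended display contour, any of which may
#' be absent (`NA`).
#'
#' @param source_id free-text identifier (e.g. an EMDB accession).
#' @param reported_resolution resolution in Å, or `NA`; must be positive when
#'   present.
#' @param recommended_contour recommended contour level, or `NA`.
#' @return An object of class `map_metadata`.
#' @export
map_metadata <- function(source_id = NA_character_,
                         reported_resolution = NA_real_,
                         recommended_contour = NA_real_) {
  reported_resolution <- as.numeric(reported_resolution)
  if (!is.na(reported_resolution) && reported_resolution <= 0)
    stop("reported_resolution must be positive when present", call. = FALSE)
  structure(list(source_id = as.character(source_id),
                 reported_resolution = reported_resolution,
                 recommended_contour = as.numeric(recommended_contour)),
            class = "map_metadata")
}

# do two grids share shape, voxel size and origin (within tol)?
same_geometry <- function(a, b, tol = 1e-4) {
  identical(dim(a$data), dim(b$data)) &&
    all(abs(a$voxel_size - b$voxel_size) <= tol) &&
    all(abs(a$origin - b$origin) <= tol)
}

# ---- MRC2014 header layout -------------------------------------------------
# 1024-byte header; 4-byte words. Words used here (1-based):
#   1-3   NC, NR, NS       storage dims: columns (fastest), rows, sections
#   4     MODE             0=int8, 1=int16, 2=float32
#   5-7   NCSTART/NRSTART/NSSTART
#   8-10  MX, MY, MZ       sampling along crystallographic X, Y, Z
#   11-13 CELLA            cell edge lengths (Å) along X, Y, Z
#   14-16 CELLB            cell angles (deg); only 90/90/90 supported
#   17-19 MAPC, MAPR, MAPS axis (1=X,2=Y,3=Z) for columns/rows/sections
#   20-22 DMIN, DMAX, DMEAN
#   23    ISPG    24 NSYMBT (bytes of extended header, skipped)
#   50-52 ORIGIN           physical origin (Å) along X, Y, Z
#   53    "MAP "  54 MACHST  55 RMS  56 NLABL  57-256 labels

#' Read an MRC/CCP4 density map
#'
#' Reads a volume and normalizes it to the package's canonical form: the data
#' array is reordered to `(z, y, x)` regardless of the header's axis mapping
#' (`MAPC`/`MAPR`/`MAPS`), the voxel size is `CELLA / (MX, MY, MZ)` per axis,
#' and the physical origin is resolved as: the `ORIGIN` header record when any
#' of its components is nonzero, otherwise the `N*START` offsets multiplied by
#' the voxel size. This is the prevailing convention across EMDB depositions.
#'
#' Only orthogonal cells (all angles 90°) are supported; single-particle
#' cryo-EM maps satisfy this.
#'
#' @param path path to an MRC/CCP4 file (modes 0, 1 and 2).
#' @return A [voxel_grid()].
#' @seealso [write_map()]
#' @export
read_map <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  con <- file(path, "rb")
  on.exit(close(con))
  hdr <- readBin(con, "raw", n = 1024L)
  if (length(hdr) < 1024L)
    stop("malformed MRC header: file shorter than 1024 bytes", call. = FALSE)

  # endianness from MACHST (word 54); 0x11 first byte means big-endian
  machst <- hdr[213:216]
  endian <- if (as.integer(machst[1]) == 0x11) "big" else "little"
  word_int <- function(w, n = 1L)
    readBin(hdr[(4L * (w - 1L) + 1L):(4L * (w + n - 1L))], "integer",
            n = n, size = 4L, endian = endian)
  word_dbl <- function(w, n = 1L)
    readBin(hdr[(4L * (w - 1L) + 1L):(4L * (w + n - 1L))], "numeric",
            n = n, size = 4L, endian = endian)

  nc <- word_int(1L); nr <- word_int(2L); ns <- word_int(3L)
  mode <- word_int(4L)
  nstart <- word_int(5L, 3L)
  m_xyz <- word_int(8L, 3L)
  cella <- word_dbl(11L, 3L)
  cellb <- word_dbl(14L, 3L)
  axes <- word_int(17L, 3L)      # c(mapc, mapr, maps)
  nsymbt <- word_int(24L)
  origin_rec <- word_dbl(50L, 3L)

  if (any(c(nc, nr, ns) <= 0L))
    stop("malformed MRC header: non-positive dimension in NX/NY/NZ",
         call. = FALSE)
  if (!(mode %in% c(0L, 1L, 2L)))
    stop("malformed MRC header: unsupported MODE ", mode, call. = FALSE)
  if (!setequal(axes, 1:3))
    stop("malformed MRC header: MAPC/MAPR/MAPS is not a permutation of 1..3",
         call. = FALSE)
  if (any(m_xyz <= 0L))
    stop("malformed MRC header: non-positive MX/MY/MZ", call. = FALSE)
  if (any(abs(cellb - 90) > 1e-3))
    stop("unsupported geometry: non-orthogonal cell (CELLB = ",
         paste(format(cellb), collapse = ", "), ")", call. = FALSE)
  if (any(cella <= 0))
    stop("malformed MRC header: non-positive CELLA", call. = FALSE)

  if (nsymbt > 0L) invisible(readBin(con, "raw", n = nsymbt))
  nvox <- as.numeric(nc) * nr * ns
  values <- switch(as.character(mode),
    "0" = as.numeric(readBin(con, "integer", n = nvox, size = 1L,
                             signed = TRUE)),
    "1" = as.numeric(readBin(con, "integer", n = nvox, size = 2L,
                             signed = TRUE, endian = endian)),
    "2" = readBin(con, "numeric", n = nvox, size = 4L, endian = endian)
  )
  if (length(values) < nvox)
    stop("malformed MRC file: data section truncated", call. = FALSE)

  file_arr <- array(values, dim = c(nc, nr, ns))
  # reorder storage axes (columns, rows, sections) to crystal axes (X, Y, Z)
  arr_xyz <- aperm(file_arr, match(1:3, axes))
  data_zyx <- aperm(arr_xyz, 3:1)

  voxel_xyz <- cella / m_xyz
  nstart_xyz <- numeric(3L)
  nstart_xyz[axes] <- nstart
  origin_xyz <- if (any(origin_rec != 0)) origin_rec else nstart_xyz * voxel_xyz

  voxel_grid(data_zyx, voxel_size = rev(voxel_xyz), origin = rev(origin_xyz))
}

#' Write a voxel grid as an MRC2014 file
#'
#' Writes mode-2 (32-bit float) with the canonical axis mapping
#' (`MAPC,MAPR,MAPS = 1,2,3`), the grid's voxel size encoded in
#' `CELLA`/`MX,MY,MZ`, and the physical origin in the `ORIGIN` record, so
#' that [read_map()] inverts the write exactly (up to float32 rounding of the
#' density values).
#'
#' @param grid a [voxel_grid()].
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_map <- function(grid, path) {
  stopifnot(is.voxel_grid(grid))
  d <- dim(grid$data)                 # (nz, ny, nx)
  n_xyz <- rev(d)
  voxel_xyz <- rev(grid$voxel_size)
  origin_xyz <- rev(grid$origin)

  con <- tryCatch(file(path, "wb"),
                  error = function(e) stop("cannot open for writing: ", path,
                                           call. = FALSE))
  on.exit(close(con))
  wi <- function(x) writeBin(as.integer(x), con, size = 4L, endian = "little")
  wf <- function(x) writeBin(as.numeric(x), con, size = 4L, endian = "little")

  vals <- as.numeric(grid$data)
  wi(n_xyz)                                   # NC, NR, NS
  wi(2L)                                      # MODE float32
  wi(c(0L, 0L, 0L))                           # N*START
  wi(n_xyz)                                   # MX, MY, MZ
  wf(n_xyz * voxel_xyz)                       # CELLA
  wf(c(90, 90, 90))                           # CELLB
  wi(1:3)                                     # MAPC, MAPR, MAPS
  wf(c(min(vals), max(vals), mean(vals)))     # DMIN, DMAX, DMEAN
  wi(c(1L, 0L))                               # ISPG, NSYMBT
  wi(rep(0L, 2L))                             # EXTRA words 25-26
  writeChar("MRCO", con, nchars = 4L, eos = NULL)  # EXTTYP
  wi(20140L)                                  # NVERSION
  wi(rep(0L, 21L))                            # EXTRA words 29-49
  wf(origin_xyz)                              # ORIGIN
  writeChar("MAP ", con, nchars = 4L, eos = NULL)
  writeBin(as.raw(c(0x44, 0x44, 0x00, 0x00)), con)  # MACHST little-endian
  wf(stats::sd(vals))                         # RMS
  wi(1L)                                      # NLABL
  lab <- formatC("Created by cryolabel", width = -80L)
  writeChar(lab, con, nchars = 80L, eos = NULL)
  writeBin(raw(9L * 80L), con)                # remaining label slots

  wf(as.numeric(aperm(grid$data, 3:1)))       # x fastest, z slowest
  invisible(path)
}
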