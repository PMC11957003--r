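# Voxel-label volume construction: the package's core output.
#
# Three aligned volumes are produced on the experimental map's grid:
#   regression     -- simulated density inside the 6 Å neighbourhood, else 0
#   classification -- 1 at atom voxels, 2 in the neighbourhood, 0 background
#   atom_type      -- atom class (1..5) at atom voxels only, 0 elsewhere
# Labels depend only on the experimental map's GEOMETRY, never its densities.

#' Neighbourhood specification
#'
#' Defines how labelled regions are extended around each atom: a voxel
#' belongs to the neighbourhood when the Euclidean distance from its CENTER
#' to the atom's continuous coordinate is within `radius` (inclusive by
#' default). The 6 Å default reflects the spatial extent of electron density
#' around an atom in high-resolution maps.
#'
#' @param radius neighbourhood radius in Å (>= 0), default 6.
#' @param inclusive logical; whether distance exactly equal to `radius`
#'   counts as inside (default `TRUE`).
#' @return An object of class `neighborhood_spec`.
#' @export
neighborhood_spec <- function(radius = 6.0, inclusive = TRUE) {
  if (!is.finite(radius) || radius < 0)
    stop("radius must be >= 0", call. = FALSE)
  structure(list(radius = radius, inclusive = isTRUE(inclusive)),
            class = "neighborhood_spec")
}

#' Convert Cartesian coordinates to voxel indices
#'
#' Maps continuous atomic coordinates `(x, y, z)` in Å onto 0-based grid
#' indices `(i, j, k)` with the floor convention:
#' `i = floor((z - oz)/vz)`, `j = floor((y - oy)/vy)`,
#' `k = floor((x - ox)/vx)`. Note the pairing: `i` indexes z, `k` indexes x,
#' matching the array's `(z, y, x)` order. Out-of-bounds indices are
#' returned as-is; callers decide how to handle them.
#'
#' @param coord numeric length-3 `(x, y, z)` or an n-by-3 matrix of such rows.
#' @param grid a [voxel_grid()] supplying origin and voxel size.
#' @param rounding `"floor"` (the standard cell-index convention, default)
#'   or `"nearest"`.
#' @return Integer matrix n-by-3 with columns `i`, `j`, `k` (0-based).
#' @examples
#' g <- empty_grid(c(16, 16, 16))
#' coord_to_voxel(c(10.4, 5.0, 3.7), g)   # i=3, j=5, k=10
#' @export
coord_to_voxel <- function(coord, grid, rounding = c("floor", "nearest")) {
  rounding <- match.arg(rounding)
  stopifnot(is.voxel_grid(grid))
  coord <- matrix(as.numeric(coord), ncol = 3L)
  # origin/voxel are (z,y,x); rearrange to match coord's (x,y,z) columns
  org_xyz <- rev(grid$origin)
  vox_xyz <- rev(grid$voxel_size)
  t_xyz <- sweep(sweep(coord, 2L, org_xyz, "-"), 2L, vox_xyz, "/")
  t_xyz <- if (rounding == "floor") floor(t_xyz) else round(t_xyz)
  out <- matrix(as.integer(t_xyz[, 3:1, drop = FALSE]), ncol = 3L)
  colnames(out) <- c("i", "j", "k")
  out
}

# TRUE for index rows falling inside the grid
in_bounds <- function(ijk, shape) {
  ijk[, 1L] >= 0L & ijk[, 1L] < shape[1L] &
    ijk[, 2L] >= 0L & ijk[, 2L] < shape[2L] &
    ijk[, 3L] >= 0L & ijk[, 3L] < shape[3L]
}

#' Distance-dilated atom mask
#'
#' Boolean grid that is `TRUE` exactly where the minimum Euclidean distance
#' from the voxel center to any atom coordinate is within the neighbourhood
#' radius.
#'
#' @param structure a `cryo_structure`.
#' @param grid a [voxel_grid()] supplying the geometry.
#' @param spec a [neighborhood_spec()].
#' @return Logical array with the grid's shape.
#' @export
dilated_mask <- function(structure, grid, spec = neighborhood_spec()) {
  stopifnot(inherits(spec, "neighborhood_spec"), is.voxel_grid(grid))
  if (!inherits(structure, "cryo_structure") || nrow(structure) == 0L)
    stop("structure must be a non-empty cryo_structure", call. = FALSE)
  n <- dim(grid$data)
  org <- grid$origin
  vox <- grid$voxel_size
  r <- spec$radius
  r2max <- r^2 + if (spec$inclusive) 1e-9 else -1e-9

  mask <- array(FALSE, dim = n)
  coords <- structure_coords(structure)
  for (a in seq_len(nrow(coords))) {
    p_zyx <- c(coords[a, 3L], coords[a, 2L], coords[a, 1L])
    lo <- pmax(ceiling((p_zyx - r - org) / vox - 1e-9), 0)
    hi <- pmin(floor((p_zyx + r - org) / vox + 1e-9), n - 1)
    if (any(lo > hi)) next
    dz <- org[1] + (lo[1]:hi[1]) * vox[1] - p_zyx[1]
    dy <- org[2] + (lo[2]:hi[2]) * vox[2] - p_zyx[2]
    dx <- org[3] + (lo[3]:hi[3]) * vox[3] - p_zyx[3]
    r2 <- outer(outer(dz^2, dy^2, "+"), dx^2, "+")
    sub <- mask[(lo[1]:hi[1]) + 1L, (lo[2]:hi[2]) + 1L, (lo[3]:hi[3]) + 1L,
                drop = FALSE]
    mask[(lo[1]:hi[1]) + 1L, (lo[2]:hi[2]) + 1L, (lo[3]:hi[3]) + 1L] <-
      sub | (r2 <= r2max)
  }
  mask
}

#' Regression label map
#'
#' Copies the simulated density at every voxel of the dilated neighbourhood
#' mask and sets everything else to exactly 0: a noise-free regression
#' target spatially aligned with the experimental map.
#'
#' @param structure a `cryo_structure`.
#' @param reference experimental-map [voxel_grid()] defining the geometry.
#' @param simulated simulated-map [voxel_grid()]; must share the reference's
#'   geometry.
#' @param spec a [neighborhood_spec()].
#' @return A [voxel_grid()] on the reference geometry.
#' @export
make_regression_label <- function(structure, reference, simulated,
                                  spec = neighborhood_spec()) {
  if (!same_geometry(reference, simulated))
    stop("alignment error: simulated map geometry differs from the reference",
         call. = FALSE)
  mask <- dilated_mask(structure, reference, spec)
  voxel_grid(simulated$data * mask,
             voxel_size = reference$voxel_size, origin = reference$origin)
}

#' Three-class segmentation label map
#'
#' Integer grid over `{0, 1, 2}`: voxels hit by an atom's index (via
#' [coord_to_voxel()]) get 1, remaining voxels of the dilated neighbourhood
#' get 2, background stays 0. Value 1 takes precedence over 2 regardless of
#' atom order.
#'
#' @inheritParams make_regression_label
#' @return A [voxel_grid()] with integer-valued data in `{0, 1, 2}`.
#' @export
make_classification_label <- function(structure, reference,
                                      spec = neighborhood_spec()) {
  stopifnot(is.voxel_grid(reference))
  lab <- array(0, dim = dim(reference$data))
  lab[dilated_mask(structure, reference, spec)] <- 2
  ijk <- coord_to_voxel(structure_coords(structure), reference)
  ok <- in_bounds(ijk, dim(reference$data))
  if (!any(ok)) {
    warning("all atoms fall outside the grid; classification label is all zero",
            call. = FALSE)
  } else {
    lab[ijk[ok, , drop = FALSE] + 1L] <- 1
  }
  voxel_grid(lab, voxel_size = reference$voxel_size, origin = reference$origin)
}

#' Atom-type label map
#'
#' Integer grid over `{0, ..., 5}`. Only the voxel holding each atom's index
#' is labelled (no neighbourhood dilation), with the class from
#' [classify_atoms()]; class-0 atoms leave no label. When two atoms map to
#' the same voxel the later atom in file order wins (deterministic
#' tie-break); collisions are reported via a message.
#'
#' @inheritParams make_regression_label
#' @return A [voxel_grid()] with integer-valued data in `{0, ..., 5}`.
#' @export
make_atomtype_label <- function(structure, reference) {
  stopifnot(is.voxel_grid(reference))
  lab <- array(0, dim = dim(reference$data))
  cls <- classify_atoms(structure)
  ijk <- coord_to_voxel(structure_coords(structure), reference)
  keep <- cls > 0L & in_bounds(ijk, dim(reference$data))
  if (any(keep)) {
    ijk <- ijk[keep, , drop = FALSE]
    lin <- 1L + ijk[, 1L] +
      dim(lab)[1L] * (ijk[, 2L] + dim(lab)[2L] * ijk[, 3L])
    if (anyDuplicated(lin))
      message(sum(duplicated(lin)),
              " atom-type collision(s): last atom in file order kept")
    # subassignment with duplicated indices keeps the last write
    lab[lin] <- cls[keep]
  }
  voxel_grid(lab, voxel_size = reference$voxel_size, origin = reference$origin)
}

#' Generate the full label bundle for one map/model pair
#'
#' Simulates density on the experimental map's grid, then builds the three
#' label volumes. All outputs share the experimental map's geometry, and the
#' labels are a function only of that geometry (plus the structure and
#' parameters) — the experimental density values themselves are never read.
#'
#' @param structure a `cryo_structure`.
#' @param experimental_map a [voxel_grid()], typically already resampled to
#'   1 Å with [resample()].
#' @param params a [simulation_params()].
#' @param spec a [neighborhood_spec()].
#' @return A `label_bundle`: list with [voxel_grid()] elements `regression`,
#'   `classification`, `atom_type`, plus the `simulated` intermediate.
#' @export
generate_labels <- function(structure, experimental_map, params,
                            spec = neighborhood_spec()) {
  simulated <- simulate_on_map(structure, experimental_map, params)
  structure(
    list(
      regression = make_regression_label(structure, experimental_map,
                                         simulated, spec),
      classification = make_classification_label(structure, experimental_map,
                                                 spec),
      atom_type = make_atomtype_label(structure, experimental_map),
      simulated = simulated
    ),
    class = "label_bundle"
  )
}

#' @export
print.label_bundle <- function(x, ...) {
  d <- dim(x$regression$data)
  cat(sprintf("<label_bundle> %d x %d x %d (z,y,x)\n", d[1], d[2], d[3]))
  cat(sprintf("  atom voxels: %d, neighbourhood voxels: %d\n",
              sum(x$classification$data == 1),
              sum(x$classification$data == 2)))
  cat(sprintf("  atom-type voxels by class 1..5: %s\n",
              paste(tabulate(x$atom_type$data[x$atom_type$data > 0],
                             nbins = 5L), collapse = ", ")))
  invisible(x)
}

#' Extract sub-cubes from a volume
#'
#' Tiles a volume into fixed-size cubes (default 64 voxels per edge) for
#' patch-based training. Tiles start at offsets `0, stride, 2*stride, ...`
#' on every axis; tiles crossing the boundary are zero-padded to the full
#' edge. Each tile records its 0-based `(i, j, k)` offset so positions are
#' recoverable; with `stride == cube_edge` the tiles partition the volume
#' and [reassemble_subcubes()] inverts the extraction.
#'
#' @param x a [voxel_grid()] or a 3-D array.
#' @param cube_edge tile edge in voxels (default 64).
#' @param stride step between tile starts in voxels (default `cube_edge`).
#' @return List of tiles, each a list with `data` (a `cube_edge`^3 array)
#'   and `offset` (integer length-3, 0-based).
#' @export
extract_subcubes <- function(x, cube_edge = 64L, stride = cube_edge) {
  arr <- if (is.voxel_grid(x)) x$data else x
  stopifnot(is.array(arr), length(dim(arr)) == 3L)
  cube_edge <- as.integer(cube_edge)
  stride <- as.integer(stride)
  if (cube_edge < 1L) stop("cube_edge must be >= 1", call. = FALSE)
  if (stride < 1L) stop("stride must be positive", call. = FALSE)
  n <- dim(arr)
  starts <- lapply(n, function(na) seq.int(0L, na - 1L, by = stride))
  tiles <- list()
  for (s1 in starts[[1]]) for (s2 in starts[[2]]) for (s3 in starts[[3]]) {
    cube <- array(0, dim = rep(cube_edge, 3L))
    e <- pmin(c(s1, s2, s3) + cube_edge, n)   # exclusive end in source
    len <- e - c(s1, s2, s3)
    cube[seq_len(len[1]), seq_len(len[2]), seq_len(len[3])] <-
      arr[(s1 + 1L):e[1], (s2 + 1L):e[2], (s3 + 1L):e[3], drop = FALSE]
    tiles[[length(tiles) + 1L]] <- list(data = cube,
                                        offset = c(s1, s2, s3))
  }
  tiles
}

#' Reassemble non-overlapping sub-cubes into a volume
#'
#' Inverse of [extract_subcubes()] for `stride == cube_edge`: places each
#' tile at its recorded offset and trims the zero padding.
#'
#' @param tiles list of tiles from [extract_subcubes()].
#' @param shape integer length-3 target shape `(nz, ny, nx)`.
#' @return A 3-D array of dimension `shape`.
#' @export
reassemble_subcubes <- function(tiles, shape) {
  out <- array(0, dim = shape)
  for (t in tiles) {
    s <- t$offset
    e <- pmin(s + dim(t$data), shape)
    len <- e - s
    out[(s[1] + 1L):e[1], (s[2] + 1L):e[2], (s[3] + 1L):e[3]] <-
      t$data[seq_len(len[1]), seq_len(len[2]), seq_len(len[3]), drop = FALSE]
  }
  out
}
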