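# Idealized noise-free density simulation by truncated Gaussian convolution.
#
# Each atom contributes a unit-integral isotropic Gaussian of width
# sigma = kernel_sigma_factor * resolution, truncated at cutoff_sigmas * sigma,
# evaluated at voxel centers. The default sigma factor 1/(2*sqrt(2*log(2)))
# makes the Gaussian FWHM equal the nominal resolution.

# monoisotopic-ish average masses for the "mass" amplitude mode
ATOMIC_MASS <- c(
  H = 1.008, C = 12.011, N = 14.007, O = 15.999, S = 32.06, P = 30.974,
  SE = 78.971, FE = 55.845, ZN = 65.38, MG = 24.305, CA = 40.078,
  MN = 54.938, "NA" = 22.99, K = 39.098, CL = 35.45, CU = 63.546, NI = 58.693
)

#' Simulation parameters
#'
#' Bundles the kernel settings for density simulation. `sigma` of the
#' Gaussian kernel is `kernel_sigma_factor * resolution`; the default factor
#' `1/(2*sqrt(2*log(2))) ~= 0.4247` sets the kernel FWHM equal to the nominal
#' resolution, a standard real-space convolution convention. Contributions
#' are truncated at `cutoff_sigmas * sigma` from the atom (spherical cutoff).
#'
#' @param resolution nominal resolution in Å (> 0); typically the map's
#'   reported resolution.
#' @param kernel_sigma_factor dimensionless; `sigma = factor * resolution`.
#' @param amplitude_mode `"unit"` (every atom weight 1) or `"mass"` (weight
#'   by atomic mass).
#' @param cutoff_sigmas truncation radius in sigma units (>= 3).
#' @return An object of class `simulation_params`.
#' @export
simulation_params <- function(resolution,
                              kernel_sigma_factor = 1 / (2 * sqrt(2 * log(2))),
                              amplitude_mode = c("unit", "mass"),
                              cutoff_sigmas = 4) {
  amplitude_mode <- match.arg(amplitude_mode)
  if (!is.finite(resolution) || resolution <= 0)
    stop("resolution must be positive", call. = FALSE)
  if (!is.finite(kernel_sigma_factor) || kernel_sigma_factor <= 0)
    stop("kernel_sigma_factor must be positive", call. = FALSE)
  if (!is.finite(cutoff_sigmas) || cutoff_sigmas < 3)
    stop("cutoff_sigmas must be >= 3", call. = FALSE)
  structure(list(resolution = resolution,
                 kernel_sigma_factor = kernel_sigma_factor,
                 amplitude_mode = amplitude_mode,
                 cutoff_sigmas = cutoff_sigmas),
            class = "simulation_params")
}

#' Simulate an idealized density map from a structure
#'
#' Real-space convolution of the atomic positions with a truncated,
#' unit-integral isotropic Gaussian: the field is
#' `sum_atoms a_atom * G_sigma(|r_center - r_atom|)` with
#' `G_sigma(r) = (2*pi*sigma^2)^(-3/2) * exp(-r^2 / (2*sigma^2))`, zero
#' beyond `cutoff_sigmas * sigma`. With unit amplitudes and 1 Å voxels the
#' values of one atom sum to ~1 (up to truncation error); total density is
#' linear in atom count.
#'
#' @param structure a `cryo_structure`.
#' @param grid_spec target geometry: a [voxel_grid()] (its density values are
#'   ignored) such as one built by [empty_grid()].
#' @param params a [simulation_params()].
#' @return A [voxel_grid()] with exactly `grid_spec`'s geometry. Warns when
#'   the kernel is narrower than half a voxel (aliasing) and when no atom
#'   falls inside the box (all-zero output).
#' @export
simulate_density <- function(structure, grid_spec, params) {
  stopifnot(inherits(params, "simulation_params"), is.voxel_grid(grid_spec))
  if (!inherits(structure, "cryo_structure") || nrow(structure) == 0L)
    stop("structure must be a non-empty cryo_structure", call. = FALSE)

  sigma <- params$kernel_sigma_factor * params$resolution
  if (sigma < max(grid_spec$voxel_size) / 2)
    warning("kernel sigma (", format(sigma, digits = 4),
            " Å) is below half the voxel size; expect aliasing",
            call. = FALSE)

  amp <- if (params$amplitude_mode == "mass") {
    m <- ATOMIC_MASS[toupper(structure$element)]
    if (anyNA(m)) {
      warning("unknown element(s) ",
              paste(unique(structure$element[is.na(m)]), collapse = ", "),
              "; using carbon mass", call. = FALSE)
      m[is.na(m)] <- ATOMIC_MASS[["C"]]
    }
    as.numeric(m)
  } else rep(1, nrow(structure))

  n <- dim(grid_spec$data)            # (nz, ny, nx)
  org <- grid_spec$origin             # (oz, oy, ox)
  vox <- grid_spec$voxel_size
  cutoff <- params$cutoff_sigmas * sigma
  norm <- (2 * pi * sigma^2)^(-1.5)
  inv2s2 <- 1 / (2 * sigma^2)

  out <- array(0, dim = n)
  coords <- structure_coords(structure)   # (x, y, z)
  n_hit <- 0L
  for (a in seq_len(nrow(coords))) {
    p_zyx <- c(coords[a, 3L], coords[a, 2L], coords[a, 1L])
    lo <- pmax(ceiling((p_zyx - cutoff - org) / vox), 0)
    hi <- pmin(floor((p_zyx + cutoff - org) / vox), n - 1)
    if (any(lo > hi)) next
    n_hit <- n_hit + 1L
    dz <- org[1] + (lo[1]:hi[1]) * vox[1] - p_zyx[1]
    dy <- org[2] + (lo[2]:hi[2]) * vox[2] - p_zyx[2]
    dx <- org[3] + (lo[3]:hi[3]) * vox[3] - p_zyx[3]
    r2 <- outer(outer(dz^2, dy^2, "+"), dx^2, "+")
    g <- amp[a] * norm * exp(-r2 * inv2s2)
    g[r2 > cutoff^2] <- 0
    out[(lo[1]:hi[1]) + 1L, (lo[2]:hi[2]) + 1L, (lo[3]:hi[3]) + 1L] <-
      out[(lo[1]:hi[1]) + 1L, (lo[2]:hi[2]) + 1L, (lo[3]:hi[3]) + 1L] + g
  }
  if (n_hit == 0L)
    warning("no atom contributes inside the target box; map is all zero",
            call. = FALSE)
  voxel_grid(out, voxel_size = vox, origin = org)
}

#' Simulate density on the grid of a reference map
#'
#' Runs [simulate_density()] on the reference map's exact geometry (shape,
#' voxel size, origin), guaranteeing voxel-wise alignment between the
#' simulated map and the experimental map it mirrors.
#'
#' @param structure a `cryo_structure`.
#' @param reference a [voxel_grid()] whose geometry is copied.
#' @param params a [simulation_params()].
#' @return A [voxel_grid()] aligned with `reference`.
#' @export
simulate_on_map <- function(structure, reference, params) {
  simulate_density(structure, reference, params)
}
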