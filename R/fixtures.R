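# Synthetic fixtures: toy structures plus matched noisy maps, so the whole
# label-generation and validation pipeline is exercisable with no downloads.
#
# Chemical realism is not the goal here; determinism and plausible geometry
# are. The helix constants (rise 1.5 Å, twist 100 degrees, CA radius 2.3 Å)
# are the textbook alpha-helix parameters; the non-CA atoms sit at fixed
# offsets in the local helical frame with roughly bond-length magnitudes.

#' Fixture specification
#'
#' Conditions for one synthetic map/model pair. Defaults describe a
#' mid-resolution single-particle scenario: a 10-residue helix, a 3 Å
#' kernel, 1 Å voxels, 8 Å of solvent padding, and white noise with
#' standard deviation 0.02 density units (moderate SNR relative to the
#' ~0.03 single-atom peak at 3 Å).
#'
#' @param n_residues residues in the poly-alanine helix (>= 1).
#' @param noise_sigma standard deviation of the additive Gaussian white
#'   noise (>= 0), in density units.
#' @param resolution nominal resolution in Å for the simulation kernel.
#' @param voxel_size fixture map voxel edge in Å.
#' @param box_pad padding around the structure's bounding box, Å per side.
#' @param seed integer seed for the noise.
#' @return An object of class `fixture_spec`.
#' @export
fixture_spec <- function(n_residues = 10L, noise_sigma = 0.02,
                         resolution = 3.0, voxel_size = 1.0,
                         box_pad = 8.0, seed = 1L) {
  if (n_residues < 1L) stop("n_residues must be >= 1", call. = FALSE)
  if (voxel_size <= 0) stop("voxel_size must be positive", call. = FALSE)
  if (noise_sigma < 0) stop("noise_sigma must be >= 0", call. = FALSE)
  structure(list(n_residues = as.integer(n_residues),
                 noise_sigma = noise_sigma, resolution = resolution,
                 voxel_size = voxel_size, box_pad = box_pad,
                 seed = as.integer(seed)),
            class = "fixture_spec")
}

#' Idealized poly-alanine alpha-helix
#'
#' Places N, CA, C, O and CB for each residue on a rigid helix: the CA trace
#' has rise 1.5 Å per residue, twist 100 degrees, radius 2.3 Å; the other
#' atoms sit at fixed offsets in the residue's local (radial, tangential,
#' axial) frame. Fully deterministic.
#'
#' @param n_residues number of residues (>= 1); 5 atoms per residue.
#' @return A `cryo_structure` with `5 * n_residues` atoms.
#' @export
make_helix <- function(n_residues) {
  if (n_residues < 1L) stop("n_residues must be >= 1", call. = FALSE)
  rise <- 1.5
  twist <- 100 * pi / 180
  radius <- 2.3
  # offsets (radial u, tangential v, axial w) per atom, roughly bond-scaled
  offsets <- rbind(
    N  = c(-0.35, -1.20, -0.60),
    CA = c(0, 0, 0),
    C  = c(-0.25, 1.25, 0.60),
    O  = c(0.35, 1.50, 1.65),
    CB = c(1.20, 0.45, -0.95)
  )
  elements <- c("N", "C", "C", "O", "C")

  rows <- vector("list", n_residues)
  for (t in seq_len(n_residues) - 1L) {
    theta <- t * twist
    u <- c(cos(theta), sin(theta), 0)
    v <- c(-sin(theta), cos(theta), 0)
    w <- c(0, 0, 1)
    ca <- c(radius * cos(theta), radius * sin(theta), t * rise)
    xyz <- t(apply(offsets, 1L, function(o) ca + o[1] * u + o[2] * v + o[3] * w))
    rows[[t + 1L]] <- data.frame(
      element = elements,
      atom_name = rownames(offsets),
      residue_name = "ALA",
      chain_id = "A",
      x = xyz[, 1], y = xyz[, 2], z = xyz[, 3],
      occupancy = 1,
      stringsAsFactors = FALSE
    )
  }
  as_structure(do.call(rbind, rows),
               source_id = sprintf("helix-%d", n_residues))
}

#' Simulated map plus a matched noisy "experimental-like" map
#'
#' Builds a grid sized to the structure's bounding box plus `box_pad` per
#' side, simulates the clean density, and adds seeded Gaussian white noise
#' of standard deviation `noise_sigma`. The noise model is deliberately
#' simple — white Gaussian background only, none of the structured noise
#' sources of real micrographs.
#'
#' @param structure a `cryo_structure`.
#' @param spec a [fixture_spec()].
#' @return List with `noisy` and `clean` [voxel_grid()]s on the same grid.
#' @export
make_noisy_map <- function(structure, spec) {
  stopifnot(inherits(spec, "fixture_spec"))
  coords <- structure_coords(structure)
  lo_xyz <- apply(coords, 2L, min) - spec$box_pad
  hi_xyz <- apply(coords, 2L, max) + spec$box_pad
  shape_xyz <- as.integer(floor((hi_xyz - lo_xyz) / spec$voxel_size)) + 1L
  geom <- empty_grid(rev(shape_xyz), voxel_size = spec$voxel_size,
                     origin = rev(lo_xyz))
  params <- simulation_params(resolution = spec$resolution)
  clean <- simulate_density(structure, geom, params)

  noisy <- clean
  if (spec$noise_sigma > 0) {
    old_seed <- if (exists(".Random.seed", envir = globalenv()))
      get(".Random.seed", envir = globalenv()) else NULL
    on.exit(if (!is.null(old_seed))
      assign(".Random.seed", old_seed, envir = globalenv()))
    set.seed(spec$seed)
    noisy$data <- clean$data +
      array(stats::rnorm(length(clean$data), sd = spec$noise_sigma),
            dim = dim(clean$data))
  }
  list(noisy = noisy, clean = clean)
}

#' End-to-end synthetic fixture bundle
#'
#' Helix, matched clean and noisy maps, standardization of the noisy map to
#' 1 Å when the fixture voxel differs, and the full label bundle on the
#' standardized grid — everything mutually aligned.
#'
#' @param spec a [fixture_spec()].
#' @return List with `structure`, `noisy`, `clean`, `standardized` (the
#'   noisy map at 1 Å) and `labels` (a `label_bundle`).
#' @export
make_fixture_bundle <- function(spec = fixture_spec()) {
  stru <- make_helix(spec$n_residues)
  maps <- make_noisy_map(stru, spec)
  standardized <- if (abs(spec$voxel_size - 1) > 1e-12)
    resample(maps$noisy, 1.0) else maps$noisy
  labels <- generate_labels(stru, standardized,
                            simulation_params(resolution = spec$resolution))
  list(structure = stru, noisy = maps$noisy, clean = maps$clean,
       standardized = standardized, labels = labels)
}

#' Write a structure as a minimal PDB file
#'
#' Enough of the PDB format for the fixture structures to round-trip through
#' [read_structure()]: ATOM records with coordinates, occupancy and element.
#'
#' @param structure a `cryo_structure`.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_structure_pdb <- function(structure, path) {
  name4 <- ifelse(nchar(structure$atom_name) < 4L,
                  sprintf(" %-3s", structure$atom_name),
                  structure$atom_name)
  # residue numbering: start a new residue when an atom name repeats
  resno <- integer(nrow(structure))
  current <- 0L
  seen <- character(0)
  for (i in seq_len(nrow(structure))) {
    if (structure$atom_name[i] %in% seen) {
      current <- current + 1L
      seen <- character(0)
    }
    if (current == 0L) current <- 1L
    seen <- c(seen, structure$atom_name[i])
    resno[i] <- current
  }
  lines <- sprintf(
    "ATOM  %5d %s %3s %s%4d    %8.3f%8.3f%8.3f%6.2f%6.2f          %2s",
    seq_len(nrow(structure)), name4, structure$residue_name,
    substr(structure$chain_id, 1, 1), resno,
    structure$x, structure$y, structure$z,
    structure$occupancy, 0, toupper(structure$element)
  )
  writeLines(c(lines, "END"), path)
  invisible(path)
}
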