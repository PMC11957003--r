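test_that("coordinate-to-index conversion follows the floor convention", {
  g <- empty_grid(16L, voxel_size = 1, origin = 0)
  expect_identical(as.integer(coord_to_voxel(c(10.4, 5.0, 3.7), g)),
                   c(3L, 5L, 10L))                    # (i,j,k) = (z,y,x)
  expect_identical(as.integer(coord_to_voxel(c(0, 0, 0), g)),
                   c(0L, 0L, 0L))
  g2 <- empty_grid(16L, voxel_size = 1, origin = -2)
  expect_identical(as.integer(coord_to_voxel(c(7.5, 2.25, 0.0), g2)),
                   c(2L, 4L, 9L))
  # nearest-integer alternative is available but floor is the default
  expect_identical(as.integer(coord_to_voxel(c(10.6, 0, 0), g, "nearest")[, "k"]),
                   11L)
})

test_that("radius-0 dilation marks exactly the atom's voxel", {
  g <- empty_grid(9L, voxel_size = 1, origin = 0)
  m <- dilated_mask(single_atom(4, 4, 4), g, neighborhood_spec(0))
  expect_identical(sum(m), 1L)
  expect_true(m[5, 5, 5])
})

test_that("a centered atom at radius 6 covers the 925-point lattice ball", {
  g <- empty_grid(21L, voxel_size = 1, origin = 0)
  m <- dilated_mask(single_atom(10, 10, 10), g, neighborhood_spec(6))
  expect_identical(sum(m), 925L)   # lattice offsets in [-6,6]^3 with ||.||<=6
})

test_that("disjoint atom balls add up; overlapping ones do not", {
  g <- empty_grid(c(15L, 15L, 41L), voxel_size = 1, origin = 0)
  two <- as_structure(rbind(single_atom(10, 7, 7), single_atom(30, 7, 7)))
  m <- dilated_mask(two, g, neighborhood_spec(6))
  expect_identical(sum(m), 2L * 925L)   # 20 A apart: disjoint
})

test_that("dilated_mask equals brute-force minimum-distance enumeration", {
  set.seed(31)
  for (trial in 1:4) {
    n <- sample(10:20, 1)
    natoms <- sample(1:5, 1)
    atoms <- as_structure(data.frame(
      element = "C", atom_name = "CA", residue_name = "ALA", chain_id = "A",
      x = runif(natoms, 0, n - 1), y = runif(natoms, 0, n - 1),
      z = runif(natoms, 0, n - 1), occupancy = 1, stringsAsFactors = FALSE))
    g <- empty_grid(n, voxel_size = 1, origin = 0)
    r <- runif(1, 2, 6)
    expect_identical(dilated_mask(atoms, g, neighborhood_spec(r)),
                     brute_mask(atoms, g, r))
  }
})

test_that("dilation is monotone in the radius", {
  set.seed(37)
  atoms <- as_structure(rbind(single_atom(5, 6, 7), single_atom(9, 9, 9)))
  g <- empty_grid(17L, voxel_size = 1, origin = 0)
  radii <- c(0, 1.5, 3, 4.5, 6)
  masks <- lapply(radii, function(r)
    dilated_mask(atoms, g, neighborhood_spec(r)))
  for (i in seq_len(length(radii) - 1))
    expect_true(all(masks[[i + 1]][masks[[i]]])) # mask(r1) subset of mask(r2)
})

test_that("regression label copies simulated density inside the mask only", {
  s <- make_helix(2)
  ref <- empty_grid(c(20L, 20L, 20L), voxel_size = 1, origin = c(-6, -6, -6))
  sim <- simulate_on_map(s, ref, simulation_params(3))
  reg <- make_regression_label(s, ref, sim, neighborhood_spec(6))
  mask <- dilated_mask(s, ref, neighborhood_spec(6))
  expect_identical(reg$data[mask], sim$data[mask])    # bitwise copy
  expect_true(all(reg$data[!mask] == 0))
  # geometry mismatch is an alignment error
  sim_shift <- sim
  sim_shift$origin <- sim$origin + 1
  expect_error(make_regression_label(s, ref, sim_shift), "alignment")
  # all-zero simulated map gives an all-zero label
  zero <- voxel_grid(array(0, dim = dim(ref$data)), 1, ref$origin)
  expect_true(all(make_regression_label(s, ref, zero)$data == 0))
})

test_that("classification label uses 1 for atoms, 2 for neighbours, 0 back", {
  s <- single_atom(8, 8, 8)
  ref <- empty_grid(17L, voxel_size = 1, origin = 0)
  lab <- make_classification_label(s, ref, neighborhood_spec(6))
  expect_identical(sort(unique(as.numeric(lab$data))), c(0, 1, 2))
  expect_identical(sum(lab$data == 1), 1L)
  expect_identical(sum(lab$data == 2), 924L)          # ball minus center
  # two atoms in one voxel still yield a single 1-voxel
  two <- as_structure(rbind(single_atom(8.2, 8.2, 8.2),
                            single_atom(8.4, 8.4, 8.4)))
  lab2 <- make_classification_label(two, ref, neighborhood_spec(6))
  expect_identical(sum(lab2$data == 1), 1L)
  # radius 0 leaves no 2s
  lab3 <- make_classification_label(s, ref, neighborhood_spec(0))
  expect_identical(sort(unique(as.numeric(lab3$data))), c(0, 1))
  # atoms entirely outside the grid: all zero with a warning
  far <- single_atom(500, 500, 500)
  expect_warning(lab4 <- make_classification_label(far, ref,
                                                   neighborhood_spec(6)),
                 "outside")
  expect_true(all(lab4$data == 0))
})

test_that("atom-type label marks atom voxels only, last writer wins", {
  ref <- empty_grid(17L, voxel_size = 1, origin = 0)
  gly <- as_structure(data.frame(
    element = c("N", "C", "C", "O"),
    atom_name = c("N", "CA", "C", "O"),
    residue_name = "GLY", chain_id = "A",
    x = c(2, 4, 6, 8), y = 8, z = 8, occupancy = 1,
    stringsAsFactors = FALSE))
  lab <- make_atomtype_label(gly, ref)
  expect_identical(sum(lab$data > 0), 4L)             # no dilation
  expect_identical(sum(lab$data == 2), 0L)            # glycine has no CB
  expect_identical(lab$data[9, 9, 5], 1)              # CA at x=4
  # collision: CA then N in the same voxel -> N (later in file order) wins
  clash <- as_structure(data.frame(
    element = c("C", "N"), atom_name = c("CA", "N"),
    residue_name = "ALA", chain_id = "A",
    x = c(8.1, 8.3), y = 8, z = 8, occupancy = 1, stringsAsFactors = FALSE))
  expect_message(lab2 <- make_atomtype_label(clash, ref), "collision")
  expect_identical(lab2$data[9, 9, 9], 5)
})

test_that("generated bundles satisfy the label-bundle invariants", {
  b <- make_fixture_bundle(fixture_spec(n_residues = 5, seed = 7))
  lab <- b$labels
  ref <- b$standardized
  for (grid in lab[c("regression", "classification", "atom_type")]) {
    expect_identical(dim(grid$data), dim(ref$data))
    expect_equal(grid$origin, ref$origin)
    expect_equal(grid$voxel_size, ref$voxel_size)
  }
  expect_true(all(lab$classification$data %in% 0:2))
  expect_true(all(lab$atom_type$data %in% 0:5))
  expect_true(all(lab$classification$data[lab$atom_type$data > 0] == 1))
  expect_true(all(lab$regression$data[lab$classification$data == 0] == 0))
  expect_true(all(lab$regression$data >= 0))
  # 1-voxels bounded by the in-bounds atom count
  expect_lte(sum(lab$classification$data == 1), nrow(b$structure))
})

test_that("labels depend on map geometry, not its density values", {
  s <- make_helix(3)
  ref <- empty_grid(c(24L, 20L, 20L), voxel_size = 1, origin = c(-6, -6, -6))
  noisy1 <- ref; noisy2 <- ref
  set.seed(1); noisy1$data[] <- rnorm(length(ref$data))
  set.seed(2); noisy2$data[] <- rnorm(length(ref$data))
  p <- simulation_params(3)
  b1 <- generate_labels(s, noisy1, p)
  b2 <- generate_labels(s, noisy2, p)
  expect_identical(b1$regression$data, b2$regression$data)
  expect_identical(b1$classification$data, b2$classification$data)
  expect_identical(b1$atom_type$data, b2$atom_type$data)
})

test_that("sub-cube extraction tiles, pads and round-trips", {
  g <- random_grid(n = 10L, seed = 13)
  one <- extract_subcubes(g, cube_edge = 10L)
  expect_length(one, 1L)
  expect_identical(one[[1]]$offset, c(0L, 0L, 0L))
  expect_identical(one[[1]]$data, g$data)

  tiles <- extract_subcubes(g, cube_edge = 6L, stride = 6L)
  expect_length(tiles, 8L)                     # ceil(10/6) = 2 per axis
  expect_identical(reassemble_subcubes(tiles, dim(g$data)), g$data)
  expect_error(extract_subcubes(g, cube_edge = 6L, stride = 0L), "stride")

  big <- array(0, dim = c(100, 100, 100))
  expect_length(extract_subcubes(big, 64L, 64L), 8L)
})
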