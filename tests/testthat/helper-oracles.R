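# Independent oracles and tiny fixture builders shared across tests.

# one heavy atom as a structure
single_atom <- function(x, y, z, element = "C", atom_name = "CA",
                        residue_name = "ALA") {
  as_structure(data.frame(element = element, atom_name = atom_name,
                          residue_name = residue_name, chain_id = "A",
                          x = x, y = y, z = z, occupancy = 1,
                          stringsAsFactors = FALSE))
}

# brute-force minimum-distance mask: full pairwise voxel-center/atom distances
brute_mask <- function(structure, grid, radius) {
  n <- dim(grid$data)
  org <- grid$origin
  vox <- grid$voxel_size
  idx <- which(array(TRUE, n), arr.ind = TRUE) - 1L
  centers <- cbind(org[1] + idx[, 1] * vox[1],
                   org[2] + idx[, 2] * vox[2],
                   org[3] + idx[, 3] * vox[3])   # (z, y, x)
  atoms <- cbind(structure$z, structure$y, structure$x)
  d2min <- rep(Inf, nrow(centers))
  for (a in seq_len(nrow(atoms))) {
    d2 <- (centers[, 1] - atoms[a, 1])^2 +
      (centers[, 2] - atoms[a, 2])^2 +
      (centers[, 3] - atoms[a, 3])^2
    d2min <- pmin(d2min, d2)
  }
  array(d2min <= radius^2 + 1e-9, dim = n)
}

# direct dense-matrix discrete Fourier transform (no stats::fft anywhere)
dft3 <- function(arr) {
  n <- dim(arr)
  dftmat <- function(na) {
    k <- 0:(na - 1)
    exp(-2i * pi * outer(k, k) / na)
  }
  out <- arr + 0i
  out <- array(dftmat(n[1]) %*% matrix(out, n[1], n[2] * n[3]), n)
  out <- aperm(out, c(2, 1, 3))
  out <- array(dftmat(n[2]) %*% matrix(out, n[2], n[1] * n[3]),
               c(n[2], n[1], n[3]))
  out <- aperm(out, c(2, 1, 3))
  out <- aperm(out, c(3, 2, 1))
  out <- array(dftmat(n[3]) %*% matrix(out, n[3], n[2] * n[1]),
               c(n[3], n[2], n[1]))
  aperm(out, c(3, 2, 1))
}

# FSC oracle built on dft3, with its own straightforward shell loop
oracle_fsc <- function(a, b) {
  n <- dim(a$data)
  vox <- a$voxel_size
  fa <- dft3(a$data)
  fb <- dft3(b$data)
  freq_axis <- function(na, va) {
    k <- 0:(na - 1)
    ifelse(k <= na %/% 2, k, k - na) / (na * va)
  }
  fz <- freq_axis(n[1], vox[1])
  fy <- freq_axis(n[2], vox[2])
  fx <- freq_axis(n[3], vox[3])
  ds <- 1 / max(n * vox)
  max_shell <- floor(1 / (2 * max(vox)) / ds + 1e-9)
  num <- den_a <- den_b <- numeric(max_shell)
  for (i in seq_len(n[1])) for (j in seq_len(n[2])) for (k in seq_len(n[3])) {
    s <- sqrt(fz[i]^2 + fy[j]^2 + fx[k]^2)
    sh <- round(s / ds)
    if (sh >= 1 && sh <= max_shell) {
      num[sh] <- num[sh] + Re(fa[i, j, k] * Conj(fb[i, j, k]))
      den_a[sh] <- den_a[sh] + abs(fa[i, j, k])^2
      den_b[sh] <- den_b[sh] + abs(fb[i, j, k])^2
    }
  }
  ok <- den_a > 0 & den_b > 0
  data.frame(shell_freq = (seq_len(max_shell) * ds)[ok],
             correlation = (num / sqrt(den_a * den_b))[ok])
}

# raw MRC writer for crafting header variants (permuted axes, nstart
# origins, bad modes); file_arr is in storage order (columns, rows, sections)
write_mrc_raw <- function(path, file_arr, axes = 1:3, cella, m_xyz,
                          nstart = c(0L, 0L, 0L), origin = c(0, 0, 0),
                          mode = 2L, cellb = c(90, 90, 90)) {
  con <- file(path, "wb")
  on.exit(close(con))
  wi <- function(x) writeBin(as.integer(x), con, size = 4L, endian = "little")
  wf <- function(x) writeBin(as.numeric(x), con, size = 4L, endian = "little")
  d <- dim(file_arr)
  wi(d); wi(mode); wi(nstart); wi(m_xyz); wf(cella); wf(cellb); wi(axes)
  wf(c(min(file_arr), max(file_arr), mean(file_arr)))
  wi(c(1L, 0L)); wi(rep(0L, 2L))
  writeChar("MRCO", con, nchars = 4L, eos = NULL)
  wi(20140L); wi(rep(0L, 21L)); wf(origin)
  writeChar("MAP ", con, nchars = 4L, eos = NULL)
  writeBin(as.raw(c(0x44, 0x44, 0x00, 0x00)), con)
  wf(sd(as.numeric(file_arr))); wi(0L)
  writeBin(raw(800L), con)
  wf(as.numeric(file_arr))
  invisible(path)
}

# minimal glycine (plus a hydrogen and a water that parsers must drop)
write_gly_pdb <- function(path) {
  writeLines(c(
    "ATOM      1  N   GLY A   1       1.000   2.000   3.000  1.00  0.00           N",
    "ATOM      2  CA  GLY A   1       2.000   2.500   3.500  1.00  0.00           C",
    "ATOM      3  C   GLY A   1       3.200   2.100   3.100  1.00  0.00           C",
    "ATOM      4  O   GLY A   1       3.900   3.000   2.800  1.00  0.00           O",
    "ATOM      5  H   GLY A   1       1.100   1.500   2.500  1.00  0.00           H",
    "HETATM    6  O   HOH A   2       8.000   8.000   8.000  1.00  0.00           O",
    "END"), path)
  path
}

write_gly_cif <- function(path) {
  writeLines(c(
    "data_gly",
    "loop_",
    "_atom_site.group_PDB", "_atom_site.id", "_atom_site.type_symbol",
    "_atom_site.label_atom_id", "_atom_site.label_alt_id",
    "_atom_site.label_comp_id", "_atom_site.label_asym_id",
    "_atom_site.label_entity_id", "_atom_site.label_seq_id",
    "_atom_site.pdbx_PDB_ins_code", "_atom_site.Cartn_x",
    "_atom_site.Cartn_y", "_atom_site.Cartn_z", "_atom_site.occupancy",
    "_atom_site.B_iso_or_equiv", "_atom_site.pdbx_formal_charge",
    "_atom_site.auth_seq_id", "_atom_site.auth_comp_id",
    "_atom_site.auth_asym_id", "_atom_site.auth_atom_id",
    "_atom_site.pdbx_PDB_model_num",
    "ATOM 1 N N . GLY A 1 1 ? 1.000 2.000 3.000 1.00 0.00 ? 1 GLY A N 1",
    "ATOM 2 C CA . GLY A 1 1 ? 2.000 2.500 3.500 1.00 0.00 ? 1 GLY A CA 1",
    "ATOM 3 C C . GLY A 1 1 ? 3.200 2.100 3.100 1.00 0.00 ? 1 GLY A C 1",
    "ATOM 4 O O . GLY A 1 1 ? 3.900 3.000 2.800 1.00 0.00 ? 1 GLY A O 1",
    "ATOM 5 H H . GLY A 1 1 ? 1.100 1.500 2.500 1.00 0.00 ? 1 GLY A H 1",
    "HETATM 6 O O . HOH A 2 . ? 8.000 8.000 8.000 1.00 0.00 ? 2 HOH A O 1"),
    path)
  path
}

# the six-entry toy manifest exercising every curation rule
toy_manifest <- function() {
  data.frame(
    map_id = c("A", "B", "C", "D", "E", "F"),
    model_id = c("M1", NA, "M4", "M2", "M3", "M3"),
    reported_resolution = c(2.5, 3.0, NA, 4.5, 2.0, 2.5),
    stringsAsFactors = FALSE
  )
}

random_grid <- function(n = 8L, voxel = 1, origin = 0, seed = 1L) {
  set.seed(seed)
  voxel_grid(array(rnorm(prod(rep(n, 3L))), dim = rep(n, 3L)),
             voxel_size = voxel, origin = origin)
}
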