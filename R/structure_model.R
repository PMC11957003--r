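# Atomic structure parsing and atom-class assignment.

# 3-letter codes treated as standard amino-acid residues for the CA/CB/C
# classes (the 20 canonical residues plus selenomethionine).
STANDARD_AA <- c(
  "ALA", "ARG", "ASN", "ASP", "CYS", "GLN", "GLU", "GLY", "HIS", "ILE",
  "LEU", "LYS", "MET", "PHE", "PRO", "SER", "THR", "TRP", "TYR", "VAL",
  "MSE"
)

WATER_RESIDUES <- c("HOH", "WAT", "DOD", "H2O")

#' Read an atomic structure
#'
#' Parses a PDB or mmCIF file (format chosen by extension: `.cif` is mmCIF,
#' anything else is PDB) and returns the heavy atoms in file order. Hydrogen
#' and deuterium atoms are dropped, as are waters; all other HETATM records
#' (ligands, ions, nucleotides) are kept. For atoms with alternate locations,
#' only the first conformer encountered is retained.
#'
#' @param path path to a `.pdb`/`.ent` or `.cif` file.
#' @param source_id identifier stored with the structure; defaults to the
#'   file name without extension.
#' @return A `cryo_structure`: a data frame with one row per atom and columns
#'   `element`, `atom_name`, `residue_name`, `chain_id`, `x`, `y`, `z`,
#'   `occupancy`, plus a `source_id` attribute.
#' @export
read_structure <- function(path, source_id = NULL) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  ext <- tolower(tools::file_ext(path))
  parsed <- tryCatch(
    if (ext == "cif") suppressWarnings(bio3d::read.cif(path))
    else bio3d::read.pdb(path),
    error = function(e) stop("cannot parse structure file '", path, "': ",
                             conditionMessage(e), call. = FALSE)
  )
  at <- parsed$atom

  element <- toupper(trimws(at$elesy))
  # fall back to the first alphabetic character of the atom name when the
  # element column is absent or blank (common in minimal PDB files)
  missing_el <- is.na(element) | element == ""
  if (any(missing_el)) {
    guess <- toupper(sub("^[0-9' ]*([A-Za-z]).*$", "\\1",
                         trimws(at$elety[missing_el])))
    element[missing_el] <- guess
  }

  keep <- !(element %in% c("H", "D")) &
    !(toupper(trimws(at$resid)) %in% WATER_RESIDUES)
  # first conformer per atom site
  site <- paste(at$chain, at$resno, at$insert, trimws(at$elety), sep = "|")
  keep <- keep & !duplicated(site)

  atoms <- data.frame(
    element = element[keep],
    atom_name = trimws(at$elety[keep]),
    residue_name = toupper(trimws(at$resid[keep])),
    chain_id = as.character(at$chain[keep]),
    x = at$x[keep], y = at$y[keep], z = at$z[keep],
    occupancy = ifelse(is.na(at$o[keep]), 1, at$o[keep]),
    stringsAsFactors = FALSE
  )
  if (nrow(atoms) == 0L)
    stop("empty structure: no heavy atoms in '", path, "'", call. = FALSE)
  if (any(!is.finite(as.matrix(atoms[, c("x", "y", "z")]))))
    stop("non-finite atom coordinates in '", path, "'", call. = FALSE)

  if (is.null(source_id))
    source_id <- tools::file_path_sans_ext(basename(path))
  structure(atoms, class = c("cryo_structure", "data.frame"),
            source_id = source_id)
}

#' Build a structure from in-memory atom records
#'
#' Used by the fixture generator and in tests; performs the same validation
#' as [read_structure()] but no filtering.
#'
#' @param atoms data frame with columns `element`, `atom_name`,
#'   `residue_name`, `chain_id`, `x`, `y`, `z`, and optionally `occupancy`.
#' @param source_id identifier stored with the structure.
#' @return A `cryo_structure`.
#' @export
as_structure <- function(atoms, source_id = "in-memory") {
  required <- c("element", "atom_name", "residue_name", "chain_id",
                "x", "y", "z")
  missing <- setdiff(required, names(atoms))
  if (length(missing))
    stop("atoms is missing columns: ", paste(missing, collapse = ", "),
         call. = FALSE)
  if (nrow(atoms) == 0L) stop("empty structure", call. = FALSE)
  if (is.null(atoms$occupancy)) atoms$occupancy <- 1
  structure(as.data.frame(atoms, stringsAsFactors = FALSE),
            class = c("cryo_structure", "data.frame"),
            source_id = source_id)
}

#' @export
print.cryo_structure <- function(x, ...) {
  cat(sprintf("<cryo_structure> %s: %d heavy atoms, %d chain(s)\n",
              attr(x, "source_id"), nrow(x),
              length(unique(x$chain_id))))
  invisible(x)
}

# n x 3 coordinate matrix in (x, y, z) order
structure_coords <- function(structure) {
  cbind(x = structure$x, y = structure$y, z = structure$z)
}

#' Classify atoms into the five atom-type label classes
#'
#' Assigns each heavy atom one of six integer classes used by the atom-type
#' label map: C-alpha (1), C-beta (2), backbone carbonyl carbon (3),
#' oxygen (4), nitrogen (5), and everything else (0: side-chain carbons,
#' sulfur, phosphorus, metals, ligand atoms).
#'
#' The carbon classes 1-3 require the element to be carbon AND the residue to
#' be a standard amino acid: a calcium ion is named "CA" in PDB files but is
#' not a C-alpha. Classes 4 and 5 apply to every oxygen/nitrogen atom,
#' backbone or side chain, in any residue.
#'
#' @param structure a `cryo_structure`, or a data frame with `element`,
#'   `atom_name` and `residue_name` columns.
#' @return Integer vector in `{0, ..., 5}`, one value per atom.
#' @export
classify_atoms <- function(structure) {
  el <- toupper(structure$element)
  nm <- toupper(structure$atom_name)
  res <- toupper(structure$residue_name)
  aa_carbon <- el == "C" & res %in% STANDARD_AA
  cls <- integer(nrow(structure))
  cls[el == "O"] <- 4L
  cls[el == "N"] <- 5L
  cls[aa_carbon & nm == "CA"] <- 1L
  cls[aa_carbon & nm == "CB"] <- 2L
  cls[aa_carbon & nm == "C"] <- 3L
  cls
}

#' Classify a single atom
#'
#' Scalar convenience wrapper around [classify_atoms()].
#'
#' @param atom_name PDB atom name (e.g. `"CA"`, `"CB"`, `"C"`).
#' @param element chemical element symbol.
#' @param residue_name 3-letter residue code.
#' @return Integer class in `{0, ..., 5}`.
#' @examples
#' classify_atom("CA", "C", "ALA")   # 1: C-alpha
#' classify_atom("C",  "C", "ALA")   # 3: carbonyl carbon
#' classify_atom("SG", "S", "CYS")   # 0: not a labelled class
#' @export
classify_atom <- function(atom_name, element, residue_name) {
  classify_atoms(data.frame(element = element, atom_name = atom_name,
                            residue_name = residue_name,
                            stringsAsFactors = FALSE))
}
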