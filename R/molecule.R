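#' Standard atomic weights
#'
#' Named vector of standard atomic weights (amu) for the elements that occur
#' in drug-like ligands and their common counter-ions, abridged from the
#' IUPAC 2021 standard atomic weight tables. Used to mass-weight the ligand
#' centroid.
#'
#' @format Named numeric vector, names are element symbols.
#' @export
atomic_weights <- c(
  H  = 1.008,   He = 4.0026, Li = 6.94,    Be = 9.0122, B  = 10.81,
  C  = 12.011,  N  = 14.007, O  = 15.999,  F  = 18.998, Ne = 20.180,
  Na = 22.990,  Mg = 24.305, Al = 26.982,  Si = 28.085, P  = 30.974,
  S  = 32.06,   Cl = 35.45,  Ar = 39.95,   K  = 39.098, Ca = 40.078,
  Mn = 54.938,  Fe = 55.845, Co = 58.933,  Ni = 58.693, Cu = 63.546,
  Zn = 65.38,   As = 74.922, Se = 78.971,  Br = 79.904, I  = 126.90,
  Du = 0.0
)

#' Look up atomic masses for element symbols
#'
#' @param element character vector of element symbols (case is normalised:
#'   first letter upper, rest lower).
#' @return numeric vector of masses in amu.
#' @keywords internal
element_mass <- function(element) {
  sym <- normalise_element(element)
  m <- atomic_weights[sym]
  if (anyNA(m)) {
    bad <- unique(sym[is.na(m)])
    stop("unknown element symbol(s): ", paste(bad, collapse = ", "),
         call. = FALSE)
  }
  unname(m)
}

normalise_element <- function(element) {
  paste0(toupper(substr(element, 1, 1)), tolower(substring(element, 2)))
}

#' Construct a molecule
#'
#' A molecule is an ordered set of atoms with element symbols, Cartesian
#' coordinates in Angstrom and atomic masses; atom order is significant and
#' preserved through all file round trips, because pose-to-reference atom
#' correspondence is positional.
#'
#' @param name molecule name (string).
#' @param element character vector of element symbols, one per atom.
#' @param coords numeric matrix, one row per atom, columns x, y, z (Angstrom).
#' @param charges optional numeric vector of per-atom partial charges.
#' @param sd_tags optional named character vector of SD data tags.
#' @return An object of class `molecule` with components `name`, `atoms`
#'   (data.frame: element, x, y, z, mass, is_heavy, charge) and `sd_tags`.
#' @examples
#' m <- molecule("co", c("C", "O"), rbind(c(0, 0, 0), c(1, 0, 0)))
#' centroid(m)
#' @export
molecule <- function(name, element, coords, charges = NULL, sd_tags = NULL) {
  coords <- matrix(as.numeric(coords), ncol = 3)
  n <- nrow(coords)
  if (n < 1L) stop("a molecule needs at least one atom", call. = FALSE)
  if (length(element) != n)
    stop("element/coords length mismatch", call. = FALSE)
  if (!all(is.finite(coords)))
    stop("non-finite coordinates", call. = FALSE)
  element <- normalise_element(element)
  mass <- element_mass(element)
  if (is.null(charges)) charges <- rep(NA_real_, n)
  atoms <- data.frame(
    element = element,
    x = coords[, 1], y = coords[, 2], z = coords[, 3],
    mass = mass,
    is_heavy = element != "H",
    charge = as.numeric(charges),
    stringsAsFactors = FALSE
  )
  structure(
    list(name = as.character(name), atoms = atoms,
         sd_tags = as_sd_tags(sd_tags)),
    class = "molecule"
  )
}

as_sd_tags <- function(x) {
  if (is.null(x) || length(x) == 0L) return(character(0))
  stopifnot(!is.null(names(x)))
  vapply(x, as.character, character(1))
}

#' @export
print.molecule <- function(x, ...) {
  cat("<molecule> ", x$name, ": ", nrow(x$atoms), " atoms (",
      sum(x$atoms$is_heavy), " heavy)", sep = "")
  if (length(x$sd_tags))
    cat(", tags: ", paste(names(x$sd_tags), collapse = ", "), sep = "")
  cat("\n")
  invisible(x)
}

#' @export
n_atoms <- function(mol) UseMethod("n_atoms")

#' @export
n_atoms.molecule <- function(mol) nrow(mol$atoms)

#' Coordinate matrix of a molecule
#'
#' @param mol a `molecule`.
#' @param heavy_only if TRUE, drop hydrogens.
#' @return numeric matrix with columns x, y, z.
#' @export
coords <- function(mol, heavy_only = FALSE) {
  a <- mol$atoms
  if (heavy_only) a <- a[a$is_heavy, , drop = FALSE]
  as.matrix(a[, c("x", "y", "z")])
}

#' Translate a molecule by a fixed vector
#'
#' @param mol a `molecule`.
#' @param shift numeric 3-vector in Angstrom.
#' @return the translated `molecule`.
#' @export
translate <- function(mol, shift) {
  stopifnot(length(shift) == 3L)
  mol$atoms$x <- mol$atoms$x + shift[1]
  mol$atoms$y <- mol$atoms$y + shift[2]
  mol$atoms$z <- mol$atoms$z + shift[3]
  mol
}

#' Reference ligand-protein complex
#'
#' Bundles the crystallographic metadata a benchmark cell needs: PDB code,
#' resolution (used as the per-structure RMSD cutoff R), ligand chemical
#' component code and the reference ligand structure.
#'
#' @param pdb_id 4-character PDB code.
#' @param resolution crystallographic resolution in Angstrom, > 0.
#' @param ligand_code 3-letter PDB chemical component id.
#' @param ligand the reference ligand as a `molecule`.
#' @param protein_path optional path to the protein structure file.
#' @return object of class `reference_complex`.
#' @export
reference_complex <- function(pdb_id, resolution, ligand_code, ligand,
                              protein_path = NA_character_) {
  if (!is.numeric(resolution) || length(resolution) != 1L || resolution <= 0)
    stop("resolution must be a single positive number", call. = FALSE)
  stopifnot(inherits(ligand, "molecule"))
  structure(
    list(pdb_id = as.character(pdb_id), resolution = as.numeric(resolution),
         ligand_code = as.character(ligand_code), ligand = ligand,
         protein_path = protein_path),
    class = "reference_complex"
  )
}

#' @export
print.reference_complex <- function(x, ...) {
  cat("<reference_complex> ", x$pdb_id, " (R = ", x$resolution, " A), ligand ",
      x$ligand_code, "\n", sep = "")
  invisible(x)
}

#' A set of docking poses for one structure-protocol pair
#'
#' @param structure_id PDB code of the target structure.
#' @param ligand_code 3-letter ligand id.
#' @param protocol_abbrev protocol abbreviation from [dock_protocols()].
#' @param poses ordered list of `molecule` poses (may be empty; an empty set
#'   marks a failed docking run downstream).
#' @return object of class `pose_set`.
#' @export
pose_set <- function(structure_id, ligand_code, protocol_abbrev, poses) {
  stopifnot(is.list(poses),
            all(vapply(poses, inherits, logical(1), "molecule")))
  structure(
    list(structure_id = as.character(structure_id),
         ligand_code = as.character(ligand_code),
         protocol_abbrev = as.character(protocol_abbrev),
         poses = poses),
    class = "pose_set"
  )
}

#' @export
print.pose_set <- function(x, ...) {
  cat("<pose_set> ", format_output_name(x$ligand_code, x$structure_id,
                                        x$protocol_abbrev),
      ": ", length(x$poses), " poses\n", sep = "")
  invisible(x)
}

#' Binding affinity record
#'
#' @param measure one of "Ki", "Kd", "IC50".
#' @param value positive affinity value.
#' @param unit unit string (e.g. "nM").
#' @return object of class `binding_record`.
#' @export
binding_record <- function(measure, value, unit = "nM") {
  measure <- match.arg(measure, c("Ki", "Kd", "IC50"))
  if (!is.numeric(value) || value <= 0)
    stop("binding value must be positive", call. = FALSE)
  structure(list(measure = measure, value = as.numeric(value),
                 unit = as.character(unit)),
            class = "binding_record")
}
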