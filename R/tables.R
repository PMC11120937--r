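#' @title Chemical constant tables
#' @description Internal lookup tables: van der Waals radii, heavy-atom
#'   dictionaries for the 20 standard amino acids, donor/acceptor/aromatic
#'   flags, and the element-specific mosaic-distance maxima used by the
#'   water-mediated contact mode.
#' @name contactvol-tables
#' @keywords internal
NULL

.cv_env <- new.env(parent = emptyenv())

#' Standard amino-acid heavy atoms
#'
#' Heavy (non-hydrogen) atom names per standard residue, backbone included.
#' Used to decide whether a (residue, atom) pair is a radii-table hit and
#' whether a residue counts as a standard amino acid.
#'
#' @return named list, residue 3-letter code -> character vector of atom names
#' @export
standard_residue_atoms <- function() {
  bb <- c("N", "CA", "C", "O", "OXT")
  side <- list(
    ALA = c("CB"),
    ARG = c("CB", "CG", "CD", "NE", "CZ", "NH1", "NH2"),
    ASN = c("CB", "CG", "OD1", "ND2"),
    ASP = c("CB", "CG", "OD1", "OD2"),
    CYS = c("CB", "SG"),
    GLN = c("CB", "CG", "CD", "OE1", "NE2"),
    GLU = c("CB", "CG", "CD", "OE1", "OE2"),
    GLY = character(0),
    HIS = c("CB", "CG", "ND1", "CD2", "CE1", "NE2"),
    ILE = c("CB", "CG1", "CG2", "CD1"),
    LEU = c("CB", "CG", "CD1", "CD2"),
    LYS = c("CB", "CG", "CD", "CE", "NZ"),
    MET = c("CB", "CG", "SD", "CE"),
    PHE = c("CB", "CG", "CD1", "CD2", "CE1", "CE2", "CZ"),
    PRO = c("CB", "CG", "CD"),
    SER = c("CB", "OG"),
    THR = c("CB", "OG1", "CG2"),
    TRP = c("CB", "CG", "CD1", "CD2", "NE1", "CE2", "CE3", "CZ2", "CZ3", "CH2"),
    TYR = c("CB", "CG", "CD1", "CD2", "CE1", "CE2", "CZ", "OH"),
    VAL = c("CB", "CG1", "CG2")
  )
  lapply(side, function(s) c(bb, s))
}

#' Element van der Waals radii table
#'
#' The pinned element radius set (Bondi heavy-atom values) bundled with the
#' package as a versioned CSV.  All geometry in the package is driven by
#' these radii.
#'
#' @return data.frame with columns `element`, `radius` (Angstrom)
#' @export
vdw_radii_table <- function() {
  if (is.null(.cv_env$vdw)) {
    path <- system.file("extdata", "vdw_radii.csv", package = "contactvol")
    .cv_env$vdw <- utils::read.csv(path, stringsAsFactors = FALSE)
  }
  .cv_env$vdw
}

#' Donor/acceptor/aromatic atom-class table
#'
#' Per-(residue, atom-name) hydrogen-bond donor, acceptor and aromatic flags
#' for standard residues.  Residue `*` rows apply to the backbone of every
#' standard amino acid; residue-specific rows override them (e.g. proline N
#' is not a donor).  The histidine aromatic set is restricted to the three
#' imidazole carbons CG, CD2 and CE1.
#'
#' @return data.frame with columns `residue`, `atom`, `donor`, `acceptor`,
#'   `aromatic`
#' @export
atom_class_table <- function() {
  if (is.null(.cv_env$classes)) {
    path <- system.file("extdata", "atom_classes.csv", package = "contactvol")
    .cv_env$classes <- utils::read.csv(path, stringsAsFactors = FALSE)
  }
  .cv_env$classes
}

#' Mosaic-distance maxima for hydrophilic elements
#'
#' Maximum allowed interpenetration (mosaic distance) between a water sphere
#' and the van der Waals sphere of each hydrophilic element, plus the water
#' geometry used throughout the water-mediated mode.
#'
#' @return list with `max_mosaic` (named numeric, Angstrom), `water_radius`
#'   (1.4 Angstrom) and `water_diameter` (2.8 Angstrom)
#' @export
mosaic_table <- function() {
  list(
    max_mosaic = c(N = 0.1, O = 0.2, P = 0.3, S = 0.5),
    water_radius = 1.4,
    water_diameter = 2.8
  )
}

#' Maximum mosaic distance for a hydrophilic element
#'
#' @param element element symbol; must be one of N, O, P, S
#' @return mosaic-distance maximum in Angstrom
#' @export
mosaic_threshold <- function(element) {
  tab <- mosaic_table()$max_mosaic
  el <- toupper(element)
  if (!el %in% names(tab)) {
    stop("no mosaic threshold for element '", element,
         "': only hydrophilic elements (N, O, P, S) bridge water")
  }
  unname(tab[[el]])
}

# element lookup with atom-name fallback; returns list(element, guessed)
.guess_element <- function(element_field, atom_name, resname) {
  el <- toupper(trimws(element_field))
  known <- vdw_radii_table()$element
  if (nzchar(el) && el %in% known) {
    return(list(element = el, guessed = FALSE))
  }
  nm <- toupper(trimws(atom_name))
  # two-letter ions/metals written as full atom name (FE, ZN, MG, ...)
  if (nm %in% known && nchar(nm) == 2 && !grepl("[0-9]", nm)) {
    return(list(element = nm, guessed = TRUE))
  }
  first <- sub("^[0-9']*", "", nm)
  first <- substr(first, 1L, 1L)
  if (nzchar(first) && first %in% known) {
    return(list(element = first, guessed = TRUE))
  }
  stop("cannot resolve element for atom '", atom_name, "' in residue '",
       resname, "' from either the element column or the atom name")
}

.element_radius <- function(element) {
  tab <- vdw_radii_table()
  i <- match(toupper(element), tab$element)
  if (is.na(i)) return(NA_real_)
  tab$radius[i]
}
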