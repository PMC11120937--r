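#' Analytic spherical-cap contact area
#'
#' Closed-form area of the portion of the host sphere's surface lying
#' inside the other sphere: `2*pi*r_host*h` with cap height
#' `h = r_host - (d^2 + r_host^2 - r_other^2) / (2d)`.  Used as the
#' independent reference for the grid estimator; never on the production
#' path.
#'
#' @param r_host radius of the sphere whose surface is counted, Angstrom
#' @param r_other radius of the covering sphere, Angstrom
#' @param d center distance, Angstrom
#' @return cap area, Angstrom^2 (0 when disjoint; full sphere when the host
#'   is nested inside the other)
#' @export
cap_area_oracle <- function(r_host, r_other, d) {
  stopifnot(r_host > 0, r_other > 0, d >= 0)
  if (d >= r_host + r_other) return(0)
  if (d + r_host <= r_other) return(4 * pi * r_host^2)  # host fully inside
  if (d + r_other <= r_host) {
    # other nested inside host: cap of host inside other is empty surface?
    # the host surface lies entirely outside the smaller nested sphere
    return(0)
  }
  h <- r_host - (d^2 + r_host^2 - r_other^2) / (2 * d)
  2 * pi * r_host * h
}

#' Analytic sphere-sphere lens (overlap) volume
#'
#' Closed-form volume of the intersection of two spheres; nested and
#' tangent configurations are handled by their limits.
#'
#' @param r1,r2 sphere radii, Angstrom
#' @param d center distance, Angstrom
#' @return overlap volume, Angstrom^3
#' @export
lens_volume_oracle <- function(r1, r2, d) {
  stopifnot(r1 > 0, r2 > 0, d >= 0)
  if (d >= r1 + r2) return(0)
  if (d + r1 <= r2) return(4 / 3 * pi * r1^3)
  if (d + r2 <= r1) return(4 / 3 * pi * r2^3)
  pi * (r1 + r2 - d)^2 *
    (d^2 + 2 * d * r2 - 3 * r2^2 + 2 * d * r1 + 6 * r1 * r2 - 3 * r1^2) /
    (12 * d)
}

#' Build a toy PDB file with two single-atom residues
#'
#' The two atoms sit on one chain, separated by `distance` along x.
#' Elements are mapped to representative standard-residue atoms so that
#' radius and class assignment exercise the table-hit path
#' (C -> ALA CB, N -> GLY N, O -> GLY O, S -> CYS SG); other elements are
#' emitted as HETATM with a generic residue name.
#'
#' @param elements character pair of element symbols
#' @param distance separation along x, Angstrom (> 0)
#' @param path output file; a tempfile by default
#' @return the path, invisibly; the emitted text is deterministic
#' @export
make_two_atom_pdb <- function(elements, distance,
                              path = tempfile(fileext = ".pdb")) {
  stopifnot(length(elements) == 2, distance > 0)
  map <- list(C = c("ALA", "CB"), N = c("GLY", "N"),
              O = c("GLY", "O"), S = c("CYS", "SG"))
  lines <- character(2)
  for (k in 1:2) {
    el <- toupper(elements[k])
    if (!is.null(map[[el]])) {
      rn <- map[[el]][1]; an <- map[[el]][2]; het <- FALSE
    } else {
      rn <- "UNL"; an <- el; het <- TRUE
    }
    lines[k] <- .format_pdb_atom(k, an, rn, "A", k,
                                 (k - 1) * distance, 0, 0, el, het = het)
  }
  writeLines(c(lines, "END"), path)
  invisible(path)
}

#' Build a toy PDB from an atom table
#'
#' General fixture builder: one line per row of `atoms` (columns `name`,
#' `resname`, `chain`, `resseq`, `x`, `y`, `z`, `element`, optional `het`).
#'
#' @param atoms data.frame describing the atoms
#' @param path output file; a tempfile by default
#' @return the path, invisibly
#' @export
make_atoms_pdb <- function(atoms, path = tempfile(fileext = ".pdb")) {
  het <- if (is.null(atoms$het)) rep(FALSE, nrow(atoms)) else atoms$het
  lines <- .format_pdb_atom(seq_len(nrow(atoms)), atoms$name, atoms$resname,
                            atoms$chain, atoms$resseq,
                            atoms$x, atoms$y, atoms$z, atoms$element,
                            het = het)
  writeLines(c(lines, "END"), path)
  invisible(path)
}

#' Build a multi-model (ensemble) toy PDB
#'
#' Each model is the base atom table rigidly displaced by the corresponding
#' 3-vector, wrapped in MODEL/ENDMDL blocks.  Per-atom displacement is also
#' supported by passing a function.
#'
#' @param atoms base atom data.frame (as for [make_atoms_pdb()])
#' @param displacements list of 3-vectors (one per model), or list of
#'   functions mapping the atom table to a displaced copy
#' @param path output file; a tempfile by default
#' @return the path, invisibly
#' @export
make_ensemble_pdb <- function(atoms, displacements,
                              path = tempfile(fileext = ".pdb")) {
  stopifnot(length(displacements) >= 1)
  het <- if (is.null(atoms$het)) rep(FALSE, nrow(atoms)) else atoms$het
  out <- character(0)
  for (m in seq_along(displacements)) {
    d <- displacements[[m]]
    a <- atoms
    if (is.function(d)) {
      a <- d(a)
    } else {
      a$x <- a$x + d[1]; a$y <- a$y + d[2]; a$z <- a$z + d[3]
    }
    out <- c(out, sprintf("MODEL %8d", m),
             .format_pdb_atom(seq_len(nrow(a)), a$name, a$resname,
                              a$chain, a$resseq, a$x, a$y, a$z, a$element,
                              het = het),
             "ENDMDL")
  }
  writeLines(c(out, "END"), path)
  invisible(path)
}
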