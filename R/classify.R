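#' Detect a disulfide bond
#'
#' True iff both atoms are the SG sulfur of a cysteine and their center
#' distance lies in the 1.95 to 2.1 Angstrom window.
#'
#' @param a,b one-row atom data.frames
#' @return logical
#' @export
detect_disulfide <- function(a, b) {
  if (!(a$resname == "CYS" && a$name == "SG" &&
        b$resname == "CYS" && b$name == "SG")) return(FALSE)
  d <- sqrt((a$x - b$x)^2 + (a$y - b$y)^2 + (a$z - b$z)^2)
  d >= 1.95 && d <= 2.1
}

#' Detect a peptide bond
#'
#' True iff `c_atom` is the backbone carbonyl C of residue i and `n_atom`
#' the backbone N of residue i+1 on the same chain, with center distance
#' at most 1.6 Angstrom (a canonical peptide bond is about 1.33 Angstrom;
#' 1.6 separates bonded from chain-break geometry).
#'
#' @param c_atom,n_atom one-row atom data.frames
#' @return logical
#' @export
detect_peptide_bond <- function(c_atom, n_atom) {
  if (!(c_atom$name == "C" && n_atom$name == "N")) return(FALSE)
  if (c_atom$chain != n_atom$chain) return(FALSE)
  if (n_atom$resseq != c_atom$resseq + 1L) return(FALSE)
  d <- sqrt((c_atom$x - n_atom$x)^2 + (c_atom$y - n_atom$y)^2 +
              (c_atom$z - n_atom$z)^2)
  d <= 1.6
}

#' Non-covalent contact type labels of an atom pair
#'
#' Returns every applicable label, ordered by the fixed priority
#' HB > AROM > PHOB > DC > OTHER (labels can co-occur: e.g. two aromatic
#' carbons are AROM and PHOB).  HB requires a donor/acceptor combination
#' at a center distance within 1.5 to 3.5 Angstrom; AROM both atoms
#' aromatic; PHOB both hydrophobic; DC one hydrophobic and one
#' hydrophilic; OTHER when no rule fires.
#'
#' @param a,b one-row atom data.frames with class flags
#' @param distance center distance, Angstrom
#' @return character vector of labels (at least one)
#' @export
contact_type <- function(a, b, distance) {
  labels <- character(0)
  hb_pair <- (isTRUE(a$donor) && isTRUE(b$acceptor)) ||
    (isTRUE(a$acceptor) && isTRUE(b$donor))
  if (hb_pair && distance >= 1.5 && distance <= 3.5) labels <- c(labels, "HB")
  if (isTRUE(a$aromatic) && isTRUE(b$aromatic)) labels <- c(labels, "AROM")
  if (isTRUE(a$hydrophobic) && isTRUE(b$hydrophobic)) labels <- c(labels, "PHOB")
  if ((isTRUE(a$hydrophobic) && isTRUE(b$hydrophilic)) ||
      (isTRUE(a$hydrophilic) && isTRUE(b$hydrophobic))) labels <- c(labels, "DC")
  if (length(labels) == 0) labels <- "OTHER"
  labels
}

#' Sequence-separation class of a residue pair
#'
#' Inner-chain pairs are partitioned by the absolute residue-number
#' difference: S (1-2), M (3-4), L1 (5-10), L2 (11-20), L3 (21-30),
#' L4 (31-40), L5 (41-50), L6 (>50).  Pairs on different chains are
#' class I regardless of numbering.
#'
#' @param chain_a,chain_b chain identifiers
#' @param seq_a,seq_b residue sequence numbers
#' @return one of "S", "M", "L1".."L6", "I"
#' @export
separation_class <- function(chain_a, seq_a, chain_b, seq_b) {
  if (chain_a != chain_b) return("I")
  dd <- abs(seq_a - seq_b)
  if (dd == 0) {
    stop("separation_class: same residue (self-contacts are excluded upstream)")
  }
  if (dd <= 2) "S"
  else if (dd <= 4) "M"
  else if (dd <= 10) "L1"
  else if (dd <= 20) "L2"
  else if (dd <= 30) "L3"
  else if (dd <= 40) "L4"
  else if (dd <= 50) "L5"
  else "L6"
}

#' Torsion (dihedral) angle of four points
#'
#' Signed dihedral about the p2-p3 axis, IUPAC convention, in degrees,
#' mapped to (-180, 180].  Returns `NA` for collinear geometry.
#'
#' @param p1,p2,p3,p4 3-vectors
#' @return angle in degrees, or `NA`
#' @export
torsion_angle <- function(p1, p2, p3, p4) {
  b1 <- p2 - p1; b2 <- p3 - p2; b3 <- p4 - p3
  cross <- function(u, v) c(u[2] * v[3] - u[3] * v[2],
                            u[3] * v[1] - u[1] * v[3],
                            u[1] * v[2] - u[2] * v[1])
  n1 <- cross(b1, b2); n2 <- cross(b2, b3)
  if (sum(n1^2) < 1e-12 || sum(n2^2) < 1e-12) return(NA_real_)
  b2h <- b2 / sqrt(sum(b2^2))
  ang <- atan2(sum(cross(n1, n2) * b2h), sum(n1 * n2)) * 180 / pi
  if (ang <= -180) ang <- ang + 360
  ang
}

#' Backbone phi/psi dihedrals of a model
#'
#' `phi = torsion(C[i-1], N[i], CA[i], C[i])` and
#' `psi = torsion(N[i], CA[i], C[i], N[i+1])`.  Angles are reported only
#' for standard amino acids with the full set of backbone atoms present
#' and a peptide-bonded neighbor; otherwise `NA` (terminal residues lose
#' one angle each).
#'
#' @param model assigned per-model atom data.frame
#' @return data.frame with one row per solute residue: `resid`, `chain`,
#'   `resseq`, `icode`, `resname`, `is_standard`, `phi`, `psi` (degrees)
#' @export
dihedrals <- function(model) {
  sol <- solute_atoms(model)
  key <- paste(sol$chain, sol$resseq, sol$icode, sep = "\r")
  res <- sol[!duplicated(key), c("resid", "chain", "resseq", "icode",
                                 "resname", "is_standard")]
  res <- res[order(res$chain, res$resseq, res$icode), , drop = FALSE]
  rownames(res) <- NULL
  res$phi <- NA_real_
  res$psi <- NA_real_

  bb <- function(chain, resseq, icode, name) {
    m <- sol[sol$chain == chain & sol$resseq == resseq &
               sol$icode == icode & sol$name == name, , drop = FALSE]
    if (nrow(m) == 0) return(NULL)
    c(m$x[1], m$y[1], m$z[1])
  }
  linked <- function(ci, cj) {  # peptide bond between C of ci and N of cj
    a <- sol[sol$chain == res$chain[ci] & sol$resseq == res$resseq[ci] &
               sol$icode == res$icode[ci] & sol$name == "C", , drop = FALSE]
    b <- sol[sol$chain == res$chain[cj] & sol$resseq == res$resseq[cj] &
               sol$icode == res$icode[cj] & sol$name == "N", , drop = FALSE]
    nrow(a) == 1 && nrow(b) == 1 && detect_peptide_bond(a[1, ], b[1, ])
  }

  for (k in seq_len(nrow(res))) {
    if (!res$is_standard[k]) next
    N <- bb(res$chain[k], res$resseq[k], res$icode[k], "N")
    CA <- bb(res$chain[k], res$resseq[k], res$icode[k], "CA")
    C <- bb(res$chain[k], res$resseq[k], res$icode[k], "C")
    if (is.null(N) || is.null(CA) || is.null(C)) next
    if (k > 1 && res$chain[k - 1] == res$chain[k] && linked(k - 1, k)) {
      Cprev <- bb(res$chain[k - 1], res$resseq[k - 1], res$icode[k - 1], "C")
      if (!is.null(Cprev)) res$phi[k] <- torsion_angle(Cprev, N, CA, C)
    }
    if (k < nrow(res) && res$chain[k + 1] == res$chain[k] && linked(k, k + 1)) {
      Nnext <- bb(res$chain[k + 1], res$resseq[k + 1], res$icode[k + 1], "N")
      if (!is.null(Nnext)) res$psi[k] <- torsion_angle(N, CA, C, Nnext)
    }
  }
  res
}
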