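# Shared in-code fixtures: all PDB inputs are generated at test time.

# Extended three-residue backbone with plausible bond geometry:
# C(i)-N(i+1) about 1.48 A (peptide-bonded), well-defined torsions.
toy_tripeptide_atoms <- function(resnames = c("ALA", "ALA", "ALA")) {
  rows <- list()
  for (i in 0:2) {
    x0 <- 3.8 * i
    zig <- if (i %% 2 == 0) 1 else -1
    rows[[length(rows) + 1]] <- data.frame(
      name = c("N", "CA", "C", "O", "CB"),
      resname = resnames[i + 1], chain = "A", resseq = i + 1,
      x = x0 + c(0, 1.458, 2.55, 2.75, 1.9),
      y = c(0, 0, 0.8, 2.0, -0.9) * zig,
      z = c(0, 0, 0, 0, 1.1),
      element = c("N", "C", "C", "O", "C"),
      stringsAsFactors = FALSE)
  }
  df <- do.call(rbind, rows)
  if (resnames[1] == "GLY") df <- df[!(df$resseq == 1 & df$name == "CB"), ]
  df
}

toy_tripeptide_pdb <- function(path = tempfile(fileext = ".pdb"), ...) {
  make_atoms_pdb(toy_tripeptide_atoms(...), path)
}

# one parsed, assigned model from an atom table
assigned_model <- function(atoms) {
  parse_structure(make_atoms_pdb(atoms))$models[[1]]
}

# a single-row pseudo atom for the pairwise classify/solvation operations
fake_atom <- function(name, resname, chain = "A", resseq = 1,
                      x = 0, y = 0, z = 0, element = substr(name, 1, 1),
                      vdw = NULL, serial = 1L) {
  hydro <- element %in% c("N", "O", "P", "S")
  if (is.null(vdw)) {
    vdw <- c(C = 1.70, N = 1.55, O = 1.52, S = 1.80, P = 1.80)[[element]]
  }
  data.frame(serial = serial, name = name, resname = resname, chain = chain,
             resseq = resseq, icode = "", x = x, y = y, z = z,
             element = element, vdw = vdw, hydrophilic = hydro,
             hydrophobic = element == "C", donor = FALSE, acceptor = FALSE,
             aromatic = FALSE, is_water = FALSE, is_standard = TRUE,
             resid = paste0(chain, ":", resseq, ":", resname),
             stringsAsFactors = FALSE)
}

# Monte-Carlo overlap estimators, independent of both the closed forms and
# the grid path (used to validate the oracles themselves)
mc_lens_volume <- function(r1, r2, d, n = 1e6) {
  lo <- c(d - r2, -min(r1, r2), -min(r1, r2))
  hi <- c(r1, min(r1, r2), min(r1, r2))
  p <- cbind(runif(n, lo[1], hi[1]), runif(n, lo[2], hi[2]),
             runif(n, lo[3], hi[3]))
  inside <- rowSums(p^2) <= r1^2 &
    ((p[, 1] - d)^2 + p[, 2]^2 + p[, 3]^2) <= r2^2
  prod(hi - lo) * mean(inside)
}

mc_cap_area <- function(r_host, r_other, d, n = 1e6) {
  z <- runif(n, -1, 1)
  phi <- runif(n, 0, 2 * pi)
  s <- sqrt(1 - z^2)
  p <- cbind(s * cos(phi), s * sin(phi), z) * r_host
  inside <- ((p[, 1] - d)^2 + p[, 2]^2 + p[, 3]^2) <= r_other^2
  4 * pi * r_host^2 * mean(inside)
}
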