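#' Filter contacts by area/volume cutoffs
#'
#' Keeps records with `area >= min_area` and `volume >= min_volume`
#' (boundary inclusive).  Defaults of 0 keep everything.  Suggested
#' genuine-contact thresholds for NMR ensembles are 0.5 Angstrom^2 and
#' 0.25 Angstrom^3.
#'
#' @param contacts contact record data.frame
#' @param min_area,min_volume non-negative thresholds
#' @return filtered data.frame
#' @export
apply_cutoff <- function(contacts, min_area = 0, min_volume = 0) {
  if (min_area < 0 || min_volume < 0) {
    stop("cutoff thresholds must be non-negative")
  }
  contacts[contacts$area >= min_area & contacts$volume >= min_volume, ,
           drop = FALSE]
}

.resid_sort_key <- function(resid) {
  parts <- strsplit(resid, ":", fixed = TRUE)
  chain <- vapply(parts, `[`, "", 1)
  seqi <- vapply(parts, `[`, "", 2)
  num <- as.integer(sub("[^0-9-]+$", "", seqi))
  icode <- sub("^[0-9-]+", "", seqi)
  order(chain, num, icode)
}

#' Aggregate atom-pair contacts to residue pairs
#'
#' One summary row per unordered residue pair with at least one surviving
#' atom contact; `area`/`volume`/`aowv` are the exact sums of the pair's
#' atom-level values, accumulated over a canonically ordered contact list
#' so the floating-point totals are bit-identical under input permutation.
#'
#' @param contacts contact record data.frame (one model)
#' @return data.frame with `residue1`, `residue2`, `class`, `area`,
#'   `volume`, `aowv`, `n_atom_pairs`
#' @export
residue_pair_totals <- function(contacts) {
  if (nrow(contacts) == 0) {
    return(data.frame(residue1 = character(0), residue2 = character(0),
                      class = character(0), area = numeric(0),
                      volume = numeric(0), aowv = numeric(0),
                      n_atom_pairs = integer(0), stringsAsFactors = FALSE))
  }
  cc <- contacts[order(contacts$serial1, contacts$serial2), , drop = FALSE]
  key <- paste(cc$residue1, cc$residue2, sep = "\r")
  groups <- split(seq_len(nrow(cc)), key)
  # deterministic group order: first appearance in the serial-sorted list
  groups <- groups[order(vapply(groups, min, 1L))]
  rows <- lapply(groups, function(ix) {
    g <- cc[ix, , drop = FALSE]
    data.frame(residue1 = g$residue1[1], residue2 = g$residue2[1],
               class = g$class[1],
               area = sum(g$area), volume = sum(g$volume),
               aowv = sum(g$aowv), n_atom_pairs = nrow(g),
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Per-residue contact summary
#'
#' Aggregates atom-pair records to one row per solute residue, splitting
#' covalent (Cova) from non-covalent (NC) totals disjointly; contacts of
#' non-standard residues at covalent-bond distance (< 1.6 Angstrom) that
#' are not recognized peptide/disulfide bonds are attributed to UNDEF
#' (ambiguous link type) instead of being guessed.  Backbone phi/psi
#' angles and per-residue SASA are attached when available.
#'
#' @param model assigned per-model atom data.frame
#' @param contacts contact record data.frame for that model
#' @param atom_sasa optional named per-atom SASA vector (names = serials)
#' @return data.frame, one row per residue
#' @export
residue_summaries <- function(model, contacts, atom_sasa = NULL) {
  dih <- dihedrals(model)
  sol <- solute_atoms(model)

  n <- nrow(dih)
  zero <- numeric(n)
  out <- data.frame(resid = dih$resid, resname = dih$resname,
                    is_standard = dih$is_standard,
                    phi = dih$phi, psi = dih$psi,
                    cova_area = zero, nc_area = zero,
                    cova_volume = zero, nc_volume = zero,
                    cova_aowv = zero, nc_aowv = zero,
                    undef_area = zero, undef_volume = zero,
                    sasa = NA_real_, stringsAsFactors = FALSE)

  if (!is.null(atom_sasa)) {
    per_res <- tapply(atom_sasa[as.character(sol$serial)], sol$resid, sum)
    out$sasa <- as.numeric(per_res[out$resid])
  }

  if (nrow(contacts) > 0) {
    std <- stats::setNames(dih$is_standard, dih$resid)
    amb <- (!std[contacts$residue1] | !std[contacts$residue2]) &
      !contacts$covalent & contacts$distance < 1.6
    amb[is.na(amb)] <- FALSE
    for (side in c("residue1", "residue2")) {
      ids <- contacts[[side]]
      for (k in seq_len(nrow(contacts))) {
        i <- match(ids[k], out$resid)
        if (is.na(i)) next
        if (amb[k]) {
          out$undef_area[i] <- out$undef_area[i] + contacts$area[k]
          out$undef_volume[i] <- out$undef_volume[i] + contacts$volume[k]
        } else if (contacts$covalent[k]) {
          out$cova_area[i] <- out$cova_area[i] + contacts$area[k]
          out$cova_volume[i] <- out$cova_volume[i] + contacts$volume[k]
          out$cova_aowv[i] <- out$cova_aowv[i] + contacts$aowv[k]
        } else {
          out$nc_area[i] <- out$nc_area[i] + contacts$area[k]
          out$nc_volume[i] <- out$nc_volume[i] + contacts$volume[k]
          out$nc_aowv[i] <- out$nc_aowv[i] + contacts$aowv[k]
        }
      }
    }
  }
  out
}
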