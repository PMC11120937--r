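#' Atom sphere
#'
#' Minimal sphere representation for the pairwise geometry operations: a
#' center and the radius actually used by the grid (i.e. already expanded
#' by the applicable solvent term).
#'
#' @param center 3-vector, Angstrom
#' @param radius sphere radius, Angstrom (> 0)
#' @return list of class `atom_sphere`
#' @export
atom_sphere <- function(center, radius) {
  stopifnot(length(center) == 3, radius > 0)
  structure(list(center = as.numeric(center), radius = as.numeric(radius)),
            class = "atom_sphere")
}

# logical containment matrix: points (m x 3) vs spheres (list of atom_sphere)
.inside_matrix <- function(points, spheres) {
  m <- nrow(points)
  out <- matrix(FALSE, m, length(spheres))
  for (k in seq_along(spheres)) {
    s <- spheres[[k]]
    d2 <- (points[, 1] - s$center[1])^2 + (points[, 2] - s$center[2])^2 +
      (points[, 3] - s$center[3])^2
    # closed-ball membership with a relative guard so points lying exactly
    # on the sphere are classified consistently despite rounding
    out[, k] <- d2 <= s$radius^2 * (1 + 1e-9)
  }
  out
}

.check_degenerate <- function(a, b) {
  d <- sqrt(sum((a$center - b$center)^2))
  if (d < 0.01) {
    stop("degenerate geometry: sphere centers coincide (distance ",
         format(d), " Angstrom)")
  }
  d
}

# one-sided contact area: surface of `host` inside `other`, occupancy-shared
.area_one_sided <- function(host, other, context, spec) {
  pts <- surface_points(host$center, host$radius, spec$n_surface_points)
  ds <- 4 * pi * host$radius^2 / spec$n_surface_points
  ins <- .inside_matrix(pts, c(list(other), context))
  ci <- rowSums(ins)
  sel <- ins[, 1]
  if (!any(sel)) return(0)
  ds * sum(1 / ci[sel])
}

# one-sided contact volume/AOWV: lattice of `host` restricted to `other`
.volume_one_sided <- function(host, other, context, spec) {
  lat <- lattice_points(host$center, host$radius, spec$lattice_spacing)
  ins <- .inside_matrix(lat, c(list(other), context))
  ci <- rowSums(ins)
  sel <- ins[, 1]
  if (!any(sel)) return(c(V = 0, V0 = 0))
  c(V = spec$delta_v * sum(1 / ci[sel]),
    V0 = spec$delta_v * sum(1 + ci[sel]))
}

#' Grid contact surface area between two spheres
#'
#' Surface points of each sphere lying inside the other are tallied; a
#' point covered by `ci` atoms besides its host contributes `1/ci` of its
#' surface element, so area shared among several contacts is never double
#' counted.  The reported pair area is the mean of the two one-sided areas
#' (the two spheres' curvatures differ, so their one-sided areas do).
#'
#' @param a,b `atom_sphere` objects (radii already expanded)
#' @param context list of additional `atom_sphere`s competing for the same
#'   surface elements
#' @param spec a [grid_spec()]
#' @param sides `"mean"` (default) or `"a"`/`"b"` for the one-sided value
#' @return contact area, Angstrom^2 (0 when the spheres are disjoint)
#' @export
contact_area <- function(a, b, context = list(), spec = grid_spec(),
                         sides = c("mean", "a", "b")) {
  sides <- match.arg(sides)
  d <- .check_degenerate(a, b)
  if (d >= a$radius + b$radius) return(0)
  if (sides == "a") return(.area_one_sided(a, b, context, spec))
  if (sides == "b") return(.area_one_sided(b, a, context, spec))
  (.area_one_sided(a, b, context, spec) +
     .area_one_sided(b, a, context, spec)) / 2
}

#' Grid contact volume between two spheres
#'
#' The overlap (lens) volume, estimated as the mean of two one-sided cubic
#' lattice sums (lattice of `a` restricted to points inside `b`, and vice
#' versa), each summing `delta_v / ci` per point so that volume shared by
#' several atom pairs is counted once per host traversal.  Averaging the
#' two one-sided estimates makes the result exactly symmetric in (a, b)
#' and halves the discretization bias.
#'
#' @inheritParams contact_area
#' @return contact volume, Angstrom^3 (0 when disjoint)
#' @export
contact_volume <- function(a, b, context = list(), spec = grid_spec()) {
  d <- .check_degenerate(a, b)
  if (d >= a$radius + b$radius) return(0)
  va <- .volume_one_sided(a, b, context, spec)
  vb <- .volume_one_sided(b, a, context, spec)
  unname((va["V"] + vb["V"]) / 2)
}

#' Atomic-overlap-weighted volume (AOWV) between two spheres
#'
#' Same lattice traversal as [contact_volume()], but each overlap element
#' is weighted by the total number of atoms covering it (`1 + ci`) instead
#' of being shared.  On an isolated pair every element has `ci = 1`, so the
#' AOWV equals exactly twice the contact volume; with deeper multi-atom
#' overlap it grows beyond that, emphasizing crowded regions.
#'
#' @inheritParams contact_area
#' @return weighted overlap volume, Angstrom^3
#' @export
aowv <- function(a, b, context = list(), spec = grid_spec()) {
  d <- .check_degenerate(a, b)
  if (d >= a$radius + b$radius) return(0)
  va <- .volume_one_sided(a, b, context, spec)
  vb <- .volume_one_sided(b, a, context, spec)
  unname((va["V0"] + vb["V0"]) / 2)
}

#' Grid solvent-accessible surface area of one sphere
#'
#' Surface points of `a` (expanded radius) lying inside no context sphere,
#' times the per-point surface element.
#'
#' @param a `atom_sphere` with the probe-expanded radius
#' @param context list of `atom_sphere`s that can bury the surface
#' @param spec a [grid_spec()]
#' @return exposed area, Angstrom^2
#' @export
sasa <- function(a, context = list(), spec = grid_spec()) {
  pts <- surface_points(a$center, a$radius, spec$n_surface_points)
  ds <- 4 * pi * a$radius^2 / spec$n_surface_points
  if (length(context) == 0) return(ds * nrow(pts))
  ins <- .inside_matrix(pts, context)
  ds * sum(rowSums(ins) == 0)
}

# ---------------------------------------------------------------------------
# whole-model engine

.atom_type_label <- function(donor, acceptor, aromatic, hydrophilic) {
  ifelse(donor & acceptor, "don/acc",
    ifelse(donor, "don",
      ifelse(acceptor, "acc",
        ifelse(aromatic, "arom",
          ifelse(hydrophilic, "phil", "phob")))))
}

#' Compute all atom-pair contacts of one model
#'
#' The engine behind the per-structure analysis.  In the default mode every
#' solute atom is a sphere of radius vdW + `spec$solvent_radius`; a contact
#' record is emitted for every pair of overlapping spheres belonging to
#' different residues, carrying the grid contact area `S`, shared contact
#' volume `V`, overlap-weighted volume `V0`, covalent flag (peptide and
#' disulfide bonds), non-covalent type labels and sequence-separation
#' class.  Occupancy counts `ci` are taken over all other overlapping
#' solute atoms, so surface and volume shared with third atoms is split.
#' In the water-mediated mode (see [water_mediated_pair()]) records are
#' emitted only for hydrophilic-bearing pairs whose vdW-sphere gap is
#' below the water diameter, and the reported S/V/V0 are the bridge-water
#' contact values.
#'
#' @param model assigned per-model atom data.frame
#' @param spec a [grid_spec()]
#' @param mode `"default"` or `"water"`
#' @param custom_d optional custom contact distance (Angstrom): in default
#'   mode restricts pairs to vdW gap < `custom_d`; in water mode replaces
#'   the 2.8 Angstrom eligibility gap
#' @param with_sasa also compute per-atom SASA
#' @return list with `contacts` (one row per surviving atom pair) and
#'   `atom_sasa` (named by serial, or NULL)
#' @export
compute_model_contacts <- function(model, spec = grid_spec(),
                                   mode = c("default", "water"),
                                   custom_d = NULL, with_sasa = FALSE) {
  mode <- match.arg(mode)
  sol <- solute_atoms(model)
  sol <- sol[order(sol$serial), , drop = FALSE]
  rownames(sol) <- NULL
  n <- nrow(sol)
  pos <- cbind(sol$x, sol$y, sol$z)

  if (mode == "default") {
    r <- sol$vdw + spec$solvent_radius
  } else {
    r <- sol$vdw + ifelse(sol$hydrophilic, spec$solvent_radius, 0)
  }

  # geometric adjacency over expanded spheres via the cell list
  cutoff_global <- 2 * max(r)
  idx <- build_cell_index(sol, cell_size = max(cutoff_global, 1))
  adj <- vector("list", n)
  for (i in seq_len(n)) {
    nb <- neighbors_within(idx, i, cutoff_global)
    if (length(nb)) {
      d <- sqrt(colSums((t(pos[nb, , drop = FALSE]) - pos[i, ])^2))
      if (any(d < 0.01)) {
        j <- nb[which(d < 0.01)[1]]
        stop("degenerate geometry: atoms ", sol$serial[i], " (", sol$name[i],
             " ", sol$resid[i], ") and ", sol$serial[j], " (", sol$name[j],
             " ", sol$resid[j], ") are coincident")
      }
      nb <- nb[d < r[i] + r[nb]]
    }
    adj[[i]] <- nb
  }

  sasa_vec <- NULL
  if (with_sasa) {
    sasa_vec <- numeric(n)
    for (i in seq_len(n)) {
      ctx <- lapply(adj[[i]], function(j) atom_sphere(pos[j, ], r[j]))
      sasa_vec[i] <- sasa(atom_sphere(pos[i, ], r[i]), ctx, spec)
    }
    names(sasa_vec) <- sol$serial
  }

  if (mode == "water") {
    contacts <- .water_mode_contacts(sol, pos, spec, custom_d)
  } else {
    contacts <- .default_mode_contacts(sol, pos, r, adj, spec, custom_d)
  }
  list(contacts = contacts, atom_sasa = sasa_vec, solute = sol)
}

.pair_meta <- function(sol, i, j, d) {
  cov_ss <- detect_disulfide(sol[i, ], sol[j, ])
  cov_pep <- detect_peptide_bond(sol[i, ], sol[j, ]) ||
    detect_peptide_bond(sol[j, ], sol[i, ])
  covalent <- cov_ss || cov_pep
  labels <- if (covalent) "Cova" else contact_type(sol[i, ], sol[j, ], d)
  contact <- labels[1]
  cls <- separation_class(sol$chain[i], sol$resseq[i],
                          sol$chain[j], sol$resseq[j])
  list(covalent = covalent, labels = paste(labels, collapse = "+"),
       contact = contact, class = cls)
}

.contact_row <- function(sol, i, j, d, S, V, V0, meta) {
  data.frame(
    serial1 = sol$serial[i], residue1 = sol$resid[i], atom1 = sol$name[i],
    type1 = .atom_type_label(sol$donor[i], sol$acceptor[i],
                             sol$aromatic[i], sol$hydrophilic[i]),
    serial2 = sol$serial[j], residue2 = sol$resid[j], atom2 = sol$name[j],
    type2 = .atom_type_label(sol$donor[j], sol$acceptor[j],
                             sol$aromatic[j], sol$hydrophilic[j]),
    distance = d, area = S, volume = V, aowv = V0,
    covalent = meta$covalent, contact = meta$contact,
    labels = meta$labels, class = meta$class,
    stringsAsFactors = FALSE
  )
}

.default_mode_contacts <- function(sol, pos, r, adj, spec, custom_d) {
  n <- nrow(sol)
  S_one <- vector("list", n); V_one <- vector("list", n)
  V0_one <- vector("list", n)
  for (i in seq_len(n)) {
    nb <- adj[[i]]
    S_one[[i]] <- stats::setNames(numeric(length(nb)), nb)
    V_one[[i]] <- stats::setNames(numeric(length(nb)), nb)
    V0_one[[i]] <- stats::setNames(numeric(length(nb)), nb)
    if (!length(nb)) next
    spheres <- lapply(nb, function(j) atom_sphere(pos[j, ], r[j]))
    ds <- 4 * pi * r[i]^2 / spec$n_surface_points
    pts <- surface_points(pos[i, ], r[i], spec$n_surface_points)
    ins <- .inside_matrix(pts, spheres)
    ci <- rowSums(ins)
    lat <- lattice_points(pos[i, ], r[i], spec$lattice_spacing)
    insv <- .inside_matrix(lat, spheres)
    civ <- rowSums(insv)
    for (k in seq_along(nb)) {
      sel <- ins[, k]
      if (any(sel)) S_one[[i]][k] <- ds * sum(1 / ci[sel])
      selv <- insv[, k]
      if (any(selv)) {
        V_one[[i]][k] <- spec$delta_v * sum(1 / civ[selv])
        V0_one[[i]][k] <- spec$delta_v * sum(1 + civ[selv])
      }
    }
  }

  rows <- list()
  for (i in seq_len(n)) {
    for (j in adj[[i]]) {
      if (j <= i) next
      if (sol$resid[i] == sol$resid[j]) next  # intra-residue never emitted
      d <- sqrt(sum((pos[i, ] - pos[j, ])^2))
      if (!is.null(custom_d) && (d - sol$vdw[i] - sol$vdw[j]) >= custom_d) next
      S <- (S_one[[i]][[as.character(j)]] + S_one[[j]][[as.character(i)]]) / 2
      V <- (V_one[[i]][[as.character(j)]] + V_one[[j]][[as.character(i)]]) / 2
      V0 <- (V0_one[[i]][[as.character(j)]] + V0_one[[j]][[as.character(i)]]) / 2
      meta <- .pair_meta(sol, i, j, d)
      rows[[length(rows) + 1]] <- .contact_row(sol, i, j, d, S, V, V0, meta)
    }
  }
  if (!length(rows)) return(.empty_contacts())
  out <- do.call(rbind, rows)
  out[order(out$serial1, out$serial2), , drop = FALSE]
}

.water_mode_contacts <- function(sol, pos, spec, custom_d) {
  n <- nrow(sol)
  gap_max <- if (is.null(custom_d)) mosaic_table()$water_diameter else custom_d
  rows <- list()
  for (i in seq_len(n - 1)) {
    for (j in (i + 1):n) {
      if (sol$resid[i] == sol$resid[j]) next
      if (!(sol$hydrophilic[i] || sol$hydrophilic[j])) next
      d <- sqrt(sum((pos[i, ] - pos[j, ])^2))
      gap <- d - sol$vdw[i] - sol$vdw[j]
      if (gap >= gap_max) next
      wm <- water_mediated_pair(sol[i, ], sol[j, ], spec = spec)
      meta <- .pair_meta(sol, i, j, d)
      rows[[length(rows) + 1]] <-
        .contact_row(sol, i, j, d, wm["area"], wm["volume"],
                     2 * wm["volume"], meta)
    }
  }
  if (!length(rows)) return(.empty_contacts())
  out <- do.call(rbind, rows)
  out[order(out$serial1, out$serial2), , drop = FALSE]
}

.empty_contacts <- function() {
  data.frame(serial1 = integer(0), residue1 = character(0),
             atom1 = character(0), type1 = character(0),
             serial2 = integer(0), residue2 = character(0),
             atom2 = character(0), type2 = character(0),
             distance = numeric(0), area = numeric(0),
             volume = numeric(0), aowv = numeric(0),
             covalent = logical(0), contact = character(0),
             labels = character(0), class = character(0),
             stringsAsFactors = FALSE)
}
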