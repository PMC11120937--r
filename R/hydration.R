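#' Nearest water to an atom, by spherical distance
#'
#' The spherical distance is the center distance minus both van der Waals
#' radii (the atom's and the water oxygen's); negative values mean the
#' spheres interpenetrate (a mosaic distance).  Ties are broken by the
#' lowest water serial.
#'
#' @param atom one-row atom data.frame (assigned)
#' @param waters data.frame of water oxygen atoms (assigned)
#' @return list with `water` (one-row data.frame) and
#'   `spherical_distance` (Angstrom)
#' @export
nearest_water <- function(atom, waters) {
  if (is.null(waters) || nrow(waters) == 0) {
    stop("no water molecules present in the model")
  }
  d <- sqrt((waters$x - atom$x)^2 + (waters$y - atom$y)^2 +
              (waters$z - atom$z)^2) - atom$vdw - waters$vdw
  best <- which(d == min(d))
  best <- best[which.min(waters$serial[best])]
  list(water = waters[best, , drop = FALSE], spherical_distance = d[best])
}

#' Interference label of an atom's nearest-water pairing
#'
#' `"no_interference"` iff the focal atom is also the solute atom nearest
#' (by spherical distance) to that water; otherwise another atom stands
#' between them and the label is `"interference"`.  Ties resolve to the
#' lowest serial.
#'
#' @param atom one-row atom data.frame
#' @param water one-row water data.frame (from [nearest_water()])
#' @param solute data.frame of all solute atoms
#' @return `"no_interference"` or `"interference"`
#' @export
interference_label <- function(atom, water, solute) {
  d <- sqrt((solute$x - water$x)^2 + (solute$y - water$y)^2 +
              (solute$z - water$z)^2) - solute$vdw - water$vdw
  best <- which(d == min(d))
  best <- best[which.min(solute$serial[best])]
  if (solute$serial[best] == atom$serial) "no_interference" else "interference"
}

.atom_category <- function(name, element) {
  backbone <- name %in% c("N", "C", "O")
  ifelse(element %in% c("C", "N", "O"),
         ifelse(backbone, element, paste0(element, "*")),
         element)
}

#' Nearest-water hydration records for a model
#'
#' One record per solute atom: its nearest water, the spherical distance,
#' the (amino acid, atom category) cell and the interference label.
#' Categories follow the peptide-plane convention: backbone N/C/O keep
#' their element symbol, all remaining atoms of that element are starred
#' (C*, N*, O*); CA counts as C*.
#'
#' @param model assigned per-model atom data.frame containing waters
#' @return data.frame of per-atom records
#' @export
hydration_records <- function(model) {
  sol <- solute_atoms(model)
  waters <- model[model$is_water & model$element == "O", , drop = FALSE]
  if (nrow(waters) == 0) stop("no water molecules present in the model")
  rows <- lapply(seq_len(nrow(sol)), function(i) {
    nw <- nearest_water(sol[i, ], waters)
    data.frame(
      serial = sol$serial[i], resid = sol$resid[i],
      resname = sol$resname[i], atom = sol$name[i],
      category = .atom_category(sol$name[i], sol$element[i]),
      water_serial = nw$water$serial,
      spherical_distance = nw$spherical_distance,
      interference = interference_label(sol[i, ], nw$water, sol),
      stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Bin hydration records into a spherical-distance profile
#'
#' Left-closed 0.1 Angstrom bins over -2.0 to 2.8 Angstrom by default.
#' Counts and ratios are reported per (amino acid, atom category) cell;
#' ratios normalize each cell's counts by its in-range total (cells with
#' no in-range records get ratio 0).
#'
#' @param records output of [hydration_records()]
#' @param bin bin width, Angstrom (> 0)
#' @param range length-2 numeric, profiled distance window
#' @return object of class `hydration_profile`: list with `breaks`,
#'   `table` (resname, category, bin_left, count, ratio) and `records`
#' @export
bin_profile <- function(records, bin = 0.1, range = c(-2.0, 2.8)) {
  if (bin <= 0) stop("bin width must be positive")
  if (nrow(records) == 0) stop("no hydration records to bin")
  breaks <- seq(range[1], range[2], by = bin)
  inr <- records$spherical_distance >= range[1] &
    records$spherical_distance < range[2]
  rec <- records[inr, , drop = FALSE]
  cells <- unique(records[, c("resname", "category")])
  cells <- cells[order(cells$resname, cells$category), , drop = FALSE]
  rows <- list()
  for (k in seq_len(nrow(cells))) {
    sel <- rec$resname == cells$resname[k] & rec$category == cells$category[k]
    h <- if (any(sel)) {
      graphics::hist(rec$spherical_distance[sel], breaks = breaks,
                     plot = FALSE, right = FALSE)$counts
    } else rep(0L, length(breaks) - 1)
    tot <- sum(h)
    rows[[k]] <- data.frame(
      resname = cells$resname[k], category = cells$category[k],
      bin_left = breaks[-length(breaks)], count = h,
      ratio = if (tot > 0) h / tot else rep(0, length(h)),
      stringsAsFactors = FALSE)
  }
  structure(list(breaks = breaks, table = do.call(rbind, rows),
                 records = records),
            class = "hydration_profile")
}

#' Export a hydration profile as CSV files
#'
#' Writes `records.csv` (per-atom nearest-water records) and
#' `profile.csv` (binned counts and ratios) into a directory.
#'
#' @param profile a `hydration_profile`
#' @param dir output directory (created if needed)
#' @return character vector of the two paths, invisibly
#' @export
write_hydration_csv <- function(profile, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  p1 <- file.path(dir, "records.csv")
  p2 <- file.path(dir, "profile.csv")
  utils::write.csv(profile$records, p1, row.names = FALSE)
  utils::write.csv(profile$table, p2, row.names = FALSE)
  invisible(c(p1, p2))
}
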