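#' Is an atom pair eligible for water-mediated contact?
#'
#' Eligible when at least one of the two atoms is hydrophilic (N, O, P or
#' S) and the closest distance between their van der Waals spheres (center
#' distance minus both vdW radii) is smaller than one water diameter.
#'
#' @param a,b one-row atom data.frames (assigned model rows) with columns
#'   `x`, `y`, `z`, `vdw`, `hydrophilic`
#' @param gap_max eligibility gap, Angstrom (water diameter 2.8 by default;
#'   the CLI `-d` flag overrides it)
#' @return logical
#' @export
bridge_eligible <- function(a, b, gap_max = mosaic_table()$water_diameter) {
  if (!(isTRUE(a$hydrophilic) || isTRUE(b$hydrophilic))) return(FALSE)
  d <- sqrt((a$x - b$x)^2 + (a$y - b$y)^2 + (a$z - b$z)^2)
  (d - a$vdw - b$vdw) < gap_max
}

# on-axis anchored water position: distance t from the anchor center.
# The water aims at overlap m_h with the anchor's vdW sphere, but is pushed
# away from the anchor (never toward it) when needed to respect the
# partner's own mosaic allowance, so the achieved mosaic distance never
# exceeds the anchor element's table maximum.
.anchored_water_t <- function(r_h, m_h, r_p, m_p, d, water_r) {
  max(r_h + water_r - m_h, d - r_p - water_r + m_p)
}

#' Place a virtual bridge water between two atoms
#'
#' The 1.4 Angstrom water sphere is placed on the segment joining the two
#' atom centers.  With a single hydrophilic atom `h`, the water sits at
#' `r_vdW,h + 1.4 - m_h` from `h` (exactly the element's maximum mosaic
#' overlap), pushed towards mid-gap when the partner's sphere leaves no
#' room, which only ever reduces the achieved overlap.  With two
#' hydrophilic atoms, the shared water sits at the point minimizing the
#' larger violation of the two mosaic targets (both met exactly when the
#' gap equals `2.8 - m_a - m_b`).
#'
#' @param a,b one-row atom data.frames (assigned model rows)
#' @param table a [mosaic_table()]
#' @return list of class `bridge_water` with `center`, `radius`,
#'   `anchors` (serials), `achieved_mosaic` (named per anchor)
#' @export
place_bridge_water <- function(a, b, table = mosaic_table()) {
  if (!bridge_eligible(a, b, table$water_diameter)) {
    stop("atom pair ", a$serial, "-", b$serial,
         " is not eligible for a bridge water")
  }
  ca <- c(a$x, a$y, a$z); cb <- c(b$x, b$y, b$z)
  d <- sqrt(sum((ca - cb)^2))
  u <- (cb - ca) / d
  wr <- table$water_radius
  ma <- if (isTRUE(a$hydrophilic)) table$max_mosaic[[a$element]] else NA_real_
  mb <- if (isTRUE(b$hydrophilic)) table$max_mosaic[[b$element]] else NA_real_

  if (isTRUE(a$hydrophilic) && isTRUE(b$hydrophilic)) {
    t_a <- a$vdw + wr - ma                # exact target for a
    t_b <- d - (b$vdw + wr - mb)          # exact target for b
    t <- (t_a + t_b) / 2                  # minimizes the larger violation
    achieved <- c(a$vdw + wr - t, b$vdw + wr - (d - t))
    names(achieved) <- c(as.character(a$serial), as.character(b$serial))
    anchors <- c(a$serial, b$serial)
  } else if (isTRUE(a$hydrophilic)) {
    t <- .anchored_water_t(a$vdw, ma, b$vdw, 0, d, wr)
    achieved <- stats::setNames(a$vdw + wr - t, as.character(a$serial))
    anchors <- a$serial
  } else {
    t_b <- .anchored_water_t(b$vdw, mb, a$vdw, 0, d, wr)
    t <- d - t_b
    achieved <- stats::setNames(b$vdw + wr - t_b, as.character(b$serial))
    anchors <- b$serial
  }
  structure(list(center = ca + t * u, radius = wr, anchors = anchors,
                 achieved_mosaic = achieved),
            class = "bridge_water")
}

# per-anchor water for scoring: anchor x against partner p (each hydrophilic
# atom of a pair gets its own water, the partner's mosaic allowance taken
# into account when clamping)
.anchor_water_sphere <- function(xatom, patom, table) {
  ca <- c(xatom$x, xatom$y, xatom$z)
  cb <- c(patom$x, patom$y, patom$z)
  d <- sqrt(sum((ca - cb)^2))
  u <- (cb - ca) / d
  wr <- table$water_radius
  mx <- table$max_mosaic[[xatom$element]]
  mp <- if (isTRUE(patom$hydrophilic)) table$max_mosaic[[patom$element]] else 0
  t <- .anchored_water_t(xatom$vdw, mx, patom$vdw, mp, d, wr)
  atom_sphere(ca + t * u, wr)
}

#' Water-mediated contact area and volume of an atom pair
#'
#' Scores an eligible pair through its virtual bridge water.  If only one
#' atom is hydrophilic, the returned area/volume are the grid contact of
#' that atom's bare vdW sphere with its placed water sphere.  If both are
#' hydrophilic, each atom gets its own anchored water and the returned
#' values are the mean of the two single-atom water contacts.  No direct
#' atom-atom sphere overlap enters: the contact exists only through the
#' water.
#'
#' @param a,b one-row atom data.frames (assigned model rows); the pair must
#'   be [bridge_eligible()]
#' @param table a [mosaic_table()]
#' @param spec a [grid_spec()]
#' @return named numeric `c(area =, volume =)` in Angstrom^2 / Angstrom^3
#' @export
water_mediated_pair <- function(a, b, table = mosaic_table(),
                                spec = grid_spec()) {
  if (!bridge_eligible(a, b, table$water_diameter)) {
    stop("atom pair ", a$serial, "-", b$serial,
         " is not eligible for water-mediated contact")
  }
  score_one <- function(xatom, patom) {
    w <- .anchor_water_sphere(xatom, patom, table)
    s <- atom_sphere(c(xatom$x, xatom$y, xatom$z), xatom$vdw)
    d <- sqrt(sum((s$center - w$center)^2))
    if (d >= s$radius + w$radius) return(c(area = 0, volume = 0))
    c(area = contact_area(s, w, spec = spec),
      volume = contact_volume(s, w, spec = spec))
  }
  if (isTRUE(a$hydrophilic) && isTRUE(b$hydrophilic)) {
    (score_one(a, b) + score_one(b, a)) / 2
  } else if (isTRUE(a$hydrophilic)) {
    score_one(a, b)
  } else {
    score_one(b, a)
  }
}
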