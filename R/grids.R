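#' Grid specification
#'
#' Bundles the discretization constants of the engine: number of surface
#' points per atom, cubic lattice spacing, the volume element they imply
#' and the solvent (probe) radius.  Default precision uses 5000 surface
#' points and a 0.2 Angstrom lattice; enhanced precision uses 15092 points
#' and 0.1 Angstrom.
#'
#' @param precision `"default"` or `"enhanced"`
#' @param solvent_radius probe radius in Angstrom (1.4 default)
#' @return list with `precision`, `n_surface_points`, `lattice_spacing`,
#'   `delta_v` (= spacing^3) and `solvent_radius`
#' @export
grid_spec <- function(precision = c("default", "enhanced"),
                      solvent_radius = 1.4) {
  precision <- match.arg(precision)
  n <- if (precision == "default") 5000L else 15092L
  sp <- if (precision == "default") 0.2 else 0.1
  list(precision = precision,
       n_surface_points = n,
       lattice_spacing = sp,
       delta_v = sp^3,
       solvent_radius = solvent_radius)
}

#' Deterministic surface point set of a sphere
#'
#' Spherical Fibonacci (golden-angle) lattice: `n` near-uniform points at
#' exactly `radius` from `center`.  Fully deterministic; two calls with the
#' same arguments give bit-identical point sets.  Each point represents a
#' surface element of `4*pi*radius^2 / n`.
#'
#' @param center 3-vector
#' @param radius sphere radius, Angstrom (> 0)
#' @param n number of points (>= 4)
#' @return `n` x 3 matrix of coordinates
#' @export
surface_points <- function(center, radius, n) {
  if (radius <= 0) stop("surface_points: radius must be positive")
  if (n < 4) stop("surface_points: need at least 4 points")
  i <- seq_len(n) - 1
  z <- 1 - (2 * i + 1) / n
  phi <- i * pi * (3 - sqrt(5))
  r_xy <- sqrt(pmax(0, 1 - z^2))
  p <- cbind(r_xy * cos(phi), r_xy * sin(phi), z) * radius
  sweep(p, 2, as.numeric(center), "+")
}

#' Cubic volume lattice of a sphere
#'
#' All points of an axis-aligned cubic lattice anchored at the sphere
#' center (the center itself is always a lattice point) whose distance to
#' the center is at most `radius`.  Each point represents a volume element
#' `spacing^3`; the represented volume converges to `(4/3)*pi*radius^3` as
#' the spacing shrinks.
#'
#' @param center 3-vector
#' @param radius sphere radius, Angstrom (> 0)
#' @param spacing lattice spacing, Angstrom (0 < spacing < radius)
#' @return m x 3 matrix of lattice points
#' @export
lattice_points <- function(center, radius, spacing) {
  if (radius <= 0) stop("lattice_points: radius must be positive")
  if (spacing <= 0) stop("lattice_points: spacing must be positive")
  if (spacing >= radius) {
    stop("lattice_points: spacing ", spacing, " >= radius ", radius,
         " gives a degenerate lattice")
  }
  k <- floor(radius / spacing)
  ax <- seq(-k, k) * spacing
  g <- as.matrix(expand.grid(x = ax, y = ax, z = ax, KEEP.OUT.ATTRS = FALSE))
  # boundary points (distance exactly `radius`) kept despite fp rounding
  keep <- rowSums(g^2) <= radius^2 * (1 + 1e-9)
  sweep(g[keep, , drop = FALSE], 2, as.numeric(center), "+")
}

#' Build a cell-list spatial index over atoms
#'
#' Uniform-grid bucketing of atom centers for neighbor search.  Every atom
#' belongs to exactly one cell.
#'
#' @param model atom data.frame with columns x, y, z
#' @param cell_size cell edge length, Angstrom
#' @return object of class `cell_index`
#' @export
build_cell_index <- function(model, cell_size) {
  if (cell_size <= 0) stop("cell_size must be positive")
  pos <- cbind(model$x, model$y, model$z)
  cells <- floor(sweep(pos, 2, c(0, 0, 0), "-") / cell_size)
  key <- paste(cells[, 1], cells[, 2], cells[, 3], sep = ",")
  structure(
    list(model = model, pos = pos, cells = cells, cell_size = cell_size,
         buckets = split(seq_len(nrow(model)), key)),
    class = "cell_index"
  )
}

#' Neighbors of an atom within a cutoff
#'
#' Exact neighbor query over the cell index: all atoms (excluding the query
#' itself) whose center distance to the query atom is at most `cutoff`.
#' Agrees with a brute-force all-pairs scan.
#'
#' @param index a `cell_index`
#' @param i row number of the query atom in the indexed model
#' @param cutoff distance cutoff, Angstrom (> 0)
#' @return integer vector of neighbor row numbers
#' @export
neighbors_within <- function(index, i, cutoff) {
  if (!inherits(index, "cell_index")) stop("not a cell_index")
  if (cutoff <= 0) stop("cutoff must be positive")
  n <- nrow(index$pos)
  if (length(i) != 1 || is.na(i) || i < 1 || i > n) {
    stop("atom ", i, " is not in the index")
  }
  reach <- ceiling(cutoff / index$cell_size)
  ctr <- index$cells[i, ]
  off <- expand.grid(dx = -reach:reach, dy = -reach:reach, dz = -reach:reach)
  keys <- paste(ctr[1] + off$dx, ctr[2] + off$dy, ctr[3] + off$dz, sep = ",")
  cand <- unlist(index$buckets[keys], use.names = FALSE)
  cand <- cand[!is.na(cand) & cand != i]
  if (length(cand) == 0) return(integer(0))
  d2 <- colSums((t(index$pos[cand, , drop = FALSE]) - index$pos[i, ])^2)
  sort(cand[d2 <= cutoff^2])
}
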