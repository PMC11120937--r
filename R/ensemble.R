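#' Mean and range contact matrices across an ensemble
#'
#' Builds symmetric residue-by-residue matrices of the chosen metric over
#' all models of a multi-model structure: the per-pair mean and the
#' per-pair range (max minus min).  A pair absent from a model contributes
#' 0 to that model — this matters for intermittent contacts, whose range
#' therefore reaches their full maximum.
#'
#' @param per_model list of [residue_pair_totals()] data.frames, one per
#'   model, with consistent residue identities
#' @param metric `"volume"` (default), `"area"`, `"aowv"`, or
#'   `"frequency"` (presence/absence per model)
#' @return object of class `ensemble_matrices`: list with `residues`,
#'   `mean`, `range`, `n_models`, `metric`
#' @export
ensemble_matrices <- function(per_model,
                              metric = c("volume", "area", "aowv",
                                         "frequency")) {
  metric <- match.arg(metric)
  stopifnot(length(per_model) >= 1)
  residues <- unique(unlist(lapply(per_model, function(p) {
    c(p$residue1, p$residue2)
  })))
  if (length(residues) == 0) {
    stop("no residue pairs in any model")
  }
  residues <- residues[.resid_sort_key(residues)]
  nr <- length(residues)
  nm <- length(per_model)
  vals <- array(0, dim = c(nr, nr, nm))
  for (m in seq_len(nm)) {
    p <- per_model[[m]]
    if (nrow(p) == 0) next
    i <- match(p$residue1, residues)
    j <- match(p$residue2, residues)
    if (anyNA(i) || anyNA(j)) {
      bad <- unique(c(p$residue1[is.na(i)], p$residue2[is.na(j)]))
      stop("residue identities inconsistent across models: ",
           paste(bad, collapse = ", "))
    }
    v <- if (metric == "frequency") rep(1, nrow(p)) else p[[metric]]
    for (k in seq_along(i)) {
      vals[i[k], j[k], m] <- vals[i[k], j[k], m] + v[k]
      vals[j[k], i[k], m] <- vals[j[k], i[k], m] + v[k]
    }
  }
  mmean <- apply(vals, c(1, 2), mean)
  mrange <- apply(vals, c(1, 2), max) - apply(vals, c(1, 2), min)
  dimnames(mmean) <- dimnames(mrange) <- list(residues, residues)
  structure(list(residues = residues, mean = mmean, range = mrange,
                 n_models = nm, metric = metric),
            class = "ensemble_matrices")
}

#' Ensemble matrices straight from a multi-model PDB file
#'
#' Convenience wrapper: runs the contact engine on every model and feeds
#' the residue-pair summaries to [ensemble_matrices()].
#'
#' @param path multi-model PDB file
#' @param metric passed to [ensemble_matrices()]
#' @param opts options passed to [analyze_file()]
#' @return an `ensemble_matrices` object
#' @export
ensemble_contacts <- function(path, metric = "volume", opts = list()) {
  res <- analyze_file(path, out_dir = NULL, opts = opts)
  ensemble_matrices(lapply(res$models, `[[`, "pairs"), metric = metric)
}

#' Flag flexible residue-pair contacts
#'
#' Pairs whose ensemble mean is at least `min_mean` and whose range
#' (max minus min over models) is at least `min_range`, sorted by
#' descending range.  The defaults follow the working criterion for
#' functionally flexible charged pairs in NMR ensembles: moderate mean
#' contact volume (about 30 Angstrom^3) with a wide range (over 100
#' Angstrom^3).
#'
#' @param m an `ensemble_matrices` object
#' @param min_mean,min_range non-negative thresholds
#' @return data.frame `residue1`, `residue2`, `mean`, `range`
#' @export
flag_flexible_contacts <- function(m, min_mean = 30, min_range = 100) {
  stopifnot(inherits(m, "ensemble_matrices"),
            min_mean >= 0, min_range >= 0)
  nr <- length(m$residues)
  rows <- list()
  for (i in seq_len(nr)) {
    for (j in seq_len(nr)) {
      if (j <= i) next
      if ((m$mean[i, j] > 0 || m$range[i, j] > 0) &&
          m$mean[i, j] >= min_mean && m$range[i, j] >= min_range) {
        rows[[length(rows) + 1]] <- data.frame(
          residue1 = m$residues[i], residue2 = m$residues[j],
          mean = m$mean[i, j], range = m$range[i, j],
          stringsAsFactors = FALSE)
      }
    }
  }
  if (!length(rows)) {
    return(data.frame(residue1 = character(0), residue2 = character(0),
                      mean = numeric(0), range = numeric(0),
                      stringsAsFactors = FALSE))
  }
  out <- do.call(rbind, rows)
  out <- out[order(-out$range, out$residue1, out$residue2), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Export an ensemble matrix as CSV
#'
#' @param m an `ensemble_matrices` object
#' @param path output CSV path
#' @param which `"mean"` or `"range"`
#' @return path, invisibly
#' @export
write_matrix_csv <- function(m, path, which = c("mean", "range")) {
  which <- match.arg(which)
  utils::write.csv(as.data.frame(m[[which]]), path, row.names = TRUE)
  invisible(path)
}

#' Render a residue contact heatmap to PNG
#'
#' Deterministic rasterization (no graphics device): the mean matrix is
#' mapped white-to-blue, flagged (flexible) pairs are overdrawn in red,
#' and each matrix cell becomes a square block of pixels.  Identical input
#' gives byte-identical files.
#'
#' @param m an `ensemble_matrices` object
#' @param path output PNG path
#' @param highlight optional data.frame with `residue1`, `residue2`
#'   (e.g. from [flag_flexible_contacts()]) to mark in red
#' @param which `"mean"` or `"range"` matrix to draw
#' @param cell_px pixels per matrix cell
#' @return path, invisibly
#' @export
render_heatmap <- function(m, path, highlight = NULL,
                           which = c("mean", "range"), cell_px = 8L) {
  stopifnot(inherits(m, "ensemble_matrices"))
  which <- match.arg(which)
  mat <- m[[which]]
  if (length(mat) == 0) stop("empty matrix")
  top <- max(mat)
  frac <- if (top > 0) mat / top else mat * 0
  nr <- nrow(mat)
  # white (1,1,1) -> blue (0,0,0.8)
  img <- array(0, dim = c(nr, nr, 3))
  img[, , 1] <- 1 - frac
  img[, , 2] <- 1 - frac
  img[, , 3] <- 1 - 0.2 * frac
  if (!is.null(highlight) && nrow(highlight) > 0) {
    i <- match(highlight$residue1, m$residues)
    j <- match(highlight$residue2, m$residues)
    for (k in seq_along(i)) {
      if (is.na(i[k]) || is.na(j[k])) next
      img[i[k], j[k], ] <- c(1, 0, 0)
      img[j[k], i[k], ] <- c(1, 0, 0)
    }
  }
  big <- array(0, dim = c(nr * cell_px, nr * cell_px, 3))
  ix <- rep(seq_len(nr), each = cell_px)
  for (ch in 1:3) big[, , ch] <- img[ix, ix, ch]
  png::writePNG(big, path)
  invisible(path)
}

#' Render heavy-atom scatter images
#'
#' Writes one PNG per model showing solute heavy-atom positions projected
#' on the x-y plane, point size graded by z.  Waters are excluded.
#'
#' @param x a `contact_structure` or a single model data.frame
#' @param path output path; for multi-model structures, `_model<k>` is
#'   inserted before the extension
#' @return character vector of paths written, invisibly
#' @export
render_atom_scatter <- function(x, path) {
  models <- if (inherits(x, "contact_structure")) x$models else list(x)
  paths <- character(0)
  for (k in seq_along(models)) {
    sol <- solute_atoms(models[[k]])
    if (nrow(sol) == 0) stop("model ", k, " has no solute atoms to draw")
    p <- path
    if (length(models) > 1) {
      p <- sub("(\\.[A-Za-z]+)$", sprintf("_model%d\\1", k), path)
    }
    grDevices::png(p, width = 600, height = 600)
    zr <- sol$z - min(sol$z)
    cex <- 0.6 + if (max(zr) > 0) zr / max(zr) else 0
    graphics::plot(sol$x, sol$y, pch = 19, cex = cex,
                   col = ifelse(sol$hydrophilic, "steelblue", "grey40"),
                   xlab = "x (A)", ylab = "y (A)", asp = 1,
                   main = sprintf("model %d heavy atoms", k))
    grDevices::dev.off()
    paths <- c(paths, p)
  }
  invisible(paths)
}
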