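#' Parse a PDB coordinate file
#'
#' Reads ATOM/HETATM records (MODEL/ENDMDL aware) into a multi-model
#' structure object.  Hydrogen (and deuterium) atoms are dropped: the
#' contact engine is a heavy-atom analysis, and experimental PDB files are
#' inconsistent about hydrogens.  Crystallographic waters (HOH/WAT) are
#' kept but flagged and excluded from the solute set.  Alternate locations
#' are resolved by keeping the first record seen for each
#' (chain, residue, insertion code, atom name) key within a model.
#'
#' @param path path to a PDB file
#' @param assign if `TRUE` (default), van der Waals radii and chemical
#'   class flags are assigned to every atom on the way in
#' @return an object of class `contact_structure`: a list with `models`
#'   (list of per-model atom data.frames), `source_path` and `header`
#' @export
parse_structure <- function(path, assign = TRUE) {
  if (!file.exists(path)) {
    stop("cannot read PDB file: '", path, "' does not exist")
  }
  lines <- readLines(path, warn = FALSE)
  rec <- substr(lines, 1, 6)
  header <- paste(sub("^\\s+|\\s+$", "",
                      substring(lines[rec %in% c("HEADER", "TITLE ")], 11)),
                  collapse = " ")

  model_ids <- integer(length(lines))
  cur <- 0L
  seen_model_card <- FALSE
  for (i in seq_along(lines)) {
    r <- rec[i]
    if (r == "MODEL ") {
      cur <- suppressWarnings(as.integer(substr(lines[i], 11, 14)))
      if (is.na(cur)) cur <- max(model_ids) + 1L
      seen_model_card <- TRUE
    } else if (r == "ENDMDL") {
      cur <- 0L
    }
    model_ids[i] <- if (seen_model_card && cur > 0L) cur else 1L
  }

  keep <- rec %in% c("ATOM  ", "HETATM")
  if (!any(keep)) {
    stop("empty structure: '", path, "' contains no ATOM or HETATM records")
  }
  idx <- which(keep)
  ln <- lines[idx]

  num_field <- function(txt, from, to, what, lineno) {
    raw <- substr(txt, from, to)
    val <- suppressWarnings(as.numeric(raw))
    bad <- is.na(val) & nzchar(trimws(raw))
    bad <- bad | !nzchar(trimws(raw))
    if (any(bad)) {
      j <- which(bad)[1]
      stop("malformed ", what, " field '", trimws(raw[j]), "' at line ",
           lineno[j], " of '", path, "'")
    }
    val
  }

  atoms <- data.frame(
    serial  = suppressWarnings(as.integer(substr(ln, 7, 11))),
    name    = trimws(substr(ln, 13, 16)),
    altloc  = trimws(substr(ln, 17, 17)),
    resname = trimws(substr(ln, 18, 20)),
    chain   = substr(ln, 22, 22),
    resseq  = suppressWarnings(as.integer(substr(ln, 23, 26))),
    icode   = trimws(substr(ln, 27, 27)),
    x = num_field(ln, 31, 38, "x coordinate", idx),
    y = num_field(ln, 39, 46, "y coordinate", idx),
    z = num_field(ln, 47, 54, "z coordinate", idx),
    element_field = substr(ln, 77, 78),
    het = substr(ln, 1, 6) == "HETATM",
    model_index = model_ids[idx],
    stringsAsFactors = FALSE
  )
  if (anyNA(atoms$resseq)) {
    j <- which(is.na(atoms$resseq))[1]
    stop("malformed residue sequence field at line ", idx[j], " of '", path, "'")
  }
  if (anyNA(atoms$serial)) atoms$serial[is.na(atoms$serial)] <- seq_len(nrow(atoms))[is.na(atoms$serial)]

  el <- mapply(function(e, n, r) .guess_element(e, n, r),
               atoms$element_field, atoms$name, atoms$resname,
               SIMPLIFY = FALSE)
  atoms$element <- vapply(el, `[[`, "", "element")
  atoms$element_guessed <- vapply(el, `[[`, NA, "guessed")
  atoms$element_field <- NULL

  # heavy atoms only
  atoms <- atoms[!atoms$element %in% c("H", "D"), , drop = FALSE]
  if (nrow(atoms) == 0) {
    stop("empty structure: '", path, "' contains no heavy atoms")
  }
  atoms$is_water <- atoms$resname %in% c("HOH", "WAT")

  models <- lapply(split(atoms, atoms$model_index), function(m) {
    # first alternate location per atom key
    key <- paste(m$chain, m$resseq, m$icode, m$name, sep = "\r")
    m <- m[!duplicated(key), , drop = FALSE]
    rownames(m) <- NULL
    m
  })
  ord <- order(as.integer(names(models)))
  models <- models[ord]
  for (m in models) {
    if (!any(!m$is_water)) {
      stop("model ", m$model_index[1], " of '", path,
           "' contains no non-water atoms")
    }
  }

  st <- structure(
    list(models = models, source_path = path, header = header),
    class = "contact_structure"
  )
  if (assign) st <- assign_radii(st)
  st
}

#' @export
print.contact_structure <- function(x, ...) {
  cat("contact_structure:", length(x$models), "model(s) from",
      basename(x$source_path), "\n")
  m <- x$models[[1]]
  cat("  model 1:", sum(!m$is_water), "solute atoms,",
      sum(m$is_water), "waters\n")
  invisible(x)
}

#' Assign van der Waals radii and chemical classes
#'
#' Every atom receives a radius from the bundled element table; atoms whose
#' (residue, atom-name) pair is not a standard-residue dictionary entry are
#' flagged as guessed (element-based fallback).  Hydrogen-bond
#' donor/acceptor and aromatic flags, hydrophilic/hydrophobic classes and a
#' canonical residue identity string are attached at the same time.
#' Assignment is a pure function of (residue name, atom name, element).
#'
#' @param x a `contact_structure` or a single model data.frame
#' @param table radii table (data.frame element/radius); defaults to the
#'   bundled set
#' @return object of the same shape with columns `vdw`, `radius_guessed`,
#'   `is_standard`, `hydrophilic`, `hydrophobic`, `donor`, `acceptor`,
#'   `aromatic` and `resid` added
#' @export
assign_radii <- function(x, table = vdw_radii_table()) {
  if (inherits(x, "contact_structure")) {
    x$models <- lapply(x$models, assign_radii, table = table)
    return(x)
  }
  m <- x
  i <- match(toupper(m$element), table$element)
  if (anyNA(i)) {
    j <- which(is.na(i))[1]
    stop("no radius for element '", m$element[j], "' (atom ", m$serial[j],
         " ", m$name[j], " ", m$resname[j], ")")
  }
  m$vdw <- table$radius[i]
  std <- standard_residue_atoms()
  dict_hit <- mapply(function(rn, an) {
    !is.null(std[[rn]]) && an %in% std[[rn]]
  }, m$resname, m$name, USE.NAMES = FALSE)
  m$is_standard <- m$resname %in% names(std)
  m$radius_guessed <- m$element_guessed | !(dict_hit | m$is_water)
  m$hydrophilic <- m$element %in% c("N", "O", "P", "S")
  m$hydrophobic <- m$element == "C"

  cls <- atom_class_table()
  m$donor <- FALSE
  m$acceptor <- FALSE
  m$aromatic <- FALSE
  generic <- cls[cls$residue == "*", , drop = FALSE]
  specific <- cls[cls$residue != "*", , drop = FALSE]
  gi <- match(m$name, generic$atom)
  ok <- !is.na(gi) & m$is_standard
  m$donor[ok] <- generic$donor[gi[ok]] == 1
  m$acceptor[ok] <- generic$acceptor[gi[ok]] == 1
  m$aromatic[ok] <- generic$aromatic[gi[ok]] == 1
  si <- match(paste(m$resname, m$name), paste(specific$residue, specific$atom))
  ok <- !is.na(si)
  m$donor[ok] <- specific$donor[si[ok]] == 1
  m$acceptor[ok] <- specific$acceptor[si[ok]] == 1
  m$aromatic[ok] <- specific$aromatic[si[ok]] == 1

  m$resid <- paste0(m$chain, ":", m$resseq, m$icode, ":", m$resname)
  m
}

#' Discover PDB input files
#'
#' A single file yields itself; a directory yields all `*.pdb` files in it,
#' sorted lexicographically.
#'
#' @param path file or directory path
#' @return character vector of file paths
#' @export
discover_inputs <- function(path) {
  if (!file.exists(path)) stop("input path '", path, "' does not exist")
  if (!dir.exists(path)) return(path)
  files <- sort(list.files(path, pattern = "\\.pdb$", full.names = TRUE))
  if (length(files) == 0) {
    stop("no PDB files found in directory '", path, "'")
  }
  files
}

#' Solute atoms of a model
#'
#' @param model per-model atom data.frame
#' @return the non-water rows
#' @export
solute_atoms <- function(model) {
  model[!model$is_water, , drop = FALSE]
}

# fixed-column PDB record formatter shared with the fixture generators
.format_pdb_atom <- function(serial, name, resname, chain, resseq, x, y, z,
                             element, het = FALSE, icode = "") {
  rec <- ifelse(het, "HETATM", "ATOM  ")
  nm <- ifelse(nchar(name) < 4, sprintf(" %-3s", name), sprintf("%-4s", name))
  sprintf("%s%5d %s%1s%-3s %1s%4d%1s   %8.3f%8.3f%8.3f%6.2f%6.2f          %2s",
          rec, serial, nm, "", resname, chain, resseq, substr(paste0(icode, " "), 1, 1),
          x, y, z, 1.0, 0.0, element)
}

#' Write one model back to PDB text
#'
#' @param model per-model atom data.frame
#' @param path output file path
#' @return `path`, invisibly
#' @export
write_model_pdb <- function(model, path) {
  lines <- .format_pdb_atom(model$serial, model$name, model$resname,
                            model$chain, model$resseq,
                            model$x, model$y, model$z, model$element,
                            het = model$het, icode = model$icode)
  writeLines(c(lines, "END"), path)
  invisible(path)
}
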