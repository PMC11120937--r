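.fmt_num <- function(x) {
  ifelse(is.na(x), "", sprintf("%.4f", x))
}

.open_out <- function(path, gz) {
  if (gz) gzfile(paste0(path, ".gz"), "wt") else file(path, "wt")
}

.write_table <- function(df, path, flags) {
  con <- .open_out(path, isTRUE(flags$z))
  on.exit(close(con))
  writeLines(paste(colnames(df), collapse = ","), con)
  if (nrow(df) > 0) {
    body <- do.call(paste, c(unname(as.list(df)), sep = ","))
    writeLines(body, con)
  }
  invisible(if (isTRUE(flags$z)) paste0(path, ".gz") else path)
}

#' Write the per-atom-pair (_ALL) CSV
#'
#' Header: `Residue1,Atom1,Type1,Residue2,Atom2,Type2,Distance,Area`
#' `[,Volume][,AOWV],Contact,Class`; the Volume column is present unless
#' the surface-only flag `s` is set, AOWV is present iff the weighted
#' flag `w` is set.  Numbers are fixed to 4 decimals.
#'
#' @param contacts contact record data.frame
#' @param path output file path (`.gz` appended when `flags$z`)
#' @param flags list of logical flags `a`, `w`, `s`, `z`
#' @return path written, invisibly
#' @export
write_all_csv <- function(contacts, path, flags = list()) {
  df <- data.frame(
    Residue1 = contacts$residue1, Atom1 = contacts$atom1,
    Type1 = contacts$type1,
    Residue2 = contacts$residue2, Atom2 = contacts$atom2,
    Type2 = contacts$type2,
    Distance = .fmt_num(contacts$distance),
    Area = .fmt_num(contacts$area),
    stringsAsFactors = FALSE, check.names = FALSE
  )
  if (!isTRUE(flags$s)) df$Volume <- .fmt_num(contacts$volume)
  if (isTRUE(flags$w)) df$AOWV <- .fmt_num(contacts$aowv)
  df$Contact <- contacts$contact
  df$Class <- contacts$class
  .write_table(df, path, flags)
}

#' Write the per-residue (_SUM) CSV
#'
#' One row per residue with dihedrals and covalent/non-covalent totals.
#' Non-standard residue names carry a trailing underscore; undefined
#' angles serialize as empty fields.  SASA appears with flag `a`,
#' Cova_AOWV/NC_AOWV with flag `w`, volume columns disappear with `s`,
#' and UNDEF columns appear when the model holds non-standard residues.
#'
#' @param summaries output of [residue_summaries()]
#' @param path output file path
#' @param flags list of logical flags `a`, `w`, `s`, `z`
#' @return path written, invisibly
#' @export
write_sum_csv <- function(summaries, path, flags = list()) {
  name <- ifelse(summaries$is_standard, summaries$resid,
                 paste0(summaries$resid, "_"))
  df <- data.frame(
    Residue = name,
    Phi = .fmt_num(summaries$phi), Psi = .fmt_num(summaries$psi),
    Cova_Area = .fmt_num(summaries$cova_area),
    NC_Area = .fmt_num(summaries$nc_area),
    stringsAsFactors = FALSE, check.names = FALSE
  )
  if (!isTRUE(flags$s)) {
    df$Cova_Volu <- .fmt_num(summaries$cova_volume)
    df$NC_Volu <- .fmt_num(summaries$nc_volume)
  }
  if (isTRUE(flags$a)) df$SASA <- .fmt_num(summaries$sasa)
  if (isTRUE(flags$w)) {
    df$Cova_AOWV <- .fmt_num(summaries$cova_aowv)
    df$NC_AOWV <- .fmt_num(summaries$nc_aowv)
  }
  if (any(!summaries$is_standard)) {
    df$UNDEF_Area <- .fmt_num(summaries$undef_area)
    if (!isTRUE(flags$s)) df$UNDEF_Volu <- .fmt_num(summaries$undef_volume)
  }
  .write_table(df, path, flags)
}

#' Write the residue-pair (_RES) CSV
#'
#' Columns `Residue1,Residue2,Class,Area[,Volume][,AOWV]` under the same
#' flag rules as the _ALL file.
#'
#' @param pair_summaries output of [residue_pair_totals()]
#' @param path output file path
#' @param flags list of logical flags `a`, `w`, `s`, `z`
#' @return path written, invisibly
#' @export
write_res_csv <- function(pair_summaries, path, flags = list()) {
  df <- data.frame(
    Residue1 = pair_summaries$residue1,
    Residue2 = pair_summaries$residue2,
    Class = pair_summaries$class,
    Area = .fmt_num(pair_summaries$area),
    stringsAsFactors = FALSE, check.names = FALSE
  )
  if (!isTRUE(flags$s)) df$Volume <- .fmt_num(pair_summaries$volume)
  if (isTRUE(flags$w)) df$AOWV <- .fmt_num(pair_summaries$aowv)
  .write_table(df, path, flags)
}

#' Analyze one PDB file end to end
#'
#' Parses the file, computes contacts for every model, aggregates, and
#' writes the `_ALL` / `_SUM` / `_RES` CSVs into
#' `out_dir/<basename>/` (with `model_<k>/` subfolders when the file has
#' several models).  Returns the in-memory per-model results so the same
#' computation can drive programmatic analysis and the ensemble module.
#'
#' @param path PDB file path
#' @param out_dir output directory root; `NULL` for compute-only
#' @param opts options list: `precision`, `water` (`-p`), `custom_d`
#'   (`-d`), `sasa` (`-a`), `weighted` (`-w`), `gzip` (`-z`),
#'   `per_residue` (`-r`), `cutoff` (length-2 `c(area, volume)`, `-c`),
#'   `surface_only` (`-s`), `threads` (`-t`)
#' @return invisible list with `structure`, `models` (per model: contacts,
#'   pair summaries, residue summaries, atom SASA), and `out_paths`
#' @export
analyze_file <- function(path, out_dir = NULL, opts = list()) {
  o <- utils::modifyList(list(precision = "default", water = FALSE,
                              custom_d = NULL, sasa = FALSE, weighted = FALSE,
                              gzip = FALSE, per_residue = FALSE,
                              cutoff = c(0, 0), surface_only = FALSE,
                              threads = 1L), opts)
  if (length(o$cutoff) == 1) o$cutoff <- rep(o$cutoff, 2)
  if (o$threads < 1) stop("thread count must be >= 1")
  spec <- grid_spec(o$precision)
  st <- parse_structure(path)
  flags <- list(a = o$sasa, w = o$weighted, s = o$surface_only, z = o$gzip)
  base <- sub("\\.pdb$", "", basename(path))

  multi <- length(st$models) > 1
  results <- list()
  out_paths <- character(0)
  for (k in seq_along(st$models)) {
    model <- st$models[[k]]
    eng <- compute_model_contacts(model, spec,
                                  mode = if (o$water) "water" else "default",
                                  custom_d = o$custom_d, with_sasa = o$sasa)
    contacts <- apply_cutoff(eng$contacts, o$cutoff[1], o$cutoff[2])
    pairs <- residue_pair_totals(contacts)
    ressum <- residue_summaries(model, contacts, eng$atom_sasa)
    results[[k]] <- list(contacts = contacts, pairs = pairs,
                         residues = ressum, atom_sasa = eng$atom_sasa)

    if (!is.null(out_dir)) {
      dir <- file.path(out_dir, base)
      if (multi) dir <- file.path(dir, paste0("model_", k))
      dir.create(dir, recursive = TRUE, showWarnings = FALSE)
      p1 <- write_all_csv(contacts, file.path(dir, paste0(base, "_ALL.csv")), flags)
      p2 <- write_sum_csv(ressum, file.path(dir, paste0(base, "_SUM.csv")), flags)
      p3 <- write_res_csv(pairs, file.path(dir, paste0(base, "_RES.csv")), flags)
      out_paths <- c(out_paths, p1, p2, p3)
      if (o$per_residue) {
        rdir <- file.path(dir, "residues")
        dir.create(rdir, showWarnings = FALSE)
        for (rid in unique(c(contacts$residue1, contacts$residue2))) {
          sel <- contacts$residue1 == rid | contacts$residue2 == rid
          fn <- file.path(rdir, paste0(gsub("[^A-Za-z0-9]", "_", rid), ".csv"))
          out_paths <- c(out_paths, write_all_csv(contacts[sel, , drop = FALSE],
                                                  fn, flags))
        }
      }
    }
  }
  invisible(list(structure = st, models = results, out_paths = out_paths))
}

.cli_usage <- function() {
  paste(
    "usage: contactvol <input.pdb | directory> [options]",
    "  -o DIR    output directory (default: contactvol_out)",
    "  -e        enhanced precision (15092 surface points, 0.1 A lattice)",
    "  -p        water-mediated hydrophilic contact mode",
    "  -d DIST   custom contact distance / eligibility gap (Angstrom)",
    "  -a        compute solvent accessible surface area",
    "  -w        atomic-overlap-weighted volume column",
    "  -z        gzip-compressed outputs",
    "  -t N      threads (results are independent of N)",
    "  -r        per-residue CSV files",
    "  -c A[,V]  lower cutoffs for area[,volume]",
    "  -s        surface only (skip volume columns)",
    sep = "\n")
}

#' Command-line driver
#'
#' Thin batch front end over [analyze_file()]: one positional input (PDB
#' file or directory of PDB files) plus the single-letter flags documented
#' in [.cli_usage].  Returns the process exit status (0 on success)
#' instead of quitting, so it is testable in-session; the installed
#' `inst/scripts/contactvol` wrapper forwards the status to the shell.
#'
#' @param args character vector of command-line arguments
#' @return integer exit status, invisibly
#' @export
run_cli <- function(args = commandArgs(trailingOnly = TRUE)) {
  opts <- list()
  out_dir <- "contactvol_out"
  input <- NULL
  i <- 1
  ok <- TRUE
  take <- function(i) {
    if (i + 1 > length(args)) stop("flag ", args[i], " needs a value")
    args[i + 1]
  }
  res <- try({
    while (i <= length(args)) {
      a <- args[i]
      if (a == "-o") { out_dir <- take(i); i <- i + 2 }
      else if (a == "-e") { opts$precision <- "enhanced"; i <- i + 1 }
      else if (a == "-p") { opts$water <- TRUE; i <- i + 1 }
      else if (a == "-d") { opts$custom_d <- as.numeric(take(i)); i <- i + 2 }
      else if (a == "-a") { opts$sasa <- TRUE; i <- i + 1 }
      else if (a == "-w") { opts$weighted <- TRUE; i <- i + 1 }
      else if (a == "-z") { opts$gzip <- TRUE; i <- i + 1 }
      else if (a == "-t") { opts$threads <- as.integer(take(i)); i <- i + 2 }
      else if (a == "-r") { opts$per_residue <- TRUE; i <- i + 1 }
      else if (a == "-c") {
        opts$cutoff <- as.numeric(strsplit(take(i), ",")[[1]]); i <- i + 2
      }
      else if (a == "-s") { opts$surface_only <- TRUE; i <- i + 1 }
      else if (startsWith(a, "-")) stop("unknown flag: ", a)
      else if (is.null(input)) { input <- a; i <- i + 1 }
      else stop("multiple input paths given: ", input, " and ", a)
    }
    if (is.null(input)) stop("no input path given")
    if (!is.null(opts$custom_d) && (is.na(opts$custom_d) || opts$custom_d <= 0))
      stop("-d needs a positive distance")
    if (!is.null(opts$cutoff) && (anyNA(opts$cutoff) || any(opts$cutoff < 0)))
      stop("-c needs non-negative cutoffs")
    files <- discover_inputs(input)
    for (f in files) analyze_file(f, out_dir, opts)
  }, silent = TRUE)
  if (inherits(res, "try-error")) {
    message(conditionMessage(attr(res, "condition")))
    message(.cli_usage())
    ok <- FALSE
  }
  invisible(if (ok) 0L else 2L)
}
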