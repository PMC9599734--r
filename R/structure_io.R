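#' Read a macromolecular structure
#'
#' Parses a PDB or mmCIF file into the flat atom table used throughout the
#' pipeline. Hydrogens are dropped (the survey works on X-ray structures where
#' hydrogen positions are absent and all distances are heavy-atom distances),
#' only the first model of multi-model entries is kept, and alternate
#' locations are collapsed to a single conformer per atom: the highest
#' occupancy wins, ties break to the alphabetically first altloc code.
#' Residue identity uses author numbering so that annotations can be compared
#' with residue labels in the literature. Water residues (HOH/WAT/DOD) are
#' normalised to HOH.
#'
#' @param path file to read.
#' @param format `"pdb"`, `"cif"` or `"auto"` (by file extension; `.cif` /
#'   `.mmcif` read as mmCIF, anything else as PDB).
#' @return An object of class `ploop_structure`: a list with
#'   \describe{
#'     \item{id}{structure identifier (file stem, uppercased when it looks
#'       like a PDB id).}
#'     \item{resolution}{resolution in ångström, or `NA` when the header does
#'       not state one.}
#'     \item{atoms}{data frame with one row per heavy atom: `chain`, `resno`,
#'       `insert`, `resid`, `elety` (atom name), `elesy` (element), `x`, `y`,
#'       `z`, `o` (occupancy), `alt`, `het` (HETATM flag).}
#'   }
#' @export
#' @examples
#' bp <- site_blueprint()
#' f <- tempfile(fileext = ".pdb")
#' write_structure(build_ideal_site(bp)$model, f)
#' m <- read_structure(f)
#' nrow(m$atoms)
read_structure <- function(path, format = c("auto", "pdb", "cif")) {
  format <- match.arg(format)
  if (!file.exists(path)) stop("file not found: ", path)
  if (format == "auto") {
    format <- if (grepl("\\.(cif|mmcif)$", path, ignore.case = TRUE)) "cif" else "pdb"
  }
  parsed <- tryCatch(
    if (format == "cif") suppressWarnings(bio3d::read.cif(path, verbose = FALSE))
    else bio3d::read.pdb(path, verbose = FALSE, multi = FALSE),
    error = function(e) stop("cannot parse ", path, " as ", format, ": ",
                             conditionMessage(e), call. = FALSE))
  at <- parsed$atom
  if (is.null(at) || nrow(at) == 0L) stop("empty structure: ", path)

  atoms <- data.frame(
    chain  = ifelse(is.na(at$chain), "", at$chain),
    resno  = at$resno,
    insert = ifelse(is.na(at$insert), "", at$insert),
    resid  = toupper(at$resid),
    elety  = at$elety,
    elesy  = toupper(ifelse(is.na(at$elesy) | at$elesy == "",
                            guess_element(at$elety), at$elesy)),
    x = at$x, y = at$y, z = at$z,
    o = ifelse(is.na(at$o), 1, at$o),
    alt = ifelse(is.na(at$alt), "", at$alt),
    het = at$type == "HETATM",
    stringsAsFactors = FALSE
  )
  atoms <- atoms[atoms$elesy != "H" & atoms$elesy != "D", , drop = FALSE]
  if (nrow(atoms) == 0L) stop("no heavy atoms in ", path)
  atoms$resid[atoms$resid %in% c("WAT", "DOD")] <- "HOH"
  atoms <- apply_altloc_policy(atoms)
  if (!any(!atoms$het)) {
    # a purely synthetic site file may be all-HETATM; only reject when there
    # is truly nothing polymer-like (no amino-acid residue names at all)
    if (!any(atoms$resid %in% aa3())) stop("zero polymer atoms in ", path)
  }
  stopifnot(all(is.finite(atoms$x)), all(is.finite(atoms$y)), all(is.finite(atoms$z)))

  id <- toupper(sub("\\.(pdb|ent|cif|mmcif)$", "", basename(path), ignore.case = TRUE))
  structure(list(id = id, resolution = read_resolution(path, format),
                 atoms = atoms),
            class = "ploop_structure")
}

# highest occupancy wins; ties to the alphabetically first altloc code
apply_altloc_policy <- function(atoms) {
  key <- paste(atoms$chain, atoms$resno, atoms$insert, atoms$resid, atoms$elety,
               sep = "\r")
  if (!anyDuplicated(key)) return(atoms)
  ord <- order(key, -atoms$o, atoms$alt)
  atoms <- atoms[ord, , drop = FALSE]
  atoms <- atoms[!duplicated(key[ord]), , drop = FALSE]
  rownames(atoms) <- NULL
  atoms
}

# resolution from the raw header (bio3d does not expose it)
read_resolution <- function(path, format) {
  lines <- readLines(path, warn = FALSE)
  if (format == "pdb") {
    r <- grep("^REMARK   2 RESOLUTION", lines, value = TRUE)
    if (length(r)) {
      v <- suppressWarnings(as.numeric(sub(".*RESOLUTION\\.?\\s+([0-9.]+).*", "\\1", r[1])))
      return(v)
    }
  } else {
    r <- grep("_reflns\\.d_resolution_high|_refine\\.ls_d_res_high", lines, value = TRUE)
    if (length(r)) {
      v <- suppressWarnings(as.numeric(sub(".*\\s([0-9.]+)\\s*$", "\\1", r[1])))
      return(v)
    }
  }
  NA_real_
}

guess_element <- function(elety) {
  e <- sub("^[0-9]*", "", trimws(elety))
  two <- toupper(substr(e, 1, 2))
  known2 <- c("MG", "MN", "CA", "FE", "ZN", "NA", "CL", "AL", "BE", "BR")
  ifelse(two %in% known2 & nchar(e) == 2, two, toupper(substr(e, 1, 1)))
}

aa3 <- function() c("ALA", "ARG", "ASN", "ASP", "CYS", "GLN", "GLU", "GLY",
                    "HIS", "ILE", "LEU", "LYS", "MET", "PHE", "PRO", "SER",
                    "THR", "TRP", "TYR", "VAL")

#' Write a structure as a PDB file
#'
#' Fixed-column PDB writer used by the synthetic-site generator (and for
#' round-tripping). Coordinates are written at 0.001 ångström precision.
#'
#' @param model a `ploop_structure`.
#' @param path output file.
#' @return `path`, invisibly.
#' @export
write_structure <- function(model, path) {
  at <- model$atoms
  rec <- ifelse(at$het, "HETATM", "ATOM  ")
  name <- vapply(seq_len(nrow(at)), function(i) {
    nm <- at$elety[i]
    # standard PDB justification: element columns 13-14
    if (nchar(nm) >= 4) substr(nm, 1, 4)
    else if (nchar(at$elesy[i]) == 2) sprintf("%-4s", nm)
    else sprintf(" %-3s", nm)
  }, character(1))
  lines <- sprintf("%s%5d %s%1s%3s %1s%4d%1s   %8.3f%8.3f%8.3f%6.2f%6.2f          %2s",
                   rec, seq_len(nrow(at)) %% 100000L, name, at$alt,
                   sprintf("%3s", at$resid), substr(paste0(at$chain, " "), 1, 1),
                   at$resno, substr(paste0(at$insert, " "), 1, 1),
                   at$x, at$y, at$z, at$o, 0, at$elesy)
  hdr <- character(0)
  if (!is.null(model$resolution) && is.finite(model$resolution)) {
    hdr <- sprintf("REMARK   2 RESOLUTION.    %4.2f ANGSTROMS.", model$resolution)
  }
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c(hdr, lines, "END"), con)
  invisible(path)
}

#' @export
print.ploop_structure <- function(x, ...) {
  cat(sprintf("<ploop_structure> %s: %d heavy atoms, %d chains, resolution %s\n",
              x$id, nrow(x$atoms), length(unique(x$atoms$chain[!x$atoms$het])),
              ifelse(is.finite(x$resolution %||% NA_real_),
                     sprintf("%.2f A", x$resolution), "NA")))
  invisible(x)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

site_record_columns <- function() {
  c("structure_id", "chain", "site", "ligand_class", "resolution",
    "lys_wa", "k_plus_1", "k_minus_3", "wb_residue", "wb_fallback",
    "wb_k1_distance", "hnk3_o2g_distance", "k1_mg_distance", "mg_wb_distance",
    "shell_n", "shell_edge_mean", "hbond_class", "delta_pka",
    "asp_wb_rel_sasa", "qc_pass", "warnings")
}

#' Write per-site records as TSV
#'
#' One header row, one row per catalytic site, missing measurements encoded
#' as `NA`. The fixed column schema is the one produced by [scan_structures()].
#'
#' @param records data frame of site records (may have zero rows).
#' @param path output file.
#' @return `path`, invisibly.
#' @export
write_site_records <- function(records, path) {
  cols <- site_record_columns()
  if (is.null(records) || nrow(records) == 0L) {
    records <- as.data.frame(setNames(rep(list(character(0)), length(cols)), cols))
  }
  missing_cols <- setdiff(cols, names(records))
  for (mc in missing_cols) records[[mc]] <- NA
  utils::write.table(records[, cols, drop = FALSE], path, sep = "\t",
                     quote = FALSE, row.names = FALSE, na = "NA")
  invisible(path)
}

#' Read per-site records written by [write_site_records()]
#' @param path TSV file.
#' @return data frame of site records.
#' @export
read_site_records <- function(path) {
  utils::read.delim(path, stringsAsFactors = FALSE, na.strings = "NA")
}
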