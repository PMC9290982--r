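# Structure input/output.  Parsing of the PDB and mmCIF formats is
# delegated to bio3d; this layer resolves alternate locations, normalises
# the atom table into the hw_structure model and writes standard PDB.

#' Read a macromolecular structure
#'
#' Reads a PDB or mmCIF file into the uniform atom model.  Alternate
#' locations are resolved at parse time to the highest-occupancy conformer
#' (ties broken by altloc label order) so downstream geometry is always
#' single-conformer.  Waters and heteroatoms are retained but flagged.
#' Hydrogens present in the file are discarded; the hydrogen-bond module
#' rebuilds amide hydrogens with a uniform placement rule.  Only the first
#' model of a multi-model file is used.
#'
#' @param path Path to the structure file.
#' @param format `"pdb"`, `"mmcif"` or `"auto"` (by file extension).
#' @param keep_hydrogens Keep file hydrogens instead of discarding them.
#' @return A [hw_structure].
#' @export
read_structure <- function(path, format = c("auto", "pdb", "mmcif"),
                           keep_hydrogens = FALSE) {
  format <- match.arg(format)
  if (!file.exists(path)) stop("file does not exist: ", path)
  if (format == "auto") {
    ext <- tolower(tools::file_ext(path))
    format <- if (ext %in% c("cif", "mmcif")) "mmcif" else "pdb"
  }
  pdb <- tryCatch(
    if (format == "mmcif") bio3d::read.cif(path, verbose = FALSE)
    else bio3d::read.pdb(path, rm.alt = FALSE, verbose = FALSE),
    error = function(e) stop("cannot parse ", format, " file '", path,
                             "': ", conditionMessage(e), call. = FALSE))
  at <- pdb$atom
  if (is.null(at) || nrow(at) == 0) stop("empty structure: ", path)
  at$insert[is.na(at$insert)] <- ""
  at$alt[is.na(at$alt)] <- ""
  at$chain[is.na(at$chain)] <- " "
  at$o[is.na(at$o)] <- 1
  # altloc resolution: per residue+atom-name, keep the highest occupancy,
  # ties broken by altloc label order
  if (any(nzchar(at$alt))) {
    grp <- paste(at$chain, at$resno, at$insert, at$elety, sep = "|")
    ord <- order(grp, -at$o, at$alt)
    at <- at[ord, , drop = FALSE]
    at <- at[!duplicated(paste(at$chain, at$resno, at$insert, at$elety,
                               sep = "|")), , drop = FALSE]
    at <- at[order(match(paste(at$chain, at$resno, at$insert, sep = "|"),
                         unique(paste(at$chain, at$resno, at$insert,
                                      sep = "|")))), , drop = FALSE]
  }
  elesy <- at$elesy
  if (is.null(elesy)) elesy <- rep(NA_character_, nrow(at))
  bad <- is.na(elesy) | !nzchar(trimws(elesy))
  elesy[bad] <- infer_element(at$elety[bad])
  elesy <- trimws(elesy)
  atom <- data.frame(chain = at$chain, resno = at$resno, insert = at$insert,
                     resid = at$resid, elety = at$elety, elesy = elesy,
                     het = at$type == "HETATM" | at$resid %in%
                       c("HOH", "WAT", "DOD"),
                     x = at$x, y = at$y, z = at$z,
                     stringsAsFactors = FALSE)
  if (!keep_hydrogens) atom <- atom[toupper(atom$elesy) != "H", , drop = FALSE]
  if (nrow(atom) == 0) stop("empty structure (no non-hydrogen atoms): ", path)
  hw_structure(atom, id = sub("\\.[^.]*$", "", basename(path)),
               format = format)
}

#' Write a structure as a PDB file
#'
#' Coordinates are written at 3 decimals.  Chains are terminated with TER
#' records and the file ends with END.
#'
#' @param s A [hw_structure].
#' @param path Output path.
#' @return Invisibly, `path`.
#' @export
write_structure <- function(s, path) {
  at <- s$atom
  if (nrow(at) > 99999L) stop("PDB capacity exceeded: more than 99999 atoms")
  if (nrow(at) > 0 && any(nchar(at$resid) > 3L))
    stop("residue names longer than 3 characters cannot be written to PDB")
  if (nrow(at) > 0 && any(is.na(at$resno) | at$resno > 9999L))
    stop("residue numbers must be present and <= 9999 for PDB output")
  if (nrow(at) == 0) {
    writeLines("END", path)
    return(invisible(path))
  }
  bio3d::write.pdb(file = path,
                   xyz = as.numeric(t(as.matrix(at[, c("x", "y", "z")]))),
                   type = ifelse(at$het, "HETATM", "ATOM"),
                   resno = at$resno, resid = at$resid,
                   eleno = seq_len(nrow(at)), elety = at$elety,
                   chain = ifelse(nzchar(trimws(at$chain)),
                                  substr(at$chain, 1L, 1L), " "),
                   insert = ifelse(nzchar(at$insert), at$insert, ""),
                   o = rep(1, nrow(at)), b = rep(0, nrow(at)),
                   elesy = at$elesy, end = TRUE)
  invisible(path)
}
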