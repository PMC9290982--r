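# Minimal occupancy-free structure model shared by all analysis stages.
# A `hw_structure` wraps a single flat atom table; author residue numbering
# is kept verbatim and a 0-based sequential index per chain is derived on
# demand so that i -> i+4 arithmetic survives numbering gaps.

#' Construct a structure object from an atom table
#'
#' @param atom A data.frame with columns `chain`, `resno` (integer author
#'   numbering), `insert` (insertion code, `""` when absent), `resid`
#'   (3-letter residue name), `elety` (PDB atom name), `elesy` (element
#'   symbol), `het` (logical heteroatom/water flag) and coordinates `x`,
#'   `y`, `z` in Angstrom.
#' @param id Structure identifier.
#' @param format Source format tag (`"pdb"`, `"mmcif"` or `"built"`).
#' @return An object of class `hw_structure`.
#' @export
hw_structure <- function(atom, id = "structure", format = "built") {
  required <- c("chain", "resno", "insert", "resid", "elety", "elesy",
                "het", "x", "y", "z")
  missing_cols <- setdiff(required, names(atom))
  if (length(missing_cols) > 0)
    stop("atom table lacks columns: ", paste(missing_cols, collapse = ", "))
  if (nrow(atom) > 0 && !all(is.finite(c(atom$x, atom$y, atom$z))))
    stop("atom coordinates must be finite")
  if (nrow(atom) > 0 && any(!nzchar(atom$elesy)))
    stop("element symbols must be non-empty")
  atom$chain <- as.character(atom$chain)
  atom$resno <- as.integer(atom$resno)
  atom$insert <- as.character(atom$insert)
  atom <- atom[order(atom$chain, atom$resno, atom$insert,
                     seq_len(nrow(atom))), , drop = FALSE]
  rownames(atom) <- NULL
  structure(list(id = id, atom = atom, format = format),
            class = "hw_structure")
}

#' @export
print.hw_structure <- function(x, ...) {
  ch <- unique(x$atom$chain)
  nres <- nrow(unique(x$atom[!x$atom$het, c("chain", "resno", "insert")]))
  cat(sprintf("<hw_structure> %s [%s]: %d atoms, %d residues, chains: %s\n",
              x$id, x$format, nrow(x$atom), nres,
              paste(ch, collapse = " ")))
  invisible(x)
}

#' @export
dim.hw_structure <- function(x) c(atoms = nrow(x$atom))

#' Coordinates of all atoms as an n x 3 matrix
#' @param s A `hw_structure`.
#' @return Numeric matrix with columns x, y, z.
#' @export
atom_coords <- function(s) {
  as.matrix(s$atom[, c("x", "y", "z")])
}

#' Replace all atom coordinates
#' @param s A `hw_structure`.
#' @param xyz Numeric n x 3 matrix matching the atom table.
#' @return The modified structure.
#' @export
set_coords <- function(s, xyz) {
  stopifnot(nrow(xyz) == nrow(s$atom), ncol(xyz) == 3L)
  s$atom$x <- xyz[, 1L]
  s$atom$y <- xyz[, 2L]
  s$atom$z <- xyz[, 3L]
  s
}

#' Chains present in a structure
#' @param s A `hw_structure`.
#' @return Character vector of chain identifiers.
#' @export
structure_chains <- function(s) unique(s$atom$chain[!s$atom$het])

# Residue key (chain|resno|insert) for each atom row.
residue_key <- function(atom) {
  paste(atom$chain, atom$resno, atom$insert, sep = "|")
}

#' Backbone view of one chain
#'
#' Restricts a chain to its polymer residues and reports, per residue, the
#' backbone atoms N, CA, C, O (and the amide hydrogen H when present) as
#' coordinate matrices.  Residues missing any of N/CA/C/O are flagged
#' incomplete; they stay in the table (numbering is never silently
#' compacted) but are excluded from hydrogen-bond analysis downstream.
#'
#' @param s A `hw_structure`.
#' @param chain Chain identifier.
#' @return A list with elements `chain`, `resno`, `insert`, `resid`
#'   (per-residue vectors, in chain order), `complete` (logical), and
#'   matrices `N`, `CA`, `C`, `O`, `H` (n x 3; `NA` rows where the atom is
#'   absent).
#' @export
backbone_view <- function(s, chain) {
  at <- s$atom[!s$atom$het & s$atom$chain == chain, , drop = FALSE]
  if (nrow(at) == 0) stop("unknown chain: ", chain)
  key <- residue_key(at)
  ukey <- unique(key)
  n <- length(ukey)
  first <- match(ukey, key)
  out <- list(chain = chain,
              resno = at$resno[first],
              insert = at$insert[first],
              resid = at$resid[first])
  pick <- function(name) {
    m <- matrix(NA_real_, n, 3L)
    sel <- at$elety == name
    idx <- match(ukey, key[sel])
    hit <- !is.na(idx)
    rows <- which(sel)[idx[hit]]
    m[hit, ] <- as.matrix(at[rows, c("x", "y", "z")])
    m
  }
  out$N <- pick("N"); out$CA <- pick("CA"); out$C <- pick("C")
  out$O <- pick("O"); out$H <- pick("H")
  out$complete <- !(is.na(out$N[, 1L]) | is.na(out$CA[, 1L]) |
                      is.na(out$C[, 1L]) | is.na(out$O[, 1L]))
  out
}

# All heavy (non-hydrogen) side-chain atoms of one chain, with the residue
# index each belongs to (index into the backbone_view order).
sidechain_atoms <- function(s, chain, bb = backbone_view(s, chain)) {
  at <- s$atom[!s$atom$het & s$atom$chain == chain, , drop = FALSE]
  bbnames <- c("N", "CA", "C", "O", "H", "OXT")
  sc <- at[!(at$elety %in% bbnames) & at$elesy != "H", , drop = FALSE]
  rkey <- paste(sc$chain, sc$resno, sc$insert, sep = "|")
  bkey <- paste(bb$chain, bb$resno, bb$insert, sep = "|")
  sc$res_idx <- match(rkey, bkey)
  sc
}

# Atoms of one residue (by chain/author number/insert), polymer only.
residue_atoms <- function(s, chain, resno, insert = "") {
  s$atom[!s$atom$het & s$atom$chain == chain & s$atom$resno == resno &
           s$atom$insert == insert, , drop = FALSE]
}

# van der Waals radii by element (Angstrom); used by the cavity and clash
# machinery.  Unknown elements fall back to carbon.
vdw_radius <- function(elesy) {
  radii <- c(C = 1.70, N = 1.55, O = 1.52, S = 1.80, H = 1.20, P = 1.80)
  r <- radii[toupper(elesy)]
  r[is.na(r)] <- 1.70
  unname(r)
}

# Infer the element symbol from a PDB atom name.
infer_element <- function(elety) {
  nm <- toupper(trimws(elety))
  first <- substr(nm, 1L, 1L)
  ifelse(first %in% c("C", "N", "O", "S", "P", "H"), first, "C")
}
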