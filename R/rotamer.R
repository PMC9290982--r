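# Side-chain chi angles, canonical rotamer labels, side-chain rebuilds at
# requested chi values, and the leucine-gate assessment that ties the
# rotamer state of position 2x46 to the sodium escape-channel verdict.

# IUPAC chi-angle atom quadruples (chi1..chi4 as available per type).
.chi_atoms <- list(
  SER = list(c("N", "CA", "CB", "OG")),
  THR = list(c("N", "CA", "CB", "OG1")),
  CYS = list(c("N", "CA", "CB", "SG")),
  VAL = list(c("N", "CA", "CB", "CG1")),
  LEU = list(c("N", "CA", "CB", "CG"), c("CA", "CB", "CG", "CD1")),
  ILE = list(c("N", "CA", "CB", "CG1"), c("CA", "CB", "CG1", "CD1")),
  ASN = list(c("N", "CA", "CB", "CG"), c("CA", "CB", "CG", "OD1")),
  ASP = list(c("N", "CA", "CB", "CG"), c("CA", "CB", "CG", "OD1")),
  HIS = list(c("N", "CA", "CB", "CG"), c("CA", "CB", "CG", "ND1")),
  PHE = list(c("N", "CA", "CB", "CG"), c("CA", "CB", "CG", "CD1")),
  TYR = list(c("N", "CA", "CB", "CG"), c("CA", "CB", "CG", "CD1")),
  TRP = list(c("N", "CA", "CB", "CG"), c("CA", "CB", "CG", "CD1")),
  MET = list(c("N", "CA", "CB", "CG"), c("CA", "CB", "CG", "SD"),
             c("CB", "CG", "SD", "CE")),
  GLU = list(c("N", "CA", "CB", "CG"), c("CA", "CB", "CG", "CD"),
             c("CB", "CG", "CD", "OE1")),
  GLN = list(c("N", "CA", "CB", "CG"), c("CA", "CB", "CG", "CD"),
             c("CB", "CG", "CD", "OE1")),
  LYS = list(c("N", "CA", "CB", "CG"), c("CA", "CB", "CG", "CD"),
             c("CB", "CG", "CD", "CE"), c("CG", "CD", "CE", "NZ")),
  ARG = list(c("N", "CA", "CB", "CG"), c("CA", "CB", "CG", "CD"),
             c("CB", "CG", "CD", "NE"), c("CG", "CD", "NE", "CZ")),
  PRO = list(c("N", "CA", "CB", "CG"), c("CA", "CB", "CG", "CD"))
)

#' Side-chain chi angles of a residue
#'
#' @param s A [hw_structure].
#' @param chain,resno,insert Residue selector.
#' @return A list: `resid`, `chi` (named numeric vector, degrees;
#'   `NA` where a defining atom is absent), `incomplete` (names of
#'   chi angles whose atoms were missing).
#' @export
chi_angles <- function(s, chain, resno, insert = "") {
  res <- residue_atoms(s, chain, resno, insert)
  if (nrow(res) == 0) stop("no residue ", resno, " in chain ", chain)
  resid <- res$resid[1L]
  quads <- .chi_atoms[[resid]]
  if (is.null(quads))
    return(list(resid = resid, chi = numeric(0), incomplete = character(0)))
  chi <- rep(NA_real_, length(quads))
  names(chi) <- paste0("chi", seq_along(quads))
  incomplete <- character(0)
  for (k in seq_along(quads)) {
    pts <- lapply(quads[[k]], function(a) {
      row <- res[res$elety == a, , drop = FALSE]
      if (nrow(row) == 0) NULL else as.numeric(row[1L, c("x", "y", "z")])
    })
    if (any(vapply(pts, is.null, logical(1L)))) {
      incomplete <- c(incomplete, names(chi)[k])
      next
    }
    chi[k] <- torsion_angle(pts[[1L]], pts[[2L]], pts[[3L]], pts[[4L]])
  }
  list(resid = resid, chi = chi, incomplete = incomplete)
}

#' Canonical rotamer label from chi angles
#'
#' Each chi angle is binned to the nearest of the three staggered wells:
#' `m` (-60), `t` (180) and `p` (+60); the label concatenates the bins
#' (`"mt"`, `"tp"`, ...).  `NA` angles are skipped.
#'
#' @param chi Numeric vector of chi angles in degrees (or the list from
#'   [chi_angles()]).
#' @return Character label (empty string when no chi is defined).
#' @export
classify_rotamer <- function(chi) {
  if (is.list(chi)) chi <- chi$chi
  chi <- chi[!is.na(chi)]
  if (length(chi) == 0) return("")
  centers <- c(m = -60, t = 180, p = 60)
  bins <- vapply(chi, function(x) {
    d <- abs(((x - centers + 180) %% 360) - 180)
    names(centers)[which.min(d)]
  }, character(1L))
  paste(bins, collapse = "")
}

#' Rebuild a side chain at given chi angles
#'
#' Strips the residue's side chain beyond CB and rebuilds it with ideal
#' internal coordinates at the requested chi angles (no refinement).
#' Only residue types with a full topology (L, S, T, N, D, C, Y, W) can
#' be rebuilt.
#'
#' @param s A [hw_structure].
#' @param chain,resno,insert Residue selector.
#' @param chis Chi angles in degrees.
#' @return The modified structure.
#' @export
rebuild_sidechain <- function(s, chain, resno, chis, insert = "") {
  res <- residue_atoms(s, chain, resno, insert)
  if (nrow(res) == 0) stop("no residue ", resno, " in chain ", chain)
  resid <- res$resid[1L]
  if (is.null(.sc_topology[[resid]]))
    stop("no rebuild topology for residue type ", resid)
  get1 <- function(a) {
    row <- res[res$elety == a, , drop = FALSE]
    if (nrow(row) == 0) stop("residue lacks backbone atom ", a)
    as.numeric(row[1L, c("x", "y", "z")])
  }
  sc <- build_sidechain_atoms(resid, get1("N"), get1("CA"), get1("C"), chis)
  # backbone clash check against other residues
  bbsel <- !s$atom$het & s$atom$elety %in% c("N", "CA", "C", "O") &
    !(s$atom$chain == chain & s$atom$resno == resno & s$atom$insert == insert)
  bb <- as.matrix(s$atom[bbsel, c("x", "y", "z")])
  new_xyz <- as.matrix(sc[, c("x", "y", "z")])
  if (nrow(bb) > 0) {
    d2 <- outer(rowSums(new_xyz^2), rowSums(bb^2), `+`) -
      2 * new_xyz %*% t(bb)
    if (min(d2) < 1.0)
      stop("side-chain rebuild clashes with the backbone")
  }
  drop <- s$atom$chain == chain & s$atom$resno == resno &
    s$atom$insert == insert &
    !(s$atom$elety %in% c("N", "CA", "C", "O", "H"))
  keep <- s$atom[!drop, , drop = FALSE]
  sc$chain <- chain; sc$resno <- resno; sc$insert <- insert
  sc$resid <- resid; sc$het <- FALSE
  hw_structure(rbind(keep, sc[, names(keep)]), id = s$id, format = s$format)
}

#' Assess the rotamer gate at position 2x46
#'
#' Runs the escape-channel test with the gate residue's current side
#' chain and again with the side chain rebuilt at `alt_chis`, and lists
#' blocking contacts of the rebuilt (alternative) rotamer: atoms of other
#' residues closer to a rebuilt side-chain atom than the sum of their van
#' der Waals radii minus `clash_allowance`.  When blocking contacts
#' exist, the alternative rotamer is reported as unreachable.  Missing
#' triad residues degrade the assessment to a partial result with a
#' diagnostic instead of an error.
#'
#' @param s A [hw_structure].
#' @param numbering A `hw_numbering` table.
#' @param alt_chis Chi angles of the alternative rotamer.
#' @param start Generic position of the gate residue.
#' @param triad Generic positions of the hydrophobic barrier.
#' @param clash_allowance Soft-clash allowance in Angstrom.
#' @param highlight Generic positions highlighted when implicated in
#'   blocking (Asp 2x50 and Tyr 7x53 in receptors).
#' @param ... Passed to [escape_channel_test()].
#' @return An object of class `hw_gate`: `current_rotamer`,
#'   `alt_rotamer`, `verdict_current`, `verdict_alt` (`"unreachable"`
#'   when blocked), `blocking` (data.frame of contacts), `triad_present`,
#'   `diagnostics`.
#' @export
gate_assessment <- function(s, numbering, alt_chis,
                            start = "2x46",
                            triad = c("2x46", "3x43", "6x40"),
                            clash_allowance = 0.4,
                            highlight = c("2x50", "7x53"), ...) {
  diagnostics <- character(0)
  present <- vapply(triad, function(g) {
    hit <- generic_lookup(numbering, g)
    !is.null(hit) && nrow(residue_atoms(s, hit$chain, hit$resno)) > 0
  }, logical(1L))
  if (!all(present))
    diagnostics <- c(diagnostics,
                     paste("triad residues missing:",
                           paste(triad[!present], collapse = ", ")))
  gate <- generic_lookup(numbering, start)
  if (is.null(gate) || nrow(residue_atoms(s, gate$chain, gate$resno)) == 0) {
    out <- list(current_rotamer = NA_character_,
                alt_rotamer = NA_character_,
                verdict_current = NA_character_,
                verdict_alt = NA_character_,
                blocking = NULL, triad_present = present,
                diagnostics = c(diagnostics,
                                paste("gate residue", start, "missing")))
    class(out) <- "hw_gate"
    return(out)
  }
  cur <- chi_angles(s, gate$chain, gate$resno)
  cur_lab <- classify_rotamer(cur)
  r_cur <- escape_channel_test(s, numbering, start = start, ...)
  s_alt <- rebuild_sidechain(s, gate$chain, gate$resno, alt_chis)
  alt_res <- residue_atoms(s_alt, gate$chain, gate$resno)
  alt_sc <- alt_res[!(alt_res$elety %in% c("N", "CA", "C", "O", "CB")), ,
                    drop = FALSE]
  other <- s_alt$atom[!s_alt$atom$het &
                        !(s_alt$atom$chain == gate$chain &
                            s_alt$atom$resno == gate$resno), , drop = FALSE]
  blocking <- NULL
  if (nrow(alt_sc) > 0 && nrow(other) > 0) {
    a <- as.matrix(alt_sc[, c("x", "y", "z")])
    b <- as.matrix(other[, c("x", "y", "z")])
    d <- sqrt(outer(rowSums(a^2), rowSums(b^2), `+`) - 2 * a %*% t(b))
    lim <- outer(vdw_radius(alt_sc$elesy), vdw_radius(other$elesy), `+`) -
      clash_allowance
    hit <- which(d < lim, arr.ind = TRUE)
    if (nrow(hit) > 0) {
      blk <- data.frame(
        atom = alt_sc$elety[hit[, 1L]],
        chain = other$chain[hit[, 2L]],
        resno = other$resno[hit[, 2L]],
        resid = other$resid[hit[, 2L]],
        partner_atom = other$elety[hit[, 2L]],
        overlap = lim[hit] - d[hit],
        stringsAsFactors = FALSE)
      key <- paste(blk$chain, blk$resno)
      blk <- blk[order(-blk$overlap), , drop = FALSE]
      blk <- blk[!duplicated(key[order(-blk$overlap)]), , drop = FALSE]
      gm <- paste(numbering$chain, numbering$resno)
      blk$generic <- numbering$generic[match(paste(blk$chain, blk$resno), gm)]
      blk$highlighted <- !is.na(blk$generic) & blk$generic %in% highlight
      blocking <- blk
    }
  }
  if (is.null(blocking)) {
    r_alt <- escape_channel_test(s_alt, numbering, start = start, ...)
    verdict_alt <- r_alt$verdict
  } else {
    verdict_alt <- "unreachable"
  }
  out <- list(current_rotamer = cur_lab,
              alt_rotamer = classify_rotamer(alt_chis),
              verdict_current = r_cur$verdict,
              verdict_alt = verdict_alt,
              blocking = blocking, triad_present = present,
              diagnostics = diagnostics,
              escape_current = r_cur)
  class(out) <- "hw_gate"
  out
}

#' @export
print.hw_gate <- function(x, ...) {
  cat("<hw_gate> current rotamer", x$current_rotamer, "->",
      x$verdict_current, "; alternative", x$alt_rotamer, "->",
      x$verdict_alt, "\n")
  if (!is.null(x$blocking))
    cat("  blocking contacts:",
        paste(unique(paste0(x$blocking$resid, " ",
                            ifelse(is.na(x$blocking$generic),
                                   x$blocking$resno, x$blocking$generic))),
              collapse = ", "), "\n")
  for (d in x$diagnostics) cat("  note:", d, "\n")
  invisible(x)
}
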