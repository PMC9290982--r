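# Backbone hydrogen-bond energetics: amide hydrogen placement, the
# electrostatic bond energy, classification into normal / weak / missing,
# and the per-donor bond ledger over the helical register offsets
# -3 / -4 / -5 that distinguishes 3-10, alpha and pi geometry.

# Energy sentinel for donors without an amide hydrogen (proline,
# chain-initial residues, incomplete backbones).
HB_SENTINEL <- Inf

#' Place backbone amide hydrogens on one chain
#'
#' Each amide hydrogen is placed 1.0 Angstrom from its nitrogen in the
#' peptide plane, opposite the bisector of the N-CA and N-C(i-1) bonds
#' (the sp2 amide convention; for an ideal trans peptide this coincides
#' with the anti-carbonyl direction of the preceding residue).  Prolines
#' have no amide proton and the first residue of a chain has no preceding
#' carbonyl; both are flagged donor-incapable.
#'
#' @param s A [hw_structure].
#' @param chain Chain identifier.
#' @return A data.frame with one row per residue: `resno`, `insert`,
#'   `resid`, `donor_capable`, `reason` (`""`, `"proline"`,
#'   `"chain_start"` or `"incomplete"`), and H coordinates `hx`, `hy`,
#'   `hz` (`NA` when incapable).
#' @export
place_amide_hydrogens <- function(s, chain) {
  bb <- backbone_view(s, chain)
  n <- length(bb$resno)
  H <- matrix(NA_real_, n, 3L)
  capable <- rep(FALSE, n)
  reason <- character(n)
  for (i in seq_len(n)) {
    if (bb$resid[i] == "PRO") { reason[i] <- "proline"; next }
    if (i == 1L) { reason[i] <- "chain_start"; next }
    if (!bb$complete[i] || is.na(bb$C[i - 1L, 1L])) {
      reason[i] <- "incomplete"; next
    }
    dirv <- -unit(unit(bb$CA[i, ] - bb$N[i, ]) +
                    unit(bb$C[i - 1L, ] - bb$N[i, ]))
    H[i, ] <- bb$N[i, ] + dirv
    capable[i] <- TRUE
  }
  data.frame(resno = bb$resno, insert = bb$insert, resid = bb$resid,
             donor_capable = capable, reason = reason,
             hx = H[, 1L], hy = H[, 2L], hz = H[, 3L],
             stringsAsFactors = FALSE)
}

#' Electrostatic backbone hydrogen-bond energy
#'
#' The Kabsch-Sander dipole-dipole model: placing partial charges on the
#' donor N-H and acceptor C=O groups gives
#' `E = 27.888 * (1/r_ON + 1/r_CH - 1/r_OH - 1/r_CN)` kcal/mol with
#' distances in Angstrom.  A donor without an amide hydrogen returns the
#' `Inf` sentinel ("no bond possible").
#'
#' @param n_don,h_don Donor nitrogen and amide hydrogen coordinates
#'   (3-vectors); `h_don` may be `NA` for donor-incapable residues.
#' @param c_acc,o_acc Acceptor carbonyl carbon and oxygen coordinates.
#' @return Energy in kcal/mol (negative is favourable), or `Inf`.
#' @export
hbond_energy <- function(n_don, h_don, c_acc, o_acc) {
  if (any(is.na(h_don))) return(HB_SENTINEL)
  r_on <- vnorm(o_acc - n_don)
  r_ch <- vnorm(c_acc - h_don)
  r_oh <- vnorm(o_acc - h_don)
  r_cn <- vnorm(c_acc - n_don)
  if (min(r_on, r_ch, r_oh, r_cn) < 0.5)
    stop("overlapping atoms in hydrogen-bond energy evaluation")
  27.888 * (1 / r_on + 1 / r_ch - 1 / r_oh - 1 / r_cn)
}

#' Classify a hydrogen-bond energy
#'
#' A bond is `normal` when at least as favourable as `e_strong`, `weak`
#' ("very weak" in the structural sense) between `e_strong` and `e_weak`,
#' and `missing` otherwise (including the donor-incapable sentinel).
#' Thresholds are calibrated so ideal-helix bonds are normal and bonds
#' over-stretched by roughly 0.4-0.8 Angstrom become weak; both are
#' configurable.
#'
#' @param energy Energy in kcal/mol (vectorised).
#' @param e_strong,e_weak Class thresholds in kcal/mol.
#' @return Character vector in `{"normal", "weak", "missing"}`.
#' @export
classify_hbond <- function(energy, e_strong = -1.2, e_weak = -0.5) {
  ifelse(!is.finite(energy) | energy > e_weak, "missing",
         ifelse(energy <= e_strong, "normal", "weak"))
}

#' Per-donor backbone hydrogen-bond ledger of one chain
#'
#' For every donor the energy to the acceptors at sequence offsets -3, -4
#' and -5 is evaluated (the 3-10 / alpha / pi helical register).  The
#' lowest-energy partner is marked `best`; the canonical -4 record is kept
#' even when it is not the best.
#'
#' @param s A [hw_structure].
#' @param chain Chain identifier.
#' @param offsets Acceptor offsets to evaluate.
#' @param e_strong,e_weak Classification thresholds, see [classify_hbond()].
#' @return A data.frame with columns `chain`, `donor_idx`, `donor_resno`,
#'   `donor_resid`, `acceptor_idx`, `acceptor_resno`, `offset`, `r_NO`,
#'   `r_HO`, `energy`, `class`, `best`, `donor_capable`.  Indices are
#'   1-based sequential positions within the chain.
#' @export
backbone_hbond_map <- function(s, chain, offsets = c(-3L, -4L, -5L),
                               e_strong = -1.2, e_weak = -0.5) {
  bb <- backbone_view(s, chain)
  hyd <- place_amide_hydrogens(s, chain)
  n <- length(bb$resno)
  rows <- list()
  for (i in seq_len(n)) {
    if (i == 1L) next
    recs <- list()
    for (off in offsets) {
      j <- i + off
      if (j < 1L || j > n) next
      if (!bb$complete[j]) next
      h <- c(hyd$hx[i], hyd$hy[i], hyd$hz[i])
      e <- if (!hyd$donor_capable[i]) HB_SENTINEL
      else hbond_energy(bb$N[i, ], h, bb$C[j, ], bb$O[j, ])
      recs[[length(recs) + 1L]] <- data.frame(
        chain = chain, donor_idx = i, donor_resno = bb$resno[i],
        donor_resid = bb$resid[i], acceptor_idx = j,
        acceptor_resno = bb$resno[j], offset = off,
        r_NO = vnorm(bb$O[j, ] - bb$N[i, ]),
        r_HO = if (hyd$donor_capable[i]) vnorm(bb$O[j, ] - h) else NA_real_,
        energy = e, class = classify_hbond(e, e_strong, e_weak),
        best = FALSE, donor_capable = hyd$donor_capable[i],
        stringsAsFactors = FALSE)
    }
    if (length(recs) == 0) next
    rec <- do.call(rbind, recs)
    rec$best[which.min(rec$energy)] <- TRUE
    rows[[length(rows) + 1L]] <- rec
  }
  if (length(rows) == 0)
    return(data.frame(chain = character(0), donor_idx = integer(0),
                      donor_resno = integer(0), donor_resid = character(0),
                      acceptor_idx = integer(0), acceptor_resno = integer(0),
                      offset = integer(0), r_NO = numeric(0),
                      r_HO = numeric(0), energy = numeric(0),
                      class = character(0), best = logical(0),
                      donor_capable = logical(0)))
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Side-chain to backbone hydrogen bonds within a helix
#'
#' Reports polar side-chain atoms (Ser OG, Thr OG1, Asn OD1/ND2, Asp
#' OD1/OD2, Cys SG, Tyr OH) lying within `cutoff` of a backbone carbonyl
#' oxygen or amide nitrogen of residues i-4..i+4 in the same chain.  A
#' pure distance criterion is used; cysteine SG records are flagged as
#' weak donors.
#'
#' @param s A [hw_structure].
#' @param chain Chain identifier.
#' @param cutoff Distance cutoff in Angstrom.
#' @param window Sequence window (residues each side) searched.
#' @return A data.frame: `resno`, `resid`, `atom`, `partner_idx`,
#'   `partner_resno`, `partner_atom` (`"O"` or `"N"`), `offset`,
#'   `distance`, `weak_donor`.
#' @export
sidechain_backbone_hbonds <- function(s, chain, cutoff = 3.5, window = 4L) {
  bb <- backbone_view(s, chain)
  sc <- sidechain_atoms(s, chain, bb)
  polar <- c("OG", "OG1", "OD1", "ND2", "OD2", "SG", "OH")
  sc <- sc[sc$elety %in% polar, , drop = FALSE]
  out <- list()
  for (r in seq_len(nrow(sc))) {
    i <- sc$res_idx[r]
    if (is.na(i)) next
    p <- as.numeric(sc[r, c("x", "y", "z")])
    for (j in seq(max(1L, i - window), min(length(bb$resno), i + window))) {
      if (j == i) next
      for (pa in c("O", "N")) {
        q <- bb[[pa]][j, ]
        if (any(is.na(q))) next
        d <- vnorm(p - q)
        if (d <= cutoff) {
          out[[length(out) + 1L]] <- data.frame(
            resno = sc$resno[r], resid = sc$resid[r], atom = sc$elety[r],
            partner_idx = j, partner_resno = bb$resno[j], partner_atom = pa,
            offset = j - i, distance = d,
            weak_donor = sc$elety[r] == "SG",
            stringsAsFactors = FALSE)
        }
      }
    }
  }
  if (length(out) == 0)
    return(data.frame(resno = integer(0), resid = character(0),
                      atom = character(0), partner_idx = integer(0),
                      partner_resno = integer(0), partner_atom = character(0),
                      offset = integer(0), distance = numeric(0),
                      weak_donor = logical(0)))
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}
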