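# Helix detection, irregularity annotation (pi-bulge / 3-10 constriction /
# kink) and weak-spot calling with mechanism attribution.  A weak spot is
# an interior i -> i-4 backbone hydrogen bond classified weak or missing;
# its mechanism is attributed in fixed priority order: proline at the
# donor, then a polar side chain clamping the weakened carbonyl or amide,
# then glycine flexibility near the donor, then an inter-helix contact
# pushing the backbone, else unexplained.

.empty_weakspots <- function() {
  data.frame(chain = character(0), donor_idx = integer(0),
             donor_resno = integer(0), donor_resid = character(0),
             acceptor_resno = integer(0), generic = character(0),
             class = character(0), mechanism = character(0),
             causal = character(0), stringsAsFactors = FALSE)
}

#' Backbone torsion angles of one chain
#'
#' @param s A [hw_structure].
#' @param chain Chain identifier.
#' @return A data.frame with per-residue `resno`, `resid`, `phi`, `psi`,
#'   `omega` (degrees, `NA` at chain termini or next to incomplete
#'   residues).
#' @export
backbone_torsions <- function(s, chain) {
  bb <- backbone_view(s, chain)
  n <- length(bb$resno)
  phi <- psi <- omega <- rep(NA_real_, n)
  for (i in seq_len(n)) {
    if (!bb$complete[i]) next
    if (i > 1L && bb$complete[i - 1L]) {
      phi[i] <- torsion_angle(bb$C[i - 1L, ], bb$N[i, ], bb$CA[i, ], bb$C[i, ])
      omega[i] <- torsion_angle(bb$CA[i - 1L, ], bb$C[i - 1L, ], bb$N[i, ],
                                bb$CA[i, ])
    }
    if (i < n && bb$complete[i + 1L])
      psi[i] <- torsion_angle(bb$N[i, ], bb$CA[i, ], bb$C[i, ], bb$N[i + 1L, ])
  }
  data.frame(resno = bb$resno, resid = bb$resid, phi = phi, psi = psi,
             omega = omega, stringsAsFactors = FALSE)
}

#' Detect helical segments in a chain
#'
#' A residue is helical when its phi/psi fall in the helical window
#' (`phi` in `[-120, -20]`, `psi` in `[-80, +10]`; termini with undefined
#' torsions inherit their neighbour's verdict).  Maximal runs of at least
#' `min_length` helical residues are reported, merging runs separated by a
#' single non-helical residue, and kept only when at least `min_bonded` of
#' their donors have a helical hydrogen-bond partner at offset -3, -4 or
#' -5 (class not missing).
#'
#' @param s A [hw_structure].
#' @param chain Chain identifier (default: all chains).
#' @param min_length Minimum run length in residues.
#' @param min_bonded Minimum fraction of donors with a helical partner.
#' @param phi_range,psi_range Helical torsion windows (degrees).
#' @return A list of segments; each is a list with `chain`, `start`,
#'   `end` (1-based chain indices), `resno_start`, `resno_end`, and an
#'   empty `irregularities` data.frame (filled by
#'   [annotate_irregularities()]).
#' @export
detect_helices <- function(s, chain = NULL, min_length = 6L,
                           min_bonded = 0.7,
                           phi_range = c(-120, -20), psi_range = c(-80, 10)) {
  chains <- if (is.null(chain)) structure_chains(s) else chain
  out <- list()
  for (ch in chains) {
    tor <- backbone_torsions(s, ch)
    bb <- backbone_view(s, ch)
    n <- nrow(tor)
    if (n < min_length) next
    ok <- !is.na(tor$phi) & !is.na(tor$psi) &
      tor$phi >= phi_range[1L] & tor$phi <= phi_range[2L] &
      tor$psi >= psi_range[1L] & tor$psi <= psi_range[2L]
    # chain termini lack one torsion; let them extend an adjacent run
    if (n >= 2L) {
      if (is.na(tor$phi[1L]) && !is.na(tor$psi[1L]))
        ok[1L] <- ok[2L] && tor$psi[1L] >= psi_range[1L] &
          tor$psi[1L] <= psi_range[2L]
      if (is.na(tor$psi[n]) && !is.na(tor$phi[n]))
        ok[n] <- ok[n - 1L] && tor$phi[n] >= phi_range[1L] &
          tor$phi[n] <= phi_range[2L]
    }
    ok[!bb$complete] <- FALSE
    # merge single-residue breaks
    merged <- ok
    for (i in seq_len(n)) {
      if (!ok[i] && i > 1L && i < n && ok[i - 1L] && ok[i + 1L])
        merged[i] <- TRUE
    }
    r <- rle(merged)
    ends <- cumsum(r$lengths)
    starts <- ends - r$lengths + 1L
    map <- backbone_hbond_map(s, ch)
    for (k in seq_along(r$values)) {
      if (!r$values[k] || r$lengths[k] < min_length) next
      st <- starts[k]; en <- ends[k]
      donors <- map[map$donor_idx >= st & map$donor_idx <= en &
                      map$acceptor_idx >= st, , drop = FALSE]
      if (nrow(donors) > 0) {
        per <- tapply(donors$class != "missing", donors$donor_idx, any)
        frac <- mean(per)
        if (frac < min_bonded) next
      }
      out[[length(out) + 1L]] <- list(
        chain = ch, start = st, end = en,
        resno_start = bb$resno[st], resno_end = bb$resno[en],
        irregularities = data.frame(idx = integer(0), resno = integer(0),
                                    kind = character(0),
                                    stringsAsFactors = FALSE))
    }
  }
  out
}

# Fit a local helix axis to the CA atoms of a residue index window.  The
# CA spiral is first collapsed onto near-axis points by a 4-residue
# running mean (about one helical turn) so the principal axis is not
# biased by an incomplete final turn.
local_axis <- function(bb, idx) {
  xyz <- bb$CA[idx, , drop = FALSE]
  xyz <- xyz[stats::complete.cases(xyz), , drop = FALSE]
  n <- nrow(xyz)
  if (n < 5L) return(NULL)
  mids <- t(vapply(seq_len(n - 3L), function(i)
    colMeans(xyz[i:(i + 3L), , drop = FALSE]), numeric(3L)))
  fit_axis(mids)$axis
}

#' Annotate helix irregularities on a segment
#'
#' A pi-bulge is called where at least `min_run` consecutive donors prefer
#' the -5 acceptor, a 3-10 constriction where they prefer -3, and a kink
#' where the axes fitted to the residue windows before and after a
#' position diverge by more than `kink_angle` degrees.  Kink detection
#' needs a sufficiently long segment and is skipped (with a flag) below 9
#' residues.
#'
#' @param s A [hw_structure].
#' @param segment One segment from [detect_helices()].
#' @param map Optional precomputed [backbone_hbond_map()] for the chain.
#' @param min_run Consecutive-donor run length for register calls.
#' @param kink_angle Kink threshold in degrees.
#' @param kink_window Residues on each side of the position used for the
#'   axis fits.
#' @return The segment with its `irregularities` data.frame filled
#'   (columns `idx`, `resno`, `kind` in `{"pi_bulge", "three10",
#'   "kink"}`); attribute `kink_skipped` is set when the segment was too
#'   short for kink detection.
#' @export
annotate_irregularities <- function(s, segment, map = NULL, min_run = 2L,
                                    kink_angle = 20, kink_window = 7L) {
  ch <- segment$chain
  if (is.null(map)) map <- backbone_hbond_map(s, ch)
  bb <- backbone_view(s, ch)
  st <- segment$start; en <- segment$end
  irr <- list()
  seg_map <- map[map$donor_idx >= st & map$donor_idx <= en &
                   map$acceptor_idx >= st & map$best, , drop = FALSE]
  for (target in c(-5L, -3L)) {
    kind <- if (target == -5L) "pi_bulge" else "three10"
    donors <- sort(seg_map$donor_idx[seg_map$offset == target &
                                       seg_map$class != "missing"])
    if (length(donors) == 0) next
    runs <- split(donors, cumsum(c(1L, diff(donors) != 1L)))
    for (run in runs) {
      if (length(run) >= min_run) {
        irr[[length(irr) + 1L]] <- data.frame(
          idx = run[1L], resno = bb$resno[run[1L]], kind = kind,
          stringsAsFactors = FALSE)
      }
    }
  }
  kink_skipped <- FALSE
  if (en - st + 1L < 9L) {
    kink_skipped <- TRUE
  } else {
    w <- min(kink_window, (en - st) %/% 2L)
    kpos <- integer(0)
    kang <- numeric(0)
    for (p in (st + w):(en - w)) {
      a1 <- local_axis(bb, (p - w):(p - 1L))
      a2 <- local_axis(bb, (p + 1L):(p + w))
      if (is.null(a1) || is.null(a2)) next
      ang <- rad2deg(acos(max(-1, min(1, sum(a1 * a2)))))
      if (ang > kink_angle) { kpos <- c(kpos, p); kang <- c(kang, ang) }
    }
    if (length(kpos) > 0) {
      # report the locally sharpest position of each contiguous stretch
      grp <- cumsum(c(1L, diff(kpos) != 1L))
      for (g in unique(grp)) {
        sel <- grp == g
        p <- kpos[sel][which.max(kang[sel])]
        irr[[length(irr) + 1L]] <- data.frame(
          idx = p, resno = bb$resno[p], kind = "kink",
          stringsAsFactors = FALSE)
      }
    }
  }
  segment$irregularities <- if (length(irr) > 0) do.call(rbind, irr)
  else segment$irregularities
  attr(segment, "kink_skipped") <- kink_skipped
  segment
}

# Mechanism attribution for one weakened -4 bond (donor chain index i).
attribute_mechanism <- function(s, segment, bb, i, scb, segments) {
  ch <- segment$chain
  clampers <- c("SER", "THR", "ASN", "ASP", "CYS")
  if (bb$resid[i] == "PRO")
    return(list(mechanism = "proline", causal = bb$resno[i]))
  if (!is.null(scb) && nrow(scb) > 0) {
    hit <- scb[scb$resid %in% clampers &
                 ((scb$partner_idx == i & scb$partner_atom == "N") |
                    (scb$partner_idx == i - 4L & scb$partner_atom == "O")), ,
               drop = FALSE]
    if (nrow(hit) > 0)
      return(list(mechanism = "sidechain_clamp",
                  causal = unique(hit$resno)))
  }
  near <- intersect((i - 1L):(i + 1L), segment$start:segment$end)
  gly <- near[bb$resid[near] == "GLY"]
  if (length(gly) > 0)
    return(list(mechanism = "glycine_flex", causal = bb$resno[gly]))
  # inter-helix contact pushing the backbone near the donor
  if (!is.null(segments) && length(segments) > 1L) {
    own <- as.matrix(rbind(bb$N[near, , drop = FALSE],
                           bb$CA[near, , drop = FALSE],
                           bb$C[near, , drop = FALSE],
                           bb$O[near, , drop = FALSE]))
    own <- own[stats::complete.cases(own), , drop = FALSE]
    for (other in segments) {
      if (identical(other$chain, ch) && other$start == segment$start) next
      at <- s$atom[!s$atom$het & s$atom$chain == other$chain, , drop = FALSE]
      obb <- backbone_view(s, other$chain)
      sel <- at$resno %in% obb$resno[other$start:other$end] &
        at$elesy != "H"
      oxyz <- as.matrix(at[sel, c("x", "y", "z")])
      if (nrow(oxyz) == 0 || nrow(own) == 0) next
      d2 <- outer(rowSums(own^2), rowSums(oxyz^2), `+`) -
        2 * own %*% t(oxyz)
      if (min(d2) < 3.8^2) {
        j <- which(d2 == min(d2), arr.ind = TRUE)[1L, 2L]
        return(list(mechanism = "pushed_backbone",
                    causal = at$resno[sel][j]))
      }
    }
  }
  list(mechanism = "unexplained", causal = NA_integer_)
}

#' Call weak spots on an annotated helix segment
#'
#' Every interior -4 bond of class weak or missing becomes a weak spot.
#' Mechanisms are attributed in the fixed priority order proline >
#' sidechain_clamp > glycine_flex > pushed_backbone.
#'
#' @param s A [hw_structure].
#' @param segment A segment from [detect_helices()] (annotation optional).
#' @param map,scb Optional precomputed [backbone_hbond_map()] and
#'   [sidechain_backbone_hbonds()] for the chain.
#' @param segments All segments of the structure (used for inter-helix
#'   contact attribution).
#' @param numbering Optional [assign_generic_numbers()] table; adds
#'   generic numbers to the report.
#' @return A data.frame: `chain`, `donor_idx`, `donor_resno`,
#'   `donor_resid`, `acceptor_resno`, `generic`, `class`, `mechanism`,
#'   `causal` (comma-separated author numbers).
#' @export
call_weak_spots <- function(s, segment, map = NULL, scb = NULL,
                            segments = NULL, numbering = NULL) {
  ch <- segment$chain
  if (is.null(map)) map <- backbone_hbond_map(s, ch)
  if (is.null(scb)) scb <- sidechain_backbone_hbonds(s, ch)
  bb <- backbone_view(s, ch)
  st <- segment$start; en <- segment$end
  rows <- list()
  m4 <- map[map$offset == -4L & map$donor_idx >= st + 4L &
              map$donor_idx <= en, , drop = FALSE]
  m4 <- m4[m4$class != "normal", , drop = FALSE]
  for (r in seq_len(nrow(m4))) {
    i <- m4$donor_idx[r]
    att <- attribute_mechanism(s, segment, bb, i, scb, segments)
    gen <- NA_character_
    if (!is.null(numbering)) {
      hit <- numbering[numbering$chain == ch &
                         numbering$resno == m4$donor_resno[r], , drop = FALSE]
      if (nrow(hit) == 1L) gen <- hit$generic
    }
    rows[[length(rows) + 1L]] <- data.frame(
      chain = ch, donor_idx = i, donor_resno = m4$donor_resno[r],
      donor_resid = m4$donor_resid[r], acceptor_resno = m4$acceptor_resno[r],
      generic = gen, class = m4$class[r], mechanism = att$mechanism,
      causal = paste(att$causal, collapse = ","),
      stringsAsFactors = FALSE)
  }
  if (length(rows) == 0) return(.empty_weakspots())
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Weak-spot report for a whole structure
#'
#' Detects helices on the requested chains, calls weak spots per segment
#' and concatenates the reports, stably sorted by chain then position.
#'
#' @param s A [hw_structure].
#' @param chains Chains to analyse (default all).
#' @param numbering Optional generic-numbering table.
#' @param segments Optional precomputed segments.
#' @return A data.frame as from [call_weak_spots()].
#' @export
weakspot_table <- function(s, chains = NULL, numbering = NULL,
                           segments = NULL) {
  if (nrow(s$atom) == 0 || length(structure_chains(s)) == 0)
    return(.empty_weakspots())
  if (is.null(chains)) chains <- structure_chains(s)
  if (is.null(segments)) segments <- detect_helices(s)
  segments <- Filter(function(sg) sg$chain %in% chains, segments)
  out <- list()
  for (sg in segments) {
    map <- backbone_hbond_map(s, sg$chain)
    scb <- sidechain_backbone_hbonds(s, sg$chain)
    out[[length(out) + 1L]] <-
      call_weak_spots(s, sg, map, scb, segments, numbering)
  }
  if (length(out) == 0) return(.empty_weakspots())
  res <- do.call(rbind, out)
  res <- res[order(res$chain, res$donor_idx), , drop = FALSE]
  rownames(res) <- NULL
  res
}
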