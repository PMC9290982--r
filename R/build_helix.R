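# Deterministic internal-coordinate helix builder.  Backbone atoms are
# placed NeRF-style from ideal bond lengths/angles at the requested phi /
# psi / omega torsions; side chains are built from ideal internal
# coordinates at requested chi angles for the residue types whose
# weakening mechanisms the analysis models (L, S, T, N, D, C, Y, W), and
# as CB stubs otherwise.  The builder is deterministic: a seed only drives
# the optional coordinate jitter.

# Ideal backbone internal coordinates (Angstrom / degrees).
.bb <- list(
  b_n_ca = 1.458, b_ca_c = 1.525, b_c_n = 1.329, b_c_o = 1.231,
  a_n_ca_c = 111.2, a_ca_c_n = 116.2, a_c_n_ca = 121.7, a_ca_c_o = 120.8
)

# Canonical helix torsions used for planted irregularities.
helix_torsions <- function(kind = c("alpha", "three10", "pi")) {
  kind <- match.arg(kind)
  switch(kind,
         alpha = c(phi = -57, psi = -47),
         three10 = c(phi = -49, psi = -26),
         pi = c(phi = -57, psi = -70))
}

# Side-chain topology: per residue type, a list of atoms with NeRF
# reference atoms, ideal bond length / angle, and a torsion that is either
# a chi angle (possibly offset for branches) or fixed (ring closure).
.chi_tors <- function(k, offset = 0) list(type = "chi", k = k, offset = offset)
.fix_tors <- function(v) list(type = "fixed", value = v)

.sc_topology <- list(
  LEU = list(
    list("CG", c("N", "CA", "CB"), 1.530, 116.3, .chi_tors(1)),
    list("CD1", c("CA", "CB", "CG"), 1.521, 110.7, .chi_tors(2)),
    list("CD2", c("CA", "CB", "CG"), 1.521, 110.7, .chi_tors(2, 122.6))),
  SER = list(
    list("OG", c("N", "CA", "CB"), 1.417, 110.8, .chi_tors(1))),
  THR = list(
    list("OG1", c("N", "CA", "CB"), 1.433, 109.6, .chi_tors(1)),
    list("CG2", c("N", "CA", "CB"), 1.521, 110.5, .chi_tors(1, -122))),
  CYS = list(
    list("SG", c("N", "CA", "CB"), 1.808, 114.4, .chi_tors(1))),
  ASN = list(
    list("CG", c("N", "CA", "CB"), 1.516, 112.6, .chi_tors(1)),
    list("OD1", c("CA", "CB", "CG"), 1.231, 120.8, .chi_tors(2)),
    list("ND2", c("CA", "CB", "CG"), 1.328, 116.4, .chi_tors(2, 180))),
  ASP = list(
    list("CG", c("N", "CA", "CB"), 1.516, 112.6, .chi_tors(1)),
    list("OD1", c("CA", "CB", "CG"), 1.249, 118.4, .chi_tors(2)),
    list("OD2", c("CA", "CB", "CG"), 1.249, 118.4, .chi_tors(2, 180))),
  TYR = list(
    list("CG", c("N", "CA", "CB"), 1.512, 113.9, .chi_tors(1)),
    list("CD1", c("CA", "CB", "CG"), 1.389, 120.8, .chi_tors(2)),
    list("CD2", c("CA", "CB", "CG"), 1.389, 120.8, .chi_tors(2, 180)),
    list("CE1", c("CB", "CG", "CD1"), 1.382, 121.2, .fix_tors(180)),
    list("CE2", c("CB", "CG", "CD2"), 1.382, 121.2, .fix_tors(180)),
    list("CZ", c("CG", "CD1", "CE1"), 1.378, 119.6, .fix_tors(0)),
    list("OH", c("CD1", "CE1", "CZ"), 1.376, 119.9, .fix_tors(180))),
  TRP = list(
    list("CG", c("N", "CA", "CB"), 1.498, 113.6, .chi_tors(1)),
    list("CD1", c("CA", "CB", "CG"), 1.365, 126.9, .chi_tors(2)),
    list("CD2", c("CA", "CB", "CG"), 1.433, 126.8, .chi_tors(2, 180)),
    list("NE1", c("CB", "CG", "CD1"), 1.374, 110.2, .fix_tors(180)),
    list("CE2", c("CB", "CG", "CD2"), 1.409, 107.2, .fix_tors(180)),
    list("CE3", c("CB", "CG", "CD2"), 1.398, 133.9, .fix_tors(0)),
    list("CZ2", c("CG", "CD2", "CE2"), 1.398, 122.4, .fix_tors(180)),
    list("CZ3", c("CG", "CD2", "CE3"), 1.391, 118.6, .fix_tors(180)),
    list("CH2", c("CD2", "CE3", "CZ3"), 1.368, 121.1, .fix_tors(0)))
)

.default_chis <- list(
  LEU = c(-60, 175), SER = c(-60), THR = c(-60), CYS = c(-60),
  ASN = c(-60, -20), ASP = c(-60, -20), TYR = c(-60, 90), TRP = c(-60, 90))

# Place CB in the CA frame (L-amino-acid chirality).
place_cb <- function(n, ca, c) {
  u1 <- unit(n - ca)
  u2 <- unit(c - ca)
  v <- solve_direction(u1, u2, 110.4, 110.5, s = -1)
  ca + 1.53 * v
}

# Build the side chain of one residue from its backbone frame.  Returns a
# data.frame of atom name / element / coordinates (possibly empty).
build_sidechain_atoms <- function(resid, n, ca, c, chis = NULL) {
  if (resid == "GLY") return(NULL)
  cb <- place_cb(n, ca, c)
  coords <- list(N = n, CA = ca, C = c, CB = cb)
  names_out <- "CB"
  topo <- .sc_topology[[resid]]
  if (!is.null(topo)) {
    want <- .default_chis[[resid]]
    if (!is.null(chis)) want[seq_along(chis)] <- chis
    for (row in topo) {
      tors <- row[[5L]]
      tval <- if (tors$type == "chi") want[tors$k] + tors$offset else tors$value
      refs <- row[[2L]]
      pos <- place_atom(coords[[refs[1L]]], coords[[refs[2L]]],
                        coords[[refs[3L]]], row[[3L]], row[[4L]], tval)
      coords[[row[[1L]]]] <- pos
      names_out <- c(names_out, row[[1L]])
    }
  }
  xyz <- do.call(rbind, coords[names_out])
  data.frame(elety = names_out,
             elesy = infer_element(names_out),
             x = xyz[, 1L], y = xyz[, 2L], z = xyz[, 3L],
             stringsAsFactors = FALSE)
}

#' Build a helix from internal coordinates
#'
#' Constructs a polypeptide at the requested backbone torsions with ideal
#' bond geometry.  Distortions plant the weakening mechanisms the analysis
#' detects: `proline` (residue becomes PRO, hence no amide donor),
#' `pi_bulge` / `three10` (a four-residue window switched to pi / 3-10
#' helix torsions), `sidechain_clamp` (residue becomes Asn (or keeps an
#' existing S/T/N/D/C identity), its side-chain amide is oriented at the
#' i-4 carbonyl, and that carbonyl oxygen is rotated toward the side
#' chain, over-stretching the backbone hydrogen bond it accepts), and
#' `kink` (rigid rotation of all residues past the position by `angle`
#' degrees).
#'
#' @param sequence One-letter amino-acid string.
#' @param phi,psi,omega Backbone torsions in degrees (scalar or
#'   per-residue vector).
#' @param distortions List of `list(position=, kind=, ...)` entries with
#'   `kind` one of `"proline"`, `"pi_bulge"`, `"three10"`,
#'   `"sidechain_clamp"`, `"kink"` (the latter takes `angle`, default 25).
#' @param chis Named list: `chis[["7"]] = c(-60, 175)` sets the chi angles
#'   of residue at position 7.
#' @param seed Integer seed for the optional coordinate jitter.
#' @param noise_sd Standard deviation (Angstrom) of isotropic Gaussian
#'   jitter added to every coordinate; 0 (default) disables it.
#' @param chain Chain identifier.
#' @param resno_start First author residue number.
#' @param id Structure identifier.
#' @param clamp_rotation Carbonyl rotation (degrees) used by the
#'   `sidechain_clamp` distortion; the default over-stretches the clamped
#'   bond into the weak class while keeping the side-chain hydrogen bond
#'   at a donor-acceptor distance near 3.1 Angstrom.
#' @return A [hw_structure].  The attribute `"distortions"` records the
#'   applied distortion list.
#' @export
build_helix <- function(sequence, phi = -57, psi = -47, omega = 180,
                        distortions = list(), chis = list(),
                        seed = 1L, noise_sd = 0, chain = "A",
                        resno_start = 1L, id = "helix",
                        clamp_rotation = 40) {
  aa <- strsplit(toupper(sequence), "")[[1L]]
  n <- length(aa)
  if (n < 1L) stop("empty sequence")
  valid <- rownames(bio3d::aa.table)
  resid <- vapply(aa, function(a) {
    r <- suppressWarnings(bio3d::aa123(a))
    if (is.na(r) || !(r %in% valid)) stop("unknown residue code: ", a)
    r
  }, character(1L), USE.NAMES = FALSE)
  if (any(abs(phi) > 180) || any(abs(psi) > 180))
    stop("phi/psi must lie in [-180, 180]")
  phi <- rep_len(phi, n); psi <- rep_len(psi, n); omega <- rep_len(omega, n)

  clamp_at <- integer(0)
  kinks <- list()
  for (d in distortions) {
    k <- d$position
    if (is.null(k) || k < 1L || k > n) stop("distortion position out of range")
    kind <- match.arg(d$kind, c("proline", "pi_bulge", "three10",
                                "sidechain_clamp", "kink"))
    if (kind == "proline") {
      resid[k] <- "PRO"
    } else if (kind %in% c("pi_bulge", "three10")) {
      tt <- helix_torsions(if (kind == "pi_bulge") "pi" else "three10")
      win <- k:min(n, k + 3L)
      phi[win] <- tt["phi"]; psi[win] <- tt["psi"]
    } else if (kind == "sidechain_clamp") {
      if (k <= 4L) stop("sidechain_clamp needs position > 4")
      if (!(resid[k] %in% c("SER", "THR", "ASN", "ASP", "CYS")))
        resid[k] <- "ASN"
      if (is.null(chis[[as.character(k)]]))
        chis[[as.character(k)]] <- if (resid[k] == "ASN") c(-90, -90) else -60
      clamp_at <- c(clamp_at, k)
    } else if (kind == "kink") {
      kinks <- c(kinks, list(list(position = k,
                                  angle = if (is.null(d$angle)) 25 else d$angle)))
    }
  }

  # backbone
  N <- CA <- C <- O <- matrix(NA_real_, n, 3L)
  N[1L, ] <- c(0, 0, 0)
  CA[1L, ] <- c(.bb$b_n_ca, 0, 0)
  C[1L, ] <- place_atom(c(0, 1, 0), N[1L, ], CA[1L, ],
                        .bb$b_ca_c, .bb$a_n_ca_c, 0)
  for (i in seq_len(n)) {
    if (i > 1L) {
      N[i, ] <- place_atom(N[i - 1L, ], CA[i - 1L, ], C[i - 1L, ],
                           .bb$b_c_n, .bb$a_ca_c_n, psi[i - 1L])
      CA[i, ] <- place_atom(CA[i - 1L, ], C[i - 1L, ], N[i, ],
                            .bb$b_n_ca, .bb$a_c_n_ca, omega[i])
      C[i, ] <- place_atom(C[i - 1L, ], N[i, ], CA[i, ],
                           .bb$b_ca_c, .bb$a_n_ca_c, phi[i])
    }
    O[i, ] <- place_atom(N[i, ], CA[i, ], C[i, ],
                         .bb$b_c_o, .bb$a_ca_c_o, psi[i] + 180)
  }

  rows <- vector("list", n)
  for (i in seq_len(n)) {
    bb <- data.frame(elety = c("N", "CA", "C", "O"),
                     elesy = c("N", "C", "C", "O"),
                     x = c(N[i, 1L], CA[i, 1L], C[i, 1L], O[i, 1L]),
                     y = c(N[i, 2L], CA[i, 2L], C[i, 2L], O[i, 2L]),
                     z = c(N[i, 3L], CA[i, 3L], C[i, 3L], O[i, 3L]),
                     stringsAsFactors = FALSE)
    sc <- build_sidechain_atoms(resid[i], N[i, ], CA[i, ], C[i, ],
                                chis[[as.character(i)]])
    r <- rbind(bb, sc)
    r$chain <- chain; r$resno <- resno_start + i - 1L
    r$insert <- ""; r$resid <- resid[i]; r$het <- FALSE
    rows[[i]] <- r
  }
  atom <- do.call(rbind, rows)
  s <- hw_structure(atom, id = id, format = "built")

  # clamp distortions: rotate the i-4 carbonyl oxygen toward the clamping
  # side chain (the side-chain hydrogen bond pulls the backbone carbonyl
  # out of its ideal position)
  for (k in clamp_at) {
    target <- residue_atoms(s, chain, resno_start + k - 1L)
    polar <- target[target$elety %in% c("ND2", "OG", "OG1", "OD1", "OD2",
                                        "SG"), , drop = FALSE]
    toward <- if (nrow(polar) > 0)
      as.numeric(polar[1L, c("x", "y", "z")]) else NULL
    s <- rotate_carbonyl(s, chain, resno_start + k - 5L,
                         angle = clamp_rotation, toward = toward)
  }
  for (kk in kinks) {
    s <- apply_kink(s, chain, resno_start + kk$position - 1L, kk$angle)
  }
  if (noise_sd > 0) {
    old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
    set.seed(seed)
    xyz <- atom_coords(s)
    s <- set_coords(s, xyz + matrix(stats::rnorm(length(xyz), 0, noise_sd),
                                    ncol = 3L))
    if (!is.null(old)) assign(".Random.seed", old, globalenv())
  }
  attr(s, "distortions") <- distortions
  s
}

#' Rotate a backbone carbonyl oxygen about its CA-C axis
#'
#' The carbonyl oxygen is a leaf atom, so this perturbs exactly one
#' hydrogen-bond acceptor without touching any other geometry.  Used to
#' emulate the backbone displacement exerted by a clamping side chain.
#'
#' @param s A [hw_structure].
#' @param chain,resno Residue whose O is rotated.
#' @param angle Rotation in degrees.
#' @param toward Optional 3-vector; when given, O is rotated about its
#'   carbonyl carbon within the C-O-target plane, moving it toward the
#'   point (the C=O bond length is preserved).  Without a target, O is
#'   rotated about the CA-C axis in the sense that moves it farther from
#'   the i+4 amide nitrogen.
#' @return The modified structure.
#' @export
rotate_carbonyl <- function(s, chain, resno, angle = 35, toward = NULL) {
  res <- residue_atoms(s, chain, resno)
  if (nrow(res) == 0) stop("no residue ", resno, " in chain ", chain)
  need <- c("CA", "C", "O")
  if (!all(need %in% res$elety)) stop("residue lacks CA/C/O")
  ca <- as.numeric(res[res$elety == "CA", c("x", "y", "z")])
  cc <- as.numeric(res[res$elety == "C", c("x", "y", "z")])
  oo <- as.numeric(res[res$elety == "O", c("x", "y", "z")])
  if (!is.null(toward)) {
    ax <- vcross(oo - cc, toward - cc)
    if (vnorm(ax) < 1e-8) ax <- vcross(oo - cc, c(0, 0, 1))
    cand <- lapply(c(angle, -angle), function(a)
      as.numeric(rotate_about_axis(matrix(oo, 1L), cc, ax, a)))
    pick <- which.min(vapply(cand, function(p) vnorm(p - toward),
                             numeric(1L)))
    new_o <- cand[[pick]]
  } else {
    cand <- lapply(c(angle, -angle), function(a)
      as.numeric(rotate_about_axis(matrix(oo, 1L), cc, cc - ca, a)))
    nxt <- residue_atoms(s, chain, resno + 4L)
    ref <- if (nrow(nxt) > 0 && "N" %in% nxt$elety)
      as.numeric(nxt[nxt$elety == "N", c("x", "y", "z")]) else NULL
    pick <- if (is.null(ref)) 1L
    else which.max(vapply(cand, function(p) vnorm(p - ref), numeric(1L)))
    new_o <- cand[[pick]]
  }
  sel <- !s$atom$het & s$atom$chain == chain & s$atom$resno == resno &
    s$atom$elety == "O"
  s$atom[sel, c("x", "y", "z")] <- as.list(new_o)
  s
}

# Rigid rotation of all residues strictly after `resno` about an axis
# perpendicular to the local helix axis through the hinge CA.
apply_kink <- function(s, chain, resno, angle) {
  sel_chain <- !s$atom$het & s$atom$chain == chain
  res <- residue_atoms(s, chain, resno)
  if (nrow(res) == 0 || !("CA" %in% res$elety)) stop("bad kink position")
  pivot <- as.numeric(res[res$elety == "CA", c("x", "y", "z")])
  cas <- s$atom[sel_chain & s$atom$elety == "CA", c("x", "y", "z")]
  ax <- fit_axis(as.matrix(cas))$axis
  perp <- unit(vcross(ax, if (abs(ax[1L]) < 0.9) c(1, 0, 0) else c(0, 1, 0)))
  move <- sel_chain & s$atom$resno > resno
  xyz <- as.matrix(s$atom[move, c("x", "y", "z")])
  s$atom[move, c("x", "y", "z")] <- rotate_about_axis(xyz, pivot, perp, angle)
  s
}
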