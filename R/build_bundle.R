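# Seven-helix bundle phantoms with planted weak spots.  Each planted
# generic position is realised by one of two distinct weakening
# mechanisms -- a proline (missing bond) or an asparagine side-chain
# clamp (over-stretched bond) -- chosen per helix from the seed, so that
# across an ensemble of bundles the same position is weakened by
# different sequence motifs.  TM3 never receives a weakener.

# Default planted positions: one per helix except TM3, inspired by the
# motif positions of class A receptors (TM1 GN motif region, TM2 2x58
# Pro/Asn, TM4 4x47 Ser/Asn, TM5 5x43 Ser/Gly, TM6 6x47 CWXP cysteine,
# TM7 7x46 region).
default_bundle_plants <- function() {
  data.frame(helix = c(1L, 2L, 4L, 5L, 6L, 7L),
             position = c(49L, 58L, 47L, 43L, 47L, 46L),
             stringsAsFactors = FALSE)
}

#' Build a 7-helix bundle phantom with planted weak spots
#'
#' Seven ideal helices are placed on a circle with axes along z
#' (antiparallel, as in a membrane bundle; the cytosolic side is -z).
#' Each helix listed in `plants` receives its weak spot through a
#' mechanism drawn from `mechanisms` using the seed; the returned truth
#' table records position and mechanism per helix.
#'
#' @param seed Integer seed (mechanism choice and coordinate jitter).
#' @param n_res Residues per helix.
#' @param radius Placement circle radius in Angstrom (the minimum
#'   inter-axis distance must stay >= 8).
#' @param plants Data.frame with columns `helix`, `position` (x50-relative
#'   generic position to weaken); default [default_bundle_plants()].
#'   An empty data.frame plants nothing.
#' @param mechanisms Mechanism pool sampled per planted helix.
#' @param noise_sd Coordinate jitter (Angstrom) applied to the assembled
#'   bundle.
#' @param id Structure identifier.
#' @return A list: `structure` (chains A-G = TM1-TM7), `truth`
#'   (chain, helix, generic, donor_resno, mechanism), `anchors`
#'   (an [anchor_config()]; x50 anchors at the helix midpoints).
#' @export
build_bundle <- function(seed = 1L, n_res = 26L, radius = 11.2,
                         plants = default_bundle_plants(),
                         mechanisms = c("proline", "sidechain_clamp"),
                         noise_sd = 0.02, id = paste0("bundle_", seed)) {
  if (2 * radius * sin(pi / 7) < 8)
    stop("helix placement too tight: inter-axis distance below 8 Angstrom")
  if (nrow(plants) > 0 &&
      any(plants$position < 35L | plants$position > 62L))
    stop("planted positions must lie in 35..62 for a ", n_res,
         "-residue helix")
  anchor_idx <- (n_res %/% 2L)  # x50 anchor
  chains <- LETTERS[1:7]
  old <- if (exists(".Random.seed", globalenv()))
    get(".Random.seed", globalenv()) else NULL
  set.seed(seed)
  mech_pick <- sample(mechanisms, 7L, replace = TRUE)
  atoms <- list()
  truth <- list()
  anchors_resno <- integer(7L)
  for (h in 1:7) {
    ch <- chains[h]
    resno_start <- 100L * h + 1L
    anchors_resno[h] <- 100L * h + anchor_idx
    dist_list <- list()
    prow <- plants[plants$helix == h, , drop = FALSE]
    if (nrow(prow) == 1L) {
      k <- anchor_idx + (prow$position - 50L)
      if (k <= 4L || k > n_res) stop("planted position outside helix")
      dist_list <- list(list(position = k, kind = mech_pick[h]))
      truth[[length(truth) + 1L]] <- data.frame(
        chain = ch, helix = h,
        generic = paste0(h, "x", prow$position),
        donor_resno = 100L * h + k, mechanism = mech_pick[h],
        stringsAsFactors = FALSE)
    }
    hx <- build_helix(strrep("A", n_res), distortions = dist_list,
                      chain = ch, resno_start = resno_start,
                      id = paste0(id, "_", ch))
    xyz <- atom_coords(hx)
    cas <- xyz[hx$atom$elety == "CA", , drop = FALSE]
    ax <- fit_axis(cas)
    target <- if (h %% 2L == 1L) c(0, 0, 1) else c(0, 0, -1)
    rot_ax <- vcross(ax$axis, target)
    if (vnorm(rot_ax) > 1e-9) {
      ang <- rad2deg(acos(max(-1, min(1, sum(ax$axis * target)))))
      xyz <- rotate_about_axis(xyz, ax$center, rot_ax, ang)
    }
    th <- 2 * pi * (h - 1L) / 7
    ctr <- colMeans(xyz[hx$atom$elety == "CA", , drop = FALSE])
    place <- c(radius * cos(th), radius * sin(th), 0)
    xyz <- sweep(xyz, 2L, place - ctr, `+`)
    hx <- set_coords(hx, xyz)
    atoms[[h]] <- hx$atom
  }
  atom <- do.call(rbind, atoms)
  s <- hw_structure(atom, id = id)
  if (noise_sd > 0) {
    xyz <- atom_coords(s)
    s <- set_coords(s, xyz + matrix(stats::rnorm(length(xyz), 0, noise_sd),
                                    ncol = 3L))
  }
  if (!is.null(old)) assign(".Random.seed", old, globalenv())
  truth <- if (length(truth) > 0) do.call(rbind, truth)
  else data.frame(chain = character(0), helix = integer(0),
                  generic = character(0), donor_resno = integer(0),
                  mechanism = character(0), stringsAsFactors = FALSE)
  list(structure = s,
       truth = truth,
       anchors = anchor_config(helix = 1:7, chain = chains,
                               resno = anchors_resno))
}
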