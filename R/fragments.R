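# Pentamer fragment databases and the backbone-similarity rotamer search:
# fragments of five residues with the same middle residue type as the
# query are superposed on the query backbone, and the side chains of the
# close matches give the local rotamer distribution.

fragment_backbone <- function(s, chain, idx_range) {
  bb <- backbone_view(s, chain)
  rows <- list()
  for (i in idx_range) {
    if (!bb$complete[i]) return(NULL)
    rows[[length(rows) + 1L]] <- rbind(bb$N[i, ], bb$CA[i, ], bb$C[i, ],
                                       bb$O[i, ])
  }
  do.call(rbind, rows)
}

#' Build a synthetic pentamer fragment database
#'
#' Background fragments have uniformly random backbone torsions and
#' random middle-residue types; planted fragments are built at specified
#' torsions (with optional jitter) and chi angles, so a search for a
#' matching query must recover exactly the planted set.
#'
#' @param n_background Number of random background pentamers.
#' @param planted List of plant specifications: each a list with
#'   `middle` (1-letter code), `phi`, `psi` (scalar or length-5),
#'   optional `chis` (middle-residue chi angles) and `jitter` (degrees
#'   of uniform torsion jitter, default 2).
#' @param seed Integer seed.
#' @param background_middles Pool of middle residues for the background.
#' @return An object of class `hw_fragment_db`: list with `fragments`
#'   (each: `id`, `planted`, `middle`, `bb` 20 x 3 backbone matrix
#'   (N, CA, C, O per residue), `structure` the 5-residue
#'   [hw_structure]) and `index` (data.frame of `id`, `middle`,
#'   `planted`).
#' @export
build_fragment_db <- function(n_background, planted = list(), seed = 1L,
                              background_middles = c("L", "A", "S", "V",
                                                     "T", "N", "F", "K")) {
  if (n_background < 0) stop("n_background must be >= 0")
  old <- if (exists(".Random.seed", globalenv()))
    get(".Random.seed", globalenv()) else NULL
  set.seed(seed)
  frags <- list()
  mk <- function(id, middle, phi, psi, chis, is_planted) {
    seqs <- paste0("AA", middle, "AA")
    ch <- list(); ch[["3"]] <- chis
    st <- build_helix(seqs, phi = phi, psi = psi, chis = ch,
                      id = id)
    bb <- fragment_backbone(st, "A", 1:5)
    list(id = id, planted = is_planted, middle = suppressWarnings(bio3d::aa123(middle)),
         bb = bb, structure = st)
  }
  for (p in seq_along(planted)) {
    pl <- planted[[p]]
    jit <- if (is.null(pl$jitter)) 2 else pl$jitter
    phi <- rep_len(pl$phi, 5L) + stats::runif(5L, -jit, jit)
    psi <- rep_len(pl$psi, 5L) + stats::runif(5L, -jit, jit)
    frags[[length(frags) + 1L]] <-
      mk(sprintf("planted_%02d", p), pl$middle, phi, psi, pl$chis, TRUE)
  }
  for (b in seq_len(n_background)) {
    phi <- stats::runif(5L, -180, 180)
    psi <- stats::runif(5L, -180, 180)
    middle <- sample(background_middles, 1L)
    frags[[length(frags) + 1L]] <-
      mk(sprintf("bg_%04d", b), middle, phi, psi, NULL, FALSE)
  }
  if (!is.null(old)) assign(".Random.seed", old, globalenv())
  index <- if (length(frags) > 0)
    data.frame(id = vapply(frags, `[[`, character(1L), "id"),
               middle = vapply(frags, `[[`, character(1L), "middle"),
               planted = vapply(frags, `[[`, logical(1L), "planted"),
               stringsAsFactors = FALSE)
  else data.frame(id = character(0), middle = character(0),
                  planted = logical(0))
  out <- list(fragments = frags, index = index)
  class(out) <- "hw_fragment_db"
  out
}

#' @export
print.hw_fragment_db <- function(x, ...) {
  cat(sprintf("<hw_fragment_db> %d fragments (%d planted)\n",
              nrow(x$index), sum(x$index$planted)))
  invisible(x)
}

#' Search a fragment database with a local pentamer query
#'
#' Candidate fragments with the query's middle residue type are
#' superposed on the query backbone (N, CA, C, O of the five residues);
#' fragments within `rmsd_threshold` are returned sorted by RMSD, with
#' the middle-residue side chain transformed into the query frame.
#'
#' @param s A [hw_structure] (the query structure).
#' @param chain Chain of the query.
#' @param center_resno Author number of the central query residue; two
#'   complete-backbone residues are required on each side.
#' @param db A `hw_fragment_db`.
#' @param rmsd_threshold Backbone RMSD cutoff in Angstrom.
#' @return A data.frame of class `hw_rotamer_hits`: `id`, `rmsd`,
#'   `rotamer` (canonical label of the fragment's middle side chain),
#'   `planted`; attribute `"sidechains"` holds the superposed middle
#'   side-chain coordinates per hit.
#' @export
pentamer_search <- function(s, chain, center_resno, db,
                            rmsd_threshold = 0.5) {
  bb <- backbone_view(s, chain)
  ci <- match(center_resno, bb$resno)
  if (is.na(ci) || ci < 3L || ci > length(bb$resno) - 2L)
    stop("query center must have two residues on each side")
  qbb <- fragment_backbone(s, chain, (ci - 2L):(ci + 2L))
  if (is.null(qbb)) stop("query pentamer has incomplete backbone")
  middle <- bb$resid[ci]
  hits <- list()
  sidechains <- list()
  for (fr in db$fragments) {
    if (fr$middle != middle) next
    sp <- superpose(fr$bb, qbb)
    if (sp$rmsd > rmsd_threshold) next
    st <- apply_transform(fr$structure, sp)
    mid <- residue_atoms(st, "A", 3L)
    sc <- mid[!(mid$elety %in% c("N", "CA", "C", "O")), , drop = FALSE]
    rot <- classify_rotamer(chi_angles(st, "A", 3L))
    hits[[length(hits) + 1L]] <- data.frame(
      id = fr$id, rmsd = sp$rmsd, rotamer = rot, planted = fr$planted,
      stringsAsFactors = FALSE)
    sidechains[[fr$id]] <- sc
  }
  out <- if (length(hits) > 0) do.call(rbind, hits)
  else data.frame(id = character(0), rmsd = numeric(0),
                  rotamer = character(0), planted = logical(0))
  out <- out[order(out$rmsd), , drop = FALSE]
  rownames(out) <- NULL
  attr(out, "sidechains") <- sidechains[out$id]
  class(out) <- c("hw_rotamer_hits", "data.frame")
  out
}

#' Rotamer distribution of fragment-search hits
#'
#' @param hits A `hw_rotamer_hits` data.frame.
#' @return Named numeric vector of rotamer-label frequencies (sums to 1;
#'   empty for no hits), with attribute `"counts"`.
#' @export
rotamer_distribution <- function(hits) {
  if (nrow(hits) == 0) {
    out <- numeric(0)
    attr(out, "counts") <- integer(0)
    return(out)
  }
  counts <- table(hits$rotamer)
  out <- as.numeric(counts) / sum(counts)
  names(out) <- names(counts)
  attr(out, "counts") <- as.integer(counts)
  out
}
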