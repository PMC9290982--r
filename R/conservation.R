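# Cross-structure conservation of weak spots and sequence-level
# profiling: alignment reading, per-column information content (the
# sequence-logo quantity), motif scanning with wildcards, PGDNST
# frequency profiles, and aggregation of weak spots from an ensemble of
# structures at generic positions.

#' Read a multiple sequence alignment from FASTA
#'
#' @param path FASTA file of equal-length aligned sequences; gaps are
#'   `-`, case is normalised to upper.
#' @return A character matrix (sequences x columns) with sequence ids as
#'   row names, class `hw_alignment`.
#' @export
read_alignment <- function(path) {
  aln <- Biostrings::readAAStringSet(path)
  if (length(aln) == 0) stop("empty alignment: ", path)
  w <- Biostrings::width(aln)
  if (length(unique(w)) != 1L)
    stop("ragged alignment: sequence lengths ", paste(unique(w), collapse = ", "))
  m <- do.call(rbind, strsplit(toupper(as.character(aln)), ""))
  rownames(m) <- names(aln)
  class(m) <- c("hw_alignment", class(m))
  m
}

.aa20 <- c("A", "C", "D", "E", "F", "G", "H", "I", "K", "L", "M", "N",
           "P", "Q", "R", "S", "T", "V", "W", "Y")

#' Information content of one alignment column
#'
#' `R = log2(20) - H` where `H` is the Shannon entropy of the residue
#' distribution in the column, gaps excluded.  No small-sample
#' correction is applied by default (closed-form determinism); the
#' WebLogo-style correction is available via `small_sample = TRUE`.
#'
#' @param aln A `hw_alignment` matrix.
#' @param column Column index.
#' @param small_sample Subtract the small-sample correction
#'   `e = 19 / (2 ln 2 n)`.
#' @return A list: `column`, `n` (non-gap count), `freq` (named residue
#'   frequencies over the 20 amino acids), `gap_fraction`,
#'   `information` (bits; `NA` with `flag = "all_gap"` for an all-gap
#'   column), `flag` (`"high_gap"` above 50% gaps).
#' @export
column_information <- function(aln, column, small_sample = FALSE) {
  if (column < 1L || column > ncol(aln)) stop("column out of range")
  col <- aln[, column]
  gaps <- col %in% c("-", ".")
  res <- col[!gaps]
  if (length(res) == 0)
    return(list(column = column, n = 0L, freq = stats::setNames(
      rep(NA_real_, 20L), .aa20), gap_fraction = 1,
      information = NA_real_, flag = "all_gap"))
  freq <- table(factor(res, levels = .aa20)) / length(res)
  p <- as.numeric(freq)
  h <- -sum(p[p > 0] * log2(p[p > 0]))
  info <- log2(20) - h
  if (small_sample) info <- info - 19 / (2 * log(2) * length(res))
  flag <- if (mean(gaps) > 0.5) "high_gap" else ""
  list(column = column, n = length(res),
       freq = stats::setNames(as.numeric(freq), .aa20),
       gap_fraction = mean(gaps), information = info, flag = flag)
}

#' Scan a sequence for a motif pattern
#'
#' Patterns use the 20 one-letter codes, `X` for any residue and
#' bracketed character classes (`"G[NS]XXV"`).  All, possibly
#' overlapping, match start positions are returned 0-based.
#'
#' @param sequence Protein sequence (string).
#' @param pattern Motif pattern.
#' @return Integer vector of 0-based match positions.
#' @export
motif_scan <- function(sequence, pattern) {
  sequence <- toupper(sequence)
  pattern <- toupper(pattern)
  ok <- gsub("\\[([ACDEFGHIKLMNPQRSTVWYX]+)\\]", "", pattern)
  if (grepl("[^ACDEFGHIKLMNPQRSTVWYX]", ok))
    stop("malformed motif pattern: ", pattern)
  if (lengths(regmatches(pattern, gregexpr("\\[", pattern))) !=
      lengths(regmatches(pattern, gregexpr("\\]", pattern))))
    stop("malformed motif pattern (unbalanced brackets): ", pattern)
  rx <- gsub("X", ".", pattern)
  m <- gregexpr(paste0("(?=", rx, ")"), sequence, perl = TRUE)[[1L]]
  if (m[1L] == -1L) return(integer(0))
  as.integer(m) - 1L
}

#' PGDNST frequency per alignment column
#'
#' Fraction of non-gap residues that are Pro, Gly, Asp, Asn, Ser or Thr
#' -- the helix-weakening residue set.
#'
#' @param aln A `hw_alignment` matrix.
#' @param columns Column indices (default all).
#' @return Data.frame with `column`, `n`, `pgdnst_fraction`.
#' @export
pgdnst_profile <- function(aln, columns = seq_len(ncol(aln))) {
  if (any(columns < 1L | columns > ncol(aln))) stop("column out of range")
  set <- c("P", "G", "D", "N", "S", "T")
  out <- lapply(columns, function(j) {
    col <- aln[, j]
    res <- col[!col %in% c("-", ".")]
    data.frame(column = j, n = length(res),
               pgdnst_fraction = if (length(res) == 0) NA_real_
               else mean(res %in% set))
  })
  do.call(rbind, out)
}

#' Aggregate weak spots across structures at generic positions
#'
#' @param spots Named list: one weak-spot data.frame (from
#'   [weakspot_table()], with generic numbers assigned) per structure.
#' @return A data.frame of class `hw_conservation`, one row per generic
#'   position observed: `generic`, `helix`, `position`, `n_structures`
#'   (ensemble size), `n_weakened`, `fraction`, one `mech_*` count
#'   column per mechanism, `face_deg` (helix-face phase angle,
#'   100 degrees per residue), and attribute `"excluded"` counting weak
#'   spots without generic numbers.
#' @export
aggregate_weak_spots <- function(spots) {
  n_struct <- length(spots)
  mechs <- c("proline", "sidechain_clamp", "glycine_flex",
             "pushed_backbone", "unexplained")
  all_rows <- list()
  excluded <- 0L
  for (sid in names(spots)) {
    ws <- spots[[sid]]
    if (is.null(ws) || nrow(ws) == 0) next
    miss <- is.na(ws$generic)
    excluded <- excluded + sum(miss)
    ws <- ws[!miss, , drop = FALSE]
    if (nrow(ws) == 0) next
    ws$structure <- sid
    all_rows[[length(all_rows) + 1L]] <- ws
  }
  if (length(all_rows) == 0) {
    out <- data.frame(generic = character(0), helix = integer(0),
                      position = integer(0), n_structures = integer(0),
                      n_weakened = integer(0), fraction = numeric(0),
                      face_deg = numeric(0))
    for (m in mechs) out[[paste0("mech_", m)]] <- integer(0)
    attr(out, "excluded") <- excluded
    class(out) <- c("hw_conservation", "data.frame")
    return(out)
  }
  ws <- do.call(rbind, all_rows)
  rows <- list()
  for (g in sort(unique(ws$generic))) {
    sel <- ws[ws$generic == g, , drop = FALSE]
    helix <- as.integer(sub("x.*", "", g))
    pos <- as.integer(sub(".*x", "", g))
    row <- data.frame(generic = g, helix = helix, position = pos,
                      n_structures = n_struct,
                      n_weakened = length(unique(sel$structure)),
                      fraction = length(unique(sel$structure)) / n_struct,
                      face_deg = (pos * 100) %% 360,
                      stringsAsFactors = FALSE)
    for (m in mechs)
      row[[paste0("mech_", m)]] <- sum(sel$mechanism == m)
    rows[[length(rows) + 1L]] <- row
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  attr(out, "excluded") <- excluded
  class(out) <- c("hw_conservation", "data.frame")
  out
}

#' Helix-face equivalence of two generic positions
#'
#' Two positions lie on the same helix face when their phase angles
#' (100 degrees per residue on an ideal alpha helix) differ by at most
#' `tol` degrees and they are within `window` turns, the operational
#' reading of "same face of the helix".
#'
#' @param p1,p2 Integer x50-relative positions on the same helix.
#' @param tol Phase tolerance in degrees.
#' @param window Maximum separation in residues.
#' @return Logical.
#' @export
same_helix_face <- function(p1, p2, tol = 40, window = 11L) {
  dphase <- abs((((p1 - p2) * 100 + 180) %% 360) - 180)
  dphase <= tol & abs(p1 - p2) <= window
}
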