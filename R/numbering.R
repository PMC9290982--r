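# GPCRdb-style generic residue numbering.  Each transmembrane helix is
# anchored at its most conserved residue (the x50 position); other
# positions are numbered linearly from the anchor along the helix
# segment, so 2x46 is four residues before the TM2 anchor.  The full
# structure-based bulge/constriction renumbering of GPCRdb is not
# reproduced; instead, positions separated from their anchor by a
# detected pi-bulge are flagged so the potential off-by-one is visible.

#' Anchor configuration for generic numbering
#'
#' @param helix Integer helix indices (1-7, 8 for helix 8).
#' @param chain Chain holding each helix.
#' @param resno Author residue number of each x50 anchor.
#' @param expected Optional expected anchor residue type (3-letter); a
#'   mismatch between expected and observed type produces a warning, not
#'   an error.
#' @return A data.frame of class `hw_anchors`.
#' @export
anchor_config <- function(helix, chain, resno, expected = NA_character_) {
  df <- data.frame(helix = as.integer(helix), chain = as.character(chain),
                   resno = as.integer(resno),
                   expected = rep_len(as.character(expected), length(helix)),
                   stringsAsFactors = FALSE)
  if (anyDuplicated(df$helix))
    stop("exactly one anchor per helix is required")
  class(df) <- c("hw_anchors", "data.frame")
  df
}

#' Read an anchor configuration file
#'
#' The file is YAML: a list of entries with fields `helix`, `chain`,
#' `resno` and optional `expected`, e.g.
#' `- {helix: 2, chain: A, resno: 80, expected: ASP}`.
#'
#' @param path File path.
#' @return A `hw_anchors` data.frame.
#' @export
read_anchor_config <- function(path) {
  y <- yaml::read_yaml(path)
  anchor_config(helix = vapply(y, `[[`, numeric(1L), "helix"),
                chain = vapply(y, `[[`, character(1L), "chain"),
                resno = vapply(y, `[[`, numeric(1L), "resno"),
                expected = vapply(y, function(e)
                  if (is.null(e$expected)) NA_character_ else e$expected,
                  character(1L)))
}

#' Write an anchor configuration file
#' @param anchors A `hw_anchors` data.frame.
#' @param path Output path.
#' @return Invisibly, `path`.
#' @export
write_anchor_config <- function(anchors, path) {
  y <- lapply(seq_len(nrow(anchors)), function(i) {
    e <- list(helix = anchors$helix[i], chain = anchors$chain[i],
              resno = anchors$resno[i])
    if (!is.na(anchors$expected[i])) e$expected <- anchors$expected[i]
    e
  })
  yaml::write_yaml(y, path)
  invisible(path)
}

#' Assign generic residue numbers from x50 anchors
#'
#' Within each anchored helix segment, position = 50 + (index - anchor
#' index); residues outside segments stay unnumbered.  An anchor that
#' falls outside every detected segment is an error; an anchor whose
#' observed residue type differs from the expected type produces a
#' warning only.
#'
#' @param s A [hw_structure].
#' @param segments Segments from [detect_helices()].
#' @param anchors A [anchor_config()] table.
#' @return A data.frame of class `hw_numbering`: `chain`, `resno`,
#'   `insert`, `resid`, `idx`, `helix`, `position`, `generic` (e.g.
#'   `"2x46"`), `bulge_flag` (TRUE when a pi-bulge annotation lies
#'   between the residue and its anchor, where the full structure-based
#'   scheme could shift the label by one).
#' @export
assign_generic_numbers <- function(s, segments, anchors) {
  rows <- list()
  for (a in seq_len(nrow(anchors))) {
    ch <- anchors$chain[a]
    rn <- anchors$resno[a]
    bb <- backbone_view(s, ch)
    aidx <- match(rn, bb$resno)
    seg <- NULL
    for (sg in segments) {
      if (sg$chain == ch && !is.na(aidx) && aidx >= sg$start &&
          aidx <= sg$end) { seg <- sg; break }
    }
    if (is.null(seg))
      stop("anchor ", anchors$helix[a], "x50 (chain ", ch, ", residue ",
           rn, ") lies outside every helix segment")
    if (!is.na(anchors$expected[a]) && bb$resid[aidx] != anchors$expected[a])
      warning("anchor ", anchors$helix[a], "x50: expected ",
              anchors$expected[a], " but observed ", bb$resid[aidx])
    idx <- seg$start:seg$end
    pos <- 50L + (idx - aidx)
    bulges <- seg$irregularities$idx[seg$irregularities$kind == "pi_bulge"]
    bulge_flag <- vapply(idx, function(i)
      length(bulges) > 0 &&
        any(bulges > min(i, aidx) & bulges < max(i, aidx)), logical(1L))
    rows[[length(rows) + 1L]] <- data.frame(
      chain = ch, resno = bb$resno[idx], insert = bb$insert[idx],
      resid = bb$resid[idx], idx = idx, helix = anchors$helix[a],
      position = pos,
      generic = paste0(anchors$helix[a], "x", pos),
      bulge_flag = bulge_flag, stringsAsFactors = FALSE)
  }
  out <- do.call(rbind, rows)
  if (anyDuplicated(out$generic))
    stop("duplicate generic numbers produced; check anchors/segments")
  rownames(out) <- NULL
  class(out) <- c("hw_numbering", "data.frame")
  out
}

#' Build a numbering table directly
#'
#' Manual constructor for phantoms and fixtures where the helix segments
#' are known by construction.
#'
#' @param chain,resno,generic Equal-length vectors; `generic` like
#'   `"2x46"`.
#' @return A `hw_numbering` data.frame.
#' @export
numbering_from_table <- function(chain, resno, generic) {
  parts <- regmatches(generic, regexec("^([0-9]+)x([0-9]+)$", generic))
  bad <- vapply(parts, length, integer(1L)) != 3L
  if (any(bad)) stop("malformed generic numbers: ",
                     paste(generic[bad], collapse = ", "))
  out <- data.frame(chain = as.character(chain), resno = as.integer(resno),
                    insert = "", resid = NA_character_, idx = NA_integer_,
                    helix = vapply(parts, function(p) as.integer(p[2L]),
                                   integer(1L)),
                    position = vapply(parts, function(p) as.integer(p[3L]),
                                      integer(1L)),
                    generic = generic, bulge_flag = FALSE,
                    stringsAsFactors = FALSE)
  if (anyDuplicated(out$generic)) stop("duplicate generic numbers")
  class(out) <- c("hw_numbering", "data.frame")
  out
}

#' Look up a residue by generic number
#'
#' @param numbering A `hw_numbering` table.
#' @param generic Generic number string, e.g. `"2x46"`.
#' @return The matching row (data.frame), or `NULL` when the position is
#'   absent.  Duplicate matches raise an integrity error.
#' @export
generic_lookup <- function(numbering, generic) {
  hit <- numbering[numbering$generic == generic, , drop = FALSE]
  if (nrow(hit) == 0) return(NULL)
  if (nrow(hit) > 1L) stop("duplicate generic number: ", generic)
  hit
}
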