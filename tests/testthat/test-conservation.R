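write_fasta <- function(seqs, path) {
  writeLines(unlist(lapply(names(seqs), function(n)
    c(paste0(">", n), seqs[[n]]))), path)
}

test_that("alignment reading normalises case and rejects ragged input", {
  f <- withr::local_tempfile(fileext = ".fasta")
  write_fasta(list(s1 = "acd-e", s2 = "ACDFE"), f)
  aln <- read_alignment(f)
  expect_equal(dim(aln), c(2L, 5L))
  expect_equal(unname(aln[1, 1]), "A")
  expect_equal(unname(aln[1, 4]), "-")
  f2 <- withr::local_tempfile(fileext = ".fasta")
  write_fasta(list(s1 = "ACDE", s2 = "ACD"), f2)
  expect_error(read_alignment(f2), "ragged")
})

test_that("column information matches the closed forms", {
  # single residue column
  m1 <- matrix("P", nrow = 6, ncol = 1)
  class(m1) <- c("hw_alignment", class(m1))
  expect_equal(column_information(m1, 1)$information, log2(20),
               tolerance = 1e-6)
  # uniform column over all 20 residues
  m2 <- matrix(c("A", "C", "D", "E", "F", "G", "H", "I", "K", "L", "M",
                 "N", "P", "Q", "R", "S", "T", "V", "W", "Y"), ncol = 1)
  class(m2) <- c("hw_alignment", class(m2))
  expect_equal(column_information(m2, 1)$information, 0, tolerance = 1e-6)
  # 50/50 column
  m3 <- matrix(rep(c("A", "G"), 10), ncol = 1)
  class(m3) <- c("hw_alignment", class(m3))
  expect_equal(column_information(m3, 1)$information, log2(20) - 1,
               tolerance = 1e-6)
  # gaps are excluded; all-gap flagged
  m4 <- matrix(c("P", "-", "-", "-"), ncol = 1)
  class(m4) <- c("hw_alignment", class(m4))
  ci <- column_information(m4, 1)
  expect_equal(ci$information, log2(20), tolerance = 1e-6)
  expect_equal(ci$flag, "high_gap")
  m5 <- matrix(c("-", "-"), ncol = 1)
  class(m5) <- c("hw_alignment", class(m5))
  expect_true(is.na(column_information(m5, 1)$information))
  expect_error(column_information(m1, 5), "out of range")
})

test_that("information content is bounded on random columns", {
  set.seed(6)
  for (i in 1:20) {
    m <- matrix(sample(c("-", "A", "C", "D", "E", "F", "G"), 30,
                       replace = TRUE), ncol = 1)
    class(m) <- c("hw_alignment", class(m))
    ci <- column_information(m, 1)
    if (!is.na(ci$information)) {
      expect_gte(ci$information, -1e-12)
      expect_lte(ci$information, log2(20) + 1e-12)
    }
  }
})

test_that("motif scanning supports wildcards, classes and overlaps", {
  expect_equal(motif_scan("GNSAV", "GNXXV"), 0L)
  expect_equal(motif_scan("CWGP", "CWXP"), 0L)
  expect_equal(motif_scan("AAAAA", "GNXXV"), integer(0))
  expect_equal(motif_scan("GNSAVGNAAV", "GNXXV"), c(0L, 5L))
  expect_equal(motif_scan("SNAAV", "[GS]NXXV"), 0L)
  expect_equal(motif_scan("AAAA", "AAA"), c(0L, 1L))  # overlapping
  expect_error(motif_scan("AAAA", "A?B"), "malformed")
})

test_that("PGDNST profile counts the weakening residue set", {
  m <- rbind(c("S", "L", "P"), c("S", "L", "L"), c("S", "L", "P"),
             c("S", "L", "L"))
  class(m) <- c("hw_alignment", class(m))
  p <- pgdnst_profile(m)
  expect_equal(p$pgdnst_fraction, c(1, 0, 0.5))
})

test_that("weak-spot aggregation is permutation-invariant and counts mechanisms", {
  ws1 <- data.frame(chain = "A", donor_idx = 12L, donor_resno = 112L,
                    donor_resid = "PRO", acceptor_resno = 108L,
                    generic = "5x46", class = "missing",
                    mechanism = "proline", causal = "112")
  ws2 <- ws1; ws2$mechanism <- "sidechain_clamp"; ws2$donor_resid <- "ASN"
  ws3 <- ws1; ws3$generic <- "2x58"
  prof <- aggregate_weak_spots(list(a = ws1, b = ws2, c = ws3))
  r546 <- prof[prof$generic == "5x46", ]
  expect_equal(r546$fraction, 2 / 3)
  expect_equal(r546$mech_proline, 1L)
  expect_equal(r546$mech_sidechain_clamp, 1L)
  prof2 <- aggregate_weak_spots(list(c = ws3, b = ws2, a = ws1))
  expect_equal(prof$fraction, prof2$fraction)
  expect_equal(nrow(aggregate_weak_spots(list())), 0L)
  # spots without generic numbers are excluded with a diagnostic count
  ws4 <- ws1; ws4$generic <- NA_character_
  prof3 <- aggregate_weak_spots(list(a = ws4))
  expect_equal(attr(prof3, "excluded"), 1L)
  expect_equal(nrow(prof3), 0L)
})

test_that("helix-face phase groups positions one turn apart", {
  expect_true(same_helix_face(43, 50))    # 7 residues ~ 2 turns, 700 mod 360 = 340
  expect_true(same_helix_face(43, 54))    # 11 residues, 1100 mod 360 = 20
  expect_false(same_helix_face(43, 45))   # 200 degrees apart
})
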