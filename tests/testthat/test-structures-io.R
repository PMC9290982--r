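test_that("minimal PDB records parse into the structure model", {
  f <- withr::local_tempfile(fileext = ".pdb")
  writeLines(c(
    "ATOM      1  CA  ALA A   1      11.000  12.000  13.000  1.00  0.00           C",
    "END"), f)
  s <- read_structure(f)
  expect_equal(nrow(s$atom), 1L)
  expect_equal(s$atom$chain, "A")
  expect_equal(s$atom$resid, "ALA")
  expect_equal(s$atom$x, 11)
  expect_equal(structure_chains(s), "A")
})

test_that("altloc resolution keeps the highest-occupancy conformer", {
  f <- withr::local_tempfile(fileext = ".pdb")
  writeLines(c(
    "ATOM      1  CA AALA A   1      10.000  10.000  10.000  0.60  0.00           C",
    "ATOM      2  CA BALA A   1      20.000  20.000  20.000  0.40  0.00           C",
    "ATOM      3  N   ALA A   1       9.000   9.000   9.000  1.00  0.00           N",
    "END"), f)
  s <- read_structure(f)
  ca <- s$atom[s$atom$elety == "CA", ]
  expect_equal(nrow(ca), 1L)
  expect_equal(ca$x, 10)  # altloc A (occupancy 0.6) wins
})

test_that("altloc occupancy ties resolve by label order", {
  f <- withr::local_tempfile(fileext = ".pdb")
  writeLines(c(
    "ATOM      1  CA BALA A   1      20.000  20.000  20.000  0.50  0.00           C",
    "ATOM      2  CA AALA A   1      10.000  10.000  10.000  0.50  0.00           C",
    "END"), f)
  s <- read_structure(f)
  expect_equal(s$atom$x, 10)
})

test_that("write/read round-trip preserves names and coordinates to 3 decimals", {
  h <- build_helix("AASLNA", chis = list(`3` = c(-60)))
  f <- withr::local_tempfile(fileext = ".pdb")
  write_structure(h, f)
  s2 <- read_structure(f)
  expect_equal(nrow(s2$atom), nrow(h$atom))
  expect_equal(s2$atom$elety, h$atom$elety)
  expect_equal(s2$atom$resid, h$atom$resid)
  expect_equal(atom_coords(s2), atom_coords(h), tolerance = 1e-3)
  # second round trip is exact
  f2 <- withr::local_tempfile(fileext = ".pdb")
  write_structure(s2, f2)
  s3 <- read_structure(f2)
  expect_identical(atom_coords(s3), atom_coords(s2))
})

test_that("empty and oversized structures are handled at write time", {
  empty <- hw_structure(build_helix("AA")$atom[0, ], id = "empty")
  f <- withr::local_tempfile(fileext = ".pdb")
  write_structure(empty, f)
  expect_identical(readLines(f), "END")
  bad <- build_helix("AA")
  bad$atom$resid <- "ABCD"
  expect_error(write_structure(bad, f), "residue names")
})

test_that("missing element columns are inferred from atom names", {
  f <- withr::local_tempfile(fileext = ".pdb")
  writeLines(c(
    "ATOM      1  N   ALA A   1       0.000   0.000   0.000  1.00  0.00",
    "ATOM      2  CA  ALA A   1       1.458   0.000   0.000  1.00  0.00",
    "END"), f)
  s <- read_structure(f)
  expect_equal(s$atom$elesy, c("N", "C"))
})

test_that("unreadable and empty files give parse errors", {
  expect_error(read_structure(file.path(tempdir(), "nope.pdb")),
               "does not exist")
  f <- withr::local_tempfile(fileext = ".pdb")
  writeLines("END", f)
  expect_error(read_structure(f))
})

test_that("backbone_view flags incomplete residues and accepts glycine", {
  h <- build_helix("AGA")
  bb <- backbone_view(h, "A")
  expect_true(all(bb$complete))           # glycine complete without CB
  h2 <- h
  h2$atom <- h2$atom[!(h2$atom$resno == 2 & h2$atom$elety == "O"), ]
  bb2 <- backbone_view(h2, "A")
  expect_equal(bb2$complete, c(TRUE, FALSE, TRUE))
  expect_equal(length(bb2$resno), 3L)     # still present in numbering
  expect_error(backbone_view(h, "Z"), "unknown chain")
})
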