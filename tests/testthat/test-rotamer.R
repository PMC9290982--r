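test_that("chi angles round-trip through the builder", {
  h <- build_helix("AAAAALAAAAA", chis = list(`6` = c(-60, 175)))
  ca <- chi_angles(h, "A", 6)
  expect_equal(unname(ca$chi), c(-60, 175), tolerance = 0.01)
  # alanine has no chi; missing atoms are flagged
  expect_length(chi_angles(h, "A", 3)$chi, 0L)
  h2 <- h
  h2$atom <- h2$atom[!(h2$atom$resno == 6 & h2$atom$elety == "CD1"), ]
  ca2 <- chi_angles(h2, "A", 6)
  expect_true(is.na(ca2$chi["chi2"]))
  expect_equal(ca2$incomplete, "chi2")
})

test_that("rotamer labels bin chi angles to the nearest staggered well", {
  expect_equal(classify_rotamer(c(-60, 175)), "mt")
  expect_equal(classify_rotamer(c(-119.9, 170)), "mt")
  expect_equal(classify_rotamer(c(65, 70)), "pp")
  expect_equal(classify_rotamer(numeric(0)), "")
})

test_that("side-chain rebuild at stated chi is an exact round-trip", {
  h <- build_helix("AAAAALAAAAA")
  h2 <- rebuild_sidechain(h, "A", 6, c(70, -150))
  expect_equal(unname(chi_angles(h2, "A", 6)$chi), c(70, -150),
               tolerance = 0.01)
  expect_error(rebuild_sidechain(h, "A", 3, c(-60)), "no rebuild topology")
})

test_that("pentamer search recovers plants, respects identity and threshold", {
  db <- build_fragment_db(100, planted = list(
    list(middle = "L", phi = -57, psi = -47, chis = c(-60, 175)),
    list(middle = "L", phi = -57, psi = -47, chis = c(-60, 175)),
    list(middle = "L", phi = -57, psi = -47, chis = c(180, 65))), seed = 7)
  q <- build_helix("AALAA")
  hits <- pentamer_search(q, "A", 3, db, rmsd_threshold = 0.3)
  expect_equal(nrow(hits), 3L)
  expect_true(all(hits$planted))
  expect_false(is.unsorted(hits$rmsd))
  # threshold 0: no fragment is an exact duplicate of the query
  expect_equal(nrow(pentamer_search(q, "A", 3, db, rmsd_threshold = 0)), 0L)
  # absent middle-residue type
  qw <- build_helix("AAWAA")
  expect_equal(nrow(pentamer_search(qw, "A", 3, db)), 0L)
  # query too close to the chain end
  expect_error(pentamer_search(q, "A", 1, db), "two residues on each side")
})

test_that("pentamer search is invariant under rigid transforms of the query", {
  db <- build_fragment_db(30, planted = list(
    list(middle = "L", phi = -57, psi = -47, chis = c(-60, 175))), seed = 2)
  q <- build_helix("AALAA")
  sp <- structure(list(rotation = helixweak:::rotation_matrix(c(2, 1, 0), 81),
                       translation = c(3, -9, 4)),
                  class = "hw_superposition")
  h1 <- pentamer_search(q, "A", 3, db)
  h2 <- pentamer_search(apply_transform(q, sp), "A", 3, db)
  expect_equal(h1$id, h2$id)
  expect_equal(h1$rmsd, h2$rmsd, tolerance = 1e-9)
})

test_that("rotamer distributions count planted conformers", {
  db <- build_fragment_db(50, planted = list(
    list(middle = "L", phi = -57, psi = -47, chis = c(-60, 175)),
    list(middle = "L", phi = -57, psi = -47, chis = c(-60, 175)),
    list(middle = "L", phi = -57, psi = -47, chis = c(180, 65))), seed = 7)
  hits <- pentamer_search(build_helix("AALAA"), "A", 3, db,
                          rmsd_threshold = 0.3)
  dist <- rotamer_distribution(hits)
  expect_equal(sum(dist), 1)
  expect_equal(unname(dist["mt"]), 2 / 3, tolerance = 1e-12)
  expect_equal(unname(dist["tp"]), 1 / 3, tolerance = 1e-12)
  expect_length(rotamer_distribution(hits[0, ]), 0L)
})

test_that("gate assessment reproduces the planted open/closed logic", {
  ph <- build_gate_phantom("closed")
  ga <- gate_assessment(ph$structure, ph$numbering, alt_chis = ph$open_chis)
  expect_equal(ga$verdict_current, "closed")
  expect_equal(ga$verdict_alt, "open")
  expect_null(ga$blocking)
  expect_true(all(ga$triad_present))
})

test_that("occluded alternative rotamers list the planted blockers", {
  ph <- build_gate_phantom("closed", blocked_alt = TRUE)
  ga <- gate_assessment(ph$structure, ph$numbering, alt_chis = ph$open_chis)
  expect_equal(ga$verdict_alt, "unreachable")
  expect_true(all(c("2x50", "7x53") %in% ga$blocking$generic))
  expect_true(all(ga$blocking$highlighted[ga$blocking$generic %in%
                                            c("2x50", "7x53")]))
})

test_that("a missing triad residue degrades to a partial assessment", {
  ph <- build_gate_phantom("closed")
  num <- ph$numbering[ph$numbering$generic != "6x40", ]
  class(num) <- class(ph$numbering)
  ga <- gate_assessment(ph$structure, num, alt_chis = ph$open_chis)
  expect_match(ga$diagnostics, "6x40")
  expect_equal(ga$verdict_current, "closed")
})
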