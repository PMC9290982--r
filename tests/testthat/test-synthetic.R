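test_that("ideal alpha helix has canonical backbone geometry", {
  h <- build_helix(strrep("A", 12))
  ca <- atom_coords(h)[h$atom$elety == "CA", ]
  d <- sqrt(rowSums(diff(ca)^2))
  expect_true(all(abs(d - 3.8) < 0.1))
  # i -> i+4 O...H distances for interior residues
  map <- backbone_hbond_map(h, "A")
  m4 <- map[map$offset == -4, ]
  expect_true(all(m4$r_HO > 1.9 & m4$r_HO < 2.3))
})

test_that("builder output is deterministic and clash-free", {
  h1 <- build_helix("ALSTNWYC", seed = 1)
  h2 <- build_helix("ALSTNWYC", seed = 99)
  expect_identical(atom_coords(h1), atom_coords(h2))  # seed only drives noise
  hn1 <- build_helix("ALSTNWYC", seed = 5, noise_sd = 0.02)
  hn2 <- build_helix("ALSTNWYC", seed = 5, noise_sd = 0.02)
  expect_identical(atom_coords(hn1), atom_coords(hn2))
  xyz <- atom_coords(h1)
  d2 <- as.matrix(dist(xyz))
  diag(d2) <- Inf
  expect_gt(min(d2), 0.8)
})

test_that("proline distortion removes the amide donor", {
  h <- build_helix(strrep("A", 10),
                   distortions = list(list(position = 5, kind = "proline")))
  expect_equal(h$atom$resid[h$atom$resno == 5][1], "PRO")
  hyd <- place_amide_hydrogens(h, "A")
  expect_false(hyd$donor_capable[5])
  expect_equal(hyd$reason[5], "proline")
})

test_that("unknown residue codes are rejected", {
  expect_error(build_helix("AB"), "unknown residue")
})

test_that("tube phantom analytic voxel count matches the cavity module exactly", {
  for (R in c(2.0, 3.0, 4.0)) {
    ph <- build_channel_phantom(R, length = 18)
    g <- label_components(mark_open_voxels(ph$structure, mode = "literal",
                                           bounds = ph$bounds))
    interior <- 0L
    for (cid in sort(unique(stats::na.omit(as.vector(g$component))))) {
      ch <- classify_component(g, cid)
      if (!any(ch$faces[c("xmin", "xmax", "ymin", "ymax")]))
        interior <- interior + ch$n_voxels
    }
    expect_identical(interior, ph$expected_open_voxels)
  }
})

test_that("sub-probe tube has no open lumen", {
  ph <- build_channel_phantom(0.5, length = 12)
  expect_identical(ph$expected_open_voxels, 0L)
  g <- label_components(mark_open_voxels(ph$structure, mode = "literal",
                                         bounds = ph$bounds))
  for (cid in sort(unique(stats::na.omit(as.vector(g$component))))) {
    ch <- classify_component(g, cid)
    expect_true(any(ch$faces[c("xmin", "xmax", "ymin", "ymax")]))
  }
})

test_that("two parallel tubes give exactly two interior channels", {
  ph1 <- build_channel_phantom(3, length = 18, center = c(0, 0))
  ph2 <- build_channel_phantom(3, length = 18, center = c(8, 0))
  s <- hw_structure(rbind(ph1$structure$atom,
                          transform(ph2$structure$atom,
                                    resno = resno + 10000)),
                    id = "two_tubes")
  bounds <- ph1$bounds
  bounds$xlim <- c(-7, 15)
  g <- label_components(mark_open_voxels(s, mode = "literal",
                                         bounds = bounds))
  interior <- 0L
  for (cid in sort(unique(stats::na.omit(as.vector(g$component))))) {
    ch <- classify_component(g, cid)
    if (!any(ch$faces[c("xmin", "xmax", "ymin", "ymax")])) {
      interior <- interior + 1L
      expect_equal(ch$verdict, "channel")
    }
  }
  expect_equal(interior, 2L)
})

test_that("bundle truth table matches construction", {
  b <- build_bundle(seed = 11)
  expect_equal(nrow(b$truth), 6L)
  expect_false("C" %in% b$truth$chain)   # TM3 never weakened
  expect_true(all(b$truth$mechanism %in% c("proline", "sidechain_clamp")))
  b0 <- build_bundle(seed = 11, plants = default_bundle_plants()[0, ])
  expect_equal(nrow(b0$truth), 0L)
  # same seed twice -> identical coordinates
  b2 <- build_bundle(seed = 11)
  expect_identical(atom_coords(b$structure), atom_coords(b2$structure))
  expect_error(build_bundle(radius = 6), "too tight")
})

test_that("planted pi-bulge is recovered by irregularity annotation", {
  h <- build_helix(strrep("A", 22),
                   distortions = list(list(position = 9, kind = "pi_bulge")))
  seg <- detect_helices(h)[[1]]
  seg <- annotate_irregularities(h, seg)
  pis <- seg$irregularities[seg$irregularities$kind == "pi_bulge", ]
  expect_gte(nrow(pis), 1L)
  expect_true(any(pis$idx >= 9 & pis$idx <= 13))
})

test_that("fragment database is deterministic and recovers plants", {
  mk <- function() build_fragment_db(50, planted = list(
    list(middle = "L", phi = -57, psi = -47, chis = c(-60, 175))), seed = 3)
  d1 <- mk(); d2 <- mk()
  expect_identical(lapply(d1$fragments, `[[`, "bb"),
                   lapply(d2$fragments, `[[`, "bb"))
  expect_equal(sum(d1$index$planted), 1L)
  q <- build_helix("AALAA")
  hits <- pentamer_search(q, "A", 3, d1, rmsd_threshold = 0.3)
  expect_equal(nrow(hits), 1L)
  expect_true(all(hits$planted))
  empty <- build_fragment_db(0, seed = 1)
  expect_equal(nrow(pentamer_search(q, "A", 3, empty)), 0L)
})
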