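test_that("amide hydrogens sit 1.0 A from N and skip incapable donors", {
  h <- build_helix("AAPAA")
  hyd <- place_amide_hydrogens(h, "A")
  bb <- backbone_view(h, "A")
  for (i in which(hyd$donor_capable)) {
    d <- sqrt(sum((c(hyd$hx[i], hyd$hy[i], hyd$hz[i]) - bb$N[i, ])^2))
    expect_equal(d, 1.0, tolerance = 1e-9)
  }
  expect_equal(hyd$reason[1], "chain_start")
  expect_equal(hyd$reason[3], "proline")
  expect_false(any(hyd$donor_capable[c(1, 3)]))
})

test_that("hbond energy matches an independent hand evaluation", {
  # evaluate the dipole-dipole expression directly on one geometry
  n <- c(0, 0, 0); hh <- c(0, -1, 0); cc <- c(0.3, -3.9, 0); o <- c(0.1, -2.9, 0)
  expected <- 27.888 * (1 / sqrt(sum((o - n)^2)) + 1 / sqrt(sum((cc - hh)^2)) -
                          1 / sqrt(sum((o - hh)^2)) - 1 / sqrt(sum((cc - n)^2)))
  expect_equal(hbond_energy(n, hh, cc, o), expected, tolerance = 1e-12)
  # ideal helix interior pair lands in the canonical range
  h <- build_helix(strrep("A", 10))
  map <- backbone_hbond_map(h, "A")
  e <- map$energy[map$offset == -4]
  expect_true(all(e > -3.5 & e < -1.5))
  # long-range pair is negligible; proline donor is the sentinel
  far_o <- c(20, 0, 0); far_c <- c(20.7, -1, 0)
  expect_lt(abs(hbond_energy(n, hh, far_c, far_o)), 0.1)
  expect_identical(hbond_energy(n, c(NA, NA, NA), cc, o), Inf)
  expect_error(hbond_energy(n, hh, cc, c(0, -0.9, 0)), "overlapping")
})

test_that("classification is a monotone step function with configurable thresholds", {
  expect_equal(classify_hbond(-2.5), "normal")
  expect_equal(classify_hbond(-0.8), "weak")
  expect_equal(classify_hbond(-0.2), "missing")
  expect_equal(classify_hbond(Inf), "missing")
  e <- seq(-4, 1, by = 0.01)
  cls <- classify_hbond(e)
  ord <- c(normal = 1, weak = 2, missing = 3)
  expect_true(all(diff(ord[cls]) >= 0))
  expect_equal(classify_hbond(-0.8, e_strong = -0.7), "normal")
})

test_that("ideal helix ledger: n-4 normal bonds at offset -4, none missing", {
  for (n in c(6, 10, 17)) {
    h <- build_helix(strrep("A", n))
    map <- backbone_hbond_map(h, "A")
    m4 <- map[map$offset == -4, ]
    expect_equal(nrow(m4), n - 4)
    expect_true(all(m4$class == "normal"))
    best <- map[map$best & map$donor_idx >= 5, ]
    expect_equal(sum(best$class == "missing"), 0L)
  }
  # best partner is the -4 acceptor for interior donors
  h <- build_helix(strrep("A", 10))
  map <- backbone_hbond_map(h, "A")
  best <- map[map$best & map$donor_idx >= 5, ]
  expect_true(all(best$offset == -4))
})

test_that("planted pi register shifts the best partner to -5", {
  h <- build_helix(strrep("A", 20),
                   distortions = list(list(position = 9, kind = "pi_bulge")))
  map <- backbone_hbond_map(h, "A")
  expect_gte(sum(map$best & map$offset == -5), 1)
})

test_that("five-residue helix evaluates a single donor", {
  h <- build_helix(strrep("A", 5))
  map <- backbone_hbond_map(h, "A")
  m4 <- map[map$offset == -4, ]
  expect_equal(nrow(m4), 1L)
  expect_equal(m4$donor_idx, 5L)
})

test_that("energy is invariant under rigid-body transforms", {
  h <- build_helix(strrep("A", 10))
  map1 <- backbone_hbond_map(h, "A")
  sp <- list(rotation = helixweak:::rotation_matrix(c(1, 1, 0), 73),
             translation = c(5, -3, 11))
  class(sp) <- "hw_superposition"
  h2 <- apply_transform(h, sp)
  map2 <- backbone_hbond_map(h2, "A")
  expect_true(all(abs(map1$energy - map2$energy) < 1e-9))
})

test_that("side-chain to backbone hydrogen bonds follow the distance rule", {
  # planted clamp: Asn amide within 3.5 A of the i-4 carbonyl
  h <- build_helix(strrep("A", 17),
                   distortions = list(list(position = 10,
                                           kind = "sidechain_clamp")))
  scb <- sidechain_backbone_hbonds(h, "A")
  hit <- scb[scb$resno == 10 & scb$partner_resno == 6 &
               scb$partner_atom == "O", ]
  expect_gte(nrow(hit), 1L)
  expect_true(all(hit$distance <= 3.5))
  # alanine-only helix has no polar side chains
  expect_equal(nrow(sidechain_backbone_hbonds(build_helix(strrep("A", 12)),
                                              "A")), 0L)
  # cysteine SG records are flagged weak donors
  hc <- build_helix("AAAAACAAAAA", chis = list(`6` = c(-90)))
  scb2 <- sidechain_backbone_hbonds(hc, "A", cutoff = 4.0)
  if (nrow(scb2) > 0) expect_true(all(scb2$weak_donor[scb2$atom == "SG"]))
})

test_that("a single interior proline flips exactly one bond to missing", {
  n <- 20; k <- 10
  clean <- backbone_hbond_map(build_helix(strrep("A", n)), "A")
  h <- build_helix(strrep("A", n),
                   distortions = list(list(position = k, kind = "proline")))
  map <- backbone_hbond_map(h, "A")
  m4 <- map[map$offset == -4, ]
  expect_equal(m4$donor_idx[m4$class == "missing"], k)
  # donors outside k-2..k+2 unchanged
  ref <- clean[clean$offset == -4, ]
  far <- abs(m4$donor_idx - k) > 2
  expect_equal(m4$energy[far],
               ref$energy[match(m4$donor_idx[far], ref$donor_idx)],
               tolerance = 1e-9)
})
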