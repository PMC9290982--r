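test_that("marking around a single atom follows the vdw + probe rule", {
  atom <- data.frame(chain = "X", resno = 1L, insert = "", resid = "UNK",
                     elety = "C", elesy = "C", het = TRUE,
                     x = 0, y = 0, z = 0)
  s <- hw_structure(atom)
  g <- mark_open_voxels(s, mode = "vdw", pad = 5)
  cells <- which(g$open)
  idx <- arrayInd(cells, g$dim)
  xyz <- sweep((idx - 1) * g$spacing, 2, g$origin, `+`)
  d <- sqrt(rowSums(xyz^2))
  expect_true(all(d > 3.1))  # 1.70 vdw + 1.40 probe
  closed <- which(!g$open)
  idxc <- arrayInd(closed, g$dim)
  xyzc <- sweep((idxc - 1) * g$spacing, 2, g$origin, `+`)
  expect_true(all(sqrt(rowSums(xyzc^2)) <= 3.1))
  expect_error(mark_open_voxels(s, spacing = 0), "spacing")
})

test_that("stamped marking equals the brute-force oracle on random clouds", {
  for (sd in 1:12) {
    s <- random_cloud(50, seed = sd)
    for (mode in c("literal", "vdw")) {
      g <- mark_open_voxels(s, mode = mode, pad = 2.5)
      expect_identical(g$open, brute_force_open(s, g))
    }
  }
})

test_that("open voxels shrink monotonically with the probe radius", {
  s <- random_cloud(40, seed = 99)
  g1 <- mark_open_voxels(s, probe = 1.0, pad = 4)
  g2 <- mark_open_voxels(s, probe = 1.8, pad = 4)
  expect_true(all(which(g2$open) %in% which(g1$open)))
})

test_that("component labels partition the open set and volumes add up", {
  ph <- build_channel_phantom(3, length = 16)
  g <- label_components(mark_open_voxels(ph$structure, mode = "literal",
                                         bounds = ph$bounds))
  comp <- g$component
  expect_identical(!is.na(comp), g$open)
  ids <- sort(unique(stats::na.omit(as.vector(comp))))
  vols <- vapply(ids, function(i) classify_component(g, i)$volume,
                 numeric(1))
  expect_equal(sum(vols), sum(g$open) * g$spacing^3)
})

test_that("connectivity semantics: 6 vs 26 on a 3-d checkerboard", {
  dims <- c(4L, 4L, 4L)
  idx <- as.matrix(expand.grid(1:4, 1:4, 1:4))
  open <- array(rowSums(idx) %% 2 == 0, dims)
  l6 <- helixweak:::flood_components(open, 6L)
  l26 <- helixweak:::flood_components(open, 26L)
  expect_equal(length(unique(stats::na.omit(as.vector(l6)))), sum(open))
  expect_equal(length(unique(stats::na.omit(as.vector(l26)))), 1L)
})

test_that("hollow sphere is an enclosed cavity of the analytic volume", {
  sp <- build_hollow_sphere(8)
  g <- label_components(mark_open_voxels(sp$structure, mode = "literal"))
  # the interior is the second-largest component (outside space is first)
  ch <- classify_component(g, 2)
  expect_equal(ch$verdict, "enclosed_cavity")
  expect_lt(abs(ch$volume - sp$expected_volume) / sp$expected_volume, 0.1)
})

test_that("tube pore radius is within one grid spacing of the channel radius", {
  for (R in c(2.0, 3.0, 4.0)) {
    ph <- build_channel_phantom(R, length = 18)
    g <- label_components(mark_open_voxels(ph$structure, mode = "literal",
                                           bounds = ph$bounds))
    for (cid in sort(unique(stats::na.omit(as.vector(g$component))))) {
      ch <- classify_component(g, cid)
      if (!any(ch$faces[c("xmin", "xmax", "ymin", "ymax")])) {
        expect_equal(ch$verdict, "channel")
        expect_lte(abs(ch$min_pore_radius - R), ph$spacing)
      }
    }
  }
})

test_that("escape verdict flips with the planted gate rotamer", {
  closed <- build_gate_phantom("closed")
  open <- build_gate_phantom("open")
  rc <- escape_channel_test(closed$structure, closed$numbering, "2x46")
  ro <- escape_channel_test(open$structure, open$numbering, "2x46")
  expect_equal(rc$verdict, "closed")
  expect_equal(ro$verdict, "open")
  expect_gte(ro$min_pore_radius, 1.02)
})

test_that("escape verdict is monotone non-increasing in ion radius", {
  open <- build_gate_phantom("open")
  radii <- c(0.6, 1.02, 1.4, 2.5, 4)
  verdicts <- vapply(radii, function(ir)
    escape_channel_test(open$structure, open$numbering, "2x46",
                        ion_radius = ir)$verdict, character(1))
  v <- verdicts == "open"
  expect_true(all(diff(as.integer(v)) <= 0))
  expect_equal(verdicts[length(verdicts)], "closed")
})
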