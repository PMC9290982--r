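test_that("helix detection finds helices and rejects strands", {
  h <- build_helix(strrep("A", 20))
  segs <- detect_helices(h)
  expect_length(segs, 1L)
  expect_equal(c(segs[[1]]$start, segs[[1]]$end), c(1L, 20L))
  beta <- build_helix(strrep("A", 12), phi = -135, psi = 135)
  expect_length(detect_helices(beta), 0L)
})

test_that("two helices joined by an extended linker give two segments", {
  n1 <- 14; nl <- 5; n2 <- 14
  phi <- c(rep(-57, n1), rep(-135, nl), rep(-57, n2))
  psi <- c(rep(-47, n1), rep(135, nl), rep(-47, n2))
  h <- build_helix(strrep("A", n1 + nl + n2), phi = phi, psi = psi)
  segs <- detect_helices(h)
  expect_length(segs, 2L)
})

test_that("irregularity annotation recovers planted registers and kinks", {
  h3 <- build_helix(strrep("A", 22),
                    distortions = list(list(position = 9, kind = "three10")))
  seg <- annotate_irregularities(h3, detect_helices(h3)[[1]])
  expect_true("three10" %in% seg$irregularities$kind)
  hk <- build_helix(strrep("A", 25),
                    distortions = list(list(position = 13, kind = "kink",
                                            angle = 25)))
  segk <- annotate_irregularities(hk, detect_helices(hk)[[1]])
  kk <- segk$irregularities[segk$irregularities$kind == "kink", ]
  expect_gte(nrow(kk), 1L)
  expect_true(any(abs(kk$idx - 13) <= 2))
  ideal <- build_helix(strrep("A", 25))
  segi <- annotate_irregularities(ideal, detect_helices(ideal)[[1]])
  expect_equal(nrow(segi$irregularities), 0L)
  # short segments skip kink detection with a flag
  short <- build_helix(strrep("A", 8))
  segs <- detect_helices(short)
  expect_true(attr(annotate_irregularities(short, segs[[1]]),
                   "kink_skipped"))
})

test_that("weak-spot mechanisms are attributed in priority order", {
  hp <- build_helix(strrep("A", 20),
                    distortions = list(list(position = 10, kind = "proline")))
  wsp <- weakspot_table(hp)
  expect_equal(nrow(wsp), 1L)
  expect_equal(wsp$donor_resno, 10L)
  expect_equal(wsp$acceptor_resno, 6L)
  expect_equal(wsp$class, "missing")
  expect_equal(wsp$mechanism, "proline")
  hc <- build_helix(strrep("A", 20),
                    distortions = list(list(position = 10,
                                            kind = "sidechain_clamp")))
  wsc <- weakspot_table(hc)
  expect_equal(nrow(wsc), 1L)
  expect_equal(wsc$donor_resno, 10L)   # same weakened position
  expect_equal(wsc$mechanism, "sidechain_clamp")
  # glycine near a weakened donor without a clamp
  hg <- rotate_carbonyl(build_helix("AAAAAAAAAGAAAAAAAAAA"), "A", 6,
                        angle = 50)
  wsg <- weakspot_table(hg)
  expect_equal(wsg$mechanism, "glycine_flex")
  # no mechanism in range -> unexplained
  hu <- rotate_carbonyl(build_helix(strrep("A", 20)), "A", 6, angle = 50)
  wsu <- weakspot_table(hu)
  expect_equal(wsu$mechanism, "unexplained")
  expect_equal(nrow(weakspot_table(build_helix(strrep("A", 20)))), 0L)
})

test_that("weak-spot tables are idempotent, sorted and per-chain identical", {
  b <- build_bundle(seed = 21)
  ws1 <- weakspot_table(b$structure)
  ws2 <- weakspot_table(b$structure)
  expect_identical(ws1, ws2)
  expect_false(is.unsorted(ws1$chain))
  # two identical chains give identical per-chain rows
  h <- build_helix(strrep("A", 20),
                   distortions = list(list(position = 10, kind = "proline")))
  h2 <- build_helix(strrep("A", 20),
                    distortions = list(list(position = 10, kind = "proline")),
                    chain = "B")
  both <- hw_structure(rbind(h$atom, h2$atom), id = "twochain")
  wsb <- weakspot_table(both)
  expect_equal(nrow(wsb), 2L)
  cols <- setdiff(names(wsb), "chain")
  expect_equal(wsb[wsb$chain == "A", cols], wsb[wsb$chain == "B", cols],
               ignore_attr = TRUE)
  # empty structure -> empty report
  expect_equal(nrow(weakspot_table(hw_structure(h$atom[0, ]))), 0L)
})

test_that("bundle weak spots match the planted truth table", {
  b <- build_bundle(seed = 8)
  segs <- detect_helices(b$structure)
  num <- assign_generic_numbers(b$structure, segs, b$anchors)
  ws <- weakspot_table(b$structure, numbering = num, segments = segs)
  expect_setequal(ws$generic, b$truth$generic)
  m <- merge(ws, b$truth, by = "generic")
  expect_equal(m$mechanism.x, m$mechanism.y)
})
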