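# Lattice geometry derivation and topology construction.

test_that("derived cylinder geometry reproduces the canonical diagonal rest lengths", {
  p <- mt_params()
  # printed values for the standard 13_3 lattice
  expect_equal(p$r0_diag_short, 5.9988, tolerance = 1e-3 / 5.9988)
  expect_equal(p$r0_diag_long, 7.1242, tolerance = 1e-3 / 7.1242)
  expect_lt(abs(p$r0_diag_short - 5.9988), 1e-3)
  expect_lt(abs(p$r0_diag_long - 7.1242), 1e-3)
  # lateral chord evaluated independently: 2 * (67.6 / 2 pi) * sin(pi / 13)
  expect_equal(p$lat_chord, 2 * (13 * 5.2 / (2 * pi)) * sin(pi / 13),
               tolerance = 1e-12)
  expect_lt(p$r0_diag_short, p$r0_diag_long)
})

test_that("unstaggered lattice collapses the two diagonals to one length", {
  p <- mt_params(pitch_monomers = 0)
  expect_equal(p$r0_diag_short, p$r0_diag_long)
  expect_equal(p$r0_diag_short, sqrt(p$lat_chord^2 + p$r0_long^2))
})

test_that("geometry derivation is homogeneous of degree one in the rest lengths", {
  p1 <- mt_params()
  p2 <- mt_params(r0_long = 2 * p1$r0_long, r0_lat = 2 * p1$r0_lat)
  expect_equal(p2$r0_diag_short, 2 * p1$r0_diag_short, tolerance = 1e-12)
  expect_equal(p2$r0_diag_long, 2 * p1$r0_diag_long, tolerance = 1e-12)
})

test_that("geometry derivation rejects degenerate inputs", {
  expect_error(mt_params(n_protofilaments = 2), "protofilaments")
  expect_error(mt_params(r0_long = -1), "positive")
  expect_error(mt_params(theta0_long_GDP = 3, theta0_long_GTP = 5),
               "curvature")
})

test_that("planar fixture topology matches hand enumeration", {
  fx <- make_fixture("planar_3x4")
  tp <- fx$lattice$topology
  # 3 protofilaments x 4 monomers: 3*3 longitudinal bonds, 2*4 lateral,
  # 6 cells with 2 diagonals each, 3*2 longitudinal triples, 4 lateral
  cnt <- table(tp$pairs$class)
  expect_equal(unname(cnt["long"]), 9L)
  expect_equal(unname(cnt["lat"]), 8L)
  expect_equal(unname(cnt["diag_short"]) + unname(cnt["diag_long"]), 12L)
  expect_equal(sum(tp$triples$class == "long"), 6L)
  expect_equal(sum(tp$triples$class == "lat"), 4L)
  # no duplicated terms, all indices valid
  expect_false(any(duplicated(tp$pairs[, c("i", "j")])))
  expect_true(all(unlist(tp$pairs[, c("i", "j")]) %in%
                    seq_len(nrow(fx$lattice$monomers))))
})

test_that("blunt tube topology has full seam closure and canonical coordination", {
  fx <- make_fixture("tube_13xN", N = 6)
  lat <- fx$lattice
  expect_equal(nrow(lat$monomers), 13 * 6)
  tp <- lat$topology
  m <- lat$monomers
  # one full interior turn carries 13 lateral bonds (12 wall + 1 seam)
  lev <- 1L
  in_turn <- (m$axial[tp$pairs$i] == lev & tp$pairs$class == "lat")
  expect_equal(sum(in_turn), 13L)
  # an interior monomer: 2 longitudinal, 2 lateral, 4 diagonal stretch terms
  i <- which(m$pf == 5 & m$axial == 3)
  deg <- function(cl) sum((tp$pairs$i == i | tp$pairs$j == i) &
                            tp$pairs$class %in% cl)
  expect_equal(deg("long"), 2L)
  expect_equal(deg("lat"), 2L)
  expect_equal(deg(c("diag_short", "diag_long")), 4L)
})

test_that("blunt tube placement is self-consistent: straight protofilaments carry no bend when the equilibrium angle matches", {
  p <- mt_params(theta0_long_GTP = 0)
  built <- build_lattice(p, n_closed_turns = 3, sheet_length_monomers = 0,
                         scenario = "all_GTP")
  e <- total_energy(built$lattice, built$conf, p)
  expect_equal(e$e_long_bend, 0, tolerance = 1e-12)
  expect_equal(e$e_long_stretch, 0, tolerance = 1e-12)
  expect_equal(e$e_diag_stretch, 0, tolerance = 1e-10)
  expect_equal(e$e_long_dihedral, 0, tolerance = 1e-12)
})

test_that("standard scenario assigns GTP to the sheet and GDP to the body", {
  p <- mt_params()
  built <- build_lattice(p, n_closed_turns = 10, sheet_length_monomers = 7)
  m <- built$lattice$monomers
  # top two monomers of every protofilament lie in the open sheet
  top <- m$axial >= max(m$axial) - 1
  expect_true(all(m$nucleotide[top] == "GTP"))
  # the bottom of the body is hydrolyzed on every protofilament
  expect_true(all(m$nucleotide[m$axial <= 1] == "GDP"))
  # dimer-level consistency: both monomers of a dimer share the state
  key <- paste(m$pf, m$axial %/% 2)
  expect_true(all(tapply(m$nucleotide, key,
                         function(v) length(unique(v)) == 1)))
})

test_that("cross-seam terms exist only for zipped pairs", {
  p <- mt_params()
  built <- build_lattice(p, n_closed_turns = 8, sheet_length_monomers = 5)
  lat <- built$lattice
  tp <- lat$topology
  m <- lat$monomers
  seam_rows <- m$pf[tp$pairs$i] == 12 & m$pf[tp$pairs$j] == 0 &
    tp$pairs$class == "lat"
  zipped_j <- sort(m$axial[tp$pairs$i[seam_rows]])
  expect_equal(zipped_j, 0:7)          # exactly the built pairs
  expect_equal(mtzip:::next_seam_pair(lat), 8L)
  expect_equal(mtzip:::sheet_length(lat), 5L)
})
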