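# Assembly thermodynamics, seam closure and hydrolysis rules.

test_that("association free energies follow the bond accounting", {
  p <- mt_params()
  expect_equal(association_energy("gap", p), 2 * (-4) + (-19) + 11)    # -16
  expect_equal(association_energy("side", p), (-4) + (-19) + 11)       # -12
  expect_equal(association_energy("crest", p), (-19) + 11)             # -8
  expect_error(association_energy("roof", p))
})

test_that("candidate evaluation classifies sites, rolls back, and a crest addition is nearly strain-free", {
  # full-precision minima: the strain estimate compares two equilibrium
  # energies, so both must be converged well below a kBT
  p <- mt_params(max_steps = 60000L)
  st <- standard_sheet_state(p, n_closed_turns = 5, sheet_length = 4)
  lat0 <- st$lattice
  conf0 <- st$conf
  sites <- candidate_assembly_energies(lat0, conf0, p, E0 = st$E0,
                                       pfs = c(0L, 6L))
  expect_true(all(sites$valid))
  # equal-length tips: no lateral neighbors above any tip, so every site
  # is a crest with dG = -8
  expect_true(all(sites$site_class == "crest"))
  expect_equal(sites$dG_assoc, c(-8, -8))
  # an unconstrained tip extension at rest geometry adds little strain
  expect_true(all(sites$strain > -1 & sites$strain < 5))
  expect_true(all(sites$dE_total < 0))
  # rollback contract: the inputs are untouched
  expect_identical(lat0$monomers, st$lattice$monomers)
  expect_identical(lat0$topology, st$lattice$topology)
  expect_identical(conf0$pos, st$conf$pos)
})

test_that("assembly site selection follows the Boltzmann policy", {
  p <- mt_params()
  fake_sites <- function(dE) {
    df <- data.frame(pf = seq_along(dE) - 1L, site_class = "crest",
                     dG_assoc = -8, strain = dE + 8, dE_total = dE,
                     valid = TRUE)
    attr(df, "candidates") <-
      replicate(length(dE), list(lattice = "L", conf = "C", E = 0),
                simplify = FALSE)
    df
  }
  # all positive: nothing happens
  set.seed(31)
  out <- attempt_assembly(fake_sites(c(2, 5, 0.1)), p)
  expect_null(out$site)
  # a single negative site is chosen with probability one
  out <- attempt_assembly(fake_sites(c(2, -3, 1)), p)
  expect_equal(out$site$pf, 1L)
  expect_equal(out$prob, 1)
  # two equally favorable sites split draws evenly (binomial 3 sigma)
  set.seed(32)
  picks <- replicate(10000,
                     attempt_assembly(fake_sites(c(-5, -5)), p)$site$pf)
  ph <- mean(picks == 0)
  expect_lt(abs(ph - 0.5), 3 * sqrt(0.25 / 10000))
})

test_that("hydrolysis rules behave and are irreversible", {
  p <- mt_params()
  # random rule with threshold 1 never fires
  built <- build_lattice(p, n_closed_turns = 4, sheet_length_monomers = 7,
                         scenario = "all_GTP")
  set.seed(33)
  h <- apply_hydrolysis(built$lattice, p, "random", threshold = 1)
  expect_equal(h$n_hydrolyzed, 0L)
  # threshold 0.5 hydrolyzes about half of 10^4 sheet dimers
  long <- data.frame(pf = rep(0:12, each = 1540),
                     axial = rep(0:1539, times = 13))
  long$kind <- ifelse(long$axial %% 2 == 0, "alpha", "beta")
  long$nucleotide <- "GTP"
  big <- mtzip:::new_lattice(long, data.frame(pair = integer(),
                                              diagonals = logical()),
                             0L, 13, 3)
  n_dimers <- sum(big$monomers$kind == "beta")
  expect_gte(n_dimers, 10000)
  set.seed(34)
  h2 <- apply_hydrolysis(big, p, "random", threshold = 0.5)
  frac <- h2$n_hydrolyzed / n_dimers
  expect_lt(abs(frac - 0.5), 3 * sqrt(0.25 / n_dimers))
  expect_equal(h2$draws, n_dimers)
  # irreversibility: a second application never restores GTP
  h3 <- apply_hydrolysis(h2$lattice, p, "random", threshold = 0.5)
  before <- h2$lattice$monomers$nucleotide == "GDP"
  after <- h3$lattice$monomers$nucleotide == "GDP"
  expect_true(all(after[before]))
  # ordered cap: only the top k dimer layers stay GTP
  h4 <- apply_hydrolysis(built$lattice, p, "ordered_cap", k_layers = 2)
  m4 <- h4$lattice$monomers
  top <- m4$axial %/% 2 > max(m4$axial %/% 2) - 2
  expect_true(all(m4$nucleotide[top] == "GTP"))
  expect_true(all(m4$nucleotide[!top] == "GDP"))
})

test_that("synchronous hydrolysis tracks the advancing closure surface", {
  p <- fast_params()
  st <- standard_sheet_state(p, n_closed_turns = 6, sheet_length = 5)
  gdp0 <- sum(st$lattice$monomers$nucleotide == "GDP")
  cl <- close_monomer_pair(st$lattice, st$conf, p, E_before = st$E0)
  gdp1 <- sum(cl$lattice$monomers$nucleotide == "GDP")
  # one helical turn's worth of monomers (13, up to dimer granularity)
  expect_gte(gdp1 - gdp0, 10)
  expect_lte(gdp1 - gdp0, 16)
  expect_equal(cl$n_hydrolyzed, (gdp1 - gdp0) / 2)
})

test_that("closure bookkeeping: one pair, five lateral terms, then error when blunt", {
  p <- fast_params()
  st <- standard_sheet_state(p, n_closed_turns = 5, sheet_length = 2)
  lat <- st$lattice
  tp0 <- lat$topology
  cl <- close_monomer_pair(lat, st$conf, p, E_before = st$E0)
  expect_equal(nrow(cl$lattice$seam), nrow(lat$seam) + 1L)
  expect_equal(cl$pair, mtzip:::next_seam_pair(lat))
  tp1 <- cl$lattice$topology
  # + 1 lateral stretch, + 2 lateral bend triples, + 2 lateral dihedrals
  expect_equal(nrow(tp1$pairs), nrow(tp0$pairs) + 1L)
  expect_equal(nrow(tp1$triples), nrow(tp0$triples) + 2L)
  expect_equal(nrow(tp1$dihedrals), nrow(tp0$dihedrals) + 2L)
  expect_gte(cl$barrier_kBT, 0)
  # zip the last pair, then the seam is blunt
  cl2 <- close_monomer_pair(cl$lattice, cl$conf, p,
                            E_before = cl$trace$e_final)
  expect_error(close_monomer_pair(cl2$lattice, cl2$conf, p),
               "blunt|zipped")
})

test_that("event logs are deterministic under a fixed seed", {
  p <- fast_params()
  st <- standard_sheet_state(p, n_closed_turns = 5, sheet_length = 4)
  run <- function() {
    set.seed(99)
    run_tetris(p, n_layers = 1, state = st, force_accept = TRUE,
               max_steps = 20000L)$events
  }
  e1 <- run()
  e2 <- run()
  expect_identical(e1, e2)
})
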