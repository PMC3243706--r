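# Potentials, angles, total energy and forces.

test_that("harmonic energy follows the quadratic form", {
  expect_equal(harmonic_energy(3.0, 0), 0)
  expect_equal(harmonic_energy(3.0, 0.1), 0.015)
  # bending constant 2.0 nN*nm at a 13 degree deviation
  expect_equal(harmonic_energy(2.0, 13 * pi / 180), 0.0514803,
               tolerance = 1e-5)
  expect_error(harmonic_energy(-1, 0.1))
})

test_that("bend angle is the supplement of the interior angle", {
  expect_equal(bend_angle(c(0, 0, 0), c(1, 0, 0), c(2, 0, 0)), 0)
  expect_equal(bend_angle(c(0, 0, 0), c(1, 0, 0), c(1, 1, 0)), pi / 2)
  expect_error(bend_angle(c(0, 0, 0), c(0, 0, 0), c(1, 0, 0)),
               "degenerate")
  # a chain kinked at exactly the GDP equilibrium angle has zero deviation
  th <- 18 * pi / 180
  A <- c(0, 0, 0); B <- c(0, 0, 4)
  C <- B + 4 * c(sin(th), 0, cos(th))
  expect_equal(bend_angle(A, B, C), th, tolerance = 1e-12)
})

test_that("rigid helical twist registers as the longitudinal dihedral angle", {
  R <- 10.76; r0 <- 4
  for (d in c(0.02, 0.05)) {
    A <- c(R, 0, 0)
    B <- c(R * cos(d), R * sin(d), r0)
    C <- c(R * cos(2 * d), R * sin(2 * d), 2 * r0)
    expect_equal(dihedral_angle(A, B, C, "long"), d, tolerance = 0.02)
    # mirror reflection negates the angle; the quadratic energy is unchanged
    expect_equal(dihedral_angle(A * c(1, -1, 1), B * c(1, -1, 1),
                                C * c(1, -1, 1), "long"),
                 -dihedral_angle(A, B, C, "long"), tolerance = 1e-12)
  }
  expect_error(dihedral_angle(c(1, 0, 0), c(2, 0, 0), c(3, 0, 0), "long"),
               "collinear|degenerate")
})

test_that("untwisted blunt tube has zero longitudinal dihedral energy", {
  fx <- make_fixture("tube_13xN", N = 6)
  e <- total_energy(fx$lattice, fx$conf, fx$params)
  expect_equal(e$e_long_dihedral, 0, tolerance = 1e-12)
})

test_that("energy breakdown matches the brute-force oracle", {
  set.seed(11)
  for (kind in c("planar_3x4", "tube_13xN")) {
    fx <- make_fixture(kind, N = 6)
    conf <- jitter_conf(fx$conf, sd = 0.05)
    e <- total_energy(fx$lattice, conf, fx$params)
    o <- oracle_energy(fx$lattice, conf, fx$params)
    for (nm in names(o))
      expect_equal(e[[nm]], o[[nm]], tolerance = 1e-10,
                   label = paste(kind, nm))
    # components sum to the total
    expect_equal(e$e_total,
                 sum(unlist(e[setdiff(names(o), "e_total")])),
                 tolerance = 1e-12)
  }
})

test_that("single isolated dimer at rest separation has zero energy", {
  p <- mt_params()
  monomers <- data.frame(pf = 0L, axial = 0:1,
                         kind = c("alpha", "beta"), nucleotide = "GTP")
  lat <- mtzip:::new_lattice(monomers,
                             data.frame(pair = integer(),
                                        diagonals = logical()),
                             0L, 13, 3)
  conf <- new_conformation(rbind(c(10, 0, 0), c(10, 0, 4)), p$monomer_mass)
  expect_equal(total_energy(lat, conf, p)$e_total, 0)
})

test_that("forces equal finite-difference gradients and obey Newton's third law", {
  set.seed(12)
  fx <- make_fixture("tube_13xN", N = 6)
  conf <- jitter_conf(fx$conf, sd = 0.04)
  f <- forces(fx$lattice, conf, fx$params)
  rows <- sample(nrow(conf$pos), 12)
  fd <- fd_forces(fx$lattice, conf, fx$params, rows)
  scale <- max(abs(f))
  expect_lt(max(abs(f[rows, ] - fd[rows, ])) / scale, 1e-6)
  # net force vanishes
  expect_lt(max(abs(colSums(f))), 1e-10 * max(1, scale))
  # net torque about the tube axis vanishes (the radial dihedral reference
  # singles out that axis; rotation about it is an exact symmetry)
  tq_z <- sum(conf$pos[, 1] * f[, 2] - conf$pos[, 2] * f[, 1])
  expect_lt(abs(tq_z), 1e-8 * max(1, scale))
})

test_that("energies are invariant under translation and rotation about the tube axis", {
  set.seed(13)
  fx <- make_fixture("tube_13xN", N = 6)
  conf <- jitter_conf(fx$conf, sd = 0.04)
  e0 <- unlist(total_energy(fx$lattice, conf, fx$params)[1:8])
  th <- 0.71
  Rz <- matrix(c(cos(th), sin(th), 0, -sin(th), cos(th), 0, 0, 0, 1), 3, 3)
  conf2 <- conf
  conf2$pos <- conf$pos %*% t(Rz) +
    matrix(c(5.3, -2.1, 7.7), nrow(conf$pos), 3, byrow = TRUE)
  e1 <- unlist(total_energy(fx$lattice, conf2, fx$params)[1:8])
  expect_equal(e1, e0, tolerance = 1e-9)
})

test_that("energy is additive over topology terms", {
  set.seed(14)
  fx <- make_fixture("planar_3x4")
  conf <- jitter_conf(fx$conf, sd = 0.05)
  full <- total_energy(fx$lattice, conf, fx$params)$e_total
  # drop one stretch term and recompute
  lat2 <- fx$lattice
  dropped <- lat2$topology$pairs[5, ]
  lat2$topology$pairs <- lat2$topology$pairs[-5, ]
  reduced <- total_energy(lat2, conf, fx$params)$e_total
  d <- sqrt(sum((conf$pos[dropped$i, ] - conf$pos[dropped$j, ])^2))
  k <- switch(dropped$class, long = fx$params$k_long_stretch,
              lat = fx$params$k_lat_stretch, fx$params$k_diag_stretch)
  r0 <- switch(dropped$class, long = fx$params$r0_long,
               lat = fx$params$r0_lat, fx$params$r0_diag_short)
  expect_equal(full - reduced, 0.5 * k * (d - r0)^2, tolerance = 1e-10)
})

test_that("a nucleotide flip changes only the longitudinal bend energy, locally", {
  fx <- make_fixture("tube_13xN", N = 6)
  set.seed(15)
  conf <- jitter_conf(fx$conf, sd = 0.03)
  p <- fx$params
  e0 <- total_energy(fx$lattice, conf, p)
  lat2 <- fx$lattice
  m <- lat2$monomers
  # flip one GTP dimer on protofilament 4
  gtp_beta <- which(m$pf == 4 & m$kind == "beta" & m$nucleotide == "GTP")
  d <- m$axial[gtp_beta[1]] %/% 2
  hit <- m$pf == 4 & m$axial %/% 2 == d
  lat2$monomers$nucleotide[hit] <- "GDP"
  e1 <- total_energy(lat2, conf, p)
  for (nm in c("e_long_stretch", "e_lat_stretch", "e_diag_stretch",
               "e_lat_bend", "e_long_dihedral", "e_lat_dihedral"))
    expect_equal(e1[[nm]], e0[[nm]], tolerance = 1e-12, label = nm)
  expect_gt(abs(e1$e_long_bend - e0$e_long_bend), 0)
})

test_that("per-monomer attribution splits each term equally and sums to the total", {
  set.seed(16)
  fx <- make_fixture("planar_3x4")
  conf <- jitter_conf(fx$conf, sd = 0.05)
  e <- total_energy(fx$lattice, conf, fx$params, per_monomer = TRUE)
  expect_equal(sum(e$per_monomer), e$e_total, tolerance = 1e-10)
  expect_true(all(e$per_monomer >= -1e-12))
})
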