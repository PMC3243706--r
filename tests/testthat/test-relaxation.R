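# Verlet integration, thermostat and convergence behavior.

test_that("zero forces and zero velocities are a fixed point", {
  fx <- make_fixture("planar_3x4")
  out <- verlet_step(fx$lattice, fx$conf, fx$params, n_steps = 5,
                     rescale = FALSE)
  expect_equal(out$conf$pos, fx$conf$pos, tolerance = 1e-12)
  expect_equal(out$conf$vel, fx$conf$vel, tolerance = 1e-12)
})

test_that("a single spring follows the analytic harmonic oscillation", {
  p <- mt_params(dt = 0.02)
  monomers <- data.frame(pf = 0L, axial = 0:1,
                         kind = c("alpha", "beta"), nucleotide = "GTP")
  lat <- mtzip:::new_lattice(monomers,
                             data.frame(pair = integer(),
                                        diagonals = logical()),
                             0L, 13, 3)
  x0 <- 0.2   # initial bond extension, nm
  conf <- new_conformation(rbind(c(10, 0, 0), c(10, 0, 4 + x0)),
                           p$monomer_mass)
  n <- 400
  out <- verlet_step(lat, conf, p, n_steps = n, rescale = FALSE)
  # relative coordinate oscillates at omega = sqrt(k / mu), mu = m/2
  omega <- sqrt(p$k_long_stretch / (p$monomer_mass / 2))
  ext <- out$conf$pos[2, 3] - out$conf$pos[1, 3] - 4
  expect_equal(ext, x0 * cos(omega * n * p$dt), tolerance = 5e-3)
})

test_that("constant-target rescaling pins the average kinetic energy exactly", {
  set.seed(21)
  fx <- make_fixture("planar_3x4")
  p <- fx$params
  conf <- jitter_conf(fx$conf, sd = 0.05)
  out <- verlet_step(fx$lattice, conf, p, n_steps = 10, rescale = TRUE)
  target <- p$kinetic_energy_target * nrow(conf$pos)
  expect_equal(out$e_kin[10], target, tolerance = 1e-12)
})

test_that("an equilibrium start converges and keeps its energy", {
  fx <- make_fixture("planar_3x4")
  r <- relax(fx$lattice, fx$conf, fx$params, max_steps = 30000)
  expect_true(r$trace$converged)
  expect_equal(r$trace$e_final, r$trace$e_initial, tolerance = 1e-6)
  # no spurious barrier from an equilibrium start
  expect_equal(r$trace$peak_energy, r$trace$e_initial, tolerance = 1e-6)
})

test_that("a displaced monomer relaxes back to its lattice site", {
  fx <- make_fixture("planar_3x4")
  conf <- fx$conf
  conf$pos[6, ] <- conf$pos[6, ] + c(0.1, 0.05, -0.08)
  r <- relax(fx$lattice, conf, fx$params, max_steps = 50000)
  expect_true(r$trace$converged)
  expect_lte(r$trace$e_final, r$trace$e_initial)
  expect_lt(max(abs(r$conf$pos[6, ] - fx$conf$pos[6, ])), 1e-2)
})

test_that("without rescaling the integrator conserves total energy to O(dt^2)", {
  set.seed(22)
  fx <- make_fixture("planar_3x4")
  p <- mt_params(dt = 0.05)
  p$r0_diag_short <- fx$params$r0_diag_short
  p$r0_diag_long <- fx$params$r0_diag_long
  p$theta0_long_GTP <- 0
  conf <- jitter_conf(fx$conf, sd = 0.03)
  out <- verlet_step(fx$lattice, conf, p, n_steps = 1000, rescale = FALSE)
  etot <- out$e_pot + out$e_kin
  drift <- (max(etot) - min(etot)) / max(etot[1], 1e-12)
  expect_lt(drift, 1e-3)
})

test_that("relaxation is idempotent", {
  fx <- make_fixture("planar_3x4")
  set.seed(23)
  conf <- jitter_conf(fx$conf, sd = 0.05)
  r1 <- relax(fx$lattice, conf, fx$params, max_steps = 50000)
  r2 <- relax(fx$lattice, r1$conf, fx$params, max_steps = 50000)
  expect_true(r2$trace$converged)
  expect_lt(abs(r2$trace$e_final - r1$trace$e_final),
            10 * fx$params$convergence_tol)
})
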